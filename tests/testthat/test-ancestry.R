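sp_map <- function(tips) {
  setNames(ifelse(grepl("^a", tips), "A", "B"), tips)
}

test_that("label_nodes applies the speciation/duplication/pure rules", {
  t1 <- read_newick("(a1:1,b1:1);")
  l1 <- label_nodes(t1, sp_map(t1$tip.label))
  root_kind <- l1$labels$kind[!l1$labels$is_tip][1]
  expect_identical(root_kind, "speciation")

  t2 <- read_newick("((a1:1,b1:1):1,(a2:1,b2:1):1);")
  l2 <- label_nodes(t2, sp_map(t2$tip.label))
  kinds <- l2$labels$kind[!l2$labels$is_tip]
  expect_identical(kinds[1], "duplication")      # root
  expect_identical(sort(kinds[-1]), c("speciation", "speciation"))

  t3 <- read_newick("((a1:1,a2:1):1,(b1:1,b2:1):1);")
  l3 <- label_nodes(t3, sp_map(t3$tip.label))
  kinds3 <- l3$labels$kind[!l3$labels$is_tip]
  expect_identical(kinds3[1], "speciation")
  expect_identical(sort(kinds3[-1]), c("pure", "pure"))

  expect_error(label_nodes(t1, c(a1 = "A")), "unmapped")
})

test_that("count_ancestral_genes applies the support-threshold rule", {
  t1 <- read_newick("(a1:1,b1:1)99;")
  c1 <- count_ancestral_genes(label_nodes(t1, sp_map(t1$tip.label)))
  expect_equal(c1$n_total, 1)
  expect_equal(c1$n_high, 1)

  t2 <- read_newick("((a1:1,b1:1)40:1,(a2:1,b2:1)90:1);")
  c2 <- count_ancestral_genes(label_nodes(t2, sp_map(t2$tip.label)))
  expect_equal(c2$n_total, 2)
  expect_equal(c2$n_high, 1)

  # one supported speciation node plus one maximal A-only branch
  t3 <- read_newick("(a1:1,(a2:1,b1:1)95:1);")
  c3 <- count_ancestral_genes(label_nodes(t3, sp_map(t3$tip.label)))
  expect_equal(c3$n_total, 2)
  expect_equal(c3$n_high, 1)
  expect_equal(unname(c3$pure_branches["A"]), 1)

  expect_error(label_nodes(ape::unroot(read_newick(
    "((a1:1,b1:1):1,(a2:1,b2:1):1,(a3:1,b3:1):1);")), NULL), "rooted")
})

test_that("n_high is monotone non-increasing in the support threshold", {
  t <- read_newick(paste0("(((a1:1,b1:1)30:1,(a2:1,b2:1)60:1)50:1,",
                          "((a3:1,b3:1)80:1,(a4:1,b4:1)95:1)90:1);"))
  lab <- label_nodes(t, sp_map(t$tip.label))
  highs <- vapply(c(0, 25, 50, 75, 100), function(th)
    count_ancestral_genes(lab, th)$n_high, numeric(1))
  expect_true(all(diff(highs) <= 0))
  expect_equal(highs[[1]], 4)
  expect_equal(highs[[5]], 0)
})

test_that("gain_loss_by_clade reproduces the clade bookkeeping", {
  # nine ancestral lineages in one clade; species B gained three genes via
  # duplications, species A lost one lineage entirely
  stems <- vapply(1:8, function(i) {
    b <- if (i <= 3) sprintf("(b%d:0.1,b%dx:0.1)99:0.9", i, i)
         else sprintf("b%d:1", i)
    sprintf("(a%d:1,%s)99", i, b)
  }, character(1))
  nwk <- stems[1]
  for (k in 2:8) nwk <- sprintf("(%s:0.5,%s:0.5)99", nwk, stems[k])
  nwk <- sprintf("(%s:0.5,b9:1.5)99;", nwk)  # lineage 9 lost in species A
  tr <- read_newick(nwk)
  species <- sp_map(tr$tip.label)
  lab <- label_nodes(tr, species)
  cnt <- count_ancestral_genes(lab)
  expect_equal(cnt$n_total, 9)
  clades <- setNames(rep("A", length(tr$tip.label)), tr$tip.label)
  gl <- gain_loss_by_clade(cnt, species, clades)
  expect_equal(gl$n_anc, 9)
  expect_equal(gl$gain_B, 3)
  expect_equal(gl$loss_B, 0)
  expect_equal(gl$gain_A, 0)
  expect_equal(gl$loss_A, 1)
  expect_equal(gl$extant_B, 12)
  expect_equal(gl$extant_A, 8)
  # extant = n_anc - loss + gain, per species
  expect_equal(gl$extant_A, gl$n_anc - gl$loss_A + gl$gain_A)
  expect_equal(gl$extant_B, gl$n_anc - gl$loss_B + gl$gain_B)
})

test_that("single-lineage trivial case has no gains or losses", {
  tr <- read_newick("(a1:1,b1:1)99;")
  species <- sp_map(tr$tip.label)
  cnt <- count_ancestral_genes(label_nodes(tr, species))
  gl <- gain_loss_by_clade(cnt, species,
                           setNames(c("A", "A"), tr$tip.label))
  expect_equal(gl$gain_A + gl$gain_B + gl$loss_A + gl$loss_B, 0)
})

test_that("extant counts inconsistent with the tree are rejected", {
  tr <- read_newick("(a1:1,b1:1)99;")
  species <- sp_map(tr$tip.label)
  cnt <- count_ancestral_genes(label_nodes(tr, species))
  expect_error(
    gain_loss_by_clade(cnt, species, setNames(c("A", "A"), tr$tip.label),
                       extant = list(A = c(A = 5), B = c(A = 1))),
    "inconsistent")
})

test_that("true simulated trees give exact lineage recovery", {
  for (seed in c(11, 12, 13)) {
    h <- simulate_family_history(sim_config(n_ancestral = 15, seed = seed))
    lab <- label_nodes(read_newick(h$tree))
    cnt <- count_ancestral_genes(lab)
    rec <- recover_ancestral_count(h, cnt)
    expect_true(rec$lineage_count_exact)
    expect_equal(unname(rec$pure_branches_inferred["SpA"]),
                 unname(rec$pure_branches_true["A"]))
    expect_equal(unname(rec$pure_branches_inferred["SpB"]),
                 unname(rec$pure_branches_true["B"]))
  }
})
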