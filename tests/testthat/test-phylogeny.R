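test_that("poisson distances: closed form and pairwise deletion", {
  aln <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAA")
  expect_equal(poisson_distance_matrix(aln)$d["a", "b"], 0)

  aln <- c(a = "AAAAAAAAAA", b = "CCCCCAAAAA")  # 5 of 10 mismatch
  expect_equal(poisson_distance_matrix(aln)$d["a", "b"], -log(0.5),
               tolerance = 1e-9)

  dm <- poisson_distance_matrix(c(a = "AA-A", b = "AAAA"))
  expect_equal(dm$compared_sites["a", "b"], 3)
  expect_equal(dm$d["a", "b"], 0)

  sat <- poisson_distance_matrix(c(a = "AAAA", b = "CCCC"))
  expect_true(is.infinite(sat$d["a", "b"]))
  expect_error(nj_tree(sat), "infinite")
})

test_that("nj_tree closed forms for 2 and 3 taxa", {
  d <- matrix(c(0, 1.4, 1.4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- nj_tree(d)
  expect_equal(sum(t2$edge.length), 1.4)

  lab <- c("a", "b", "c")
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, dimnames = list(lab, lab))
  t3 <- nj_tree(d3)
  cd <- stats::cophenetic(t3)[lab, lab]
  expect_equal(cd, d3, tolerance = 1e-9)
  # v_a = (d_ab + d_ac - d_bc)/2 = 1
  depth <- t3$edge.length[t3$edge[, 2] == which(t3$tip.label == "a")]
  expect_equal(depth, 1)
})

test_that("nj recovers a known additive 6-taxon tree exactly", {
  true <- read_newick(
    "((a:0.3,b:0.6):0.25,((c:0.2,d:0.45):0.3,e:0.7):0.2,f:0.9);")
  d <- stats::cophenetic(true)
  nj <- nj_tree(d)
  expect_identical(phylo_splits(nj), phylo_splits(true))
  expect_equal(stats::cophenetic(nj)[rownames(d), colnames(d)], d,
               tolerance = 1e-8)
})

aln_from_columns <- function(cols) {
  tips <- names(cols[[1]])
  vapply(tips, function(tp)
    paste(vapply(cols, `[[`, character(1), tp), collapse = ""), character(1))
}

test_that("bootstrap supports behave on clean and conflicting signal", {
  colAB <- c(A = "A", B = "A", C = "T", D = "T")   # supports AB|CD
  colAC <- c(A = "A", B = "T", C = "A", D = "T")   # supports AC|BD
  colA  <- c(A = "G", B = "A", C = "A", D = "A")   # singleton, uninformative
  colD  <- c(A = "A", B = "A", C = "A", D = "G")
  const <- c(A = "C", B = "C", C = "C", D = "C")

  # every informative column supports AB|CD
  aln <- aln_from_columns(c(rep(list(colAB), 10), rep(list(colA), 5),
                            rep(list(colD), 5), rep(list(const), 20)))
  bt <- bootstrap_supports(aln, n_reps = 100, seed = 1)
  sup <- suppressWarnings(as.numeric(bt$node.label))
  expect_true(100 %in% sup)

  bt2 <- bootstrap_supports(aln, n_reps = 100, seed = 1)
  expect_identical(bt$node.label, bt2$node.label)

  # 50/50 conflicting informative columns: either resolution near 50
  aln2 <- aln_from_columns(c(rep(list(colAB), 60), rep(list(colAC), 60),
                             rep(list(const), 40)))
  bt3 <- bootstrap_supports(aln2, n_reps = 1000, seed = 7)
  sup3 <- suppressWarnings(as.numeric(bt3$node.label))
  sup3 <- sup3[!is.na(sup3)]
  expect_true(all(abs(sup3 - 50) <= 5))
})

test_that("midpoint rooting places the root at the longest-path midpoint", {
  t2 <- midpoint_root(read_newick("(A:1,B:1);"))
  dd <- ape::dist.nodes(t2)
  root <- length(t2$tip.label) + 1
  expect_equal(dd[root, 1], dd[root, 2])

  tr <- read_newick("((A:1,B:2):1,C:3.5);")  # longest path B..C = 6.5
  mr <- midpoint_root(tr)
  dn <- ape::dist.nodes(mr)
  root <- length(mr$tip.label) + 1
  tipd <- dn[root, seq_along(mr$tip.label)]
  expect_equal(max(tipd), 6.5 / 2, tolerance = 1e-9)

  # re-rooting preserves the tip-to-tip metric
  big <- read_newick("(((A:0.4,B:0.9):0.2,C:1.1):0.3,(D:0.5,E:0.8):0.6);")
  m <- midpoint_root(big)
  expect_equal(sort(as.vector(stats::cophenetic(m))),
               sort(as.vector(stats::cophenetic(big))), tolerance = 1e-9)
})

test_that("assign_clades follows the smallest well-supported clan rule", {
  tr <- read_newick("(((x1:1,c1:1)90:1,(y1:1,d1:1)85:1)60:1,(z1:1,z2:1)99:2);")
  anchors <- c(c1 = "C", d1 = "D")
  cl <- assign_clades(tr, anchors)
  got <- setNames(cl$clade, cl$gene_id)
  expect_identical(unname(got["x1"]), "C")  # sister to a clade-C anchor
  expect_identical(unname(got["y1"]), "D")
  # z-tips only reach a clan containing both C and D anchors: conflict
  expect_true(all(is.na(got[c("z1", "z2")])))

  # all tips anchored: identity
  all_anchor <- setNames(c("C", "C", "D", "D", "E", "E"),
                         c("x1", "c1", "y1", "d1", "z1", "z2"))
  cl2 <- assign_clades(tr, all_anchor)
  expect_identical(setNames(cl2$clade, cl2$gene_id)[names(all_anchor)],
                   all_anchor)

  expect_error(assign_clades(tr, c(nope = "A")), "absent")
})

test_that("low-support clans are skipped when inheriting clades", {
  tr <- read_newick("((x1:1,c1:1)20:1,(d1:1,d2:1)95:2);")
  cl <- assign_clades(tr, c(c1 = "C", d1 = "D", d2 = "D"),
                      support_threshold = 50)
  got <- setNames(cl$clade, cl$gene_id)
  # x1's cherry is untrusted (20); the next clan up is the root, which holds
  # anchors of two clades -> conflict, unassigned
  expect_true(is.na(got["x1"]))
})
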