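test_that("ng86_kaks: identical pair and hand-computed single-change pair", {
  cds <- paste(rep("ATGGCT", 20), collapse = "")
  r0 <- ng86_kaks(cds, cds)
  expect_equal(r0$Ka, 0)
  expect_equal(r0$Ks, 0)
  expect_true(is.na(r0$ratio))

  # ten TTT codons vs nine TTT + one TTC: S = 10/3, p_S = 0.3
  a <- paste(rep("TTT", 10), collapse = "")
  b <- paste(c(rep("TTT", 9), "TTC"), collapse = "")
  r <- ng86_kaks(a, b)
  expect_equal(r$S, 10 / 3, tolerance = 1e-9)
  expect_equal(r$Sd, 1)
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, -0.75 * log(1 - 4 * 0.3 / 3), tolerance = 1e-9)
  expect_equal(r$Ks, 0.3831192, tolerance = 1e-6)
})

test_that("ng86_kaks: pathway averaging and stop-blocked pathways", {
  ctx <- paste(rep("GGC", 9), collapse = "")
  # ATG vs ACA differ at positions 2,3; the two orderings give (1N,1S) and
  # (2N,0S), averaging to Nd = 1.5, Sd = 0.5 (hand enumeration)
  r <- ng86_kaks(paste0("ATG", ctx), paste0("ACA", ctx))
  expect_equal(r$Nd, 1.5)
  expect_equal(r$Sd, 0.5)
  # sites: ATG contributes 0 syn, ACA 1 syn, GGC 1 syn each
  expect_equal(r$S, (0 + 9 + 1 + 9) / 2, tolerance = 1e-9)

  # TGG vs TAT: the path through TAG (stop) is excluded, leaving 2N, 0S
  r2 <- ng86_kaks(paste0("TGG", ctx), paste0("TAT", ctx))
  expect_equal(r2$Nd, 2)
  expect_equal(r2$Sd, 0)
})

test_that("ng86_kaks is symmetric and Ka = 0 for synonymous-only change", {
  pad <- paste(rep("GAA", 8), collapse = "")
  a <- paste0("ATGGCTAAAGGGTTTCCC", pad)
  b <- paste0("ATGGCCAAAGGATTTCCA", pad)  # only synonymous changes
  r1 <- ng86_kaks(a, b); r2 <- ng86_kaks(b, a)
  expect_equal(r1$Ka, r2$Ka)
  expect_equal(r1$Ks, r2$Ks)
  expect_equal(r1$Ka, 0)
  expect_gt(r1$Ks, 0)

  expect_error(ng86_kaks("ATGG", "ATGG"), "divisible")
  expect_error(ng86_kaks("ATGTAAGGG", "ATGTAAGGG"), "stop")
  expect_error(ng86_kaks("ATG", "ATGATG"), "equal length")
})

test_that("saturation flags an undefined rate", {
  a <- paste(rep("TTT", 4), collapse = "")
  b <- paste(rep("TTC", 4), collapse = "")  # every synonymous site changed
  r <- ng86_kaks(a, b)
  expect_true(r$saturated)
  expect_true(is.na(r$Ks))
})

test_that("global alignment matches identity/coverage expectations", {
  p <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  al <- global_align_identity(p, p)
  expect_equal(al$identity_pct, 100)
  expect_equal(al$coverage_pct, 100)

  half <- substr(p, 1, nchar(p) %/% 2)
  al2 <- global_align_identity(p, half)
  expect_equal(al2$coverage_pct, 100 * nchar(half) / nchar(p),
               tolerance = 2)
  expect_error(global_align_identity("", p), "non-empty")
})

test_that("alignment score equals an affine-gap DP oracle", {
  utils::data("BLOSUM62", package = "Biostrings", envir = environment())
  set.seed(11)
  aas <- c("A","R","N","D","C","Q","E","G","H","I","L","K")
  for (i in 1:6) {
    a <- paste(sample(aas, sample(6:12, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(6:12, 1), replace = TRUE), collapse = "")
    got <- global_align_identity(a, b)$score
    expect_equal(got, gotoh_score(a, b, BLOSUM62), tolerance = 1e-9,
                 label = paste(a, b))
  }
})

test_that("codon_align back-threads the protein alignment", {
  ca <- codon_align("ATGAAAACC", "ATGACC")  # MKT vs MT drops the K codon
  expect_identical(ca$cds_a, "ATGACC")
  expect_identical(ca$cds_b, "ATGACC")
  r <- ng86_kaks(ca$cds_a, ca$cds_b)
  expect_equal(r$Ka + r$Ks, 0)
})

mutate_n <- function(seq, n, seed = 1) {
  set.seed(seed)
  ch <- strsplit(seq, "")[[1]]
  idx <- sample(length(ch), n)
  for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

test_that("detect_tandem_pairs applies the 80/80 + linkage rule", {
  set.seed(5)
  base <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                collapse = "")
  seqs <- c(g1 = base,
            g2 = mutate_n(base, 10),   # ~97% identity
            g3 = mutate_n(base, 75),   # ~75% identity
            g4 = mutate_n(base, 8, seed = 2))
  mk <- function(id, chrom, start) list(
    gene_id = id, chromosome = chrom, strand = "+",
    exons = cbind(start = start, end = start + 299))
  models <- structure(list(
    g1 = mk("g1", "C01", 1000), g2 = mk("g2", "C01", 5000),
    g3 = mk("g3", "C01", 9000), g4 = mk("g4", "C02", 1000)),
    class = "pg_gene_models")
  td <- detect_tandem_pairs(models, seqs)
  expect_equal(nrow(td), 1)
  expect_identical(c(td$gene_a, td$gene_b), c("g1", "g2"))
  # g1-g3: linked but identity ~75 -> excluded; g1-g4: identity high but a
  # different chromosome -> excluded
  expect_false("g4" %in% c(td$gene_a, td$gene_b))
})

test_that("terminal_paralog_pairs keeps only high-identity cherries", {
  tr <- read_newick("((g1:1,g2:1):1,((g3:1,g4:1):1,g5:2):1);")
  ids <- paste0("g", 1:5)
  idm <- matrix(50, 5, 5, dimnames = list(ids, ids))
  idm["g1", "g2"] <- idm["g2", "g1"] <- 92
  idm["g3", "g4"] <- idm["g4", "g3"] <- 70
  idm["g1", "g5"] <- idm["g5", "g1"] <- 95  # high identity but not sisters
  tp <- terminal_paralog_pairs(tr, idm)
  expect_equal(nrow(tp), 1)
  expect_identical(pair_key(tp$gene_a, tp$gene_b), pair_key("g1", "g2"))
})
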