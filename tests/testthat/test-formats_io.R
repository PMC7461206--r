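test_that("read_fasta parses, uppercases and validates", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1 some description", "acgtaa", ">g2", "GGTACC"), f)
  s <- read_fasta(f, kind = "cds")
  expect_identical(names(s), c("g1", "g2"))
  expect_identical(unname(s[1]), "ACGTAA")

  writeLines(c(">g1", "ACG", ">g1", "TTT"), f)
  expect_error(read_fasta(f, kind = "cds"), "duplicate")
  writeLines(c(">g1", "", ">g2", "ACG"), f)
  expect_error(read_fasta(f, kind = "cds"), "empty")
  writeLines(c("just some text", "not fasta"), f)
  expect_error(read_fasta(f), "FASTA")
  writeLines(c(">g1", "ACGT"), f)
  expect_error(read_fasta(f, kind = "cds"), "divisible")
})

test_that("fasta round trip preserves records", {
  set.seed(42)
  seqs <- setNames(
    vapply(1:5, function(i)
      paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE), collapse = ""),
      character(1)),
    paste0("gene", 1:5))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, f, width = 17)
  back <- read_fasta(f, kind = "cds")
  expect_identical(unname(back[names(seqs)]), unname(seqs))
})

test_that("read_gene_models orders exons in transcription order", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t1\t298\t.\t+\t.\tID=gplus",
    "chr1\tx\tCDS\t1\t99\t.\t+\t.\tParent=gplus",
    "chr1\tx\tCDS\t200\t298\t.\t+\t.\tParent=gplus",
    "chr1\tx\tgene\t1\t298\t.\t-\t.\tID=gminus",
    "chr1\tx\tCDS\t1\t99\t.\t-\t.\tParent=gminus",
    "chr1\tx\tCDS\t200\t298\t.\t-\t.\tParent=gminus"), f)
  m <- read_gene_models(f)
  expect_equal(unname(m$gplus$exons[, "start"]), c(1, 200))
  # minus strand: highest-coordinate exon transcribed first
  expect_equal(unname(m$gminus$exons[, "start"]), c(200, 1))
  expect_equal(unname(m$gminus$exons[1, ]), c(200, 298), ignore_attr = TRUE)
})

test_that("read_gene_models rejects malformed structures", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t1\t99\t.\t+\t.\tID=g1",
    "chr1\tx\tCDS\t1\t99\t.\t+\t.\tParent=ghost"), f)
  expect_error(read_gene_models(f), "parent")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t1\t200\t.\t+\t.\tID=g1",
    "chr1\tx\tCDS\t1\t99\t.\t+\t.\tParent=g1",
    "chr1\tx\tCDS\t50\t200\t.\t+\t.\tParent=g1"), f)
  expect_error(read_gene_models(f), "overlap")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t1\t200\t.\t+\t.\tID=g1"), f)
  expect_error(read_gene_models(f), "without CDS")
})

test_that("gene model GFF3 round trip is the identity", {
  h <- simulate_family_history(sim_config(n_ancestral = 6, seed = 5))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(h$models, f)
  back <- read_gene_models(f)
  expect_setequal(names(back), names(h$models))
  for (g in names(h$models)) {
    expect_identical(back[[g]]$exons, h$models[[g]]$exons)
    expect_identical(back[[g]]$strand, h$models[[g]]$strand)
    expect_identical(back[[g]]$chromosome, h$models[[g]]$chromosome)
  }
})

test_that("read_newick parses supports and rejects malformed input", {
  t1 <- read_newick("(A:1,B:1);")
  expect_equal(length(t1$tip.label), 2)
  expect_equal(sort(t1$edge.length), c(1, 1))

  t2 <- read_newick("((A:1,B:1)73:0.5,C:2);")
  expect_true(73 %in% tree_supports(t2))

  expect_error(read_newick("((A:1,B:1;"), "invalid")
  expect_error(read_newick("(A:-1,B:1);"), "negative")
  expect_error(read_newick("(A:1,A:2);"), "duplicate")
})

test_that("newick round trip preserves topology, lengths and supports", {
  set.seed(9)
  for (i in 1:5) {
    tr <- ape::rtree(7)
    tr$node.label <- as.character(sample(0:100, tr$Nnode))
    tr$node.label[1] <- ""  # roots commonly lack a support
    back <- read_newick(write_newick(tr))
    expect_identical(phylo_splits(back), phylo_splits(tr))
    expect_equal(sort(back$edge.length), sort(tr$edge.length),
                 tolerance = 1e-6)
    expect_setequal(back$node.label, tr$node.label)
  }
})
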