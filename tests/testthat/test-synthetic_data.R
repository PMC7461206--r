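no_event_cfg <- function(n, seed = 1, ...) {
  sim_config(n_ancestral = n,
             loss_prob_by_subgenome = c(LF = 0, MF1 = 0, MF2 = 0),
             tandem_rate = 0, post_split_dup_rate_A = 0,
             post_split_dup_rate_B = 0, loss_prob_A = 0, seed = seed, ...)
}

test_that("no-loss limit: species B carries exactly 3n genes", {
  h <- simulate_family_history(no_event_cfg(10))
  expect_equal(sum(h$genes$species == "SpB"), 30)
  expect_equal(sum(h$genes$species == "SpA"), 10)
  expect_equal(nrow(h$losses), 0)
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_ancestral = 12, seed = 99)
  h1 <- simulate_family_history(cfg)
  h2 <- simulate_family_history(cfg)
  expect_identical(h1, h2)
  expect_identical(emit_sequences(h1), emit_sequences(h2))
  expect_identical(emit_expression(h1), emit_expression(h2))
  expect_identical(emit_promoters(h1), emit_promoters(h2))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(loss_prob_by_subgenome = c(LF = 0.9, MF1 = 0.5,
                                                     MF2 = 0.2)), "LF <= MF1")
  expect_error(sim_config(tandem_rate = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(category_mix = c(I = 1, II = 1, III = 0, IV = 0)),
               "sum")
  expect_error(sim_config(omega = -0.1), "omega")
  expect_error(simulate_family_history(sim_config(n_ancestral = 0)), ">= 1")
})

test_that("every extant gene traces to one lineage and counts reconcile", {
  h <- simulate_family_history(sim_config(n_ancestral = 30, seed = 6))
  expect_true(all(h$genes$lineage %in% names(h$lineage_clade)))
  # per-lineage reconciliation for species B:
  # extant = 3 - subgenome losses + tandem gains + duplicate gains
  for (li in unique(h$genes$lineage)) {
    extant_b <- sum(h$genes$lineage == li & h$genes$species == "SpB")
    lost <- sum(h$losses$lineage == li & h$losses$subgenome != "A")
    gained <- sum(h$tandem_pairs$lineage == li) +
      sum(h$dup_pairs$lineage == li & h$dup_pairs$species == "SpB")
    expect_equal(extant_b, 3 - lost + gained)
  }
})

test_that("retained-per-subgenome counts follow the binomial expectation", {
  # 200 seeded replicates; mean retained count per subgenome must fall
  # within 3 standard errors of n * (1 - p)
  lp <- c(LF = 0.5, MF1 = 0.66, MF2 = 0.71)
  n <- 68
  counts <- matrix(0, 200, 3, dimnames = list(NULL, names(lp)))
  for (r in 1:200) {
    h <- simulate_family_history(sim_config(
      n_ancestral = n, loss_prob_by_subgenome = lp, tandem_rate = 0,
      post_split_dup_rate_A = 0, post_split_dup_rate_B = 0, loss_prob_A = 0,
      seed = 1000 + r))
    for (sg in names(lp)) {
      counts[r, sg] <- sum(h$genes$subgenome == sg, na.rm = TRUE)
    }
  }
  for (sg in names(lp)) {
    expected <- n * (1 - lp[[sg]])
    se <- sqrt(n * lp[[sg]] * (1 - lp[[sg]])) / sqrt(200)
    expect_lt(abs(mean(counts[, sg]) - expected), 3 * se)
  }
})

test_that("zero divergence leaves all descendants identical", {
  h <- simulate_family_history(sim_config(n_ancestral = 6, seed = 3,
                                          subs_per_site = 0))
  sq <- emit_sequences(h)
  for (li in unique(h$genes$lineage)) {
    ids <- h$genes$gene_id[h$genes$lineage == li]
    expect_equal(length(unique(sq$cds[ids])), 1)
  }
})

test_that("omega = 0 yields Ka = 0 on every simulated pair", {
  h <- simulate_family_history(sim_config(n_ancestral = 10, seed = 8,
                                          omega = 0, tandem_rate = 0.5,
                                          post_split_dup_rate_B = 0.5))
  sq <- emit_sequences(h)
  pairs <- rbind(h$tandem_pairs[, c("gene_a", "gene_b")],
                 h$dup_pairs[, c("gene_a", "gene_b")])
  expect_gt(nrow(pairs), 0)
  for (i in seq_len(nrow(pairs))) {
    r <- ng86_kaks(sq$cds[[pairs$gene_a[i]]], sq$cds[[pairs$gene_b[i]]])
    expect_equal(r$Ka, 0)
  }
})

test_that("planted domain motifs close the loop with the scanner", {
  h <- simulate_family_history(sim_config(n_ancestral = 6, seed = 4))
  sq <- emit_sequences(h)
  for (p in sq$protein) {
    comp <- classify_pg(scan_domains(p, tolerance = 0))
    expect_identical(comp$composition, c("I", "II", "III", "IV"))
  }
  # configurable subsets
  sq2 <- emit_sequences(h, motif_domains = c("II"))
  comp2 <- classify_pg(scan_domains(sq2$protein[[1]]))
  expect_true("II" %in% comp2$composition)
})

test_that("expression planting closes the loop with categorize_pair", {
  cfg <- sim_config(n_ancestral = 20, seed = 10, tandem_rate = 0.4,
                    post_split_dup_rate_B = 0.4,
                    category_mix = c(I = 1, II = 0, III = 0, IV = 0))
  h <- simulate_family_history(cfg)
  ex <- emit_expression(h)
  expect_gt(nrow(ex$pairs), 0)
  m <- relative_expression(ex$ct, ex$reference_gene, ex$calibrator)
  pc <- categorize_pairs(m, ex$pairs[, c("gene_a", "gene_b")])
  expect_true(all(pc$category == "I"))

  cfg4 <- sim_config(n_ancestral = 20, seed = 10, tandem_rate = 0.4,
                     post_split_dup_rate_B = 0.4,
                     category_mix = c(I = 0, II = 0, III = 0, IV = 1))
  h4 <- simulate_family_history(cfg4)
  ex4 <- emit_expression(h4)
  # a pair planted IV has exactly one all-ND member
  for (i in seq_len(nrow(ex4$pairs))) {
    nd_a <- all(ex4$values[ex4$pairs$gene_a[i], ] == 0)
    nd_b <- all(ex4$values[ex4$pairs$gene_b[i], ] == 0)
    expect_equal(nd_a + nd_b, 1)
  }
  expect_error(emit_expression(
    simulate_family_history(sim_config(n_ancestral = 3, seed = 1,
                                       tissues = "root"))), "two tissues")
})

test_that("promoter planting is recovered by the scanner", {
  cfg <- sim_config(n_ancestral = 4, seed = 12, promoter_len = 500L)
  h <- simulate_family_history(cfg)
  pr <- emit_promoters(h)
  hits <- scan_promoters(pr$promoters)
  for (i in seq_len(nrow(pr$truth))) {
    tr <- pr$truth[i, ]
    expect_true(any(hits$gene_id == tr$gene_id & hits$name == tr$name &
                      hits$position == tr$position & hits$strand == tr$strand),
                label = paste("planted hit found:", tr$name, tr$position))
  }
  expect_true(any(pr$truth$strand == "-"))
})

test_that("motif-free background by rejection gives zero hits", {
  cgtca <- read_motif_dictionary()
  cgtca <- cgtca[cgtca$name == "CGTCA-motif", ]
  cfg <- sim_config(n_ancestral = 2, seed = 13, promoter_len = 300L)
  h <- simulate_family_history(cfg)
  pr <- emit_promoters(h, motifs = cgtca, n_plant_range = c(0L, 0L),
                       ensure_absent = "CGTCA-motif")
  hits <- scan_promoters(pr$promoters, cgtca)
  expect_equal(nrow(hits), 0)
  expect_equal(nrow(pr$truth), 0)
})

test_that("a motif longer than the promoter is rejected", {
  long <- data.frame(name = "huge", category = "x",
                     consensus = paste(rep("A", 50), collapse = ""))
  cfg <- sim_config(n_ancestral = 2, seed = 1, promoter_len = 40L)
  h <- simulate_family_history(cfg)
  expect_error(emit_promoters(h, motifs = long), "longer than promoter")
})
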