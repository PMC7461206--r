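#' Pipeline configuration
#'
#' Bundles the simulator configuration with the analysis thresholds used
#' across stages. All randomness is funnelled through `sim$seed`.
#'
#' @param sim a [sim_config()].
#' @param support_threshold bootstrap support threshold for ancestral-gene
#'   counting (default 50).
#' @param identity_threshold,coverage_threshold tandem/paralog 80/80 rule.
#' @param tau,fold expression thresholds (see [categorize_pair()]).
#' @param bootstrap_reps bootstrap replicates for the inferred tree; 0 skips
#'   bootstrapping and uses the simulator's true tree (with its supports).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), support_threshold = 50,
                            identity_threshold = 80, coverage_threshold = 80,
                            tau = 0.05, fold = 2, bootstrap_reps = 100L) {
  stopifnot(inherits(sim, "sim_config"))
  structure(list(sim = sim, support_threshold = support_threshold,
                 identity_threshold = identity_threshold,
                 coverage_threshold = coverage_threshold,
                 tau = tau, fold = fold,
                 bootstrap_reps = as.integer(bootstrap_reps)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' The JSON mirrors [pipeline_config()]: an optional `sim` object with
#' [sim_config()] fields plus the threshold fields.
#'
#' @param path path to a JSON file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_args <- j$sim %||% list()
  if (!is.null(sim_args$loss_prob_by_subgenome))
    sim_args$loss_prob_by_subgenome <- unlist(sim_args$loss_prob_by_subgenome)
  if (!is.null(sim_args$category_mix))
    sim_args$category_mix <- unlist(sim_args$category_mix)
  sim <- do.call(sim_config, sim_args)
  args <- j[setdiff(names(j), "sim")]
  do.call(pipeline_config, c(list(sim = sim), args))
}

# identity matrix for equal-length ungapped sequences (simulator output)
ungapped_identity_matrix <- function(seqs) {
  n <- length(seqs)
  m <- do.call(rbind, strsplit(seqs, ""))
  out <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      idp <- 100 * mean(m[i, ] == m[j, ])
      out[i, j] <- out[j, i] <- idp
    }
  }
  out
}

#' Run the full family analysis pipeline on simulated data
#'
#' Executes simulate -> identify -> structure -> phylogeny -> ancestry ->
#' tandem/Ka-Ks -> subgenome -> expression -> cis-elements, writes one TSV per
#' stage plus a plain-text report into `outdir`, and returns all stage
#' results. Every output carries a provenance header with the seed and
#' thresholds. Identical config and seed give byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if missing); `NULL` skips writing.
#' @return (invisibly) a named list with every stage result.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  res <- list(config = config)
  res$history <- stage("simulate", simulate_family_history(config$sim))
  res$sequences <- stage("simulate", emit_sequences(res$history))
  res$identify <- stage("identify", identify_family(res$sequences$protein))
  res$structure <- stage("structure", gene_structure_table(res$history$models))
  res$chromosomes <- stage("structure", chromosome_summary(res$history$models))

  aln <- res$sequences$protein  # equal-length, ungapped by construction
  res$tree <- stage("phylo", {
    if (config$bootstrap_reps > 0L)
      bootstrap_supports(aln, n_reps = config$bootstrap_reps,
                         seed = config$sim$seed + 10L)
    else read_newick(res$history$tree)
  })
  res$rooted <- stage("phylo", midpoint_root(res$tree))

  res$labelled <- stage("ancestry", label_nodes(res$rooted))
  res$ancestral <- stage("ancestry",
    count_ancestral_genes(res$labelled, config$support_threshold))
  clade_map <- setNames(res$history$genes$clade, res$history$genes$gene_id)
  res$gain_loss <- stage("ancestry",
    gain_loss_by_clade(res$ancestral, res$labelled$species, clade_map))

  res$tandem <- stage("kaks", detect_tandem_pairs(
    res$history$models, res$sequences$cds,
    min_identity = config$identity_threshold,
    min_coverage = config$coverage_threshold))
  b_tips <- res$history$genes$gene_id[res$history$genes$species == "SpB"]
  res$identity <- stage("kaks",
    ungapped_identity_matrix(res$sequences$protein[b_tips]))
  b_tree <- stage("kaks", ape::keep.tip(res$tree, b_tips))
  res$terminal_pairs <- stage("kaks", terminal_paralog_pairs(
    b_tree, res$identity, config$identity_threshold))
  res$kaks <- stage("kaks", {
    tp <- res$terminal_pairs
    kk <- lapply(seq_len(nrow(tp)), function(i)
      ng86_kaks(res$sequences$cds[[tp$gene_a[i]]],
                res$sequences$cds[[tp$gene_b[i]]]))
    tp$Ka <- vapply(kk, `[[`, numeric(1), "Ka")
    tp$Ks <- vapply(kk, `[[`, numeric(1), "Ks")
    tp$ratio <- vapply(kk, `[[`, numeric(1), "ratio")
    tp
  })

  sg_map <- with(res$history$genes,
                 setNames(ifelse(species == "SpB" & origin == "wgt",
                                 subgenome, NA_character_), gene_id))
  ref_n <- sum(res$history$genes$species == "SpA")
  res$retention <- stage("subgenome", retention_proportions(sg_map, ref_n))
  a_genes <- res$history$genes[res$history$genes$species == "SpA", ]
  b_wgt <- res$history$genes[res$history$genes$species == "SpB" &
                               res$history$genes$origin == "wgt", ]
  res$synteny <- stage("subgenome", synteny_percentages(
    sum(a_genes$lineage %in% b_wgt$lineage), nrow(a_genes),
    nrow(b_wgt), sum(res$history$genes$species == "SpB")))

  res$expression_raw <- stage("expression", emit_expression(
    res$history, tau = config$tau, fold = config$fold))
  res$expression <- stage("expression", relative_expression(
    res$expression_raw$ct, res$expression_raw$reference_gene,
    res$expression_raw$calibrator))
  res$patterns <- stage("expression",
    classify_tissue_pattern(res$expression, tau = config$tau))
  res$pair_categories <- stage("expression", categorize_pairs(
    res$expression, res$expression_raw$pairs[, c("gene_a", "gene_b")],
    tau = config$tau, fold = config$fold))
  res$divergence <- stage("expression",
    divergence_summary(res$pair_categories$category))

  res$promoters <- stage("cis", emit_promoters(res$history))
  res$cis_hits <- stage("cis", scan_promoters(res$promoters$promoters))
  res$cis_summary <- stage("cis", summarize_elements(res$cis_hits))

  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  invisible(res)
}

provenance_header <- function(config) {
  sprintf("# pgfam seed=%d support=%s identity=%s coverage=%s tau=%s fold=%s",
          config$sim$seed, config$support_threshold,
          config$identity_threshold, config$coverage_threshold,
          config$tau, config$fold)
}

write_stage_tsv <- function(x, path, header) {
  con <- file(path, "w")
  writeLines(header, con)
  close(con)
  suppressWarnings(utils::write.table(x, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hd <- provenance_header(res$config)
  p <- function(f) file.path(outdir, f)
  write_stage_tsv(res$identify, p("identify.tsv"), hd)
  write_stage_tsv(res$structure, p("structure.tsv"), hd)
  write_stage_tsv(res$gain_loss, p("gain_loss.tsv"), hd)
  write_stage_tsv(res$tandem, p("tandem_pairs.tsv"), hd)
  kk <- res$kaks
  kk$ratio <- ifelse(is.na(kk$ratio), "——", format(kk$ratio))
  write_stage_tsv(kk, p("kaks.tsv"), hd)
  write_stage_tsv(res$retention, p("retention.tsv"), hd)
  write_stage_tsv(res$pair_categories, p("pair_categories.tsv"), hd)
  write_stage_tsv(data.frame(gene_id = names(res$patterns),
                             pattern = unname(res$patterns)),
                  p("patterns.tsv"), hd)
  write_stage_tsv(res$cis_hits, p("cis_hits.tsv"), hd)
  writeLines(c(hd, write_newick(res$tree)), p("tree.nwk"))
  writeLines(c(
    hd,
    sprintf("family_size_B\t%d", sum(res$history$genes$species == "SpB")),
    sprintf("family_size_A\t%d", sum(res$history$genes$species == "SpA")),
    sprintf("chromosomal\t%d", res$chromosomes$n_chromosomal),
    sprintf("scaffold\t%d", res$chromosomes$n_scaffold),
    sprintf("n_ancestral_high\t%d", res$ancestral$n_high),
    sprintf("n_ancestral_total\t%d", res$ancestral$n_total),
    sprintf("pure_branches\t%s",
            paste(names(res$ancestral$pure_branches),
                  res$ancestral$pure_branches, sep = "=", collapse = ",")),
    sprintf("tandem_pairs\t%d", nrow(res$tandem)),
    sprintf("retention_pct\t%s",
            paste(res$retention$subgenome, res$retention$retention_pct,
                  sep = "=", collapse = ",")),
    sprintf("synteny_pct\t%s",
            paste(names(res$synteny), res$synteny, sep = "=", collapse = ",")),
    sprintf("percent_divergent\t%s", res$divergence$percent_divergent),
    sprintf("category_counts\t%s",
            paste(names(res$divergence$counts), res$divergence$counts,
                  sep = "=", collapse = ","))),
    p("report.txt"))
  invisible(outdir)
}
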