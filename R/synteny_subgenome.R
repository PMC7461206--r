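#' Subgenome retention proportions after a whole-genome triplication
#'
#' For each subgenome s the default retention percentage is
#' `100 * count(s) / (3 * reference_gene_count)` - the share of the three
#' expected post-triplication copies per reference-family gene that survives
#' in s - rounded half-up to one decimal. The per-copy alternative
#' `100 * count(s) / reference_gene_count` is reported alongside.
#'
#' @param subgenome_map named character vector mapping gene IDs to `LF`,
#'   `MF1` or `MF2` (unmapped genes omitted or NA).
#' @param reference_gene_count size of the diploid reference family (> 0).
#' @return data.frame with one row per subgenome: `subgenome`, `count`,
#'   `retention_pct` (triplicated denominator), `per_copy_pct`; attribute
#'   `total_mapped`.
#' @export
retention_proportions <- function(subgenome_map, reference_gene_count) {
  if (reference_gene_count <= 0) stop("reference_gene_count must be > 0")
  sg <- subgenome_map[!is.na(subgenome_map)]
  bad <- setdiff(unique(sg), c("LF", "MF1", "MF2"))
  if (length(bad)) stop("unknown subgenome label(s): ", paste(bad, collapse = ", "))
  counts <- vapply(c("LF", "MF1", "MF2"), function(s) sum(sg == s), integer(1))
  out <- data.frame(
    subgenome = c("LF", "MF1", "MF2"),
    count = as.integer(counts),
    retention_pct = round_half_up(100 * counts / (3 * reference_gene_count), 1),
    per_copy_pct = round_half_up(100 * counts / reference_gene_count, 1),
    stringsAsFactors = FALSE)
  attr(out, "total_mapped") <- sum(counts)
  out
}

#' Reciprocal synteny percentages between the two family sets
#'
#' @param reference_hits reference-family genes with a syntenic counterpart.
#' @param reference_total reference family size.
#' @param query_mapped query-family genes mapping to the subgenomes.
#' @param query_total query family size.
#' @return named numeric vector `c(reference_pct, query_pct)`, half-up rounded
#'   to one decimal.
#' @export
synteny_percentages <- function(reference_hits, reference_total,
                                query_mapped, query_total) {
  if (reference_total <= 0 || query_total <= 0) stop("totals must be > 0")
  if (reference_hits > reference_total || query_mapped > query_total)
    stop("hits cannot exceed totals")
  c(reference_pct = round_half_up(100 * reference_hits / reference_total, 1),
    query_pct = round_half_up(100 * query_mapped / query_total, 1))
}
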