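#' Relative expression from a qPCR Ct table (2^-ddCt)
#'
#' `dCt = Ct_target - Ct_reference` per sample; `ddCt = dCt_sample -
#' dCt_calibrator`; relative expression is `2^-ddCt`. A Ct of `"ND"` (no
#' amplification) yields 0. When a gene is not detected in the calibrator
#' sample its calibrator `dCt` is taken as 0, i.e. values for that gene are
#' `2^-dCt` (documented convention; such genes have no within-gene calibrator
#' anyway).
#'
#' @param ct long-format data.frame with columns `gene`, `sample`, `ct`
#'   (numeric or the string `"ND"`).
#' @param reference_gene internal-control gene; must have a numeric Ct in
#'   every sample.
#' @param calibrator_sample sample name used as calibrator.
#' @return numeric matrix genes x samples of relative expression (reference
#'   gene excluded), samples in first-appearance order.
#' @export
relative_expression <- function(ct, reference_gene, calibrator_sample) {
  need <- c("gene", "sample", "ct")
  if (!all(need %in% names(ct))) stop("ct table needs columns gene/sample/ct")
  samples <- unique(ct$sample)
  if (!calibrator_sample %in% samples) stop("calibrator sample absent")
  genes <- setdiff(unique(ct$gene), reference_gene)
  ctv <- suppressWarnings(as.numeric(ct$ct))
  nd <- toupper(trimws(as.character(ct$ct))) == "ND"
  ref <- ct$gene == reference_gene
  ref_ct <- setNames(rep(NA_real_, length(samples)), samples)
  for (s in samples) {
    v <- ctv[ref & ct$sample == s]
    if (length(v) == 0L || any(is.na(v))) stop("missing reference Ct in sample ", s)
    ref_ct[s] <- mean(v)
  }
  mat <- matrix(0, length(genes), length(samples),
                dimnames = list(genes, samples))
  for (g in genes) {
    dct <- setNames(rep(NA_real_, length(samples)), samples)
    for (s in samples) {
      idx <- which(ct$gene == g & ct$sample == s)
      if (length(idx) == 0L) stop("missing Ct for gene ", g, " sample ", s)
      if (all(nd[idx])) { dct[s] <- NA_real_; next }
      dct[s] <- mean(ctv[idx], na.rm = TRUE) - ref_ct[s]
    }
    dct_cal <- if (is.na(dct[calibrator_sample])) 0 else dct[[calibrator_sample]]
    vals <- 2^-(dct - dct_cal)
    vals[is.na(dct)] <- 0
    mat[g, ] <- vals
  }
  mat
}

#' Classify the tissue pattern of each gene
#'
#' A gene is `silent` if every value is below `tau`; `<tissue>-specific` if a
#' single tissue carries at least fraction `sigma` of the total signal;
#' `ubiquitous` if all tissues are expressed; otherwise a `multi:` label
#' listing the expressed-tissue set.
#'
#' @param mat expression matrix (genes x tissues).
#' @param tau expressed threshold on the relative-expression scale
#'   (default 0.05).
#' @param sigma dominance fraction for tissue specificity (0.5 < sigma <= 1,
#'   default 0.8).
#' @return named character vector of labels per gene.
#' @export
classify_tissue_pattern <- function(mat, tau = 0.05, sigma = 0.8) {
  if (tau <= 0) stop("tau must be > 0")
  if (sigma <= 0.5 || sigma > 1) stop("sigma must be in (0.5, 1]")
  apply(mat, 1, function(v) {
    expressed <- which(v >= tau)
    if (length(expressed) == 0L) return("silent")
    dom <- which.max(v)
    if (v[dom] / sum(v) >= sigma)
      return(paste0(colnames(mat)[dom], "-specific"))
    if (length(expressed) == ncol(mat)) return("ubiquitous")
    paste0("multi:", paste(colnames(mat)[expressed], collapse = "+"))
  })
}

#' Deterministic hierarchical clustering of expression profiles
#'
#' Average-linkage agglomeration on euclidean distances of `log2(x + 1)`
#' profiles.
#'
#' @param mat expression matrix (genes x tissues), >= 2 genes.
#' @return list with `order` (leaf gene IDs), `merge_heights`, and the
#'   [stats::hclust] object.
#' @export
cluster_genes <- function(mat) {
  if (nrow(mat) < 2L) stop("need at least two genes")
  hc <- stats::hclust(stats::dist(log2(mat + 1)), method = "average")
  list(order = rownames(mat)[hc$order], merge_heights = hc$height, hclust = hc)
}

#' Expression-divergence category of a paralog pair
#'
#' With expressed set `E(g)` = tissues at or above `tau`, rules are applied in
#' order: both sets empty -> I; exactly one empty -> IV; equal sets with all
#' per-tissue fold ratios below `fold` -> I; equal sets with some ratio at or
#' above `fold` -> II; different non-empty sets -> III. The classification is
#' symmetric in the two genes, total and exclusive.
#'
#' @param expr_a,expr_b named numeric vectors over the same tissue set.
#' @param tau expressed threshold (default 0.05).
#' @param fold fold-change threshold (default 2).
#' @return list with `category` (`"I"`..`"IV"`), `expressed_a`, `expressed_b`
#'   (tissue names), `max_fold` (NA when undefined).
#' @export
categorize_pair <- function(expr_a, expr_b, tau = 0.05, fold = 2) {
  if (!identical(names(expr_a), names(expr_b)))
    stop("tissue sets differ between the two genes")
  ea <- names(expr_a)[expr_a >= tau]
  eb <- names(expr_b)[expr_b >= tau]
  max_fold <- NA_real_
  category <- if (length(ea) == 0L && length(eb) == 0L) {
    "I"
  } else if (length(ea) == 0L || length(eb) == 0L) {
    "IV"
  } else if (setequal(ea, eb)) {
    ratios <- pmax(expr_a[ea], expr_b[ea]) / pmin(expr_a[ea], expr_b[ea])
    max_fold <- max(ratios)
    if (max_fold < fold) "I" else "II"
  } else {
    "III"
  }
  list(category = category, expressed_a = ea, expressed_b = eb,
       max_fold = max_fold)
}

#' Categorize many pairs against an expression matrix
#'
#' @param mat expression matrix (genes x tissues).
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @param tau,fold thresholds, see [categorize_pair()].
#' @return `pairs` with added `category` and `max_fold` columns.
#' @export
categorize_pairs <- function(mat, pairs, tau = 0.05, fold = 2) {
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    categorize_pair(mat[pairs$gene_a[i], ], mat[pairs$gene_b[i], ],
                    tau = tau, fold = fold)
  })
  pairs$category <- vapply(res, `[[`, character(1), "category")
  pairs$max_fold <- vapply(res, `[[`, numeric(1), "max_fold")
  pairs
}

#' Summary of paralog-pair expression divergence
#'
#' @param categories character vector of categories (`I`..`IV`), one per pair.
#' @return list with `counts` (named, all four categories) and
#'   `percent_divergent` = `100 * (II + III + IV) / total`, half-up rounded to
#'   one decimal.
#' @export
divergence_summary <- function(categories) {
  if (length(categories) == 0L) stop("need at least one pair")
  lev <- c("I", "II", "III", "IV")
  if (any(!categories %in% lev)) stop("invalid category value")
  counts <- vapply(lev, function(l) sum(categories == l), integer(1))
  list(counts = counts,
       percent_divergent = round_half_up(
         100 * sum(counts[c("II", "III", "IV")]) / sum(counts), 1))
}
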