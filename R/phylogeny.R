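#' Poisson-corrected pairwise-deletion distance matrix
#'
#' For each pair of aligned protein sequences, alignment columns where either
#' sequence carries a gap/unknown character are excluded (pairwise deletion);
#' the proportion of mismatches p over the remaining columns is corrected to
#' `d = -ln(1 - p)`. Pairs with `p >= 1` or no compared sites get an `Inf` /
#' `NaN` entry and will refuse to enter tree building.
#'
#' @param alignment named character vector of equal-length gapped sequences.
#' @param ambiguous characters treated as gap/unknown (default `-`, `X`, `?`).
#' @return object of class `pg_distmat`: list with `labels`, `d` (symmetric
#'   matrix, zero diagonal) and `compared_sites`.
#' @export
poisson_distance_matrix <- function(alignment, ambiguous = c("-", "X", "?")) {
  n <- length(alignment)
  if (n < 2L) stop("need at least two sequences")
  L <- unique(nchar(alignment))
  if (length(L) != 1L) stop("sequences are not aligned (unequal lengths)")
  labels <- names(alignment)
  if (is.null(labels) || anyDuplicated(labels))
    stop("alignment must have unique names")
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  ok <- !matrix(m %in% ambiguous, nrow = n)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  cs <- matrix(L, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      use <- ok[i, ] & ok[j, ]
      nc <- sum(use)
      cs[i, j] <- cs[j, i] <- nc
      if (nc == 0L) { d[i, j] <- d[j, i] <- NaN; next }
      p <- sum(m[i, use] != m[j, use]) / nc
      d[i, j] <- d[j, i] <- if (p >= 1) Inf else -log(1 - p)
    }
  }
  structure(list(labels = labels, d = d, compared_sites = cs),
            class = "pg_distmat")
}

fmt_bl <- function(x) sprintf("%.10g", max(x, 0))

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q criterion and branch-length
#' formulas. Ties in the Q matrix are broken by the lowest (row, column) index
#' pair so results are deterministic. Negative estimated branch lengths are
#' clamped to zero with the deficit transferred to the sister edge (the
#' behaviour familiar from MEGA).
#'
#' @param dm a `pg_distmat` from [poisson_distance_matrix()], or a symmetric
#'   numeric matrix with dimnames.
#' @return unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "pg_distmat")) { d <- dm$d; labels <- dm$labels }
  else { d <- as.matrix(dm); labels <- rownames(d) }
  if (is.null(labels)) stop("distance matrix must carry labels")
  if (any(!is.finite(d))) stop("infinite/undefined distance entries")
  n <- length(labels)
  if (n < 2L) stop("need at least two taxa")
  nodes <- labels
  if (n == 2L) {
    return(read_newick(sprintf("(%s:%s,%s:%s);", nodes[1], fmt_bl(d[1, 2] / 2),
                               nodes[2], fmt_bl(d[1, 2] / 2))))
  }
  while (n > 3L) {
    r <- rowSums(d)
    best <- NULL; bestq <- Inf
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        q <- (n - 2) * d[i, j] - r[i] - r[j]
        if (q < bestq - 1e-12) { bestq <- q; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- d[i, j] - vi
    # clamp negatives, moving the deficit onto the sister edge
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    vi <- max(vi, 0); vj <- max(vj, 0)
    newnode <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt_bl(vi),
                       nodes[j], fmt_bl(vj))
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    nodes <- c(nodes[keep], newnode)
    n <- n - 1L
  }
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  read_newick(sprintf("(%s:%s,%s:%s,%s:%s);",
                      nodes[1], fmt_bl(v1), nodes[2], fmt_bl(v2),
                      nodes[3], fmt_bl(v3)))
}

# Canonical bipartition keys of a tree's internal edges. A split is encoded
# by the tip side NOT containing the alphabetically first tip of `all_tips`;
# trivial splits (side size < 2 or > n - 2) are dropped unless keep_trivial.
tree_split_keys <- function(tree, all_tips = sort(tree$tip.label)) {
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  n <- length(all_tips)
  keys <- vapply(parts, function(idx) {
    side <- labs[idx]
    if (all_tips[1] %in% side) side <- setdiff(all_tips, side)
    if (length(side) < 2L || length(side) > n - 2L) return(NA_character_)
    paste(sort(side), collapse = "\r")
  }, character(1))
  keys
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Alignment columns are resampled with replacement `n_reps` times; an NJ tree
#' is built per replicate, and the support of each internal bipartition of the
#' full-data tree is the percentage of replicates containing it (rounded to
#' the nearest integer) stored in the tree's node labels.
#'
#' @param alignment named character vector of equal-length gapped sequences.
#' @param n_reps number of bootstrap replicates (>= 1), default 1000.
#' @param seed integer seed; the run is reproducible given the seed.
#' @param ambiguous characters excluded by pairwise deletion.
#' @return [ape::phylo] tree of the full data with `node.label` supports
#'   (empty string where a support is not defined, e.g. the root).
#' @export
bootstrap_supports <- function(alignment, n_reps = 1000L, seed = 1L,
                               ambiguous = c("-", "X", "?")) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  full <- nj_tree(poisson_distance_matrix(alignment, ambiguous))
  all_tips <- sort(full$tip.label)
  full_keys <- tree_split_keys(full, all_tips)
  counts <- setNames(rep(0L, length(full_keys)), full_keys)
  L <- nchar(alignment[[1]])
  chars <- strsplit(alignment, "")
  withr::with_seed(seed, {
    for (b in seq_len(n_reps)) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_aln <- vapply(chars, function(ch) paste(ch[cols], collapse = ""),
                        character(1))
      rep_tree <- tryCatch(
        nj_tree(poisson_distance_matrix(rep_aln, ambiguous)),
        error = function(e) NULL)
      if (is.null(rep_tree)) next
      rk <- tree_split_keys(rep_tree, all_tips)
      hit <- !is.na(names(counts)) & names(counts) %in% rk
      counts[hit] <- counts[hit] + 1L
    }
  })
  lab <- ifelse(is.na(full_keys), "",
                as.character(round(100 * counts / n_reps)))
  full$node.label <- lab
  full
}

#' Midpoint rooting
#'
#' Roots the tree at the midpoint of the longest tip-to-tip path; bipartition
#' supports are preserved.
#'
#' @param tree unrooted [ape::phylo] with branch lengths.
#' @return rooted [ape::phylo].
#' @export
midpoint_root <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (sum(tree$edge.length) <= 0) stop("zero-length tree cannot be rooted")
  has_support <- !is.null(tree$node.label)
  out <- phangorn::midpoint(tree,
                            node.labels = if (has_support) "support" else "delete")
  out
}

#' Assign family clades from anchored reference tips
#'
#' Each unanchored tip inherits the clade of the smallest well-supported clan
#' (support at least `support_threshold`, or no support recorded, e.g. at the
#' root) that contains it together with anchors of exactly one clade. Clans
#' whose anchors span several clades make the tip `unassigned`.
#'
#' @param tree rooted [ape::phylo] (root with [midpoint_root()] first if
#'   needed); node labels are read as supports.
#' @param anchors named character vector: names are anchor tip labels, values
#'   their clade letters (e.g. `A`..`G`).
#' @param support_threshold minimum support for a clan to be trusted
#'   (default 50).
#' @return data.frame with columns `gene_id`, `clade` (`NA` for unassigned).
#' @export
assign_clades <- function(tree, anchors, support_threshold = 50) {
  if (any(!names(anchors) %in% tree$tip.label))
    stop("anchor tip(s) absent from tree: ",
         paste(setdiff(names(anchors), tree$tip.label), collapse = ", "))
  ntip <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  supports <- tree_supports(tree)
  parent_of <- integer(ntip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  clade_of <- setNames(rep(NA_character_, ntip), tree$tip.label)
  clade_of[names(anchors)] <- unname(anchors)
  for (t in seq_len(ntip)) {
    tip <- tree$tip.label[t]
    if (!is.na(clade_of[tip])) next
    node <- parent_of[t]
    repeat {
      k <- node - ntip
      sup <- supports[k]
      if (is.na(sup) || sup >= support_threshold) {
        members <- labs[parts[[k]]]
        found <- unique(unname(anchors[intersect(members, names(anchors))]))
        if (length(found) == 1L) { clade_of[tip] <- found; break }
        if (length(found) > 1L) break  # conflict: leave unassigned
      }
      if (node == root) break
      node <- parent_of[node]
    }
  }
  data.frame(gene_id = names(clade_of), clade = unname(clade_of),
             stringsAsFactors = FALSE)
}
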