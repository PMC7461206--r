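#' Label gene-tree nodes as speciation, duplication or pure
#'
#' Works bottom-up on a rooted gene tree of two species: a node whose two
#' child subtrees split cleanly into one all-A and one all-B subtree is a
#' speciation node (it marks one ancestral gene at the species split); a node
#' with only one species below is pure; everything else is a duplication.
#' Non-binary nodes are resolved deterministically before labelling.
#'
#' @param tree rooted [ape::phylo]; node labels are read as supports.
#' @param species named character vector mapping every tip label to a species
#'   tag (exactly two distinct tags); if `NULL`, tags are taken from tip-label
#'   prefixes before `sep`.
#' @param sep separator used when deriving species from tip labels.
#' @return list with `tree` (the resolved tree), `species`, and `labels`, a
#'   data.frame with one row per node (tips included): `node`, `is_tip`,
#'   `kind` (`speciation` / `duplication` / `pure`), `species_below`,
#'   `support`.
#' @export
label_nodes <- function(tree, species = NULL, sep = "_") {
  if (!ape::is.rooted(tree)) stop("a rooted tree is required")
  tree <- ape::multi2di(tree, random = FALSE)
  tips <- tree$tip.label
  if (is.null(species)) {
    species <- setNames(split_species_prefix(tips, sep), tips)
  }
  if (any(!tips %in% names(species)))
    stop("unmapped tip(s): ",
         paste(setdiff(tips, names(species)), collapse = ", "))
  species <- species[tips]
  if (length(unique(species)) > 2L)
    stop("more than two species in tree")
  ntip <- length(tips)
  nnode <- tree$Nnode
  supports <- tree_supports(tree)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  sp_below <- vector("list", ntip + nnode)
  for (t in seq_len(ntip)) sp_below[[t]] <- unname(species[t])
  # postorder over internal nodes
  for (v in rev(seq_len(nnode) + ntip)) {
    ch <- kids[[as.character(v)]]
    sp_below[[v]] <- sort(unique(unlist(sp_below[ch])))
  }
  kind <- character(ntip + nnode)
  kind[seq_len(ntip)] <- "pure"
  for (v in seq_len(nnode) + ntip) {
    ch <- kids[[as.character(v)]]
    sets <- sp_below[ch]
    if (length(sp_below[[v]]) == 1L) kind[v] <- "pure"
    else if (length(ch) == 2L &&
             length(sets[[1]]) == 1L && length(sets[[2]]) == 1L &&
             sets[[1]] != sets[[2]]) kind[v] <- "speciation"
    else kind[v] <- "duplication"
  }
  labels <- data.frame(
    node = seq_len(ntip + nnode),
    is_tip = c(rep(TRUE, ntip), rep(FALSE, nnode)),
    kind = kind,
    species_below = vapply(sp_below, paste, character(1), collapse = "+"),
    support = c(rep(NA_real_, ntip), supports),
    stringsAsFactors = FALSE)
  list(tree = tree, species = species, labels = labels)
}

#' Count minimal common ancestral genes on a two-species gene tree
#'
#' Every speciation node marks one ancestral gene present at the species
#' split. A maximal single-species (pure) clade hanging outside all speciation
#' clades also implies one ancestral lineage - one whose counterpart was lost
#' in the other species (or gained after the split; the ambiguity is flagged,
#' not resolved). `n_total` counts both classes; `n_high` counts only
#' speciation nodes with support strictly greater than `support_threshold`,
#' reproducing the "at least N ancestral genes" reading of a bootstrap tree.
#'
#' @param labelled result of [label_nodes()].
#' @param support_threshold bootstrap percentage; speciation nodes must exceed
#'   it to enter `n_high` (default 50). Nodes without a recorded support are
#'   treated as below the threshold.
#' @return list with `n_high`, `n_total`, `pure_branches` (named count of
#'   maximal pure clades per species) and `lineages`, a data.frame with one
#'   counted lineage per row: `lineage`, `kind`, `node`, `support`, `tips`
#'   (semicolon-joined tip labels).
#' @export
count_ancestral_genes <- function(labelled, support_threshold = 50) {
  tree <- labelled$tree
  lab <- labelled$labels
  ntip <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  plabs <- attr(parts, "labels")
  tips_below <- function(v) {
    if (v <= ntip) tree$tip.label[v] else plabs[parts[[v - ntip]]]
  }
  parent_of <- integer(ntip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  spec_nodes <- lab$node[lab$kind == "speciation"]
  is_pure <- lab$kind == "pure"
  maximal_pure <- lab$node[is_pure &
    (lab$node == root |
       (!is_pure[pmax(parent_of[lab$node], 1L)] &
        lab$kind[pmax(parent_of[lab$node], 1L)] != "speciation"))]
  rows <- list()
  for (v in spec_nodes) {
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "speciation", node = v, support = lab$support[v],
      species = lab$species_below[v],
      tips = paste(tips_below(v), collapse = ";"), stringsAsFactors = FALSE)
  }
  for (v in maximal_pure) {
    rows[[length(rows) + 1L]] <- data.frame(
      kind = paste0("pure_", lab$species_below[v]), node = v,
      support = lab$support[v], species = lab$species_below[v],
      tips = paste(tips_below(v), collapse = ";"), stringsAsFactors = FALSE)
  }
  lineages <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(), node = integer(), support = numeric(),
               species = character(), tips = character(),
               stringsAsFactors = FALSE)
  if (nrow(lineages)) lineages$lineage <- seq_len(nrow(lineages))
  sp_tags <- sort(unique(unname(labelled$species)))
  pure_counts <- setNames(integer(length(sp_tags)), sp_tags)
  for (v in maximal_pure) {
    s <- lab$species_below[v]
    pure_counts[s] <- pure_counts[s] + 1L
  }
  n_total <- length(spec_nodes) + length(maximal_pure)
  sup <- lab$support[spec_nodes]
  n_high <- sum(!is.na(sup) & sup > support_threshold)
  list(n_high = n_high, n_total = n_total,
       pure_branches = pure_counts, lineages = lineages)
}

#' Per-clade gain/loss table for the two species
#'
#' For each clade c and species X: `lineages_with_X` is the number of counted
#' ancestral lineages of c with at least one extant X gene;
#' `loss_X = n_anc(c) - lineages_with_X` and
#' `gain_X = extant_X(c) - lineages_with_X`. A lineage's clade is the
#' (majority) clade of its tips.
#'
#' @param counted result of [count_ancestral_genes()].
#' @param species named species map used for the tree tips.
#' @param clades named character vector mapping gene IDs to clade letters.
#' @param extant optional list `list(<speciesA> = named counts per clade,
#'   <speciesB> = ...)`; when supplied it is validated against the tree tips.
#' @return data.frame with one row per clade: `clade`, `n_anc`, and per
#'   species `gain_*` / `loss_*` columns (suffix = species tag).
#' @export
gain_loss_by_clade <- function(counted, species, clades, extant = NULL) {
  lineages <- counted$lineages
  if (nrow(lineages) == 0L) stop("no counted lineages")
  sp_tags <- sort(unique(unname(species)))
  tip_list <- strsplit(lineages$tips, ";", fixed = TRUE)
  lineage_clade <- vapply(tip_list, function(tp) {
    cl <- clades[tp]
    cl <- cl[!is.na(cl)]
    if (length(cl) == 0L) return(NA_character_)
    tab <- sort(table(cl), decreasing = TRUE)
    names(tab)[1]
  }, character(1))
  all_tips <- unlist(tip_list)
  tip_clade <- clades[all_tips]
  tip_sp <- species[all_tips]
  derived_extant <- lapply(sp_tags, function(s)
    table(tip_clade[tip_sp == s & !is.na(tip_clade)]))
  names(derived_extant) <- sp_tags
  if (!is.null(extant)) {
    for (s in sp_tags) {
      de <- derived_extant[[s]]
      for (cl in names(extant[[s]])) {
        if (extant[[s]][[cl]] != (if (cl %in% names(de)) de[[cl]] else 0L))
          stop("supplied extant counts inconsistent with tree tips (",
               s, ", clade ", cl, ")")
      }
    }
  }
  clade_levels <- sort(unique(lineage_clade[!is.na(lineage_clade)]))
  rows <- lapply(clade_levels, function(cl) {
    idx <- which(lineage_clade == cl)
    n_anc <- length(idx)
    row <- data.frame(clade = cl, n_anc = n_anc, stringsAsFactors = FALSE)
    for (s in sp_tags) {
      with_s <- sum(vapply(tip_list[idx], function(tp)
        any(species[tp] == s), logical(1)))
      ex <- derived_extant[[s]]
      ex_c <- if (cl %in% names(ex)) as.integer(ex[[cl]]) else 0L
      row[[paste0("gain_", s)]] <- ex_c - with_s
      row[[paste0("loss_", s)]] <- n_anc - with_s
      row[[paste0("extant_", s)]] <- ex_c
    }
    row
  })
  do.call(rbind, rows)
}

#' Compare an inferred ancestry report with simulator ground truth
#'
#' @param truth `SimTruth` ledger from [simulate_family_history()].
#' @param counted result of [count_ancestral_genes()] on the true gene tree.
#' @return list of recovery metrics: `lineage_count_exact` (logical),
#'   `n_total_inferred`, `n_total_true`, `pure_branches_inferred`,
#'   `pure_branches_true`.
#' @export
recover_ancestral_count <- function(truth, counted) {
  genes <- truth$genes
  surviving <- unique(genes$lineage)
  true_pure <- c(
    A = length(setdiff(unique(genes$lineage[genes$species == "SpA"]),
                       unique(genes$lineage[genes$species == "SpB"]))),
    B = length(setdiff(unique(genes$lineage[genes$species == "SpB"]),
                       unique(genes$lineage[genes$species == "SpA"]))))
  list(lineage_count_exact = counted$n_total == length(surviving),
       n_total_inferred = counted$n_total,
       n_total_true = length(surviving),
       pure_branches_inferred = counted$pure_branches,
       pure_branches_true = true_pure)
}
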