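# Codon machinery for NG86. Tables are built once per session.
.ng86_env <- new.env(parent = emptyenv())

genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  gc
}

#' Translate an in-frame CDS to protein
#'
#' @param cds nucleotide string, length divisible by 3, standard code; stops
#'   translate to `*`.
#' @return amino-acid string.
#' @export
translate_cds <- function(cds) {
  stopifnot_scalar_seq(cds, "cds")
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) stop("CDS length not divisible by 3")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  gc <- genetic_code()
  aa <- gc[codons]
  if (any(is.na(aa))) stop("non-ACGT codon in CDS")
  paste(aa, collapse = "")
}

# Per-codon synonymous/nonsynonymous site fractions. Mutations creating a
# stop codon count toward neither class (their fraction of the site is
# dropped), which matches a mutation process that never fixes premature stops.
ng86_site_table <- function() {
  if (!is.null(.ng86_env$sites)) return(.ng86_env$sites)
  gc <- genetic_code()
  codons <- names(gc)[gc != "*"]
  syn <- nonsyn <- setNames(numeric(length(codons)), codons)
  for (cod in codons) {
    chars <- strsplit(cod, "")[[1]]
    for (pos in 1:3) {
      for (nt in setdiff(DNA4, chars[pos])) {
        alt <- chars; alt[pos] <- nt
        alt <- paste(alt, collapse = "")
        if (gc[[alt]] == "*") next
        if (gc[[alt]] == gc[[cod]]) syn[cod] <- syn[cod] + 1 / 3
        else nonsyn[cod] <- nonsyn[cod] + 1 / 3
      }
    }
  }
  .ng86_env$sites <- list(syn = syn, nonsyn = nonsyn)
  .ng86_env$sites
}

# Average synonymous/nonsynonymous substitution counts between two codons
# over all minimal mutation pathways (orderings of the differing positions).
# Pathways passing through a stop codon are excluded; if every pathway is
# blocked, all are used.
ng86_path_counts <- function(cod_a, cod_b) {
  gc <- genetic_code()
  a <- strsplit(cod_a, "")[[1]]
  b <- strsplit(cod_b, "")[[1]]
  diffpos <- which(a != b)
  k <- length(diffpos)
  if (k == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- if (k == 1L) list(diffpos) else {
    idx <- seq_len(k)
    ords <- if (k == 2L) list(c(1, 2), c(2, 1)) else
      list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
    lapply(ords, function(o) diffpos[o])
  }
  eval_path <- function(path) {
    cur <- a; s <- 0; n <- 0
    for (p in path) {
      nxt <- cur; nxt[p] <- b[p]
      aa1 <- gc[[paste(cur, collapse = "")]]
      aa2 <- gc[[paste(nxt, collapse = "")]]
      if (aa2 == "*" && !identical(nxt, b)) return(NULL)  # blocked pathway
      if (aa1 == aa2) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(syn = s, nonsyn = n)
  }
  res <- lapply(perms, eval_path)
  ok <- !vapply(res, is.null, logical(1))
  if (!any(ok)) {
    res <- lapply(perms, function(path) {
      cur <- a; s <- 0; n <- 0
      for (p in path) {
        nxt <- cur; nxt[p] <- b[p]
        if (gc[[paste(cur, collapse = "")]] == gc[[paste(nxt, collapse = "")]])
          s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      c(syn = s, nonsyn = n)
    })
    ok <- rep(TRUE, length(res))
  }
  Reduce(`+`, res[ok]) / sum(ok)
}

#' Nei-Gojobori (1986) Ka/Ks for an in-frame codon-aligned CDS pair
#'
#' Synonymous site fractions per codon come from the standard genetic code and
#' are averaged over both sequences; codons differing at several positions are
#' averaged over all minimal substitution pathways (pathways through stop
#' codons excluded). Proportions are corrected with the Jukes-Cantor formula
#' `d = -(3/4) ln(1 - 4p/3)`. The ratio is the undefined sentinel (`NA`) when
#' `Ks = 0`; `p >= 3/4` flags saturation and yields `NA` for that rate.
#'
#' @param cds_a,cds_b equal-length, gap-free, in-frame coding sequences
#'   (length divisible by 3, no internal stop codons).
#' @return list with `Ka`, `Ks`, `ratio`, site counts `N`, `S`, substitution
#'   counts `Nd`, `Sd`, and `saturated` (logical).
#' @export
ng86_kaks <- function(cds_a, cds_b) {
  stopifnot_scalar_seq(cds_a, "cds_a"); stopifnot_scalar_seq(cds_b, "cds_b")
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b)) stop("sequences must be equal length")
  if (nchar(cds_a) %% 3L != 0L) stop("CDS length not divisible by 3")
  if (grepl("-", cds_a, fixed = TRUE) || grepl("-", cds_b, fixed = TRUE))
    stop("gap-free sequences required (codon-align first)")
  nc <- nchar(cds_a) / 3L
  cods_a <- substring(cds_a, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  cods_b <- substring(cds_b, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  gc <- genetic_code()
  if (any(is.na(gc[cods_a])) || any(is.na(gc[cods_b])))
    stop("non-ACGT codon in CDS")
  internal_a <- gc[cods_a] == "*" & seq_len(nc) < nc
  internal_b <- gc[cods_b] == "*" & seq_len(nc) < nc
  if (any(internal_a) || any(internal_b)) stop("internal stop codon in CDS")
  # drop a terminal stop codon pair if present
  if (gc[[cods_a[nc]]] == "*" || gc[[cods_b[nc]]] == "*") {
    cods_a <- cods_a[-nc]; cods_b <- cods_b[-nc]; nc <- nc - 1L
  }
  st <- ng86_site_table()
  S <- (sum(st$syn[cods_a]) + sum(st$syn[cods_b])) / 2
  N <- (sum(st$nonsyn[cods_a]) + sum(st$nonsyn[cods_b])) / 2
  Sd <- Nd <- 0
  for (i in seq_len(nc)) {
    if (cods_a[i] == cods_b[i]) next
    cnt <- ng86_path_counts(cods_a[i], cods_b[i])
    Sd <- Sd + cnt[["syn"]]; Nd <- Nd + cnt[["nonsyn"]]
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3) + 0
  Ks <- jc(pS); Ka <- jc(pN)
  saturated <- is.na(Ka) || is.na(Ks)
  ratio <- if (saturated || Ks == 0) NA_real_ else Ka / Ks
  list(Ka = Ka, Ks = Ks, ratio = ratio, N = N, S = S, Nd = Nd, Sd = Sd,
       saturated = saturated)
}

#' Global alignment identity and coverage for a sequence pair
#'
#' Needleman-Wunsch global alignment (affine gaps). Identity is matches over
#' aligned columns excluding terminal gap runs; coverage is the span of the
#' longer sequence inside the non-terminal-gap region divided by its length.
#'
#' @param seq_a,seq_b sequences (same alphabet).
#' @param type `"protein"` (BLOSUM62) or `"dna"` (match 1 / mismatch -2).
#' @param gap_opening,gap_extension affine gap penalties (positive costs).
#' @return list with `identity_pct`, `coverage_pct`, `score`, `aligned_a`,
#'   `aligned_b`.
#' @export
global_align_identity <- function(seq_a, seq_b, type = c("protein", "dna"),
                                  gap_opening = 10, gap_extension = 0.5) {
  type <- match.arg(type)
  stopifnot_scalar_seq(seq_a, "seq_a"); stopifnot_scalar_seq(seq_b, "seq_b")
  if (type == "protein") {
    submat <- "BLOSUM62"
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
      type = "global", substitutionMatrix = submat,
      gapOpening = gap_opening, gapExtension = gap_extension)
  } else {
    submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = TRUE)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
      type = "global", substitutionMatrix = submat,
      gapOpening = gap_opening, gapExtension = gap_extension)
  }
  a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  nongap_a <- which(a != "-"); nongap_b <- which(b != "-")
  s <- max(min(nongap_a), min(nongap_b))
  e <- min(max(nongap_a), max(nongap_b))
  cols <- s:e
  identity <- 100 * sum(a[cols] == b[cols] & a[cols] != "-") / length(cols)
  longer_is_a <- nchar(seq_a) >= nchar(seq_b)
  span <- if (longer_is_a) sum(a[cols] != "-") else sum(b[cols] != "-")
  coverage <- 100 * span / max(nchar(seq_a), nchar(seq_b))
  list(identity_pct = identity, coverage_pct = coverage,
       score = Biostrings::score(pa),
       aligned_a = paste(a, collapse = ""), aligned_b = paste(b, collapse = ""))
}

#' Codon-align a CDS pair by back-threading the protein alignment
#'
#' Proteins are aligned globally; aligned residue columns are mapped back to
#' codons and gapped columns dropped, giving equal-length gap-free codon
#' sequences suitable for [ng86_kaks()].
#'
#' @param cds_a,cds_b in-frame coding sequences.
#' @return list with `cds_a`, `cds_b` (gap-free, equal length).
#' @export
codon_align <- function(cds_a, cds_b) {
  pa <- translate_cds(cds_a); pb <- translate_cds(cds_b)
  pa <- sub("\\*$", "", pa); pb <- sub("\\*$", "", pb)
  al <- global_align_identity(pa, pb, type = "protein")
  a <- strsplit(al$aligned_a, "")[[1]]
  b <- strsplit(al$aligned_b, "")[[1]]
  ia <- ib <- 0L
  keep_a <- keep_b <- integer(0)
  for (k in seq_along(a)) {
    if (a[k] != "-") ia <- ia + 1L
    if (b[k] != "-") ib <- ib + 1L
    if (a[k] != "-" && b[k] != "-") {
      keep_a <- c(keep_a, ia); keep_b <- c(keep_b, ib)
    }
  }
  pick <- function(cds, idx) {
    paste(substring(cds, 3 * idx - 2, 3 * idx), collapse = "")
  }
  list(cds_a = pick(toupper(cds_a), keep_a),
       cds_b = pick(toupper(cds_b), keep_b))
}

#' Detect tandem duplicate pairs under the 80/80 rule
#'
#' A pair qualifies if both genes lie on the same chromosome, are separated by
#' at most `max_sep` intervening family genes or at most `max_dist` bp, and
#' their sequences align with identity and coverage above the thresholds.
#'
#' @param models `pg_gene_models` of the family members.
#' @param seqs named character vector of sequences (CDS) for the same genes.
#' @param max_sep maximum intervening family genes (default 1).
#' @param max_dist maximum genomic separation in bp (default 100000).
#' @param min_identity,min_coverage percentage thresholds (default 80/80,
#'   strict inequality).
#' @param type alignment alphabet, see [global_align_identity()].
#' @return data.frame: `gene_a`, `gene_b`, `chromosome`, `intervening`,
#'   `distance`, `identity_pct`, `coverage_pct`.
#' @export
detect_tandem_pairs <- function(models, seqs, max_sep = 1L, max_dist = 1e5,
                                min_identity = 80, min_coverage = 80,
                                type = "dna") {
  tab <- data.frame(
    gene_id = vapply(models, `[[`, character(1), "gene_id"),
    chrom = vapply(models, `[[`, character(1), "chromosome"),
    start = vapply(models, function(m) min(m$exons), numeric(1)),
    end = vapply(models, function(m) max(m$exons), numeric(1)),
    stringsAsFactors = FALSE)
  out <- list()
  for (ch in unique(tab$chrom)) {
    sub <- tab[tab$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    n <- nrow(sub)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        intervening <- j - i - 1L
        gap <- sub$start[j] - sub$end[i]
        if (intervening > max_sep && gap > max_dist) next
        ga <- sub$gene_id[i]; gb <- sub$gene_id[j]
        if (!ga %in% names(seqs) || !gb %in% names(seqs)) next
        sa <- seqs[[ga]]; sb <- seqs[[gb]]
        # equal-length fast path: an ungapped comparison bounds the gapped
        # one tightly, so clear accepts/rejects skip the affine alignment
        al <- NULL
        if (nchar(sa) == nchar(sb)) {
          idp <- 100 * mean(strsplit(sa, "")[[1]] == strsplit(sb, "")[[1]])
          if (idp > min_identity)
            al <- list(identity_pct = idp, coverage_pct = 100)
          else if (idp < min_identity - 20)
            al <- list(identity_pct = idp, coverage_pct = 100)
        }
        if (is.null(al))
          al <- global_align_identity(sa, sb, type = type)
        if (al$identity_pct > min_identity && al$coverage_pct > min_coverage) {
          out[[length(out) + 1L]] <- data.frame(
            gene_a = ga, gene_b = gb, chromosome = ch,
            intervening = intervening, distance = gap,
            identity_pct = al$identity_pct, coverage_pct = al$coverage_pct,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      chromosome = character(), intervening = integer(),
                      distance = numeric(), identity_pct = numeric(),
                      coverage_pct = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Terminal (sister-tip) paralog pairs above an identity threshold
#'
#' @param tree [ape::phylo] whose tips are family genes of one species.
#' @param identity symmetric numeric matrix of pairwise identity percentages
#'   with gene IDs as dimnames.
#' @param min_identity threshold (strict, default 80).
#' @return data.frame: `gene_a`, `gene_b`, `identity_pct`.
#' @export
terminal_paralog_pairs <- function(tree, identity, min_identity = 80) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  out <- list()
  for (v in names(kids)) {
    ch <- kids[[v]]
    if (length(ch) == 2L && all(ch <= ntip)) {
      ga <- tree$tip.label[ch[1]]; gb <- tree$tip.label[ch[2]]
      idp <- identity[ga, gb]
      if (idp > min_identity) {
        out[[length(out) + 1L]] <- data.frame(
          gene_a = ga, gene_b = gb, identity_pct = idp,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      identity_pct = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
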