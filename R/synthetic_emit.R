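# Emitters turning a simulated family history into concrete artifacts:
# coding/protein sequences, a qPCR Ct table, and promoters with planted
# cis-elements. All are deterministic given the config seed.

iupac_map <- function() {
  list(A = "A", C = "C", G = "G", T = "T",
       R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
       K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
       D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
       N = c("A", "C", "G", "T"))
}

iupac_instantiate <- function(consensus) {
  im <- iupac_map()
  paste(vapply(strsplit(consensus, "")[[1]],
               function(ch) sample(im[[ch]], 1L), character(1)),
        collapse = "")
}

# Protein-coordinate anchor positions for the four conserved domains.
domain_plant_positions <- function() c(I = 40L, II = 100L, III = 160L, IV = 220L)

# Precomputed single-nucleotide mutation tables: for each of the 64 codons,
# the 9 possible (position, alternative base) outcomes with their class
# (1 = synonymous, 2 = nonsynonymous, 3 = creates a stop).
evolve_tables <- function() {
  if (!is.null(.ng86_env$evolve)) return(.ng86_env$evolve)
  gc <- genetic_code()
  codons <- names(gc)
  res <- matrix(0L, 64, 9)
  cls <- matrix(0L, 64, 9)
  for (ci in seq_along(codons)) {
    ch <- strsplit(codons[ci], "")[[1]]
    k <- 0L
    for (pos in 1:3) {
      for (nt in setdiff(DNA4, ch[pos])) {
        k <- k + 1L
        alt <- ch; alt[pos] <- nt
        alt <- paste(alt, collapse = "")
        res[ci, k] <- match(alt, codons)
        cls[ci, k] <- if (gc[[alt]] == "*") 3L
                      else if (gc[[alt]] == gc[[codons[ci]]]) 1L else 2L
      }
    }
  }
  .ng86_env$evolve <- list(codons = codons, res = res, cls = cls)
  .ng86_env$evolve
}

# Accept/reject codon evolution on integer codon states: propose uniform
# single-nucleotide changes at mutable codons, reject changes creating stops,
# accept synonymous changes always and nonsynonymous ones with probability
# omega, until `target` accepted substitutions have occurred.
evolve_codons <- function(codon_idx, t, omega, mutable, tab) {
  target <- stats::rpois(1, 3L * length(codon_idx) * t)
  if (target == 0L) return(list(codons = codon_idx, n_subs = 0L))
  accepted <- 0L
  attempts <- 0L
  max_attempts <- 500L * target + 2000L
  n_mut <- length(mutable)
  while (accepted < target && attempts < max_attempts) {
    attempts <- attempts + 1L
    i <- mutable[sample.int(n_mut, 1L)]
    k <- sample.int(9L, 1L)
    ci <- codon_idx[i]
    cl <- tab$cls[ci, k]
    if (cl == 3L) next
    if (cl == 2L && stats::runif(1) >= omega) next
    codon_idx[i] <- tab$res[ci, k]
    accepted <- accepted + 1L
  }
  list(codons = codon_idx, n_subs = accepted)
}

#' Emit coding and protein sequences for a simulated history
#'
#' Each ancestral lineage gets an independent stop-free random CDS with the
#' four conserved family domains planted at fixed protein positions (frozen
#' against mutation so family identification stays a closed loop). Sequences
#' evolve along the lineage's true tree by an accept/reject codon process
#' whose accepted nonsynonymous:synonymous ratio tracks the configured omega.
#'
#' @param history result of [simulate_family_history()].
#' @param motif_domains which conserved domains to plant (subset of
#'   `c("I","II","III","IV")`; default all four).
#' @return list with `cds` and `protein` (named vectors over all genes),
#'   `motif_positions` (protein coordinates of planted domains) and
#'   `substitutions` (data.frame: lineage, branch, n_subs).
#' @export
emit_sequences <- function(history, motif_domains = c("I", "II", "III", "IV")) {
  config <- history$config
  if (config$omega < 0) stop("omega must be >= 0")
  withr::with_seed(config$seed + 1L, emit_sequences_(history, motif_domains))
}

emit_sequences_ <- function(history, motif_domains) {
  config <- history$config
  gc <- genetic_code()
  tab <- evolve_tables()
  sense_idx <- which(gc[tab$codons] != "*")
  aa_of <- unname(gc[tab$codons])
  aa2idx <- vapply(unique(aa_of[sense_idx]),
                   function(a) sense_idx[aa_of[sense_idx] == a][1],
                   integer(1))
  motifs <- pg_domain_motifs()
  motifs <- motifs[motifs$domain %in% motif_domains, , drop = FALSE]
  pos <- domain_plant_positions()[motifs$domain]
  if (nrow(motifs) &&
      any(pos + nchar(motifs$motif) - 1L > config$n_codons))
    stop("n_codons too small to hold the planted domains")
  frozen_codons <- unlist(lapply(seq_len(nrow(motifs)), function(i)
    seq(pos[i], pos[i] + nchar(motifs$motif[i]) - 1L)))
  mutable <- setdiff(seq_len(config$n_codons), frozen_codons)
  bl <- config$subs_per_site
  cherry <- if (bl > 0) min(0.01, bl / 2) else 0
  omega <- config$omega
  genes <- history$genes
  cds <- character(0); subs <- list()
  note <- function(li, branch, n) subs[[length(subs) + 1L]] <<-
    data.frame(lineage = li, branch = branch, n_subs = n,
               stringsAsFactors = FALSE)
  ev <- function(codons, t, li, branch) {
    r <- evolve_codons(codons, t, omega, mutable, tab)
    note(li, branch, r$n_subs)
    r$codons
  }
  as_seq <- function(idx) paste(tab$codons[idx], collapse = "")
  emit_copy <- function(parent, base, tandem, dup, stem, li) {
    # mirrors build_copy_subtree() topology
    if (is.na(tandem) && is.na(dup)) {
      cds[[base]] <<- as_seq(ev(parent, stem, li, base))
      return(invisible())
    }
    if (!is.na(tandem) && !is.na(dup)) {
      w <- parent
      dupseq <- ev(w, cherry, li, dup)
      inner <- ev(w, max(stem - cherry, 0), li, paste0(base, ".stem"))
      cds[[base]] <<- as_seq(ev(inner, cherry, li, base))
      cds[[tandem]] <<- as_seq(ev(inner, cherry, li, tandem))
      cds[[dup]] <<- as_seq(dupseq)
      return(invisible())
    }
    other <- if (!is.na(tandem)) tandem else dup
    inner <- ev(parent, max(stem - cherry, 0), li, paste0(base, ".stem"))
    cds[[base]] <<- as_seq(ev(inner, cherry, li, base))
    cds[[other]] <<- as_seq(ev(inner, cherry, li, other))
    invisible()
  }
  for (li in unique(genes$lineage)) {
    anc <- sample(sense_idx, config$n_codons, replace = TRUE)
    for (i in seq_len(nrow(motifs))) {
      aa <- strsplit(motifs$motif[i], "")[[1]]
      anc[seq(pos[i], pos[i] + length(aa) - 1L)] <- aa2idx[aa]
    }
    g <- genes[genes$lineage == li, , drop = FALSE]
    # species A side
    a <- g[g$species == "SpA", , drop = FALSE]
    if (nrow(a)) {
      base <- a$gene_id[a$origin == "base"]
      dup <- if (any(a$origin == "dup")) a$gene_id[a$origin == "dup"] else NA
      emit_copy(anc, base, NA_character_, dup, bl, li)
    }
    # species B side
    b <- g[g$species == "SpB", , drop = FALSE]
    if (nrow(b)) {
      sgs <- unique(b$subgenome)
      n_sg <- length(sgs)
      stem_b <- if (n_sg > 1) ev(anc, 0.3 * bl, li, "B.stem") else anc
      inner_lfmf1 <- if (n_sg == 3L)
        ev(stem_b, 0.2 * bl, li, "B.lf_mf1") else stem_b
      for (sg in sgs) {
        parent <- if (n_sg == 3L && sg %in% c("LF", "MF1")) inner_lfmf1
                  else stem_b
        stem <- switch(sg, LF = 0.5 * bl, MF1 = 0.5 * bl, MF2 = 0.7 * bl)
        bb <- b[b$subgenome == sg, , drop = FALSE]
        base <- bb$gene_id[bb$origin == "wgt"]
        tand <- if (any(bb$origin == "tandem")) bb$gene_id[bb$origin == "tandem"] else NA
        dup <- if (any(bb$origin == "dup")) bb$gene_id[bb$origin == "dup"] else NA
        emit_copy(parent, base, tand, dup, stem, li)
      }
    }
  }
  protein <- vapply(cds, translate_cds, character(1))
  list(cds = cds, protein = protein,
       motif_positions = setNames(as.integer(pos), motifs$domain),
       substitutions = if (length(subs)) do.call(rbind, subs)
                       else data.frame(lineage = character(),
                                       branch = character(),
                                       n_subs = integer()))
}

#' Emit a qPCR Ct table with planted paralog-pair categories
#'
#' Every true paralog pair of species B (tandem plus dispersed duplicates) is
#' assigned one of the four divergence categories according to
#' `category_mix`, and Ct values across tissues are constructed so that
#' [categorize_pair()] at the default thresholds recovers exactly the planted
#' category. The reference gene has a constant Ct; not-detected is the
#' sentinel `"ND"`. Unpaired genes get random profiles (about 30 percent
#' silent, matching the share of family members with no detectable
#' expression).
#'
#' @param history result of [simulate_family_history()].
#' @param tau,fold thresholds the planting is designed against (defaults
#'   match [categorize_pair()]).
#' @return list with `ct` (long data.frame gene/sample/ct), `pairs`
#'   (gene_a, gene_b, planted `category`), `values` (the designed
#'   relative-expression matrix), `reference_gene`, `calibrator`.
#' @export
emit_expression <- function(history, tau = 0.05, fold = 2) {
  config <- history$config
  if (length(config$tissues) < 2L) stop("need at least two tissues")
  withr::with_seed(config$seed + 2L, emit_expression_(history, tau, fold))
}

emit_expression_ <- function(history, tau, fold) {
  config <- history$config
  tis <- config$tissues
  Tn <- length(tis)
  e1 <- tis[1]; e2 <- tis[2]; elast <- tis[Tn]
  genes_b <- history$genes$gene_id[history$genes$species == "SpB"]
  pairs <- rbind(
    history$tandem_pairs[, c("gene_a", "gene_b")],
    history$dup_pairs[history$dup_pairs$species == "SpB",
                      c("gene_a", "gene_b"), drop = FALSE])
  if (nrow(pairs)) {
    # categories are planted per gene, so a gene can only appear in one
    # planted pair; keep a maximal disjoint subset (greedy, in order)
    used <- character(0); keep <- logical(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      if (!pairs$gene_a[i] %in% used && !pairs$gene_b[i] %in% used) {
        keep[i] <- TRUE
        used <- c(used, pairs$gene_a[i], pairs$gene_b[i])
      }
    }
    pairs <- pairs[keep, , drop = FALSE]
    rownames(pairs) <- NULL
  }
  vals <- matrix(0, length(genes_b), Tn, dimnames = list(genes_b, tis))
  planted <- character(0)
  if (nrow(pairs)) {
    planted <- sample(c("I", "II", "III", "IV"), nrow(pairs), replace = TRUE,
                      prob = config$category_mix)
    for (i in seq_len(nrow(pairs))) {
      a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
      switch(planted[i],
        I = if (i %% 2L == 0L) {
          vals[a, c(e1, e2)] <- c(1, 3); vals[b, c(e1, e2)] <- c(1, 3)
        },  # odd pairs stay all-ND: the "neither expressed" face of I
        II = { vals[a, c(e1, e2)] <- c(1, 2 * fold)
               vals[b, c(e1, e2)] <- c(1, 1) },
        III = { vals[a, e2] <- 2
                if (Tn > 2L) vals[b, elast] <- 2 else vals[b, e1] <- 1 },
        IV = { vals[b, e2] <- 2 })
    }
  }
  paired_genes <- unique(c(pairs$gene_a, pairs$gene_b))
  for (g in setdiff(genes_b, paired_genes)) {
    if (stats::runif(1) < 0.3) next  # silent gene
    k <- sample(seq_len(Tn), 1L)
    chosen <- sample(tis, k)
    vals[g, chosen] <- 2^stats::runif(k, -2, 3)
    if (e1 %in% chosen) vals[g, e1] <- 1
  }
  ref <- "GAPDH"; ref_ct <- 20
  rows <- list()
  for (s in tis) rows[[length(rows) + 1L]] <-
    data.frame(gene = ref, sample = s, ct = as.character(ref_ct),
               stringsAsFactors = FALSE)
  for (g in genes_b) {
    offs <- if (vals[g, e1] >= tau) 3 else 0
    for (s in tis) {
      v <- vals[g, s]
      ctv <- if (v <= 0) "ND" else as.character(signif(ref_ct - log2(v) + offs, 12))
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, sample = s, ct = ctv, stringsAsFactors = FALSE)
    }
  }
  ct <- do.call(rbind, rows)
  pairs$category <- planted
  list(ct = ct, pairs = pairs, values = vals,
       reference_gene = ref, calibrator = e1)
}

#' Emit promoters with planted cis-elements
#'
#' Promoters are uniform-random backgrounds with instantiated IUPAC consensus
#' motifs inserted at recorded, non-overlapping positions on random strands.
#' The truth table lists every insertion.
#'
#' @param history result of [simulate_family_history()].
#' @param motifs motif dictionary, default [read_motif_dictionary()].
#' @param n_plant_range inclusive range of motif insertions per promoter.
#' @param ensure_absent names of motifs the random background must not
#'   contain (rejection sampling; keep this list short).
#' @return list with `promoters` (named character vector) and `truth`
#'   (data.frame gene_id, name, position, strand, instance).
#' @export
emit_promoters <- function(history, motifs = read_motif_dictionary(),
                           n_plant_range = c(3L, 8L),
                           ensure_absent = character(0)) {
  config <- history$config
  if (max(nchar(motifs$consensus)) > config$promoter_len)
    stop("motif longer than promoter")
  withr::with_seed(config$seed + 3L,
                   emit_promoters_(history, motifs, n_plant_range,
                                   ensure_absent))
}

emit_promoters_ <- function(history, motifs, n_plant_range, ensure_absent) {
  config <- history$config
  L <- config$promoter_len
  gene_ids <- history$genes$gene_id[history$genes$species == "SpB"]
  absent_motifs <- motifs[motifs$name %in% ensure_absent, , drop = FALSE]
  promoters <- character(0); truth <- list()
  for (g in gene_ids) {
    bg <- NULL
    for (try in 1:2000) {
      cand <- paste(sample(DNA4, L, replace = TRUE), collapse = "")
      if (nrow(absent_motifs) == 0L ||
          nrow(scan_promoter(cand, absent_motifs)) == 0L) { bg <- cand; break }
    }
    if (is.null(bg)) stop("could not build motif-free background for ", g)
    krange <- seq(n_plant_range[1], n_plant_range[2])
    k <- if (length(krange) == 1L) krange else sample(krange, 1L)
    occupied <- matrix(numeric(0), ncol = 2)
    for (j in seq_len(k)) {
      row <- motifs[sample(nrow(motifs), 1L), ]
      if (row$name %in% ensure_absent) next
      w <- nchar(row$consensus)
      placed <- FALSE
      for (try in 1:50) {
        p <- sample(L - w + 1L, 1L)
        if (nrow(occupied) == 0L ||
            all(p + w - 1L < occupied[, 1] | p > occupied[, 2])) {
          placed <- TRUE; break
        }
      }
      if (!placed) next
      inst <- iupac_instantiate(row$consensus)
      strand <- sample(c("+", "-"), 1L)
      ins <- if (strand == "+") inst else revcomp(inst)
      substr(bg, p, p + w - 1L) <- ins
      occupied <- rbind(occupied, c(p, p + w - 1L))
      truth[[length(truth) + 1L]] <- data.frame(
        gene_id = g, name = row$name, position = p, strand = strand,
        instance = inst, stringsAsFactors = FALSE)
    }
    promoters[[g]] <- bg
  }
  list(promoters = promoters,
       truth = if (length(truth)) do.call(rbind, truth)
               else data.frame(gene_id = character(), name = character(),
                               position = integer(), strand = character(),
                               instance = character()))
}
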