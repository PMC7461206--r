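#' Default conserved-domain motifs of the polygalacturonase family
#'
#' The four conserved domains used to recognise family members:
#' I `SPNTDGI`, II `GDDC`, III `CGPGHGIS`, IV `RIK`. Mismatch tolerance
#' defaults to 1 for the two long motifs (I, III) and 0 for the short ones
#' (II, IV), because a short motif matched loosely hits at random.
#'
#' @return data.frame with columns `domain`, `motif`, `tolerance`.
#' @export
pg_domain_motifs <- function() {
  data.frame(domain = c("I", "II", "III", "IV"),
             motif = c("SPNTDGI", "GDDC", "CGPGHGIS", "RIK"),
             tolerance = c(1L, 0L, 1L, 0L),
             stringsAsFactors = FALSE)
}

#' Scan a protein for the conserved family domains
#'
#' Approximate matching is Hamming distance (no indels): every window within
#' the per-domain mismatch tolerance is reported, and per domain the best hit
#' (fewest mismatches, ties broken leftmost) is flagged.
#'
#' @param protein amino-acid string (standard 20 letters plus X).
#' @param motifs data.frame as from [pg_domain_motifs()].
#' @param tolerance optional integer vector overriding `motifs$tolerance`.
#' @return data.frame with columns `domain`, `start` (1-based), `mismatches`,
#'   `best` (logical); zero rows if nothing matches.
#' @export
scan_domains <- function(protein, motifs = pg_domain_motifs(),
                         tolerance = NULL) {
  stopifnot_scalar_seq(protein, "protein")
  chars <- strsplit(toupper(protein), "")[[1]]
  if (any(!chars %in% c(AA20, "X")))
    stop("unknown residue character(s): ",
         paste(unique(chars[!chars %in% c(AA20, "X")]), collapse = ""))
  tol <- if (is.null(tolerance)) motifs$tolerance else tolerance
  if (length(tol) == 1L) tol <- rep(tol, nrow(motifs))
  out <- list()
  for (i in seq_len(nrow(motifs))) {
    m <- strsplit(motifs$motif[i], "")[[1]]
    L <- length(m)
    n_win <- length(chars) - L + 1L
    if (n_win < 1L) next
    mm <- integer(n_win)
    for (k in seq_len(L)) {
      mm <- mm + (chars[seq(k, k + n_win - 1L)] != m[k])
    }
    hit <- which(mm <= tol[i])
    if (length(hit) == 0L) next
    best <- hit[order(mm[hit], hit)][1L]
    out[[length(out) + 1L]] <- data.frame(
      domain = motifs$domain[i], start = hit, mismatches = mm[hit],
      best = hit == best, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(domain = character(), start = integer(),
                      mismatches = integer(), best = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Classify a protein as family member from its domain hits
#'
#' A protein carrying at least one of the four conserved domains is called a
#' family member; its composition is the set of domains hit.
#'
#' @param hits data.frame from [scan_domains()].
#' @return list with `is_pg` (logical) and `composition` (character vector).
#' @export
classify_pg <- function(hits) {
  comp <- sort(unique(hits$domain))
  comp <- comp[order(match(comp, c("I", "II", "III", "IV")))]
  list(is_pg = length(comp) > 0L, composition = comp)
}

# Average residue (free amino acid) masses in Da; peptide bond loses water.
aa_masses <- function() {
  c(A = 89.09, R = 174.20, N = 132.12, D = 133.10, C = 121.16,
    E = 147.13, Q = 146.15, G = 75.07, H = 155.16, I = 131.17,
    L = 131.17, K = 146.19, M = 149.21, F = 165.19, P = 115.13,
    S = 105.09, T = 119.12, W = 204.23, Y = 181.19, V = 117.15)
}

# Expasy-style pKa values for ionizable groups.
aa_pka <- function() {
  list(pos = c(Nterm = 9.09, K = 10.53, R = 12.48, H = 6.00),
       neg = c(Cterm = 2.34, D = 3.86, E = 4.25, C = 8.33, Y = 10.07))
}

net_charge_at_ph <- function(counts, ph, pka) {
  pos <- sum(counts[names(pka$pos)] / (1 + 10^(ph - pka$pos)))
  neg <- sum(-counts[names(pka$neg)] / (1 + 10^(pka$neg - ph)))
  pos + neg
}

#' Descriptive statistics for a protein sequence
#'
#' Molecular weight is the sum of residue monomer masses minus one water per
#' peptide bond. The isoelectric point is solved by bisection on the
#' Henderson-Hasselbalch net charge (termini plus ionizable side chains) to
#' `|charge| < 1e-4`.
#'
#' @param protein amino-acid string over the standard 20-letter alphabet.
#' @param masses named residue-mass vector (Da), default [aa_masses()].
#' @param pka pKa table as from `aa_pka()`.
#' @param water mass of water lost per peptide bond (default 18.02 Da).
#' @param signal_peptide optional externally supplied annotation, passed
#'   through unchanged (e.g. a length in residues, or NA).
#' @return list with `length`, `molecular_weight`, `isoelectric_point`,
#'   `signal_peptide`.
#' @export
protein_stats <- function(protein, masses = aa_masses(), pka = aa_pka(),
                          water = 18.02, signal_peptide = NA) {
  stopifnot_scalar_seq(protein, "protein")
  chars <- strsplit(toupper(protein), "")[[1]]
  if (any(!chars %in% AA20))
    stop("protein_stats requires the standard 20-residue alphabet")
  n <- length(chars)
  mw <- sum(masses[chars]) - (n - 1) * water
  counts <- c(Nterm = 1, Cterm = 1,
              K = sum(chars == "K"), R = sum(chars == "R"),
              H = sum(chars == "H"), D = sum(chars == "D"),
              E = sum(chars == "E"), C = sum(chars == "C"),
              Y = sum(chars == "Y"))
  lo <- 0; hi <- 14
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- net_charge_at_ph(counts, mid, pka)
    if (abs(q) < 1e-4) break
    if (q > 0) lo <- mid else hi <- mid
  }
  list(length = n, molecular_weight = unname(mw),
       isoelectric_point = mid, signal_peptide = signal_peptide)
}

#' Identify family members across a protein set
#'
#' Convenience wrapper running [scan_domains()], [classify_pg()] and
#' [protein_stats()] over a whole protein collection.
#'
#' @param proteins named character vector of protein sequences.
#' @param motifs motif definitions, default [pg_domain_motifs()].
#' @param signal_peptides optional named vector of externally supplied
#'   signal-peptide annotations.
#' @return data.frame with one row per protein: `gene_id`, `is_pg`,
#'   `composition` (comma-joined), `length`, `molecular_weight`,
#'   `isoelectric_point`, `signal_peptide`.
#' @export
identify_family <- function(proteins, motifs = pg_domain_motifs(),
                            signal_peptides = NULL) {
  rows <- lapply(names(proteins), function(id) {
    hits <- scan_domains(proteins[[id]], motifs)
    cls <- classify_pg(hits)
    st <- protein_stats(gsub("X", "A", proteins[[id]]))
    data.frame(gene_id = id, is_pg = cls$is_pg,
               composition = paste(cls$composition, collapse = ","),
               length = st$length,
               molecular_weight = st$molecular_weight,
               isoelectric_point = st$isoelectric_point,
               signal_peptide = if (is.null(signal_peptides)) NA
                                else unname(signal_peptides[id]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
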