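#' Intron phases of a gene model
#'
#' Phases are computed from coding (CDS) exon lengths in transcription order:
#' the phase of intron k is the cumulative coding length of exons 1..k mod 3
#' (0 = intron falls between codons, 1/2 = after the first/second nucleotide
#' of a codon). A total coding length not divisible by 3 is recorded as a
#' warning but phases are still returned.
#'
#' @param model a single gene model (list with `gene_id` and `exons` in
#'   transcription order), e.g. one element of [read_gene_models()].
#' @return list with `gene_id`, `exon_count`, `phases` (integer vector of
#'   length `exon_count - 1`) and `frame_ok` (logical).
#' @export
intron_phases <- function(model) {
  ex <- model$exons
  lens <- ex[, "end"] - ex[, "start"] + 1L
  if (any(lens <= 0L)) stop("non-positive exon length in ", model$gene_id)
  total <- sum(lens)
  frame_ok <- total %% 3L == 0L
  if (!frame_ok)
    warning("total coding length of ", model$gene_id,
            " not divisible by 3 (", total, ")")
  phases <- if (length(lens) > 1L) as.integer(cumsum(lens)[-length(lens)] %% 3L)
            else integer(0)
  list(gene_id = model$gene_id, exon_count = length(lens),
       phases = phases, frame_ok = frame_ok)
}

#' Chromosome and strand distribution of a gene set
#'
#' Counts genes per chromosome, splits named chromosomes from scaffold
#' fragments by a regular expression, and tallies transcription direction on
#' the chromosome-localized subset.
#'
#' @param models `pg_gene_models` list.
#' @param chromosome_pattern regex that identifies named chromosomes
#'   (default `^[A-Z][0-9]{2}$`, matching e.g. `C01`..`C09`).
#' @return list with `per_chromosome` (named integer vector, named
#'   chromosomes only, sorted by name), `n_chromosomal`, `n_scaffold`,
#'   `strand` (counts of `+` and `-` among chromosome-localized genes) and
#'   `total`.
#' @export
chromosome_summary <- function(models, chromosome_pattern = "^[A-Z][0-9]{2}$") {
  if (length(models) == 0L) {
    return(list(per_chromosome = integer(0), n_chromosomal = 0L,
                n_scaffold = 0L, strand = c(`+` = 0L, `-` = 0L), total = 0L))
  }
  chrom <- vapply(models, `[[`, character(1), "chromosome")
  strand <- vapply(models, `[[`, character(1), "strand")
  on_chrom <- grepl(chromosome_pattern, chrom)
  per <- table(chrom[on_chrom])
  per <- setNames(as.integer(per), names(per))
  per <- per[order(names(per))]
  list(per_chromosome = per,
       n_chromosomal = sum(on_chrom),
       n_scaffold = sum(!on_chrom),
       strand = c(`+` = sum(strand[on_chrom] == "+"),
                  `-` = sum(strand[on_chrom] == "-")),
       total = length(models))
}

#' Per-gene structure table
#'
#' @param models `pg_gene_models` list.
#' @return data.frame: `gene_id`, `chromosome`, `strand`, `exon_count`,
#'   `phases` (comma-joined).
#' @export
gene_structure_table <- function(models) {
  rows <- lapply(models, function(m) {
    ip <- suppressWarnings(intron_phases(m))
    data.frame(gene_id = m$gene_id, chromosome = m$chromosome,
               strand = m$strand, exon_count = ip$exon_count,
               phases = paste(ip$phases, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
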