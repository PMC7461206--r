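#' Load a cis-element motif dictionary
#'
#' The packaged default dictionary (`inst/extdata/cis_element_motifs.tsv`)
#' holds literature-standard IUPAC consensus strings for the commonly scanned
#' plant promoter elements (hormone response, abiotic stress, light,
#' development); it is data, not code, so users can substitute their own
#' export (e.g. from a PlantCARE query).
#'
#' @param path TSV with columns `name`, `category`, `consensus`; default the
#'   packaged dictionary.
#' @return data.frame with the three columns, names unique.
#' @export
read_motif_dictionary <- function(path = system.file("extdata",
                                                     "cis_element_motifs.tsv",
                                                     package = "pgfam")) {
  d <- read_tsv_file(path)
  need <- c("name", "category", "consensus")
  if (!all(need %in% names(d))) stop("dictionary needs columns name/category/consensus")
  if (anyDuplicated(d$name)) stop("duplicate motif names in dictionary")
  d$consensus <- toupper(d$consensus)
  iupac <- c("A","C","G","T","R","Y","S","W","K","M","B","D","H","V","N")
  bad <- vapply(strsplit(d$consensus, ""), function(ch) any(!ch %in% iupac),
                logical(1))
  if (any(bad)) stop("invalid IUPAC code in consensus: ",
                     paste(d$name[bad], collapse = ", "))
  d
}

#' Scan a promoter for IUPAC consensus motifs on both strands
#'
#' Every exact IUPAC-consistent match is reported (overlapping matches
#' included). Minus-strand hits are matches of the reverse complement of the
#' consensus; positions are 1-based on the plus strand.
#'
#' @param promoter nucleotide string over A/C/G/T/N.
#' @param motifs data.frame as from [read_motif_dictionary()].
#' @return data.frame: `name`, `category`, `position`, `strand`.
#' @export
scan_promoter <- function(promoter, motifs = read_motif_dictionary()) {
  stopifnot_scalar_seq(promoter, "promoter")
  subj <- Biostrings::DNAString(toupper(promoter))
  iupac <- c("A","C","G","T","R","Y","S","W","K","M","B","D","H","V","N")
  out <- list()
  for (i in seq_len(nrow(motifs))) {
    cons <- toupper(motifs$consensus[i])
    if (any(!strsplit(cons, "")[[1]] %in% iupac))
      stop("invalid IUPAC code in motif ", motifs$name[i])
    pat <- Biostrings::DNAString(cons)
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else Biostrings::reverseComplement(pat)
      m <- Biostrings::matchPattern(p, subj, fixed = "subject")
      if (length(m) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        name = motifs$name[i], category = motifs$category[i],
        position = BiocGenerics::start(m), strand = strand,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(name = character(), category = character(),
                      position = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$position, res$name, res$strand), , drop = FALSE]
}

#' Scan a set of promoters
#'
#' @param promoters named character vector of promoter sequences.
#' @param motifs motif dictionary.
#' @return data.frame with a leading `gene_id` column plus the
#'   [scan_promoter()] columns.
#' @export
scan_promoters <- function(promoters, motifs = read_motif_dictionary()) {
  rows <- lapply(names(promoters), function(g) {
    h <- scan_promoter(promoters[[g]], motifs)
    if (nrow(h) == 0L) return(NULL)
    cbind(gene_id = g, h, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(gene_id = character(), name = character(),
                      category = character(), position = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Promoter counts per element and per functional category
#'
#' Counts promoters (not hits): a promoter contributes once per element it
#' contains, and once per category any of whose member elements it contains.
#'
#' @param hits data.frame from [scan_promoters()].
#' @param motifs motif dictionary (defines the full element/category universe
#'   so zero-hit elements are reported as 0).
#' @return list with `per_element` and `per_category` named integer vectors.
#' @export
summarize_elements <- function(hits, motifs = read_motif_dictionary()) {
  per_element <- setNames(integer(nrow(motifs)), motifs$name)
  for (el in motifs$name) {
    per_element[el] <- length(unique(hits$gene_id[hits$name == el]))
  }
  cats <- unique(motifs$category)
  per_category <- setNames(integer(length(cats)), cats)
  for (ca in cats) {
    members <- motifs$name[motifs$category == ca]
    per_category[ca] <- length(unique(hits$gene_id[hits$name %in% members]))
  }
  list(per_element = per_element, per_category = per_category)
}
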