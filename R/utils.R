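# Shared small helpers. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

# round() in R is round-half-even; published percentages use half-up.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

read_tsv_file <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Species tag is the ID prefix before the first separator ("SpA_g1" -> "SpA").
split_species_prefix <- function(ids, sep = "_") {
  pos <- regexpr(sep, ids, fixed = TRUE)
  if (any(pos < 0)) {
    stop("gene ID(s) without species prefix separator '", sep, "': ",
         paste(head(ids[pos < 0], 3), collapse = ", "))
  }
  substr(ids, 1L, pos - 1L)
}

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

DNA4 <- c("A","C","G","T")

revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTNacgtn", "TGCANtgcan",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

stopifnot_scalar_seq <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || !nzchar(x))
    stop(what, " must be a single non-empty string")
  invisible(x)
}
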