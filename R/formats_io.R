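#' Read a FASTA file into a validated named character vector
#'
#' Sequences are uppercased and returned in file order with one element per
#' record (names are the first whitespace-delimited token of each header).
#' Validation is strict: duplicate IDs, empty sequences and residues outside
#' the alphabet implied by `kind` are errors, not repairs. CDS records must
#' have length divisible by 3.
#'
#' @param path path to a FASTA file.
#' @param kind one of `"protein"`, `"cds"`, `"promoter"`; controls the
#'   accepted alphabet (amino acids + X for proteins, ACGTN for nucleotides).
#' @return named character vector of sequences with attribute `kind`.
#' @export
read_fasta <- function(path, kind = c("protein", "cds", "promoter")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not parseable as FASTA: ", path,
                                           " (", conditionMessage(e), ")"))
  if (length(set) == 0L) stop("FASTA file has no records: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA record with empty ID")
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  alphabet <- if (kind == "protein") c(AA20, "X", "-", "*") else c(DNA4, "N", "-")
  bad <- vapply(seqs, function(s) {
    any(!strsplit(s, "")[[1]] %in% alphabet)
  }, logical(1))
  if (any(bad)) {
    stop("sequence with characters outside the ", kind, " alphabet: ",
         paste(ids[bad], collapse = ", "))
  }
  if (kind == "cds") {
    ungapped <- nchar(gsub("-", "", seqs, fixed = TRUE))
    if (any(ungapped %% 3L != 0L)) {
      stop("CDS length not divisible by 3: ",
           paste(ids[ungapped %% 3L != 0L], collapse = ", "))
    }
  }
  attr(seqs, "kind") <- kind
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses `gene` plus `CDS` (preferred) or `exon` features and groups coding
#' segments per gene. Exons are returned in transcription (5'->3') order, so
#' minus-strand genes have their highest-coordinate exon first. An exon/CDS
#' without a parent gene, overlapping exons, or a gene with no coding feature
#' are errors.
#'
#' @param path path to a GFF3 file.
#' @return object of class `pg_gene_models`: a named list of gene models,
#'   each a list with `gene_id`, `chromosome`, `strand` and `exons` (two-column
#'   matrix of 1-based inclusive start/end in transcription order).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  genes <- gr[typ == "gene"]
  if (length(genes) == 0L) stop("GFF3 contains no gene features: ", path)
  gene_ids <- as.character(genes$ID)
  segs <- gr[typ %in% c("CDS", "exon")]
  parent <- vapply(as.list(segs$Parent), function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[[1]])
  }, character(1))
  if (any(is.na(parent))) stop("exon/CDS feature without a Parent attribute")
  # parents may reference an mRNA; follow one level up if needed
  mrna <- gr[typ == "mRNA"]
  if (length(mrna) > 0L) {
    mrna_parent <- vapply(as.list(mrna$Parent), function(p) as.character(p[[1]]),
                          character(1))
    names(mrna_parent) <- as.character(mrna$ID)
    hit <- parent %in% names(mrna_parent)
    parent[hit] <- mrna_parent[parent[hit]]
  }
  if (any(!parent %in% gene_ids)) {
    stop("exon/CDS with parent not matching any gene: ",
         paste(unique(parent[!parent %in% gene_ids]), collapse = ", "))
  }
  seg_type <- as.character(segs$type)
  models <- lapply(seq_along(genes), function(i) {
    gid <- gene_ids[i]
    mine <- which(parent == gid)
    use <- mine[seg_type[mine] == "CDS"]
    if (length(use) == 0L) use <- mine[seg_type[mine] == "exon"]
    if (length(use) == 0L)
      stop("gene without CDS/exon features: ", gid)
    st <- BiocGenerics::start(segs)[use]
    en <- BiocGenerics::end(segs)[use]
    o <- order(st)
    st <- st[o]; en <- en[o]
    if (any(st[-1] <= en[-length(en)]))
      stop("overlapping exons in gene: ", gid)
    strand <- as.character(BiocGenerics::strand(genes))[i]
    if (!strand %in% c("+", "-")) stop("gene without strand: ", gid)
    if (strand == "-") { st <- rev(st); en <- rev(en) }
    list(gene_id = gid,
         chromosome = as.character(GenomicRanges::seqnames(genes))[i],
         strand = strand,
         exons = cbind(start = st, end = en))
  })
  names(models) <- gene_ids
  structure(models, class = "pg_gene_models")
}

#' Write gene models to GFF3
#'
#' @param models a `pg_gene_models` list as returned by [read_gene_models()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gene_models <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (m in models) {
    ex <- m$exons
    span <- range(c(ex[, "start"], ex[, "end"]))
    writeLines(sprintf("%s\tpgfam\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       m$chromosome, span[1], span[2], m$strand, m$gene_id), con)
    ord <- order(ex[, "start"])  # GFF convention: ascending coordinates
    for (k in ord) {
      writeLines(sprintf("%s\tpgfam\tCDS\t%d\t%d\t.\t%s\t.\tParent=%s",
                         m$chromosome, ex[k, "start"], ex[k, "end"],
                         m$strand, m$gene_id), con)
    }
  }
  invisible(path)
}

#' Read a Newick tree with internal-node supports
#'
#' Thin validating wrapper around [ape::read.tree()]. Numeric internal node
#' labels are interpreted as bootstrap percentages (0-100). Negative branch
#' lengths and unparseable text are errors.
#'
#' @param text Newick string, or `file` a path (exactly one of the two).
#' @param file optional path to a Newick file.
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  tr <- tryCatch({
    if (!is.null(file)) ape::read.tree(file = file)
    else ape::read.tree(text = text)
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("invalid Newick input")
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch length in Newick input")
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels")
  tr
}

#' Write a tree as Newick text
#'
#' Branch lengths are kept to 6 decimal places so that
#' `read_newick(write_newick(t))` round-trips topology, lengths and supports.
#'
#' @param tree an [ape::phylo] object.
#' @return Newick string.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree, digits = 6)
}

#' Extract numeric supports from a tree's internal node labels
#'
#' @param tree an [ape::phylo] object.
#' @return numeric vector of length `tree$Nnode` (NA where no label).
#' @export
tree_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}
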