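#' @importFrom Biostrings readBStringSet readQualityScaledDNAStringSet
#'   DNAStringSet BStringSet PhredQuality QualityScaledDNAStringSet
#'   writeXStringSet writeQualityScaledXStringSet
NULL

validate_labels <- function(labels, what) {
  if (any(!nzchar(labels))) stop("empty ", what, " label")
  dup <- labels[duplicated(labels)]
  if (length(dup)) {
    stop("duplicate ", what, " label(s): ",
      paste(unique(dup), collapse = ", "))
  }
  invisible(labels)
}

validate_alphabet <- function(seqs, extra = "N-") {
  pat <- paste0("[^ACGT", extra, "]")
  bad <- grepl(pat, seqs)
  if (any(bad)) {
    offender <- regmatches(seqs[bad][1],
      regexpr(pat, seqs[bad][1]))
    stop("unsupported character '", offender, "' in sequence ",
      names(seqs)[bad][1],
      " (IUPAC ambiguity codes other than N are not accepted)")
  }
  invisible(seqs)
}

#' Read / write FASTA
#'
#' Sequences are normalized to upper case and validated against the
#' alphabet {A,C,G,T,N,-}; duplicate or empty labels and empty sequences
#' are errors. The writer is deterministic byte-for-byte (LF line
#' endings, fixed wrap width).
#'
#' @param path file path (reading accepts gzip and CRLF input).
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x)) # first header token
  validate_labels(names(seqs), "FASTA")
  if (any(!nzchar(seqs))) {
    stop("empty sequence for: ",
      paste(names(seqs)[!nzchar(seqs)], collapse = ", "))
  }
  validate_alphabet(seqs)
  seqs
}

#' @param records named character vector of sequences.
#' @param wrap line width for sequence wrapping (default 80).
#' @rdname read_fasta
#' @export
write_fasta <- function(records, path, wrap = 80) {
  validate_labels(names(records), "FASTA")
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(records)) {
    writeLines(c(paste0(">", names(records)[i]),
      substring(records[i], seq(1, nchar(records[i]), wrap),
        pmin(seq(1, nchar(records[i]), wrap) + wrap - 1,
          nchar(records[i])))),
      con, sep = "\n")
  }
  invisible(path)
}

#' Read / write FASTQ (Sanger quality encoding)
#'
#' Four-line records with phred+33 qualities; gzip input is read
#' transparently and a path ending in `.gz` is written compressed.
#'
#' @param path file path.
#' @return `read_fastq`: list with `sequences` and `qualities`, both named
#'   character vectors.
#' @export
read_fastq <- function(path) {
  # the quality pairing warns about dropping its own bookkeeping metadata
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  seqs <- toupper(as.character(x))
  quals <- as.character(Biostrings::quality(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  names(quals) <- names(seqs)
  validate_labels(names(seqs), "FASTQ")
  validate_alphabet(seqs, extra = "N")
  if (any(nchar(seqs) != nchar(quals))) {
    stop("sequence/quality length mismatch")
  }
  list(sequences = seqs, qualities = quals)
}

#' @param sequences named character vector of reads.
#' @param qualities quality strings; defaults to fixed Q40 (`I`).
#' @rdname read_fastq
#' @export
write_fastq <- function(sequences, path, qualities = NULL) {
  validate_labels(names(sequences), "FASTQ")
  if (is.null(qualities)) {
    qualities <- vapply(nchar(sequences),
      function(n) strrep(rawToChar(as.raw(40L + 33L)), n), character(1))
  }
  if (any(nchar(sequences) != nchar(qualities))) {
    stop("sequence/quality length mismatch")
  }
  q <- Biostrings::PhredQuality(unname(qualities))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(sequences), q)
  # the pairing stores bookkeeping metadata columns the FASTQ writer
  # would warn about dropping
  suppressWarnings(Biostrings::writeQualityScaledXStringSet(x, path,
    compress = grepl("\\.gz$", path)))
  invisible(path)
}

#' Read / write Newick trees
#'
#' Thin wrappers over \pkg{ape} with validation: duplicate leaf labels are
#' an error, and missing branch lengths are an error when lengths are
#' required. Written lengths survive a round trip to well below 1e-9.
#'
#' @param path file path.
#' @param require_lengths error when the tree lacks branch lengths
#'   (default `TRUE`).
#' @return `read_newick`: a `phylo` object.
#' @export
read_newick <- function(path, require_lengths = TRUE) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  validate_labels(tree$tip.label, "leaf")
  if (require_lengths &&
      (is.null(tree$edge.length) || anyNA(tree$edge.length))) {
    stop("tree is missing branch lengths")
  }
  tree
}

#' @param tree a `phylo` object.
#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}

#' Read / write labelled matrices as TSV
#'
#' Header row of column names plus a leading label column. Lines starting
#' with `#` are skipped on read (output headers carry run metadata there).
#' `type = "presence"` enforces 0/1 entries; `type = "distance"` enforces
#' symmetry and a zero diagonal.
#'
#' @param path file path.
#' @param type `"presence"`, `"distance"` or `"plain"`.
#' @return `read_matrix_tsv`: a numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path, type = c("plain", "presence",
                                           "distance")) {
  type <- match.arg(type)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  ncells <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (length(unique(ncells)) != 1L) {
    stop("ragged rows in matrix TSV: ", path)
  }
  df <- read.delim(text = paste(lines, collapse = "\n"),
    check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("non-numeric cell in matrix TSV: ", path)
  if (type == "presence" && !all(m %in% c(0, 1))) {
    stop("presence/absence matrix must contain only 0 and 1")
  }
  if (type == "distance") {
    check_square_distance(m)
  }
  if (type == "presence") storage.mode(m) <- "integer"
  m
}

#' @param m matrix with dimnames.
#' @param comment optional character vector of header comment lines
#'   (written prefixed with `#`).
#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(m, path, comment = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(comment)) {
    writeLines(paste0("# ", comment), con, sep = "\n")
  }
  writeLines(paste(c("sample", colnames(m)), collapse = "\t"), con,
    sep = "\n")
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], format(m[i, ], trim = TRUE,
      scientific = FALSE)), collapse = "\t"), con, sep = "\n")
  }
  invisible(path)
}

#' Write a square PHYLIP distance matrix
#'
#' Taxon count on the first line, then one row per taxon: the label padded
#' to 10 characters followed by the distances.
#'
#' @param d symmetric distance matrix with labels.
#' @param path output path.
#' @export
write_phylip_distance <- function(d, path) {
  check_square_distance(d)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con, sep = "\n")
  for (i in seq_len(nrow(d))) {
    writeLines(paste0(sprintf("%-10s", substr(rownames(d)[i], 1, 10)),
      paste(sprintf("%.9f", d[i, ]), collapse = " ")), con, sep = "\n")
  }
  invisible(path)
}
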