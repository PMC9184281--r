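#' Read an A3M alignment
#'
#' A3M is FASTA-like: uppercase letters and `-` occupy match columns,
#' lowercase letters are insertions relative to the query. The first record
#' is taken as the query.
#'
#' @param x a file path, a single string containing the document, or a
#'   character vector of lines.
#' @return An [msa].
#' @examples
#' read_a3m(">q\nACDE\n>h\nAC-E\n")
#' @export
read_a3m <- function(x) {
  lines <- as_text_lines(x)
  rec <- parse_fasta_records(lines)
  if (length(rec$header) == 0) abort("empty alignment input")
  msa(header = rec$header, aligned = rec$seq)
}

#' Write an MSA as an A3M document
#'
#' @param x an [msa].
#' @param path optional output file; when `NULL` the document is returned as
#'   a single string.
#' @return The A3M document (invisibly when written to `path`).
#' @export
write_a3m <- function(x, path = NULL) {
  stopifnot(is_msa(x))
  doc <- paste0(">", x$header, "\n", x$aligned, "\n", collapse = "")
  if (is.null(path)) return(doc)
  writeLines(sub("\n$", "", doc), path)
  invisible(doc)
}

#' Read an alignment in any of the supported formats
#'
#' Supported formats: `a3m`, `aligned_fasta` (alias `fasta`), `stockholm`
#' (alias `sto`) and `clustal`. Non-A3M inputs are column-aligned; columns
#' where the query carries a gap are converted to lowercase insertions so the
#' result is an equivalent query-anchored [msa] regardless of the input
#' dialect. Stockholm annotation lines (`#=GF`, `#=GC`, ...) are ignored.
#'
#' @param x a file path, a single string, or a character vector of lines.
#' @param format one of `"a3m"`, `"aligned_fasta"`, `"fasta"`,
#'   `"stockholm"`, `"sto"`, `"clustal"`.
#' @return An [msa].
#' @export
read_alignment <- function(x, format = c("a3m", "aligned_fasta", "fasta",
                                         "stockholm", "sto", "clustal")) {
  format <- match.arg(format)
  switch(format,
    a3m = read_a3m(x),
    aligned_fasta = ,
    fasta = read_aligned_fasta(x),
    stockholm = ,
    sto = read_stockholm(x),
    clustal = read_clustal(x)
  )
}

# ---- internals ------------------------------------------------------------

as_text_lines <- function(x) {
  if (length(x) == 1 && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

parse_fasta_records <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  is_hdr <- startsWith(lines, ">")
  if (length(lines) > 0 && !is_hdr[[1]]) {
    abort("parse failure at line 1: expected '>' header")
  }
  idx <- cumsum(is_hdr)
  header <- sub("^>", "", lines[is_hdr])
  seq <- vapply(split(lines[!is_hdr], idx[!is_hdr]),
                paste0, character(1), collapse = "")
  if (length(seq) < length(header)) {
    # records with no sequence line
    got <- as.integer(names(seq))
    full <- rep("", length(header))
    full[got] <- seq
    seq <- full
  }
  list(header = header, seq = unname(seq))
}

# column-aligned rows (all equal length, query = first row) -> A3M rows
aligned_columns_to_a3m <- function(header, seq) {
  if (length(seq) == 0) abort("empty alignment input")
  seq <- toupper(chartr(".", "-", seq))
  L <- unique(nchar(seq))
  if (length(L) != 1) {
    abort(sprintf("rows are not column-aligned (lengths %s)",
                  paste(sort(unique(nchar(seq))), collapse = ", ")))
  }
  chars <- strsplit(seq, "", fixed = TRUE)
  qgap <- chars[[1]] == "-"
  a3m <- vapply(chars, function(cc) {
    out <- character(length(cc))
    out[!qgap] <- cc[!qgap]
    ins <- qgap & cc != "-"
    out[ins] <- tolower(cc[ins])
    paste0(out[!qgap | ins], collapse = "")
  }, character(1))
  msa(header = header, aligned = a3m)
}

read_aligned_fasta <- function(x) {
  rec <- parse_fasta_records(as_text_lines(x))
  aligned_columns_to_a3m(rec$header, rec$seq)
}

# Stockholm 1.0: "name  alignedseq" lines, possibly in several blocks;
# '#'-prefixed annotation and the '//' terminator are skipped
read_stockholm <- function(x) {
  lines <- as_text_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  keep <- !startsWith(lines, "#") & !startsWith(lines, "//")
  seqs <- list()
  order <- character(0)
  for (ln in lines[keep]) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) < 2) {
      abort(sprintf("parse failure in Stockholm input at line: '%s'", ln))
    }
    nm <- parts[[1]]
    if (is.null(seqs[[nm]])) {
      seqs[[nm]] <- parts[[2]]
      order <- c(order, nm)
    } else {
      seqs[[nm]] <- paste0(seqs[[nm]], parts[[2]])
    }
  }
  aligned_columns_to_a3m(order, unlist(seqs[order], use.names = FALSE))
}

# Clustal: a header line, then blocks of "name  sequence [count]" rows;
# conservation lines start with whitespace and are skipped
read_clustal <- function(x) {
  lines <- as_text_lines(x)
  if (length(lines) == 0 || !grepl("^CLUSTAL", lines[[1]], ignore.case = TRUE)) {
    abort("parse failure at line 1: expected a CLUSTAL header")
  }
  lines <- lines[-1]
  seqs <- list()
  order <- character(0)
  for (ln in lines) {
    if (!nzchar(trimws(ln)) || grepl("^\\s", ln)) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) < 2) {
      abort(sprintf("parse failure in Clustal input at line: '%s'", ln))
    }
    nm <- parts[[1]]
    seg <- parts[[2]]
    if (is.null(seqs[[nm]])) {
      seqs[[nm]] <- seg
      order <- c(order, nm)
    } else {
      seqs[[nm]] <- paste0(seqs[[nm]], seg)
    }
  }
  aligned_columns_to_a3m(order, unlist(seqs[order], use.names = FALSE))
}

#' Sequence identifiers of an MSA
#'
#' Headers are split at the first whitespace; the full header is retained in
#' the `header` column as the description.
#'
#' @param x an [msa].
#' @return character vector of identifiers.
#' @export
sequence_ids <- function(x) {
  stopifnot(is_msa(x))
  sub("\\s.*$", "", x$header)
}
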