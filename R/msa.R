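#' Query-anchored multiple sequence alignments
#'
#' An `msa` is a tibble with one row per aligned sequence and columns
#' `header`, `aligned`, `evalue`, `qstart`, `qend`, `qlen`, `taxid` and
#' `accession`. The first row is the query. Aligned strings follow the A3M
#' convention: uppercase letters and `-` occupy match columns (one per query
#' residue), lowercase letters are insertions relative to the query and
#' occupy no query column. The query row itself contains neither gaps nor
#' lowercase characters, and every row has exactly as many match columns as
#' the query has residues.
#'
#' @param header character vector of sequence identifiers/descriptions.
#' @param aligned character vector of aligned sequences (A3M convention).
#' @param evalue,taxid,accession optional per-row metadata (recycled `NA`).
#' @param qstart,qend,qlen optional 1-based inclusive query span per row.
#'
#' @return A tibble of class `msa`.
#' @examples
#' m <- msa(header = c("q", "h1"), aligned = c("ACDE", "AC-E"))
#' query_length(m)
#' @export
msa <- function(header, aligned, evalue = NA_real_,
                qstart = NA_integer_, qend = NA_integer_, qlen = NA_integer_,
                taxid = NA_integer_, accession = NA_character_) {
  n <- length(aligned)
  stopifnot(length(header) == n)
  out <- tibble(
    header = as.character(header),
    aligned = as.character(aligned),
    evalue = rep_len(as.double(evalue), n),
    qstart = rep_len(as.integer(qstart), n),
    qend = rep_len(as.integer(qend), n),
    qlen = rep_len(as.integer(qlen), n),
    taxid = rep_len(as.integer(taxid), n),
    accession = rep_len(as.character(accession), n)
  )
  as_msa(out)
}

#' Mark a data frame of aligned rows as an `msa` and validate it
#'
#' @param x a data frame with at least `header` and `aligned` columns.
#' @return `x` as a validated `msa` tibble.
#' @export
as_msa <- function(x) {
  x <- as_tibble(x)
  for (col in c("evalue")) if (is.null(x[[col]])) x[[col]] <- NA_real_
  for (col in c("qstart", "qend", "qlen", "taxid")) {
    if (is.null(x[[col]])) x[[col]] <- NA_integer_
  }
  if (is.null(x[["accession"]])) x[["accession"]] <- NA_character_
  class(x) <- unique(c("msa", class(x)))
  validate_msa(x)
}

#' @export
is_msa <- function(x) inherits(x, "msa")

validate_msa <- function(x) {
  if (nrow(x) == 0) abort("an MSA needs at least a query row")
  q <- x$aligned[[1]]
  if (grepl("-", q, fixed = TRUE) || grepl("[a-z]", q)) {
    abort("query row must contain no gaps and no lowercase insertions")
  }
  nm <- match_column_count(x$aligned)
  bad <- which(nm != nm[[1]])
  if (length(bad) > 0) {
    abort(sprintf(
      "record '%s' has %d match columns; query has %d",
      x$header[[bad[[1]]]], nm[[bad[[1]]]], nm[[1]]
    ))
  }
  span <- !is.na(x$qstart) & !is.na(x$qend) & !is.na(x$qlen)
  if (any(span) &&
      any(x$qstart[span] > x$qend[span] | x$qend[span] > x$qlen[span])) {
    abort("query spans must satisfy qstart <= qend <= qlen")
  }
  x
}

#' @rdname msa
#' @param x an `msa`.
#' @export
query_length <- function(x) {
  stopifnot(is_msa(x))
  match_column_count(x$aligned[[1]])
}

# number of match columns (uppercase + '-') per aligned string
match_column_count <- function(aligned) {
  nchar(gsub("[a-z]", "", aligned))
}

# match-column string: lowercase insertions removed
match_string <- function(aligned) {
  gsub("[a-z]", "", aligned)
}

# integer-encode match columns of aligned strings into an n x L matrix
# (0 gap, 1..20 residues, 21 X); unknown characters map to X
encode_rows <- function(aligned) {
  ms <- match_string(aligned)
  L <- nchar(ms[[1]])
  stopifnot(all(nchar(ms) == L))
  code <- aa_code()
  chars <- matrix(unlist(strsplit(ms, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(ms), ncol = L, byrow = TRUE)
  m <- matrix(code[chars], nrow = length(ms), ncol = L)
  m[is.na(m)] <- 21L
  storage.mode(m) <- "integer"
  m
}

#' Fractional identity of aligned rows to the query
#'
#' Identity is the number of match columns carrying the same residue as the
#' query, divided by the query length. Lowercase insertions occupy no query
#' column and are ignored; `X` and gaps never count as a match.
#'
#' @param row character vector of aligned strings (A3M convention), or an
#'   `msa` (in which case identities of every non-query row to the query are
#'   returned).
#' @param query the query's aligned string; ignored when `row` is an `msa`.
#' @return numeric vector of fractions in `[0, 1]`.
#' @examples
#' query_identity("ACDF", "ACDE")
#' @export
query_identity <- function(row, query = NULL) {
  if (is_msa(row)) {
    query <- row$aligned[[1]]
    row <- row$aligned[-1]
  }
  stopifnot(!is.null(query))
  enc <- encode_rows(c(query, row))
  q <- enc[1, ]
  valid <- q >= 1L & q <= 20L
  apply(enc[-1, , drop = FALSE], 1, function(r) {
    sum(valid & r == q) / length(q)
  })
}

#' Fractional query coverage of aligned rows
#'
#' When a query span `(qstart, qend, qlen)` is present, coverage is
#' `(qend - qstart + 1) / qlen`; otherwise it is the fraction of match
#' columns holding a residue (insertions ignored).
#'
#' @param row an `msa`, or a character vector of aligned strings.
#' @param qstart,qend,qlen optional spans when `row` is a character vector.
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
query_coverage <- function(row, qstart = NA, qend = NA, qlen = NA) {
  if (is_msa(row)) {
    qstart <- row$qstart; qend <- row$qend; qlen <- row$qlen
    row <- row$aligned
  }
  n <- length(row)
  qstart <- rep_len(qstart, n); qend <- rep_len(qend, n)
  qlen <- rep_len(qlen, n)
  span <- !is.na(qstart) & !is.na(qend) & !is.na(qlen)
  out <- numeric(n)
  out[span] <- (qend[span] - qstart[span] + 1) / qlen[span]
  if (any(!span)) {
    ms <- match_string(row[!span])
    L <- nchar(ms)
    out[!span] <- ifelse(L == 0, 0,
                         (L - nchar(gsub("[^-]", "", ms))) / L)
  }
  out
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("# An MSA: %d rows, query length %d\n", nrow(x), query_length(x)))
  NextMethod()
}
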