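#' Hit tables
#'
#' A hit table is a tibble in an extended BLAST-tabular shape: one row per
#' homology hit with columns `query_id`, `target_id`, `fident` (fractional
#' identity), `evalue`, the query span (`qstart`, `qend`, `qlen`), the target
#' span (`tstart`, `tend`, `tlen`), `aligned_target` (the target aligned into
#' the query frame, A3M convention, padded to the full query length), and the
#' optional `cluster_id`, `taxid` and `accession` columns used by cluster
#' expansion and complex pairing.
#'
#' @param path a TSV file with a header line.
#' @return A tibble with the columns above.
#' @export
read_hit_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("query_id", "target_id", "fident", "evalue",
            "qstart", "qend", "qlen", "aligned_target")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("hit table missing columns: ", paste(miss, collapse = ", ")))
  }
  for (col in c("tstart", "tend", "tlen", "taxid")) {
    if (is.null(x[[col]])) x[[col]] <- NA_integer_
  }
  for (col in c("cluster_id", "accession")) {
    if (is.null(x[[col]])) x[[col]] <- NA_character_
  }
  x
}

#' @rdname read_hit_table
#' @param hits a hit-table tibble.
#' @export
write_hit_table <- function(hits, path) {
  readr::write_tsv(hits, path)
  invisible(hits)
}

#' Read a cluster-membership table
#'
#' Tab-separated with header and columns `cluster_id`, `member_id`,
#' `aligned_member`, `aligned_representative`: each member stores its
#' pairwise alignment to the cluster representative (two equal-length gapped
#' strings). By convention the first row of each cluster is the
#' representative (aligned to itself).
#'
#' @param path a TSV file.
#' @return A tibble.
#' @export
read_cluster_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("cluster_id", "member_id", "aligned_member",
            "aligned_representative")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("cluster table missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  x
}

#' Accept hits by E-value
#'
#' Keeps hits with `evalue` strictly below `max_evalue`, preserving order.
#'
#' @param hits a hit-table tibble.
#' @param max_evalue acceptance threshold, default 0.1.
#' @return The accepted hits.
#' @export
evalue_accept <- function(hits, max_evalue = 0.1) {
  if (any(hits$evalue < 0, na.rm = TRUE)) abort("negative E-value in hit table")
  hits[!is.na(hits$evalue) & hits$evalue < max_evalue, , drop = FALSE]
}

#' Expand accepted hits into cluster-member rows
#'
#' For every accepted hit (a hit to a cluster representative, aligned in the
#' query frame), produces one aligned row per cluster member by composing the
#' stored member-to-representative alignment with the representative-to-query
#' alignment through the shared representative residues. Each cluster's rows
#' are then reduced by the per-cluster 95% redundancy filter
#' ([stage1_cluster_filter()]) before joining the MSA.
#'
#' @param accepted_hits a hit-table tibble (after [evalue_accept()]).
#' @param clusters a cluster table (see [read_cluster_table()]).
#' @param max_seq_id per-cluster redundancy threshold, default 0.95.
#' @return An [msa]-shaped tibble of member rows (no query row).
#' @export
expand_cluster_hits <- function(accepted_hits, clusters, max_seq_id = 0.95) {
  by_cluster <- split(clusters, clusters$cluster_id)
  out <- vector("list", nrow(accepted_hits))
  for (h in seq_len(nrow(accepted_hits))) {
    hit <- accepted_hits[h, ]
    cl <- by_cluster[[hit$cluster_id]]
    if (is.na(hit$cluster_id) || is.null(cl)) {
      abort(sprintf("unknown cluster id '%s' for hit '%s'",
                    hit$cluster_id, hit$target_id))
    }
    ts <- if (!is.null(hit$tstart) && !is.na(hit$tstart)) hit$tstart else 1L
    rows <- vapply(seq_len(nrow(cl)), function(i) {
      compose_alignment(hit$aligned_target,
                        cl$aligned_member[[i]],
                        cl$aligned_representative[[i]],
                        tstart = ts)
    }, character(1))
    block <- msa_rows(
      header = cl$member_id, aligned = rows, evalue = hit$evalue,
      qstart = hit$qstart, qend = hit$qend, qlen = hit$qlen
    )
    out[[h]] <- stage1_cluster_filter(block, max_seq_id = max_seq_id)
  }
  bind_rows(out)
}

# bare aligned rows (not a full msa: no query-row requirement)
msa_rows <- function(header, aligned, evalue = NA_real_,
                     qstart = NA_integer_, qend = NA_integer_,
                     qlen = NA_integer_, taxid = NA_integer_,
                     accession = NA_character_) {
  n <- length(aligned)
  tibble(
    header = as.character(header), aligned = as.character(aligned),
    evalue = rep_len(as.double(evalue), n),
    qstart = rep_len(as.integer(qstart), n),
    qend = rep_len(as.integer(qend), n),
    qlen = rep_len(as.integer(qlen), n),
    taxid = rep_len(as.integer(taxid), n),
    accession = rep_len(as.character(accession), n)
  )
}

# Compose member -> representative -> query into a query-frame A3M row.
# rep_in_query: representative aligned in the query frame (A3M), its k-th
# letter being representative residue tstart - 1 + k (local alignments may
# truncate the representative's termini); aligned_member / aligned_rep: the
# stored pairwise alignment (equal-length gapped strings). Member residues on
# representative insertion positions stay insertions; member gaps on
# insertion positions are dropped (A3M carries no lowercase gap).
compose_alignment <- function(rep_in_query, aligned_member, aligned_rep,
                              tstart = 1L) {
  am <- strsplit(toupper(aligned_member), "", fixed = TRUE)[[1]]
  ar <- strsplit(toupper(aligned_rep), "", fixed = TRUE)[[1]]
  if (length(am) != length(ar)) {
    abort("member/representative alignment strings differ in length")
  }
  memb_at <- am[ar != "-"]          # member char per representative residue
  rq <- strsplit(rep_in_query, "", fixed = TRUE)[[1]]
  n_res <- sum(rq != "-")
  if (tstart - 1L + n_res > length(memb_at)) {
    abort("member alignment missing: fewer representative residues than hit alignment")
  }
  k <- tstart - 1L
  out <- character(length(rq))
  for (i in seq_along(rq)) {
    ch <- rq[[i]]
    if (ch == "-") { out[[i]] <- "-"; next }
    k <- k + 1L
    mc <- memb_at[[k]]
    if (ch %in% letters) {                 # representative insertion
      out[[i]] <- if (mc == "-") "" else tolower(mc)
    } else {
      out[[i]] <- if (mc == "-") "-" else toupper(mc)
    }
  }
  paste0(out, collapse = "")
}

#' Build the per-database and combined MSAs from precomputed hit tables
#'
#' The full construction workflow over two sequence databases (a UniRef-like
#' clustered database and an environmental database): hits are accepted at
#' E-value < 0.1, expanded to cluster members through the stored
#' representative alignments (with the per-cluster 95% filter), passed
#' through the score-per-column filter (0.8 bits, enabled at 100+ hits), and
#' finally reduced by the bucketed diversity filter. The two databases are
#' filtered independently; the combined MSA is the query followed by the
#' surviving rows of both.
#'
#' @param query the query sequence (single string; name used as header, else
#'   `"query"`).
#' @param uniref_hits,env_hits hit-table tibbles.
#' @param clusters a cluster table resolving every hit's `cluster_id`.
#' @param params final-stage [filter_params()].
#' @param qsc,qsc_min_enable realignment-stage score filter settings.
#' @return A list with elements `uniref`, `env` and `combined`, each an [msa].
#' @export
build_msas <- function(query, uniref_hits, env_hits, clusters,
                       params = filter_params(),
                       qsc = 0.8, qsc_min_enable = 100) {
  qname <- if (!is.null(names(query))) names(query)[[1]] else "query"
  build_one <- function(hits) {
    rows <- expand_cluster_hits(evalue_accept(hits), clusters)
    m <- as_msa(bind_rows(msa_rows(header = qname, aligned = query[[1]]),
                          rows))
    m <- qsc_filter(m, min_qsc = qsc, min_enable = qsc_min_enable)
    bucketed_diff_filter(m, params)
  }
  uniref <- build_one(uniref_hits)
  env <- build_one(env_hits)
  combined <- as_msa(bind_rows(uniref, env[-1, , drop = FALSE]))
  list(uniref = uniref, env = env, combined = combined)
}

#' Naive exhaustive local-alignment search
#'
#' A deterministic Smith-Waterman search backend used as test plumbing in
#' place of a real homology-search engine: every database sequence is locally
#' aligned to the query with BLOSUM62 and affine gaps, and an E-value is
#' attached via the Karlin-Altschul formula `E = K * m * n * exp(-lambda * S)`
#' with fixed constants (`lambda = 0.267`, `K = 0.041`; gapped BLOSUM62 with
#' gap open 11, extend 1). Hits are returned sorted by E-value ascending,
#' ties by target id.
#'
#' @param query query sequence (single string).
#' @param database named character vector of target sequences.
#' @param gap_open,gap_extend affine gap penalties.
#' @param K,lambda Karlin-Altschul constants.
#' @return A hit-table tibble.
#' @export
naive_search <- function(query, database, gap_open = 11, gap_extend = 1,
                         K = 0.041, lambda = 0.267) {
  qname <- if (!is.null(names(query))) names(query)[[1]] else "query"
  query <- query[[1]]
  if (length(database) == 0) return(empty_hit_table())
  if (is.null(names(database))) {
    names(database) <- paste0("t", seq_along(database))
  }
  qlen <- nchar(query)
  b62 <- blosum62()
  rows <- purrr::map(seq_along(database), function(i) {
    target <- database[[i]]
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAString(query),
      subject = Biostrings::AAString(target),
      type = "local", substitutionMatrix = b62,
      gapOpening = gap_open, gapExtension = gap_extend
    )
    s <- Biostrings::score(pa)
    ap <- as.character(Biostrings::alignedPattern(pa))
    as <- as.character(Biostrings::alignedSubject(pa))
    qs <- pa@pattern@range@start
    qe <- qs + pa@pattern@range@width - 1L
    ts <- pa@subject@range@start
    te <- ts + pa@subject@range@width - 1L
    tibble(
      query_id = qname, target_id = names(database)[[i]],
      fident = alignment_identity(ap, as),
      evalue = K * qlen * nchar(target) * exp(-lambda * s),
      qstart = qs, qend = qe, qlen = qlen,
      tstart = ts, tend = te, tlen = nchar(target),
      aligned_target = pad_to_query_frame(ap, as, qs, qe, qlen),
      cluster_id = NA_character_, taxid = NA_integer_,
      accession = NA_character_, score = s
    )
  })
  out <- bind_rows(rows)
  out[order(out$evalue, out$target_id), , drop = FALSE]
}

empty_hit_table <- function() {
  tibble(
    query_id = character(0), target_id = character(0), fident = numeric(0),
    evalue = numeric(0), qstart = integer(0), qend = integer(0),
    qlen = integer(0), tstart = integer(0), tend = integer(0),
    tlen = integer(0), aligned_target = character(0),
    cluster_id = character(0), taxid = integer(0), accession = character(0),
    score = numeric(0)
  )
}

# identical characters / alignment length over a gapped pairwise alignment
alignment_identity <- function(aligned_a, aligned_b) {
  a <- strsplit(aligned_a, "", fixed = TRUE)[[1]]
  b <- strsplit(aligned_b, "", fixed = TRUE)[[1]]
  sum(a == b & a != "-") / length(a)
}

# turn a local pairwise alignment (query side ap, target side as) into a
# query-frame A3M row padded with '-' to the full query length
pad_to_query_frame <- function(ap, as, qstart, qend, qlen) {
  a <- strsplit(ap, "", fixed = TRUE)[[1]]
  b <- strsplit(as, "", fixed = TRUE)[[1]]
  core <- ifelse(a == "-", tolower(b), toupper(b))
  core <- core[!(a == "-" & b == "-")]
  paste0(
    strrep("-", qstart - 1),
    paste0(core, collapse = ""),
    strrep("-", qlen - qend)
  )
}
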