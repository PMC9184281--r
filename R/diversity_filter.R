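#' Parameters of the multi-stage diversity filter
#'
#' Defaults are the final-stage ("MSA construction") values: identity buckets
#' at breakpoints 0, 0.2, 0.4, 0.6, 0.8, 1; 3000 most diverse sequences kept
#' per bucket; pairwise redundancy capped at 95% identity; buckets with fewer
#' than 1000 hits passed through unfiltered. A `qsc` threshold at or below
#' zero disables score filtering in the bucketed stage (the score filter is
#' its own operation, [qsc_filter()], used earlier in the pipeline).
#'
#' @param max_seq_id maximum pairwise identity among kept rows.
#' @param qid_buckets strictly increasing identity breakpoints from 0 to 1.
#' @param diff number of most-diverse sequences kept per bucket.
#' @param qsc minimum score per query column (bits); `<= 0` disables.
#' @param filter_min_enable minimum bucket size for filtering to activate.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(max_seq_id = 0.95,
                          qid_buckets = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                          diff = 3000,
                          qsc = 0,
                          filter_min_enable = 1000) {
  stopifnot(
    length(qid_buckets) >= 2,
    all(diff(qid_buckets) > 0),
    qid_buckets[[1]] == 0,
    qid_buckets[[length(qid_buckets)]] == 1,
    diff >= 0, max_seq_id >= 0, max_seq_id <= 1
  )
  structure(
    list(max_seq_id = max_seq_id, qid_buckets = qid_buckets,
         diff = as.integer(diff), qsc = qsc,
         filter_min_enable = as.integer(filter_min_enable)),
    class = "filter_params"
  )
}

#' Greedy maximum-pairwise-identity filter
#'
#' Scans rows in input (priority) order and keeps a row iff its pairwise
#' identity to every already-kept row does not exceed `threshold`, so no kept
#' pair is more similar than the threshold. Pairwise identity counts
#' identical residues over the columns where both rows carry one, so exact
#' duplicates always collapse.
#'
#' @param rows an [msa]-shaped tibble of aligned rows (no query special-casing).
#' @param threshold maximum allowed pairwise identity, default 0.95.
#' @return The kept rows, input order preserved.
#' @export
max_seq_id_filter <- function(rows, threshold = 0.95) {
  if (nrow(rows) <= 1) return(rows)
  keep <- cpp_greedy_max_seq_id(encode_rows(rows$aligned), threshold)
  rows[keep, , drop = FALSE]
}

#' Score-per-column quality filter
#'
#' Keeps hit rows whose BLOSUM62 score against the query, summed over match
#' columns and divided by the query length, is at least `min_qsc` (in bits:
#' half-bit BLOSUM62 scores are divided by 2). The filter only activates when
#' at least `min_enable` hit rows are present; below that every row is kept.
#' The query row is exempt and always retained.
#'
#' @param x an [msa] (query first).
#' @param min_qsc minimum score per query column in bits, default 0.8.
#' @param min_enable minimum number of hits for the filter to activate.
#' @return The filtered [msa].
#' @export
qsc_filter <- function(x, min_qsc = 0.8, min_enable = 100) {
  stopifnot(is_msa(x))
  n_hits <- nrow(x) - 1
  if (n_hits < min_enable || n_hits == 0) return(x)
  keep <- qsc_scores(x) >= min_qsc
  as_msa(x[c(TRUE, keep), , drop = FALSE])
}

# BLOSUM62 bits-per-query-column of every hit row against the query
qsc_scores <- function(x) {
  enc <- encode_rows(x$aligned)
  L <- ncol(enc)
  alpha <- c(AA20, "X", "-")
  b62 <- blosum62()
  # score lookup indexed by code 0..21 (gap scores 0: no contribution)
  sc <- matrix(0, nrow = 22, ncol = 22)
  for (i in 1:21) for (j in 1:21) {
    sc[i + 1, j + 1] <- b62[alpha[[i]], alpha[[j]]]
  }
  q <- enc[1, ]
  vapply(seq_len(nrow(enc) - 1), function(i) {
    r <- enc[i + 1, ]
    sum(sc[cbind(q + 1L, r + 1L)]) / L / 2
  }, numeric(1))
}

#' Farthest-point selection of the most diverse rows
#'
#' Deterministic greedy diversity selection: the first row in input order
#' seeds the set; each step adds the row maximising its minimum distance
#' (1 - pairwise identity) to the rows already selected, ties broken by input
#' order. The result is returned in input order.
#'
#' @param rows an [msa]-shaped tibble of aligned rows sharing a query frame.
#' @param k target number of rows; all rows are returned when `k >= nrow(rows)`.
#' @return `min(k, nrow(rows))` rows, input order preserved.
#' @export
maxdiv_select <- function(rows, k) {
  stopifnot(k >= 0)
  if (k == 0) return(rows[0, , drop = FALSE])
  if (nrow(rows) <= k) return(rows)
  sel <- cpp_farthest_point_select(encode_rows(rows$aligned), as.integer(k))
  rows[sort(sel), , drop = FALSE]
}

#' Diversity filtering within sequence-identity buckets
#'
#' The final filtering stage of MSA construction. Every non-query row is
#' assigned to exactly one identity bucket by its identity to the query
#' (first bucket closed `[b1, b2]`, subsequent buckets left-open
#' `(b_i, b_{i+1}]`). Buckets holding fewer than `filter_min_enable` rows
#' pass through unfiltered; saturated buckets are reduced, within the bucket
#' only, by the 95% pairwise-redundancy filter followed by farthest-point
#' selection of the `diff` most diverse rows. Because buckets are filtered
#' independently, redundancy can never be eliminated across buckets. The
#' query is always kept and the output preserves the original relative order.
#'
#' @param x an [msa] (query first).
#' @param params a [filter_params()] object.
#' @return The filtered [msa].
#' @export
bucketed_diff_filter <- function(x, params = filter_params()) {
  stopifnot(is_msa(x), inherits(params, "filter_params"))
  if (nrow(x) <= 1) return(x)
  hits <- x[-1, , drop = FALSE]
  qid <- query_identity(x)
  bucket <- assign_buckets(qid, params$qid_buckets)
  if (params$qsc > 0) {
    keep_qsc <- qsc_scores(x) >= params$qsc
  } else {
    keep_qsc <- rep(TRUE, nrow(hits))
  }
  keep_idx <- integer(0)
  for (b in seq_len(length(params$qid_buckets) - 1)) {
    in_b <- which(bucket == b & keep_qsc)
    if (length(in_b) == 0) next
    if (length(in_b) < params$filter_min_enable) {
      keep_idx <- c(keep_idx, in_b)
      next
    }
    sub <- hits[in_b, , drop = FALSE]
    sub_keep <- cpp_greedy_max_seq_id(encode_rows(sub$aligned),
                                      params$max_seq_id)
    if (length(sub_keep) > params$diff) {
      sel <- cpp_farthest_point_select(
        encode_rows(sub$aligned[sub_keep]), params$diff
      )
      sub_keep <- sub_keep[sort(sel)]
    }
    keep_idx <- c(keep_idx, in_b[sub_keep])
  }
  as_msa(x[c(1L, 1L + sort(keep_idx)), , drop = FALSE])
}

# bucket index per identity: first bucket [b1,b2], then (b_i, b_{i+1}]
assign_buckets <- function(qid, breakpoints) {
  b <- findInterval(qid, breakpoints, left.open = TRUE)
  b[qid <= breakpoints[[2]]] <- 1L
  b[b > length(breakpoints) - 1] <- length(breakpoints) - 1L
  b
}

#' Per-cluster redundancy filter (expansion stage)
#'
#' Applied to each clustered-database cluster independently before its
#' members join the MSA, so that no pair of rows from the same cluster is
#' more than `max_seq_id` identical. Filtering never crosses clusters: the
#' same sequence arriving via two clusters survives twice.
#'
#' @param cluster_rows an [msa]-shaped tibble of one cluster's member rows.
#' @param max_seq_id maximum pairwise identity among kept members.
#' @return The kept rows, input order preserved.
#' @export
stage1_cluster_filter <- function(cluster_rows, max_seq_id = 0.95) {
  max_seq_id_filter(cluster_rows, threshold = max_seq_id)
}
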