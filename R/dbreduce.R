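#' Clustered sequence databases
#'
#' A `clustered_db` holds a set of sequences partitioned into clusters, each
#' represented by one of its members. `clusters` maps representative id to a
#' character vector of member ids (the representative included, first);
#' `sequences` is a named character vector holding every member's sequence.
#'
#' @param clusters named list: representative id -> member id vector.
#' @param sequences named character vector of sequences.
#' @return A list of class `clustered_db`.
#' @export
clustered_db <- function(clusters, sequences) {
  stopifnot(is.list(clusters), !is.null(names(clusters)),
            is.character(sequences), !is.null(names(sequences)))
  members <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(members)) {
    abort("cluster member sets must be disjoint")
  }
  for (rep_id in names(clusters)) {
    if (!(rep_id %in% clusters[[rep_id]])) {
      abort(sprintf("representative '%s' is not a member of its own cluster",
                    rep_id))
    }
    clusters[[rep_id]] <- unique(c(rep_id, clusters[[rep_id]]))
  }
  miss <- setdiff(members, names(sequences))
  if (length(miss) > 0) {
    abort(paste0("sequences missing for members: ",
                 paste(head(miss, 3), collapse = ", ")))
  }
  structure(list(clusters = clusters, sequences = sequences),
            class = "clustered_db")
}

#' @export
is_clustered_db <- function(x) inherits(x, "clustered_db")

#' Total number of member sequences in a clustered database
#' @param x a `clustered_db`.
#' @export
db_size <- function(x) {
  stopifnot(is_clustered_db(x))
  sum(lengths(x$clusters))
}

# local alignment of a new sequence against one representative; returns
# identity (identical chars / aligned length) and coverage of the new
# sequence (aligned span / its full length)
align_stats <- function(seq, rep_seq) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(seq),
    subject = Biostrings::AAString(rep_seq),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1
  )
  ap <- as.character(Biostrings::alignedPattern(pa))
  as <- as.character(Biostrings::alignedSubject(pa))
  span <- pa@pattern@range@width
  list(identity = alignment_identity(ap, as),
       coverage = span / nchar(seq))
}

#' Assign new sequences to the clusters of an existing database
#'
#' Each new sequence is locally aligned against every cluster representative
#' (the naive exhaustive search backend); the best-identity hit assigns the
#' sequence to that cluster iff its identity exceeds `min_id` and the
#' alignment covers at least `min_cov` of the new sequence's own length.
#' Sequences failing both conditions for every representative are returned
#' unassigned (to be clustered separately with [cluster_remainder()]).
#'
#' @param new_sequences named character vector.
#' @param db a [clustered_db()].
#' @param min_id identity threshold (strict `>`), default 0.3.
#' @param min_cov coverage-of-new-sequence threshold (`>=`), default 0.9.
#' @return A list with `db` (the database with assigned members added),
#'   `assigned` (tibble: `member_id`, `cluster_id`, `identity`, `coverage`)
#'   and `unassigned` (named character vector).
#' @export
assign_to_clusters <- function(new_sequences, db, min_id = 0.3, min_cov = 0.9) {
  stopifnot(is_clustered_db(db))
  reps <- names(db$clusters)
  assigned <- list()
  unassigned <- character(0)
  for (id in names(new_sequences)) {
    seq <- new_sequences[[id]]
    best <- NULL
    for (r in reps) {
      st <- align_stats(seq, db$sequences[[r]])
      if (st$identity > min_id && st$coverage >= min_cov &&
          (is.null(best) || st$identity > best$identity)) {
        best <- list(cluster = r, identity = st$identity,
                     coverage = st$coverage)
      }
    }
    if (is.null(best)) {
      unassigned[[id]] <- seq
    } else {
      assigned[[length(assigned) + 1]] <- tibble(
        member_id = id, cluster_id = best$cluster,
        identity = best$identity, coverage = best$coverage
      )
      db$clusters[[best$cluster]] <- c(db$clusters[[best$cluster]], id)
      db$sequences[[id]] <- seq
    }
  }
  list(
    db = db,
    assigned = if (length(assigned) == 0) {
      tibble(member_id = character(0), cluster_id = character(0),
             identity = numeric(0), coverage = numeric(0))
    } else bind_rows(assigned),
    unassigned = unassigned
  )
}

#' Greedy incremental clustering of unassigned sequences
#'
#' Sequences are visited in descending length (ties by id); each either
#' joins the first existing cluster whose representative it matches at the
#' identity/coverage thresholds, or seeds a new cluster with itself as
#' representative.
#'
#' @param sequences named character vector.
#' @param min_id,min_cov thresholds as in [assign_to_clusters()].
#' @return A [clustered_db()].
#' @export
cluster_remainder <- function(sequences, min_id = 0.3, min_cov = 0.9) {
  if (length(sequences) == 0) {
    return(structure(list(clusters = stats::setNames(list(), character(0)),
                          sequences = character(0)),
                     class = "clustered_db"))
  }
  ord <- order(-nchar(sequences), names(sequences))
  sequences <- sequences[ord]
  clusters <- list()
  for (id in names(sequences)) {
    seq <- sequences[[id]]
    placed <- FALSE
    for (r in names(clusters)) {
      st <- align_stats(seq, sequences[[r]])
      if (st$identity > min_id && st$coverage >= min_cov) {
        clusters[[r]] <- c(clusters[[r]], id)
        placed <- TRUE
        break
      }
    }
    if (!placed) clusters[[id]] <- id
  }
  clustered_db(clusters, sequences)
}

#' Reduce every cluster to its most diverse members
#'
#' Each cluster is reduced independently to at most `diff` members via
#' deterministic farthest-point selection over member identities (members
#' aligned into the representative's frame); the representative seeds the
#' selection and is always retained.
#'
#' @param db a [clustered_db()].
#' @param diff members kept per cluster, default 10.
#' @return The reduced [clustered_db()].
#' @export
reduce_clusters <- function(db, diff = 10L) {
  stopifnot(is_clustered_db(db), diff >= 1)
  for (r in names(db$clusters)) {
    members <- db$clusters[[r]]
    if (length(members) <= diff) next
    rep_seq <- db$sequences[[r]]
    aligned <- vapply(members, function(m) {
      if (m == r) return(rep_seq)
      member_in_rep_frame(db$sequences[[m]], rep_seq)
    }, character(1))
    rows <- msa_rows(header = members, aligned = aligned)
    keep <- maxdiv_select(rows, as.integer(diff))$header
    if (!(r %in% keep)) keep <- c(r, keep[seq_len(length(keep) - 1)])
    db$clusters[[r]] <- members[members %in% keep]
  }
  kept <- unlist(db$clusters, use.names = FALSE)
  db$sequences <- db$sequences[names(db$sequences) %in% kept]
  db
}

# align a member into the representative's coordinate frame (global-ish local
# alignment padded with gaps), for identity-based diversity selection
member_in_rep_frame <- function(seq, rep_seq) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(rep_seq),
    subject = Biostrings::AAString(seq),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1
  )
  ap <- as.character(Biostrings::alignedPattern(pa))
  as <- as.character(Biostrings::alignedSubject(pa))
  qs <- pa@pattern@range@start
  qe <- qs + pa@pattern@range@width - 1L
  pad_to_query_frame(ap, as, qs, qe, nchar(rep_seq))
}

#' Read / write cluster membership as TSV
#'
#' Two tab-separated columns, `representative_id` and `member_id`, one row
#' per member.
#'
#' @param db a [clustered_db()] (sequences are not serialized).
#' @param path output file.
#' @export
write_cluster_members <- function(db, path) {
  stopifnot(is_clustered_db(db))
  tbl <- tibble(
    representative_id = rep(names(db$clusters), lengths(db$clusters)),
    member_id = unlist(db$clusters, use.names = FALSE)
  )
  readr::write_tsv(tbl, path)
  invisible(tbl)
}
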