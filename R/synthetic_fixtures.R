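#' Synthetic MSA with controlled identity structure
#'
#' Generates a random query and mutates it row by row so every row's identity
#' to the query hits its target exactly (up to the 1/length granularity):
#' exactly `round((1 - target) * length)` positions, chosen without
#' replacement, are changed to a different residue. Targets are recycled over
#' rows. Seed-deterministic.
#'
#' @param n_rows number of non-query rows.
#' @param length query length.
#' @param qid_targets identity targets in `[0, 1]`, recycled over rows.
#' @param seed integer seed.
#' @return An [msa] with `n_rows + 1` rows (query first).
#' @export
make_msa <- function(n_rows, length, qid_targets = 0.5, seed = 1L) {
  stopifnot(all(qid_targets >= 0 & qid_targets <= 1), length >= 1)
  targets <- rep_len(qid_targets, n_rows)
  withr::with_seed(as.integer(seed), {
    query <- paste0(sample(AA20, length, replace = TRUE), collapse = "")
    qchars <- strsplit(query, "", fixed = TRUE)[[1]]
    rows <- vapply(seq_len(n_rows), function(i) {
      k <- round((1 - targets[[i]]) * length)
      cc <- qchars
      if (k > 0) {
        pos <- sample.int(length, k)
        cc[pos] <- vapply(cc[pos], function(ch) {
          sample(setdiff(AA20, ch), 1)
        }, character(1))
      }
      paste0(cc, collapse = "")
    }, character(1))
    msa(header = c("query", sprintf("row%04d_qid%.2f",
                                    seq_len(n_rows), targets)),
        aligned = c(query, rows))
  })
}

#' Synthetic per-chain hit tables with a species layout
#'
#' Realizes a requested pairing scenario: `layout` has one row per hit with
#' columns `taxid`, `chain`, `evalue`, `coverage` and optionally
#' `accession` and `target_id`. Each hit gets a query-frame alignment whose
#' span matches the requested coverage (query length 100 by default).
#'
#' @param n_chains number of chains.
#' @param layout a data frame as described above.
#' @param qlen query length used for all chains, default 100.
#' @param seed integer seed (controls hit sequences).
#' @return A list of `n_chains` hit-table tibbles.
#' @export
make_species_hits <- function(n_chains, layout, qlen = 100L, seed = 1L) {
  stopifnot(all(c("taxid", "chain", "evalue", "coverage") %in% names(layout)))
  stopifnot(all(layout$chain >= 1 & layout$chain <= n_chains))
  layout <- as_tibble(layout)
  if (!("accession" %in% names(layout))) layout$accession <- NA_character_
  if (!("target_id" %in% names(layout))) {
    layout$target_id <- sprintf("t%03d", seq_len(nrow(layout)))
  }
  withr::with_seed(as.integer(seed), {
    purrr::map(seq_len(n_chains), function(ch) {
      rows <- layout[layout$chain == ch, , drop = FALSE]
      if (nrow(rows) == 0) return(empty_hit_table())
      qend <- pmin(qlen, pmax(1L, as.integer(round(rows$coverage * qlen))))
      aligned <- vapply(seq_len(nrow(rows)), function(i) {
        paste0(paste0(sample(AA20, qend[[i]], replace = TRUE), collapse = ""),
               strrep("-", qlen - qend[[i]]))
      }, character(1))
      tibble(
        query_id = paste0("chain", ch), target_id = rows$target_id,
        fident = 0.5, evalue = rows$evalue,
        qstart = 1L, qend = qend, qlen = as.integer(qlen),
        tstart = 1L, tend = qend, tlen = qend,
        aligned_target = aligned, cluster_id = NA_character_,
        taxid = as.integer(rows$taxid), accession = rows$accession,
        score = NA_real_
      )
    })
  })
}

#' Synthetic block-structured PAE matrix
#'
#' Intra-chain entries at `intra_level`, inter-chain entries at
#' `inter_level`, plus seeded Gaussian noise clipped at zero.
#'
#' @param n total residues.
#' @param partition integer chain id per residue (length `n`).
#' @param intra_level,inter_level block levels (Angstrom).
#' @param noise_sd Gaussian noise standard deviation, default 0.
#' @param seed integer seed.
#' @return An `n x n` non-negative matrix.
#' @export
make_pae <- function(n, partition, intra_level, inter_level,
                     noise_sd = 0, seed = 1L) {
  stopifnot(length(partition) == n, intra_level >= 0, inter_level >= 0)
  cross <- outer(partition, partition, `!=`)
  m <- matrix(intra_level, n, n)
  m[cross] <- inter_level
  if (noise_sd > 0) {
    withr::with_seed(as.integer(seed), {
      m <- m + matrix(stats::rnorm(n * n, sd = noise_sd), n, n)
    })
  }
  pmax(m, 0)
}

#' Scripted mock predictor
#'
#' Builds a predictor satisfying the scheduler's contract by replaying a
#' script: a data frame with columns `model`, `recycle`, `plddt` (scalar
#' level, expanded to the query length) and optionally `structure_change`,
#' `inter_pae` and `intra_pae` (when either PAE level is present, a
#' block-structured PAE matrix is returned alongside the pLDDT). Querying a
#' (model, recycle) pair absent from the script is an explicit error, so
#' scheduler bugs surface instead of silently replaying defaults.
#'
#' @param script a data frame as described above.
#' @return A function `(feature_set, model_id, recycle_index, seed,
#'   is_training)` returning `plddt`, optional `pae`, and
#'   `structure_change`.
#' @export
make_mock_predictor <- function(script) {
  script <- as_tibble(script)
  stopifnot(all(c("model", "recycle", "plddt") %in% names(script)))
  if (!("structure_change" %in% names(script))) script$structure_change <- Inf
  function(feature_set, model_id, recycle_index, seed, is_training) {
    row <- script[script$model == model_id & script$recycle == recycle_index, ]
    if (nrow(row) == 0) {
      abort(sprintf("mock predictor has no script for model %d recycle %d",
                    model_id, recycle_index))
    }
    row <- row[1, ]
    n <- feature_set$total_length
    out <- list(
      plddt = rep(row$plddt, n),
      structure_change = row$structure_change
    )
    if ("inter_pae" %in% names(row) && !is.na(row$inter_pae)) {
      part <- chain_index(feature_set)
      intra <- if ("intra_pae" %in% names(row) && !is.na(row$intra_pae)) {
        row$intra_pae
      } else 1
      out$pae <- make_pae(n, part, intra, row$inter_pae)
      out$partition <- part
    }
    out
  }
}

#' Synthetic clustered database
#'
#' Each cluster is seeded with an independent random representative;
#' members mutate the representative at the requested divergence so
#' within-cluster identities stay high while clusters are mutually unrelated.
#'
#' @param n_clusters number of clusters.
#' @param members_per_cluster members per cluster (representative included).
#' @param length sequence length.
#' @param member_identity identity of members to their representative.
#' @param seed integer seed.
#' @return A [clustered_db()].
#' @export
make_clustered_db <- function(n_clusters, members_per_cluster, length = 100L,
                              member_identity = 0.7, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    clusters <- list()
    sequences <- character(0)
    for (c in seq_len(n_clusters)) {
      sub_seed <- sample.int(.Machine$integer.max, 1)
      m <- make_msa(members_per_cluster - 1, length,
                    qid_targets = member_identity, seed = sub_seed)
      ids <- sprintf("c%03d_m%03d", c, seq_len(members_per_cluster))
      seqs <- stats::setNames(m$aligned, ids)
      clusters[[ids[[1]]]] <- ids
      sequences <- c(sequences, seqs)
    }
    clustered_db(clusters, sequences)
  })
}

#' Synthetic cluster table for hit expansion
#'
#' Builds a cluster-membership table (representative first per cluster,
#' aligned to itself) whose members differ from the representative at a
#' controlled number of positions, using ungapped member-representative
#' alignments.
#'
#' @param representatives named character vector of representative sequences.
#' @param members_per_cluster members per cluster (incl. representative).
#' @param member_identity member-to-representative identity target.
#' @param seed integer seed.
#' @return A cluster-table tibble (`cluster_id`, `member_id`,
#'   `aligned_member`, `aligned_representative`).
#' @export
make_cluster_table <- function(representatives, members_per_cluster = 3L,
                               member_identity = 0.8, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    purrr::imap(as.list(representatives), function(rep_seq, cid) {
      L <- nchar(rep_seq)
      k <- round((1 - member_identity) * L)
      rchars <- strsplit(rep_seq, "", fixed = TRUE)[[1]]
      members <- vapply(seq_len(members_per_cluster - 1), function(i) {
        cc <- rchars
        if (k > 0) {
          pos <- sample.int(L, k)
          cc[pos] <- vapply(cc[pos], function(ch) sample(setdiff(AA20, ch), 1),
                            character(1))
        }
        paste0(cc, collapse = "")
      }, character(1))
      tibble(
        cluster_id = cid,
        member_id = c(cid, sprintf("%s_m%02d",
                                   cid, seq_len(members_per_cluster - 1))),
        aligned_member = c(rep_seq, members),
        aligned_representative = rep_seq
      )
    }) |> bind_rows()
  })
}
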