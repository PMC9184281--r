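# Pure-R oracles, kept independent of the package's C++ kernels.

# identity between two query-frame aligned strings: identical residues at
# match columns / query length; gaps and X never match
oracle_identity <- function(a, b) {
  ac <- strsplit(gsub("[a-z]", "", a), "", fixed = TRUE)[[1]]
  bc <- strsplit(gsub("[a-z]", "", b), "", fixed = TRUE)[[1]]
  stopifnot(length(ac) == length(bc))
  sum(ac == bc & ac != "-" & ac != "X") / length(ac)
}

# pairwise identity between two rows: identical residues over the columns
# where both rows carry a residue (exact duplicates score 1; X never matches)
oracle_pairwise_identity <- function(a, b) {
  ac <- strsplit(gsub("[a-z]", "", a), "", fixed = TRUE)[[1]]
  bc <- strsplit(gsub("[a-z]", "", b), "", fixed = TRUE)[[1]]
  both <- ac != "-" & bc != "-"
  if (!any(both)) return(0)
  sum(both & ac == bc & ac != "X") / sum(both)
}

# all-pairs identity matrix by brute force
oracle_identity_matrix <- function(aligned) {
  n <- length(aligned)
  m <- diag(0, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) m[i, j] <- oracle_pairwise_identity(aligned[[i]], aligned[[j]])
    }
  }
  m
}

# maximum pairwise identity among a set of rows (0 when fewer than 2 rows)
oracle_max_pairwise <- function(aligned) {
  if (length(aligned) < 2) return(0)
  m <- oracle_identity_matrix(aligned)
  max(m[upper.tri(m)])
}

# exhaustive minimum-total-distance perfect matching between two ordinal sets
# (for genome-distance pairing, <= 6 hits per side)
oracle_best_matching <- function(ord_a, ord_b, max_gap) {
  k <- min(length(ord_a), length(ord_b))
  best <- NULL
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[[i]], p))
    }), recursive = FALSE)
  }
  subsets <- function(v, k) {
    if (k == 0) return(list(integer(0)))
    utils::combn(v, k, simplify = FALSE)
  }
  for (m in seq(k, 1)) {
    for (sa in subsets(seq_along(ord_a), m)) {
      for (sb in subsets(seq_along(ord_b), m)) {
        for (p in perms(sb)) {
          d <- abs(ord_a[sa] - ord_b[p])
          if (all(d <= max_gap)) {
            tot <- sum(d)
            if (is.null(best) || m > best$m ||
                (m == best$m && tot < best$total)) {
              best <- list(m = m, total = tot)
            }
          }
        }
      }
    }
    if (!is.null(best)) break   # maximise pair count first, then distance
  }
  best
}

# hit table + singleton cluster table realizing an MSA's rows as search hits
hits_from_msa <- function(m, evalue = 1e-5, prefix = "c") {
  hits <- m[-1, , drop = FALSE]
  n <- nrow(hits)
  L <- query_length(m)
  list(
    hits = tibble::tibble(
      query_id = "q", target_id = paste0(prefix, seq_len(n)),
      fident = 0.5, evalue = rep_len(evalue, n),
      qstart = 1L, qend = L, qlen = L, tstart = 1L, tend = L, tlen = L,
      aligned_target = hits$aligned,
      cluster_id = paste0(prefix, seq_len(n)),
      taxid = NA_integer_, accession = NA_character_
    ),
    clusters = tibble::tibble(
      cluster_id = paste0(prefix, seq_len(n)),
      member_id = paste0(prefix, seq_len(n)),
      aligned_member = gsub("-", "", hits$aligned),
      aligned_representative = gsub("-", "", hits$aligned)
    )
  )
}
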