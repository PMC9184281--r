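#' Assemble a homo-oligomer MSA
#'
#' For a homo-oligomer of `copies` identical chains, the single-chain MSA is
#' copied once per chain and laid out block-diagonally: the query row is the
#' query repeated across all copies, and each non-query row appears once per
#' copy, placed in that copy's column block with every other block filled
#' with gaps. Providing a separate MSA copy per chain in this way works
#' markedly better than naive left-to-right concatenation of the same rows.
#' Lowercase insertions are dropped (feature assembly works on match
#' columns).
#'
#' @param x an [msa] (query first).
#' @param copies number of chain copies, `>= 1`.
#' @return An [msa] of width `copies * query_length(x)` with
#'   `1 + copies * (nrow(x) - 1)` rows.
#' @export
assemble_homooligomer <- function(x, copies) {
  stopifnot(is_msa(x))
  if (copies < 1) abort("copies must be >= 1")
  copies <- as.integer(copies)
  if (copies == 1L) return(x)
  L <- query_length(x)
  q <- match_string(x$aligned[[1]])
  hit <- x[-1, , drop = FALSE]
  hit$aligned <- match_string(hit$aligned)
  blocks <- purrr::map(seq_len(copies), function(c) {
    b <- hit
    b$aligned <- paste0(strrep("-", (c - 1L) * L), b$aligned,
                        strrep("-", (copies - c) * L))
    b$header <- paste0(b$header, "_copy", c)
    b
  })
  out <- bind_rows(
    msa_rows(header = x$header[[1]], aligned = strrep(q, copies),
             evalue = x$evalue[[1]]),
    bind_rows(blocks)
  )
  as_msa(out)
}

#' Assemble a hetero-oligomer MSA from paired and unpaired rows
#'
#' Layout: row 1 is the concatenation of the per-chain queries; next come the
#' paired blocks as full-width rows (one aligned sequence per chain, no gap
#' blocks); then each chain's unpaired rows appear block-diagonally, padded
#' with gaps over the other chains. Paired rows resolve inter-chain contacts
#' while the unpaired blocks guide the per-chain folds.
#'
#' @param paired a paired-blocks tibble from [pair_by_species()] or
#'   [pair_by_genome_distance()] (may be empty or `NULL`).
#' @param unpaired a list of per-chain [msa]s whose queries concatenate to
#'   the complex query.
#' @return An [msa] over the concatenated complex query.
#' @export
assemble_heterooligomer <- function(paired, unpaired) {
  stopifnot(length(unpaired) >= 1, all(vapply(unpaired, is_msa, logical(1))))
  lens <- vapply(unpaired, query_length, integer(1))
  total <- sum(lens)
  n_chains <- length(unpaired)
  offsets <- cumsum(c(0L, lens))[seq_len(n_chains)]
  query <- paste0(vapply(unpaired, function(m) match_string(m$aligned[[1]]),
                         character(1)), collapse = "")
  rows <- list(msa_rows(header = "query", aligned = query))
  if (!is.null(paired) && nrow(paired) > 0) {
    for (b in unique(paired$block)) {
      pb <- paired[paired$block == b, , drop = FALSE]
      pb <- pb[order(pb$chain), , drop = FALSE]
      if (!identical(as.integer(pb$chain), seq_len(n_chains))) {
        abort(sprintf("paired block %s does not cover every chain exactly once", b))
      }
      seg <- match_string(pb$aligned_target)
      if (!identical(nchar(seg), lens)) {
        abort(sprintf("paired block %s: chain lengths %s do not match queries %s",
                      b, paste(nchar(seg), collapse = ","),
                      paste(lens, collapse = ",")))
      }
      rows[[length(rows) + 1]] <- msa_rows(
        header = sprintf("paired_block%d_tax%s", b, pb$species_taxid[[1]]),
        aligned = paste0(seg, collapse = ""),
        evalue = pb$combined_evalue[[1]],
        taxid = pb$species_taxid[[1]]
      )
    }
  }
  for (ch in seq_len(n_chains)) {
    m <- unpaired[[ch]]
    if (nrow(m) <= 1) next
    hit <- m[-1, , drop = FALSE]
    hit$aligned <- paste0(strrep("-", offsets[[ch]]),
                          match_string(hit$aligned),
                          strrep("-", total - offsets[[ch]] - lens[[ch]]))
    hit$header <- paste0(hit$header, "_chain", ch)
    rows[[length(rows) + 1]] <- hit
  }
  as_msa(bind_rows(rows))
}

#' Residue-index vector with chain breaks
#'
#' Structure predictors using clipped relative positional encoding treat two
#' residues more than 32 index units apart as having the maximal separation;
#' jumping the residue index by more than 32 between chains therefore makes
#' the model treat them as separate polypeptides. Indices are 0-based and
#' consecutive within each chain.
#'
#' @param chain_lengths integer vector of chain lengths.
#' @param chain_gap index jump between consecutive chains; must exceed 32,
#'   the relative-position clipping cap.
#' @return Integer vector of length `sum(chain_lengths)`.
#' @examples
#' build_residue_index(c(3, 3))
#' @export
build_residue_index <- function(chain_lengths, chain_gap = 200L) {
  stopifnot(all(chain_lengths >= 1))
  if (chain_gap <= 32) {
    abort("chain_gap must exceed 32: relative positional encoding is capped at |i-j| >= 32, so smaller jumps do not create a chain break")
  }
  starts <- cumsum(c(0L, head(chain_lengths, -1) + as.integer(chain_gap)))
  unlist(purrr::map2(starts, chain_lengths,
                     function(s, l) s + seq_len(l) - 1L),
         use.names = FALSE)
}

#' Clipped relative-position encoding bins
#'
#' `bin(i, j) = clamp(index_i - index_j, -cap, cap) + cap`, so bins lie in
#' `[0, 2 * cap]` and every pair separated by `cap` or more shares a bin.
#'
#' @param residue_index integer vector.
#' @param cap clipping cap, default 32.
#' @return Integer matrix of bins.
#' @export
relative_position_bins <- function(residue_index, cap = 32L) {
  d <- outer(residue_index, residue_index, `-`)
  matrix(as.integer(pmin(pmax(d, -cap), cap) + cap),
         nrow = length(residue_index))
}

#' Subsample an MSA to cluster centers and extra rows
#'
#' Predictors consume at most `max_clusters` cluster-center rows and
#' `max_extra` extra rows. The query is always a cluster row; the remaining
#' cluster rows are drawn uniformly without replacement under `seed`, then up
#' to `max_extra` of the rest become extra rows. Different seeds select
#' different centers, which is the lever behind sampling diverse structures.
#'
#' @param x an [msa].
#' @param max_clusters,max_extra row caps (defaults 512 and 1024).
#' @param seed integer seed; same seed, same selection.
#' @return A list with sorted integer vectors `cluster_rows` and `extra_rows`.
#' @export
subsample_msa <- function(x, max_clusters = 512L, max_extra = 1024L, seed = 0L) {
  stopifnot(is_msa(x))
  n <- nrow(x)
  withr::with_seed(as.integer(seed), {
    n_cl <- min(max_clusters, n)
    cluster_rows <- if (n_cl >= n) seq_len(n) else {
      c(1L, sort(sample(2:n, n_cl - 1L)))
    }
    rest <- setdiff(seq_len(n), cluster_rows)
    n_ex <- min(max_extra, length(rest))
    extra_rows <- if (n_ex == 0) integer(0) else sort(sample(rest, n_ex))
    list(cluster_rows = as.integer(cluster_rows),
         extra_rows = as.integer(extra_rows))
  })
}

#' Build a model-input feature set from an assembled MSA
#'
#' Integer-encodes the MSA's match columns (0 gap, 1-20 residues, 21 X),
#' attaches the residue-index vector with chain breaks and the half-open
#' chain partition, and records the subsampled cluster/extra rows.
#'
#' @param x an [msa] over the (possibly concatenated) complex query.
#' @param chain_lengths chain lengths summing to the query length; default a
#'   single chain.
#' @param chain_gap residue-index jump between chains.
#' @param max_clusters,max_extra,seed subsampling controls; see
#'   [subsample_msa()].
#' @return A list of class `feature_set` with elements `msa_matrix`,
#'   `residue_index`, `chain_partition`, `total_length`, `padded_length`,
#'   `padded_rows`, `cluster_rows`, `extra_rows`.
#' @export
build_feature_set <- function(x, chain_lengths = NULL, chain_gap = 200L,
                              max_clusters = 512L, max_extra = 1024L,
                              seed = 0L) {
  stopifnot(is_msa(x))
  L <- query_length(x)
  if (is.null(chain_lengths)) chain_lengths <- L
  stopifnot(sum(chain_lengths) == L)
  ends <- cumsum(chain_lengths)
  starts <- c(0L, head(ends, -1))
  sub <- subsample_msa(x, max_clusters, max_extra, seed)
  structure(
    list(
      msa_matrix = encode_rows(x$aligned),
      residue_index = build_residue_index(chain_lengths, chain_gap),
      chain_partition = purrr::map2(starts, ends, function(s, e) c(s, e)),
      total_length = L,
      padded_length = L,
      padded_rows = nrow(x),
      cluster_rows = sub$cluster_rows,
      extra_rows = sub$extra_rows
    ),
    class = "feature_set"
  )
}

#' @export
is_feature_set <- function(x) inherits(x, "feature_set")

#' Pad a feature set to a cache-friendly fixed size
#'
#' Pads the feature width by `pad_fraction` (default 10%): the MSA matrix is
#' right-padded with the gap token and the residue index with a `-1`
#' sentinel. A compiled model for padded shape `S` is reusable for any query
#' whose total length is at most `S`, which is what makes batch processing in
#' ascending length order cheap.
#'
#' @param fs a `feature_set`.
#' @param pad_fraction non-negative padding fraction, default 0.1.
#' @return The padded `feature_set` (`padded_length = ceil(total * (1 + pad))`).
#' @export
make_fixed_size <- function(fs, pad_fraction = 0.1) {
  stopifnot(is_feature_set(fs), pad_fraction >= 0)
  # tolerance guards against 100 * 1.1 = 110.0000...01 style float error
  padded <- as.integer(ceiling(fs$total_length * (1 + pad_fraction) - 1e-9))
  extra <- padded - ncol(fs$msa_matrix)
  if (extra > 0) {
    fs$msa_matrix <- cbind(
      fs$msa_matrix,
      matrix(0L, nrow = nrow(fs$msa_matrix), ncol = extra)
    )
    fs$residue_index <- c(fs$residue_index, rep(-1L, extra))
  }
  fs$padded_length <- padded
  fs
}

#' Chain id per residue of a feature set
#'
#' @param fs a `feature_set`.
#' @return Integer vector over the unpadded length.
#' @export
chain_index <- function(fs) {
  stopifnot(is_feature_set(fs))
  unlist(purrr::imap(fs$chain_partition,
                     function(p, i) rep(as.integer(i), p[[2]] - p[[1]])),
         use.names = FALSE)
}
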