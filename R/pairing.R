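#' Pair per-chain hits by species co-occurrence
#'
#' For complex prediction, paired MSA rows help only when orthologs are
#' matched across chains. Hits whose alignment covers less than
#' `min_query_cov` of their chain's query are discarded first; a species
#' (taxonomic identifier) contributes a paired block iff it then still has at
#' least one hit for every chain, and within each chain the hit with the
#' smallest E-value is chosen (ties broken by target id for determinism).
#' One block per species is emitted; blocks are sorted by combined (summed)
#' E-value ascending. Hits without a taxid are ignored with a warning.
#'
#' @param per_chain_hits a list of hit-table tibbles, one per chain, in chain
#'   order.
#' @param min_query_cov minimum query coverage, default 0.5.
#' @return A tibble of paired rows, block-major, with columns `block`,
#'   `species_taxid`, `chain`, `target_id`, `aligned_target`, `evalue` and
#'   `combined_evalue`.
#' @export
pair_by_species <- function(per_chain_hits, min_query_cov = 0.5) {
  stopifnot(length(per_chain_hits) >= 2)
  prepped <- purrr::imap(per_chain_hits, function(h, i) {
    if (nrow(h) == 0) return(h |> mutate(chain = integer(0), coverage = numeric(0)))
    if (any(is.na(h$taxid))) {
      warn(sprintf("chain %d: %d hit(s) without taxid ignored",
                   i, sum(is.na(h$taxid))))
      h <- h[!is.na(h$taxid), , drop = FALSE]
    }
    h$coverage <- (h$qend - h$qstart + 1) / h$qlen
    h$chain <- as.integer(i)
    h[h$coverage >= min_query_cov, , drop = FALSE]
  })
  all_hits <- bind_rows(prepped)
  if (nrow(all_hits) == 0) return(empty_paired_blocks())
  best <- all_hits |>
    arrange(.data$taxid, .data$chain, .data$evalue, .data$target_id) |>
    group_by(.data$taxid, .data$chain) |>
    slice(1) |>
    ungroup()
  complete <- best |>
    group_by(.data$taxid) |>
    filter(dplyr::n_distinct(.data$chain) == length(per_chain_hits)) |>
    mutate(combined_evalue = sum(.data$evalue)) |>
    ungroup()
  if (nrow(complete) == 0) return(empty_paired_blocks())
  complete <- complete |>
    arrange(.data$combined_evalue, .data$taxid, .data$chain) |>
    mutate(block = match(.data$taxid, unique(.data$taxid)))
  complete |>
    dplyr::transmute(
      block = .data$block, species_taxid = .data$taxid,
      chain = .data$chain, target_id = .data$target_id,
      aligned_target = .data$aligned_target, evalue = .data$evalue,
      combined_evalue = .data$combined_evalue
    )
}

empty_paired_blocks <- function() {
  tibble(
    block = integer(0), species_taxid = integer(0), chain = integer(0),
    target_id = character(0), aligned_target = character(0),
    evalue = numeric(0), combined_evalue = numeric(0)
  )
}

#' Pair per-chain hits by genome proximity of accessions
#'
#' Prokaryotic interaction partners are often encoded close together on the
#' genome, which is reflected in nearby sequence-database accessions.
#' Accessions are mapped to integer ordinals (base-36 positional value of the
#' full alphanumeric accession); within each species, hits are greedily
#' matched across chains in order of increasing total pairwise ordinal
#' distance, each hit used at most once, and any candidate whose pairwise
#' ordinal distance exceeds `max_gap` is rejected. Unlike species pairing,
#' several blocks per species (paralogous operon copies) may be emitted.
#' Hits with unparseable or missing accessions are ignored with a warning.
#'
#' @param per_chain_hits a list of hit-table tibbles, one per chain.
#' @param max_gap maximum allowed ordinal distance between paired accessions.
#' @return A tibble of paired rows in the same shape as [pair_by_species()].
#' @export
pair_by_genome_distance <- function(per_chain_hits, max_gap = 10) {
  stopifnot(length(per_chain_hits) >= 2)
  n_chains <- length(per_chain_hits)
  prepped <- purrr::imap(per_chain_hits, function(h, i) {
    h$chain <- as.integer(i)
    h$ordinal <- accession_ordinal(h$accession)
    bad <- is.na(h$ordinal)
    if (any(bad)) {
      warn(sprintf("chain %d: %d hit(s) with unparseable accession ignored",
                   i, sum(bad)))
    }
    h[!bad, , drop = FALSE]
  })
  all_hits <- bind_rows(prepped)
  if (nrow(all_hits) == 0) return(empty_paired_blocks())
  species <- if (all(is.na(all_hits$taxid))) {
    list(all_hits)
  } else {
    split(all_hits, all_hits$taxid)
  }
  blocks <- purrr::map(species, function(sp) {
    match_species_by_distance(sp, n_chains, max_gap)
  })
  out <- bind_rows(blocks)
  if (nrow(out) == 0) return(empty_paired_blocks())
  out <- out |>
    arrange(.data$total_distance, .data$species_taxid) |>
    mutate(block = match(
      paste(.data$species_taxid, .data$block_key),
      unique(paste(.data$species_taxid, .data$block_key))
    ))
  out |>
    dplyr::transmute(
      block = .data$block, species_taxid = .data$species_taxid,
      chain = .data$chain, target_id = .data$target_id,
      aligned_target = .data$aligned_target, evalue = .data$evalue,
      combined_evalue = .data$combined_evalue
    )
}

# greedy minimum-distance matching of one species' hits across chains:
# candidate tuples (one hit per chain) are ranked by total pairwise ordinal
# distance and accepted greedily with each hit used at most once; a tuple is
# admissible only if every pairwise distance is <= max_gap
match_species_by_distance <- function(sp, n_chains, max_gap) {
  per_chain <- split(sp, sp$chain)
  if (length(per_chain) < n_chains) return(NULL)
  idx <- purrr::map(as.character(seq_len(n_chains)),
                    function(ch) seq_len(nrow(per_chain[[ch]])))
  tuples <- expand.grid(idx, KEEP.OUT.ATTRS = FALSE)
  if (nrow(tuples) == 0) return(NULL)
  scored <- purrr::map(seq_len(nrow(tuples)), function(t) {
    rows <- purrr::map(seq_len(n_chains), function(ch) {
      per_chain[[as.character(ch)]][tuples[t, ch][[1]], , drop = FALSE]
    })
    ords <- vapply(rows, function(r) r$ordinal, numeric(1))
    d <- as.matrix(stats::dist(ords))
    if (any(d[upper.tri(d)] > max_gap)) return(NULL)
    list(rows = rows, total = sum(d[upper.tri(d)]),
         ids = vapply(rows, function(r) paste(r$chain, r$target_id),
                      character(1)))
  })
  scored <- scored[!vapply(scored, is.null, logical(1))]
  if (length(scored) == 0) return(NULL)
  scored <- scored[order(vapply(scored, `[[`, numeric(1), "total"))]
  used <- character(0)
  out <- list()
  for (cand in scored) {
    if (any(cand$ids %in% used)) next
    used <- c(used, cand$ids)
    rows <- bind_rows(cand$rows)
    rows$total_distance <- cand$total
    rows$block_key <- paste(cand$ids, collapse = "|")
    rows$combined_evalue <- sum(rows$evalue)
    rows$species_taxid <- rows$taxid
    out[[length(out) + 1]] <- rows
  }
  bind_rows(out)
}

#' Map accessions to integer ordinals
#'
#' The base-36 positional value of the accession's alphanumeric characters
#' (digits 0-9, letters A-Z = 10-35, case-insensitive), so consecutive
#' accessions such as `A0A001` and `A0A003` sit two ordinals apart.
#'
#' @param accession character vector.
#' @return numeric vector of ordinals (`NA` where unparseable).
#' @export
accession_ordinal <- function(accession) {
  vapply(accession, function(a) {
    if (is.na(a) || !nzchar(a)) return(NA_real_)
    a <- toupper(gsub("[^A-Za-z0-9]", "", a))
    if (!nzchar(a)) return(NA_real_)
    chars <- strsplit(a, "", fixed = TRUE)[[1]]
    digits <- match(chars, c(0:9, LETTERS)) - 1
    if (anyNA(digits)) return(NA_real_)
    sum(digits * 36^rev(seq_along(digits) - 1))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Write paired blocks as a concatenated A3M
#'
#' One record per block per chain, block-major; record headers carry the
#' species taxid and chain index.
#'
#' @param blocks a paired-blocks tibble.
#' @param path output file.
#' @export
write_paired_a3m <- function(blocks, path) {
  hdr <- sprintf("block%d_tax%s_chain%d",
                 blocks$block, blocks$species_taxid, blocks$chain)
  writeLines(paste0(">", hdr, "\n", blocks$aligned_target), path)
  invisible(blocks)
}
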