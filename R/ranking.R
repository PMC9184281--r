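#' Prediction confidence scores
#'
#' Bundles a predictor's per-residue pLDDT vector (values in `[0, 100]`) and
#' its N x N predicted-aligned-error (PAE) matrix, plus an optional chain
#' partition for complexes.
#'
#' @param plddt numeric vector in `[0, 100]`.
#' @param pae square non-negative matrix (Angstrom), not assumed symmetric.
#' @param partition optional integer vector of chain ids per residue.
#' @param id optional identifier.
#' @return A list of class `prediction_scores`.
#' @export
prediction_scores <- function(plddt, pae = NULL, partition = NULL, id = NULL) {
  stopifnot(all(plddt >= 0 & plddt <= 100))
  if (!is.null(pae)) {
    pae <- as.matrix(pae)
    stopifnot(nrow(pae) == ncol(pae), all(pae >= 0))
  }
  if (!is.null(partition)) partition <- as.integer(partition)
  structure(list(plddt = as.numeric(plddt), pae = pae,
                 partition = partition, id = id),
            class = "prediction_scores")
}

#' Read predictor-output scores from JSON
#'
#' Expects `{"plddt": [...], "pae": [[...]], "partition": [...]}` with
#' `pae` and `partition` optional.
#'
#' @param path JSON file.
#' @return A [prediction_scores()] object.
#' @export
read_prediction_scores <- function(path) {
  x <- jsonlite::fromJSON(path)
  prediction_scores(
    plddt = x$plddt,
    pae = if (!is.null(x$pae)) as.matrix(x$pae),
    partition = x$partition,
    id = if (!is.null(x$id)) x$id else basename(path)
  )
}

#' Mean pLDDT
#'
#' @param v numeric pLDDT vector, or a `prediction_scores` object.
#' @return Arithmetic mean in `[0, 100]`.
#' @export
mean_plddt <- function(v) {
  if (inherits(v, "prediction_scores")) v <- v$plddt
  if (length(v) == 0) abort("empty pLDDT vector")
  mean(v)
}

#' Mean inter-chain predicted aligned error
#'
#' The mean of `pae[i, j]` over all ordered residue pairs whose chains
#' differ; low inter-PAE indicates a confidently placed interface and is used
#' to rank complex predictions.
#'
#' @param pae square PAE matrix.
#' @param partition integer vector of chain ids per residue (at least two
#'   distinct chains).
#' @return Non-negative scalar.
#' @export
inter_pae <- function(pae, partition) {
  pae <- as.matrix(pae)
  partition <- as.integer(partition)
  stopifnot(length(partition) == nrow(pae))
  if (length(unique(partition)) < 2) {
    abort("inter-chain PAE is undefined for a single-chain partition")
  }
  cross <- outer(partition, partition, `!=`)
  mean(pae[cross])
}

# TM-score distance scale for N residues (N clamped to >= 19 so d0 > 0)
tm_d0 <- function(n) {
  1.24 * (max(n, 19) - 15)^(1 / 3) - 1.8
}

#' Predicted TM-score from a PAE matrix
#'
#' `pTM = max_i mean_j 1 / (1 + (pae[i, j] / d0)^2)` with
#' `d0 = 1.24 * (max(N, 19) - 15)^(1/3) - 1.8`, the published PAE-derived
#' estimate of the TM-score an aligned structure pair would attain.
#'
#' @param pae square PAE matrix.
#' @return Scalar in `(0, 1]`.
#' @export
ptm_from_pae <- function(pae) {
  pae <- as.matrix(pae)
  d0 <- tm_d0(nrow(pae))
  max(rowMeans(1 / (1 + (pae / d0)^2)))
}

#' Predicted interface TM-score from a PAE matrix
#'
#' As [ptm_from_pae()], but for every anchor residue `i` the inner mean runs
#' only over residues `j` in chains other than `i`'s, scoring the interface
#' rather than the whole complex.
#'
#' @inheritParams inter_pae
#' @return Scalar in `(0, 1]`.
#' @export
iptm_from_pae <- function(pae, partition) {
  pae <- as.matrix(pae)
  partition <- as.integer(partition)
  stopifnot(length(partition) == nrow(pae))
  if (length(unique(partition)) < 2) {
    abort("ipTM is undefined for a single-chain partition")
  }
  d0 <- tm_d0(nrow(pae))
  term <- 1 / (1 + (pae / d0)^2)
  cross <- outer(partition, partition, `!=`)
  term[!cross] <- NA_real_
  max(rowMeans(term, na.rm = TRUE))
}

#' Rank predictions by the mode-appropriate confidence metric
#'
#' Single-chain predictions are ranked by mean pLDDT; complexes by predicted
#' TM-score (ipTM when a chain partition is available, pTM otherwise). Both
#' rankings are descending and stable for ties.
#'
#' @param scores a list of [prediction_scores()] objects.
#' @param mode `"single"` or `"complex"`.
#' @return A tibble with columns `id`, `metric`, `value` and `rank`, ordered
#'   best first.
#' @export
rank_predictions <- function(scores, mode = c("single", "complex")) {
  mode <- match.arg(mode)
  vals <- purrr::imap(scores, function(s, i) {
    id <- if (!is.null(s$id)) s$id else as.character(i)
    if (mode == "single") {
      tibble(id = id, metric = "mean_plddt", value = mean_plddt(s))
    } else if (!is.null(s$partition) &&
               length(unique(s$partition)) >= 2) {
      tibble(id = id, metric = "iptm", value = iptm_from_pae(s$pae, s$partition))
    } else {
      tibble(id = id, metric = "ptm", value = ptm_from_pae(s$pae))
    }
  })
  out <- bind_rows(vals)
  out <- out[order(-out$value), , drop = FALSE]   # stable for ties
  out$rank <- seq_len(nrow(out))
  out
}
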