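#' Batch run configuration
#'
#' Defaults mirror the standard prediction setup: five models, three
#' recycles, 10% shape padding, one seed sample, no early stopping unless a
#' `stop_at_score` (mean pLDDT for single chains, pTM/ipTM scale for
#' complexes) or a `recycle_tolerance` (structure-change threshold between
#' recycles) is given.
#'
#' @param num_models number of predictor models, default 5.
#' @param num_recycles recycles per model, default 3.
#' @param stop_at_score optional early-stop score threshold.
#' @param recycle_tolerance optional structure-change threshold below which
#'   recycling stops.
#' @param pad_fraction shape padding fraction, default 0.1.
#' @param num_samples number of random-seed samples per query.
#' @param use_templates whether template-mode model configurations are used
#'   (changes which models share a compiled configuration).
#' @param is_training pass-through flag activating the predictor's stochastic
#'   (dropout) path for ensemble sampling.
#' @return A list of class `run_config`.
#' @export
run_config <- function(num_models = 5L, num_recycles = 3L,
                       stop_at_score = NULL, recycle_tolerance = NULL,
                       pad_fraction = 0.1, num_samples = 1L,
                       use_templates = FALSE, is_training = FALSE) {
  stopifnot(num_models >= 1, num_models <= 5, num_recycles >= 1,
            num_samples >= 1, pad_fraction >= 0)
  structure(
    list(num_models = as.integer(num_models),
         num_recycles = as.integer(num_recycles),
         stop_at_score = stop_at_score,
         recycle_tolerance = recycle_tolerance,
         pad_fraction = pad_fraction,
         num_samples = as.integer(num_samples),
         use_templates = isTRUE(use_templates),
         is_training = isTRUE(is_training)),
    class = "run_config"
  )
}

#' Compiled-configuration keys per model
#'
#' Compiling a predictor graph is expensive, but models can share a compiled
#' configuration and merely swap weights. Without templates all five models
#' run under one configuration (model 5's); with templates models 1-2 share
#' model 1's configuration and models 3-5 share model 3's.
#'
#' @param use_templates logical.
#' @return Named character vector mapping `model1..model5` to a config key.
#' @export
config_keys <- function(use_templates = FALSE) {
  if (isTRUE(use_templates)) {
    stats::setNames(c("cfg1", "cfg1", "cfg3", "cfg3", "cfg3"),
                    paste0("model", 1:5))
  } else {
    stats::setNames(rep("cfg5", 5), paste0("model", 1:5))
  }
}

#' Deterministic seed series for structure sampling
#'
#' @param num_samples number of seeds, `>= 1`.
#' @param base_seed first seed.
#' @return Integer vector `base_seed, base_seed + 1, ...`.
#' @export
sample_seeds <- function(num_samples, base_seed = 0L) {
  stopifnot(num_samples >= 1)
  as.integer(base_seed) + seq_len(num_samples) - 1L
}

#' Run a batch of queries against a predictor
#'
#' Queries are processed in ascending total length (ties by input order) so
#' that one padded compile shape serves as many queries as possible: a query
#' reuses any cached shape at least as large as itself (in both padded length
#' and row count) under its models' configuration key, and a compile event
#' fires only when no cached shape fits. Per query and seed sample, models
#' run in fixed order; within a model, recycling proceeds up to
#' `num_recycles` but stops early when the predictor's structure change drops
#' below `recycle_tolerance` or the ranking score reaches `stop_at_score`;
#' once `stop_at_score` is met the remaining models (and samples) for that
#' query are skipped entirely. A predictor error marks the query failed and
#' the batch continues. Every compile, model evaluation and recycle is
#' recorded in the event log.
#'
#' @param queries a named list of `feature_set`s, [msa]s, or plain sequences.
#' @param predictor a function
#'   `(feature_set, model_id, recycle_index, seed, is_training)` returning a
#'   list with `plddt`, optional `pae`/`partition`, and `structure_change`.
#' @param config a [run_config()].
#' @param base_seed first sampling seed.
#' @return A list with `results` (tibble: query, seed, model, score metric
#'   and value, ranked best-first within query), `events` (tibble log) and
#'   `failed` (character vector of failed query names).
#' @export
run_batch <- function(queries, predictor, config = run_config(),
                      base_seed = 0L) {
  stopifnot(inherits(config, "run_config"), is.function(predictor))
  if (is.null(names(queries))) {
    names(queries) <- paste0("query", seq_along(queries))
  }
  fsets <- purrr::map(queries, as_feature_set)
  lens <- vapply(fsets, function(f) f$total_length, integer(1))
  order_idx <- order(lens)                       # stable: ties by input order
  keys <- config_keys(config$use_templates)
  seeds <- sample_seeds(config$num_samples, base_seed)

  cache <- list()    # per config key: list of c(padded_length, padded_rows)
  events <- list()
  results <- list()
  failed <- character(0)
  log_event <- function(...) events[[length(events) + 1]] <<- tibble(...)

  for (qi in order_idx) {
    qname <- names(fsets)[[qi]]
    fs <- make_fixed_size(fsets[[qi]], config$pad_fraction)
    multi <- length(fs$chain_partition) >= 2
    part <- if (multi) chain_index(fs)
    stopped <- FALSE
    ok <- TRUE
    for (seed in seeds) {
      if (stopped || !ok) break
      for (model_id in seq_len(config$num_models)) {
        if (stopped || !ok) break
        key <- keys[[paste0("model", model_id)]]
        shape <- fit_cached_shape(cache[[key]], fs$total_length, fs$padded_rows)
        if (is.null(shape)) {
          shape <- c(fs$padded_length, fs$padded_rows)
          cache[[key]] <- c(cache[[key]], list(shape))
          log_event(event = "compile", query = qname, model = model_id,
                    recycle = NA_integer_, seed = seed,
                    value = shape[[1]], detail = key)
        }
        for (recycle in seq_len(config$num_recycles)) {
          res <- tryCatch(
            predictor(fs, model_id, recycle, seed, config$is_training),
            error = function(e) e
          )
          if (inherits(res, "error")) {
            log_event(event = "failed", query = qname, model = model_id,
                      recycle = recycle, seed = seed, value = NA_real_,
                      detail = conditionMessage(res))
            failed <- c(failed, qname)
            ok <- FALSE
            break
          }
          score <- batch_score(res, multi, part)
          log_event(event = "evaluate", query = qname, model = model_id,
                    recycle = recycle, seed = seed, value = score$value,
                    detail = score$metric)
          results[[length(results) + 1]] <- tibble(
            query = qname, seed = seed, model = model_id, recycle = recycle,
            metric = score$metric, value = score$value
          )
          if (!is.null(config$stop_at_score) &&
              score$value >= config$stop_at_score) {
            log_event(event = "early_stop", query = qname, model = model_id,
                      recycle = recycle, seed = seed, value = score$value,
                      detail = "stop_at_score")
            stopped <- TRUE
            break
          }
          if (!is.null(config$recycle_tolerance) &&
              !is.null(res$structure_change) &&
              res$structure_change < config$recycle_tolerance) {
            log_event(event = "recycle_stop", query = qname, model = model_id,
                      recycle = recycle, seed = seed,
                      value = res$structure_change,
                      detail = "recycle_tolerance")
            break
          }
        }
      }
    }
  }
  res_tbl <- if (length(results) == 0) {
    tibble(query = character(0), seed = integer(0), model = integer(0),
           recycle = integer(0), metric = character(0), value = numeric(0))
  } else {
    bind_rows(results) |>
      group_by(.data$query) |>
      arrange(desc(.data$value), .by_group = TRUE) |>
      ungroup()
  }
  list(
    results = res_tbl,
    events = if (length(events) == 0) {
      tibble(event = character(0), query = character(0), model = integer(0),
             recycle = integer(0), seed = integer(0), value = numeric(0),
             detail = character(0))
    } else bind_rows(events),
    failed = unique(failed)
  )
}

# smallest cached shape (by padded length) able to host the query, or NULL
fit_cached_shape <- function(shapes, total_length, rows) {
  if (is.null(shapes)) return(NULL)
  fits <- Filter(function(s) s[[1]] >= total_length && s[[2]] >= rows, shapes)
  if (length(fits) == 0) return(NULL)
  fits[[which.min(vapply(fits, `[[`, numeric(1), 1))]]
}

# ranking score under the scheduler's stop/rank rules
batch_score <- function(res, multi, part) {
  if (multi && !is.null(res$pae)) {
    p <- if (!is.null(res$partition)) res$partition else part
    list(metric = "iptm", value = iptm_from_pae(res$pae, p))
  } else {
    list(metric = "mean_plddt", value = mean_plddt(res$plddt))
  }
}

# accept a feature_set, an msa, or a bare sequence string as a batch query
as_feature_set <- function(q) {
  if (is_feature_set(q)) return(q)
  if (is_msa(q)) return(build_feature_set(q))
  if (is.character(q) && length(q) == 1) {
    return(build_feature_set(msa(header = "query", aligned = q)))
  }
  abort("queries must be feature sets, MSAs, or sequence strings")
}
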