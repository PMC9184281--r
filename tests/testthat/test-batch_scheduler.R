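flat_script <- function(plddt = 70, models = 1:5, recycles = 1:3, ...) {
  # recycle varies fastest so a length-3 plddt vector scripts the recycles
  base <- expand.grid(recycle = recycles, model = models)
  base$plddt <- plddt
  extra <- list(...)
  for (nm in names(extra)) base[[nm]] <- extra[[nm]]
  base
}

test_that("model configuration sharing matches the template setting", {
  no_tpl <- config_keys(FALSE)
  expect_equal(length(unique(no_tpl)), 1)
  expect_equal(names(no_tpl), paste0("model", 1:5))
  tpl <- config_keys(TRUE)
  expect_equal(length(unique(tpl)), 2)
  expect_equal(unname(tpl[1:2]), rep(tpl[["model1"]], 2))
  expect_equal(unname(tpl[3:5]), rep(tpl[["model3"]], 3))
})

test_that("seed series are consecutive and disjoint across base ranges", {
  expect_equal(sample_seeds(1, 7), 7L)
  expect_equal(sample_seeds(3, 0), c(0L, 1L, 2L))
  expect_equal(length(intersect(sample_seeds(5, 0), sample_seeds(5, 5))), 0)
})

test_that("early stop halts recycling and skips the remaining models", {
  pred <- make_mock_predictor(flat_script(86))
  out <- run_batch(list(q = strrep("A", 40)), pred,
                   run_config(stop_at_score = 85))
  expect_equal(sum(out$events$event == "evaluate"), 1)
  expect_equal(sum(out$events$event == "early_stop"), 1)
  # without a threshold every model runs every recycle
  out2 <- run_batch(list(q = strrep("A", 40)),
                    make_mock_predictor(flat_script(70)), run_config())
  expect_equal(sum(out2$events$event == "evaluate"), 5 * 3)
  # a mid-script crossing stops at the recycle that reaches the threshold
  script <- flat_script(c(60, 70, 90))   # recycles 1..3 per model
  out3 <- run_batch(list(q = strrep("A", 40)), make_mock_predictor(script),
                    run_config(stop_at_score = 85))
  expect_equal(sum(out3$events$event == "evaluate"), 3)
})

test_that("recycle tolerance stops recycling without skipping models", {
  script <- flat_script(70, structure_change = 0.01)
  out <- run_batch(list(q = strrep("A", 40)), make_mock_predictor(script),
                   run_config(recycle_tolerance = 0.5))
  expect_equal(sum(out$events$event == "evaluate"), 5)  # one recycle per model
})

test_that("the compile cache reuses padded shapes across a sorted batch", {
  pred <- make_mock_predictor(flat_script(70))
  qs <- list(a = strrep("A", 100), b = strrep("C", 105),
             c = strrep("D", 109), d = strrep("E", 120))
  out <- run_batch(qs, pred, run_config())
  compiles <- out$events[out$events$event == "compile", ]
  expect_equal(nrow(compiles), 2)
  expect_equal(compiles$value, c(110, 132))   # ceil(100*1.1), ceil(120*1.1)
  # processing order is ascending length (ties by input order)
  evs <- out$events[out$events$event == "evaluate", ]
  expect_equal(unique(evs$query), c("a", "b", "c", "d"))
  # with templates the same batch needs one compile per configuration key
  out_tpl <- run_batch(qs["a"], pred, run_config(use_templates = TRUE))
  expect_equal(nrow(out_tpl$events[out_tpl$events$event == "compile", ]), 2)
})

test_that("batch runs are deterministic and work is monotone in the stop threshold", {
  script <- flat_script(c(60, 75, 88))
  pred <- make_mock_predictor(script)
  qs <- list(a = strrep("A", 30), b = strrep("C", 50))
  r1 <- run_batch(qs, pred, run_config(stop_at_score = 85), base_seed = 3)
  r2 <- run_batch(qs, pred, run_config(stop_at_score = 85), base_seed = 3)
  expect_identical(r1$results, r2$results)
  expect_identical(r1$events, r2$events)
  # raising the threshold never reduces the number of evaluations
  evals <- vapply(c(70, 80, 90, 101), function(thr) {
    out <- run_batch(qs, pred, run_config(stop_at_score = thr))
    sum(out$events$event == "evaluate")
  }, numeric(1))
  expect_true(all(diff(evals) >= 0))
})

test_that("a predictor failure marks the query failed and the batch continues", {
  script <- flat_script(70, models = 1:5, recycles = 1:3)
  good <- make_mock_predictor(script)
  pred <- function(fs, model_id, recycle, seed, is_training) {
    if (fs$total_length == 33) stop("boom")
    good(fs, model_id, recycle, seed, is_training)
  }
  out <- run_batch(list(bad = strrep("A", 33), ok = strrep("C", 44)),
                   pred, run_config())
  expect_equal(out$failed, "bad")
  expect_equal(sort(unique(out$results$query)), "ok")
  expect_equal(sum(out$events$event == "evaluate" & out$events$query == "ok"),
               15)
})

test_that("multi-chain queries stop on the complex metric, not pLDDT", {
  m <- make_msa(3, 20, seed = 9)
  fs <- build_feature_set(m, chain_lengths = c(10, 10))
  # confident interface (inter-PAE 0 -> ipTM 1) despite mediocre pLDDT
  script <- flat_script(60, inter_pae = 0, intra_pae = 0)
  out <- run_batch(list(cx = fs), make_mock_predictor(script),
                   run_config(stop_at_score = 0.9))
  expect_equal(sum(out$events$event == "evaluate"), 1)
  expect_equal(out$results$metric[[1]], "iptm")
})
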