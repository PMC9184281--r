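test_that("max_seq_id_filter keeps a greedy non-redundant subset in priority order", {
  two <- tibble::tibble(header = c("a", "b"),
                        aligned = c("ACDEACDEAC", "ACDEACDEAC"))
  expect_equal(max_seq_id_filter(two, 0.95)$header, "a")
  one <- two[1, ]
  expect_equal(max_seq_id_filter(one, 0.95)$header, "a")
  # rows 1,2 at 96% mutual identity, row 3 unrelated: priority order wins
  three <- tibble::tibble(
    header = c("r1", "r2", "r3"),
    aligned = c(strrep("D", 25),
                paste0("E", strrep("D", 24)),
                strrep("K", 25))
  )
  expect_equal(oracle_identity(three$aligned[[1]], three$aligned[[2]]), 0.96)
  expect_equal(max_seq_id_filter(three, 0.95)$header, c("r1", "r3"))
})

test_that("max_seq_id_filter output matches the brute-force all-pairs oracle", {
  for (seed in 1:4) {
    m <- make_msa(49, 40, qid_targets = c(0.3, 0.8, 0.95, 1.0), seed = seed)
    rows <- m[-1, ]
    kept <- max_seq_id_filter(rows, 0.9)
    # no kept pair exceeds the threshold
    expect_lte(oracle_max_pairwise(kept$aligned), 0.9)
    # and the greedy trace is reproduced exactly by a brute-force rescan
    idm <- oracle_identity_matrix(rows$aligned)
    keep <- integer(0)
    for (i in seq_len(nrow(rows))) {
      if (all(idm[i, keep] <= 0.9)) keep <- c(keep, i)
    }
    expect_identical(kept$header, rows$header[keep])
  }
})

test_that("qsc filter activates only at min_enable hits and passes self-like rows", {
  q <- make_msa(0, 50, seed = 9)
  # 99 hits, all unrelated junk: filter stays disabled
  junk <- make_msa(99, 50, qid_targets = 0.02, seed = 10)
  expect_equal(nrow(qsc_filter(junk, min_qsc = 0.8, min_enable = 100)), 100)
  # 100 copies of the query score >= 0.8 bits/column under BLOSUM62
  copies <- as_msa(tibble::tibble(
    header = c("q", paste0("c", 1:100)),
    aligned = rep(q$aligned[[1]], 101)
  ))
  expect_equal(nrow(qsc_filter(copies, min_qsc = 0.8, min_enable = 100)), 101)
  # query-only input is untouched
  expect_equal(nrow(qsc_filter(q)), 1)
})

test_that("maxdiv_select is deterministic farthest-point with input-order ties", {
  m <- make_msa(10, 20, qid_targets = 0.5, seed = 2)
  rows <- m[-1, ]
  expect_identical(maxdiv_select(rows, 50), rows)
  expect_identical(maxdiv_select(rows, 10), rows)
  # hand trace: identities r1-r2 0.9, r1-r3 0.2, r2-r3 0.2; k = 2 -> {r1, r3}
  tri <- tibble::tibble(
    header = c("r1", "r2", "r3"),
    aligned = c("AAAAAAAAAA", "AAAAAAAAAC", "DDAADDDDDD")
  )
  expect_equal(oracle_identity(tri$aligned[[1]], tri$aligned[[2]]), 0.9)
  expect_equal(oracle_identity(tri$aligned[[1]], tri$aligned[[3]]), 0.2)
  expect_equal(maxdiv_select(tri, 2)$header, c("r1", "r3"))
  # a 50-member cluster reduces to exactly 10
  big <- make_msa(50, 60, qid_targets = 0.7, seed = 3)[-1, ]
  expect_equal(nrow(maxdiv_select(big, 10)), 10)
})

test_that("bucketed filter caps saturated buckets and passes small ones through", {
  params <- filter_params(filter_min_enable = 50, diff = 20)
  m <- make_msa(300, 60, qid_targets = c(0.1, 0.3, 0.5, 0.7, 0.9), seed = 1)
  f <- bucketed_diff_filter(m, params)
  expect_equal(nrow(f), 1 + 5 * 20)
  # a bucket below min_enable is passed through unfiltered
  small <- make_msa(49, 60, qid_targets = 0.5, seed = 5)
  expect_equal(nrow(bucketed_diff_filter(small, params)), 50)
  # query-only MSA stays query-only
  q <- make_msa(0, 60, seed = 6)
  expect_equal(nrow(bucketed_diff_filter(q, params)), 1)
})

test_that("bucket boundaries are closed-first then left-open as printed", {
  bp <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
  b <- foldprep:::assign_buckets(c(0, 0.1, 0.2, 0.21, 0.4, 0.5, 0.8, 0.81, 1), bp)
  expect_equal(b, c(1, 1, 1, 2, 2, 3, 4, 5, 5))
})

test_that("bucketed filtering is idempotent, keeps the query first and isolates buckets", {
  params <- filter_params(filter_min_enable = 40, diff = 15)
  m <- make_msa(250, 50, qid_targets = c(0.1, 0.5, 0.9), seed = 7)
  f1 <- bucketed_diff_filter(m, params)
  f2 <- bucketed_diff_filter(f1, params)
  expect_identical(f1$aligned, f2$aligned)
  expect_equal(f1$header[[1]], m$header[[1]])
  # deleting one bucket entirely never changes what other buckets keep
  qid <- query_identity(m)
  drop_mid <- c(TRUE, !(qid > 0.4 & qid <= 0.6))
  m_wo <- as_msa(m[drop_mid, ])
  f_wo <- bucketed_diff_filter(m_wo, params)
  in_mid <- function(f) {
    qi <- query_identity(f)
    f[-1, ][qi > 0.4 & qi <= 0.6, ]$header
  }
  keep_other <- setdiff(f1$header, c(f1$header[[1]], in_mid(f1)))
  keep_other_wo <- setdiff(f_wo$header, f_wo$header[[1]])
  expect_identical(keep_other_wo, keep_other)
})

test_that("stage-1 filtering is applied per cluster, never across clusters", {
  dup <- tibble::tibble(header = c("a", "b", "c"),
                        aligned = rep(strrep("ACDEF", 6), 3))
  expect_equal(nrow(stage1_cluster_filter(dup)), 1)
  # the same sequence in two different clusters survives in both
  c1 <- stage1_cluster_filter(dup[1, ])
  c2 <- stage1_cluster_filter(dup[2, ])
  expect_equal(nrow(dplyr::bind_rows(c1, c2)), 2)
  single <- dup[1, ]
  expect_identical(stage1_cluster_filter(single), single)
})
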