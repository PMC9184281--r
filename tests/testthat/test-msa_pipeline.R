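test_that("E-value acceptance is strict and monotone in the threshold", {
  hits <- tibble::tibble(target_id = c("a", "b", "c"),
                         evalue = c(0.05, 0.1, 0.2))
  expect_equal(evalue_accept(hits)$target_id, "a")
  expect_equal(nrow(evalue_accept(hits[0, ])), 0)
  low <- tibble::tibble(target_id = "a", evalue = 1e-10)
  expect_identical(evalue_accept(low), low)
  expect_error(evalue_accept(tibble::tibble(evalue = -1)), "negative")
  # monotonicity: lowering the threshold never accepts more
  set.seed(11)
  tbl <- tibble::tibble(target_id = as.character(1:50), evalue = runif(50))
  counts <- vapply(c(0.8, 0.4, 0.2, 0.1, 0.05),
                   function(t) nrow(evalue_accept(tbl, t)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("cluster expansion composes member alignments through the representative", {
  # representative 'ACDEFG' hits the query over residues 1-5 (query col 3
  # gapped); member m1 differs from the representative at residue 3 (D -> W)
  ct <- tibble::tibble(
    cluster_id = "c1", member_id = c("c1", "m1"),
    aligned_member = c("ACDEFG", "ACWEFG"),
    aligned_representative = c("ACDEFG", "ACDEFG")
  )
  hit <- tibble::tibble(
    query_id = "q", target_id = "c1", fident = 1, evalue = 0.01,
    qstart = 1L, qend = 6L, qlen = 6L, tstart = 1L, tend = 5L, tlen = 6L,
    aligned_target = "AC-DEF", cluster_id = "c1",
    taxid = NA_integer_, accession = NA_character_
  )
  rows <- expand_cluster_hits(hit, ct)
  expect_equal(rows$aligned, c("AC-DEF", "AC-WEF"))

  # a member insertion position in the representative row stays an insertion
  hit2 <- hit
  hit2$aligned_target <- "ACdEFG"
  hit2$tend <- 6L
  rows2 <- expand_cluster_hits(hit2, ct, max_seq_id = 1)
  expect_equal(rows2$aligned[[2]], "ACwEFG")

  # a truncated hit starting at representative residue 2 shifts the frame
  hit3 <- hit
  hit3$aligned_target <- "CDEFG-"
  hit3$tstart <- 2L
  hit3$tend <- 6L
  rows3 <- expand_cluster_hits(hit3, ct)
  expect_equal(rows3$aligned, c("CDEFG-", "CWEFG-"))

  # singleton cluster yields exactly the representative row
  ct1 <- ct[1, ]
  expect_equal(expand_cluster_hits(hit, ct1)$aligned, "AC-DEF")

  # identical members collapse to one row through the per-cluster filter
  ct_dup <- tibble::tibble(
    cluster_id = "c1", member_id = c("c1", "m1", "m2"),
    aligned_member = "ACDEFG", aligned_representative = "ACDEFG"
  )
  expect_equal(nrow(expand_cluster_hits(hit, ct_dup)), 1)

  bad <- hit
  bad$cluster_id <- "missing"
  expect_error(expand_cluster_hits(bad, ct), "unknown cluster")
})

test_that("the two-database build filters independently and concatenates", {
  q <- make_msa(0, 60, seed = 20)
  query <- c(q = q$aligned[[1]])
  empty <- hits_from_msa(q)$hits
  out <- build_msas(query, empty, empty, hits_from_msa(q)$clusters)
  expect_equal(nrow(out$uniref), 1)
  expect_equal(nrow(out$env), 1)
  expect_equal(nrow(out$combined), 1)

  # saturated input: combined = query + per-bucket caps from both databases
  params <- filter_params(filter_min_enable = 30, diff = 10)
  mk <- make_msa(200, 60, qid_targets = c(0.3, 0.7), seed = 21)
  query2 <- c(q = mk$aligned[[1]])
  fu <- hits_from_msa(mk, prefix = "u")
  fe <- hits_from_msa(mk, prefix = "e")
  out2 <- build_msas(query2, fu$hits, fe$hits,
                     dplyr::bind_rows(fu$clusters, fe$clusters), params,
                     qsc = 0, qsc_min_enable = 1e9)
  expect_equal(nrow(out2$uniref), 1 + 2 * 10)
  expect_equal(nrow(out2$combined), 1 + 2 * (2 * 10))
})

test_that("the score filter can empty a bucket below its enable threshold", {
  # junk rows at ~5% identity score below 0.8 bits/col and are removed by the
  # realignment-stage qsc filter before bucketing; with the qsc stage off they
  # would saturate the first bucket instead
  q <- make_msa(0, 60, seed = 22)
  junk <- make_msa(150, 60, qid_targets = 0.05, seed = 23)
  f <- hits_from_msa(as_msa(dplyr::bind_rows(q[1, ], junk[-1, ])))
  params <- filter_params(filter_min_enable = 100, diff = 5)
  with_qsc <- build_msas(c(q = q$aligned[[1]]), f$hits, f$hits[0, ],
                         f$clusters, params)
  without_qsc <- build_msas(c(q = q$aligned[[1]]), f$hits, f$hits[0, ],
                            f$clusters, params, qsc_min_enable = 1e9)
  expect_lt(nrow(with_qsc$uniref), nrow(without_qsc$uniref))
  expect_equal(nrow(without_qsc$uniref), 1 + 5)   # saturated bucket capped
})

test_that("naive search finds self hits at full identity and ranks by E-value", {
  q <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  db <- c(self = q, junk = "GGGGGGGPPPPPPPPPPGGGGGGG")
  h <- naive_search(c(q = q), db)
  expect_equal(h$target_id[[1]], "self")
  expect_equal(h$fident[[1]], 1.0)
  expect_lt(h$evalue[[1]], 1e-10)
  expect_equal(nrow(naive_search(c(q = q), character(0))), 0)
  # hit rows drop straight into an MSA: full query frame
  expect_equal(nchar(gsub("[a-z]", "", h$aligned_target[[1]])), nchar(q))
})

test_that("unrelated reversed decoys score insignificantly", {
  # empirical null check: E > 0.1 for the large majority of random decoys
  set.seed(7)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  ev <- vapply(1:40, function(i) {
    q <- paste0(sample(aa, 80, TRUE), collapse = "")
    d <- paste0(rev(sample(aa, 80, TRUE)), collapse = "")
    naive_search(c(q = q), c(d = d))$evalue[[1]]
  }, numeric(1))
  expect_gte(mean(ev > 0.1), 0.8)
  expect_gt(stats::median(ev), 0.1)
})

test_that("transitive composition tracks direct alignment identity", {
  set.seed(30)
  reps <- make_msa(3, 80, qid_targets = 0.6, seed = 31)
  query <- reps$aligned[[1]]
  ct <- make_cluster_table(
    stats::setNames(as.list(reps$aligned[-1]), paste0("c", 1:3)),
    members_per_cluster = 3, member_identity = 0.8, seed = 32
  )
  hits <- naive_search(c(q = query), stats::setNames(reps$aligned[-1],
                                                     paste0("c", 1:3)))
  hits$cluster_id <- hits$target_id
  rows <- expand_cluster_hits(hits, ct, max_seq_id = 1)
  for (i in seq_len(nrow(rows))) {
    composed <- query_identity(rows$aligned[[i]], query)
    member_seq <- ct$aligned_member[ct$member_id == rows$header[[i]]]
    direct <- naive_search(c(q = query), c(m = gsub("-", "", member_seq)))
    direct_id <- direct$fident[[1]] * (direct$qend[[1]] - direct$qstart[[1]] + 1) /
      direct$qlen[[1]]
    expect_gte(direct_id, composed - 0.05)
  }
})
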