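test_that("homo-oligomer assembly lays copies out block-diagonally", {
  m <- make_msa(2, 8, qid_targets = 0.75, seed = 1)
  expect_identical(assemble_homooligomer(m, 1), m)
  dup <- assemble_homooligomer(m, 2)
  expect_equal(nrow(dup), 1 + 2 * 2)
  expect_equal(query_length(dup), 16)
  # each non-query row carries residues in exactly one block
  L <- 8
  for (i in 2:nrow(dup)) {
    blocks <- substring(dup$aligned[[i]], c(1, L + 1), c(L, 2 * L))
    nongap <- vapply(blocks, function(b) grepl("[A-Z]", b), logical(1))
    expect_equal(sum(nongap), 1)
  }
  expect_error(assemble_homooligomer(m, 0), ">= 1")
})

test_that("homo-oligomer copying conserves per-column residue content", {
  m <- make_msa(15, 12, qid_targets = c(0.4, 0.8), seed = 2)
  copies <- 3
  big <- assemble_homooligomer(m, copies)
  single_counts <- foldprep:::encode_rows(m$aligned[-1])
  big_enc <- foldprep:::encode_rows(big$aligned[-1])
  L <- query_length(m)
  for (b in seq_len(copies)) {
    block <- big_enc[, ((b - 1) * L + 1):(b * L), drop = FALSE]
    block <- block[rowSums(block != 0) > 0, , drop = FALSE]
    for (col in seq_len(L)) {
      expect_equal(table(factor(block[, col], levels = 0:21)),
                   table(factor(single_counts[, col], levels = 0:21)))
    }
  }
})

test_that("hetero-oligomer assembly stacks query, paired rows, then chain blocks", {
  a <- make_msa(2, 6, qid_targets = 0.8, seed = 3)
  b <- make_msa(3, 4, qid_targets = 0.8, seed = 4)
  # no paired rows: purely block-diagonal
  h0 <- assemble_heterooligomer(NULL, list(a, b))
  expect_equal(nrow(h0), 1 + 2 + 3)
  expect_equal(query_length(h0), 10)
  # one paired block + 2 + 3 unpaired rows
  paired <- tibble::tibble(
    block = 1L, species_taxid = 9606L, chain = 1:2,
    target_id = c("pa", "pb"),
    aligned_target = c(a$aligned[[2]], b$aligned[[2]]),
    evalue = c(1e-5, 1e-6), combined_evalue = 1.1e-5
  )
  h1 <- assemble_heterooligomer(paired, list(a, b))
  expect_equal(nrow(h1), 1 + 1 + 5)
  # the paired row has residues in every chain
  prow <- h1$aligned[[2]]
  expect_true(grepl("[A-Z]", substr(prow, 1, 6)))
  expect_true(grepl("[A-Z]", substr(prow, 7, 10)))
  # chain-length mismatch is rejected
  badp <- paired
  badp$aligned_target <- c(a$aligned[[2]], "ACD")
  expect_error(assemble_heterooligomer(badp, list(a, b)), "length")
})

test_that("residue index jumps by the chain gap and rejects sub-cap gaps", {
  expect_equal(build_residue_index(4), c(0, 1, 2, 3))
  expect_equal(build_residue_index(c(3, 3), 200), c(0, 1, 2, 203, 204, 205))
  expect_error(build_residue_index(c(3, 3), 32), "32")
  expect_error(build_residue_index(c(3, 3), 10), "32")
})

test_that("relative-position bins clip at the cap exactly", {
  idx <- c(0L, 5L)
  expect_equal(relative_position_bins(0L)[1, 1], 32)
  b <- relative_position_bins(c(0L, 32L, 10032L))
  expect_equal(b[2, 1], b[3, 1])          # separations 32 and 10,032 identical
  # sweep: bins become constant exactly from separation 32 onward
  bins <- relative_position_bins(0:100)[, 1]
  changes <- which(diff(bins) != 0)
  expect_equal(max(changes), 32)          # last change entering separation 32
  expect_equal(length(unique(bins[33:101])), 1)
  # symmetry: bin(i,j) reflects around the cap
  m <- relative_position_bins(c(0L, 7L, 40L))
  expect_equal(m + t(m), matrix(2 * 32, 3, 3))
})

test_that("cross-chain bins are extreme whenever the chain gap exceeds twice the cap", {
  idx <- build_residue_index(c(5, 5), chain_gap = 200)
  bins <- relative_position_bins(idx)
  cross <- outer(rep(1:2, each = 5), rep(1:2, each = 5), `!=`)
  expect_true(all(bins[cross] %in% c(0, 64)))
})

test_that("MSA subsampling respects caps, keeps the query and is seed-reproducible", {
  small <- make_msa(99, 10, seed = 5)
  s <- subsample_msa(small, seed = 1)
  expect_equal(s$cluster_rows, 1:100)
  expect_equal(s$extra_rows, integer(0))
  big <- make_msa(4999, 10, seed = 6)
  s1 <- subsample_msa(big, seed = 42)
  expect_equal(length(s1$cluster_rows), 512)
  expect_equal(length(s1$extra_rows), 1024)
  expect_true(1 %in% s1$cluster_rows)
  expect_equal(length(intersect(s1$cluster_rows, s1$extra_rows)), 0)
  s2 <- subsample_msa(big, seed = 42)
  expect_identical(s1, s2)
  s3 <- subsample_msa(big, seed = 43)
  expect_false(identical(s1$cluster_rows, s3$cluster_rows))
})

test_that("fixed-size padding extends features with gap tokens and a sentinel", {
  m <- make_msa(5, 100, seed = 7)
  fs <- build_feature_set(m)
  expect_equal(fs$padded_length, 100)
  p <- make_fixed_size(fs, 0.1)
  expect_equal(p$padded_length, 110)
  expect_true(all(p$msa_matrix[, 101:110] == 0))
  expect_equal(p$residue_index[101:110], rep(-1L, 10))
  p0 <- make_fixed_size(fs, 0)
  expect_equal(p0$padded_length, 100)
  # two-chain feature sets carry the partition through
  m2 <- make_msa(3, 10, seed = 8)
  fs2 <- build_feature_set(m2, chain_lengths = c(4, 6))
  expect_equal(chain_index(fs2), rep(1:2, c(4, 6)))
  expect_equal(diff(fs2$residue_index)[4], 201)
})
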