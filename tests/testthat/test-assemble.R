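test_that("agreeing overlap bases keep the base with the agree-probability", {
  s <- "ACGTACGT"
  eps <- rep(1e-4, 8)
  r <- reconstruct(s, s, eps, eps, overlap = 8)
  expect_equal(r$sequence, s)
  expect_equal(r$probs, rep(prob_match_given_equal(1e-4, 1e-4), 8))
  expect_equal(r$overlap_len, 8L)
  expect_equal(r$n_mismatches_resolved, 0L)
  expect_equal(r$quality, prob_match_given_equal(1e-4, 1e-4))
})

test_that("disagreeing bases resolve to the higher-quality call", {
  # single-position overlap: fwd 'A' (eps 0.001) vs rev 'G' (eps 0.1)
  r <- reconstruct("A", "G", 0.001, 0.1, overlap = 1)
  expect_equal(r$sequence, "A")
  expect_equal(r$probs, prob_match_given_unequal(0.001, 0.1))
  expect_equal(r$n_mismatches_resolved, 1L)
  # reversed qualities flip the winner
  r2 <- reconstruct("A", "G", 0.1, 0.001, overlap = 1)
  expect_equal(r2$sequence, "G")
  # equal eps: deterministic tie toward the forward base
  r3 <- reconstruct("A", "G", 0.01, 0.01, overlap = 1)
  expect_equal(r3$sequence, "A")
})

test_that("uncalled bases are rescued from the called mate at p = 1/4", {
  r <- reconstruct("N", "C", 1, 1e-4, overlap = 1)
  expect_equal(r$sequence, "C")
  expect_equal(r$probs, 0.25)
  expect_equal(r$n_uncalled_rescued, 1L)
  rb <- reconstruct("N", "N", 1, 1, overlap = 1)
  expect_equal(rb$sequence, "N")
  expect_equal(rb$probs, 0.25)
})

test_that("masked overlap positions use the masked-pair rule", {
  # fwd base masked, bases agree: p = 1 - eps of the unmasked mate
  r <- reconstruct("A", "A", 0.63, 0.001, overlap = 1,
                   masked_fwd = TRUE, masked_rev = FALSE)
  expect_equal(r$probs, 0.999)
  # disagreeing masked pair: uniform 1/4, higher-quality base kept
  r2 <- reconstruct("A", "G", 0.63, 0.001, overlap = 1,
                    masked_fwd = TRUE, masked_rev = FALSE)
  expect_equal(r2$probs, 0.25)
  expect_equal(r2$sequence, "G")
  # both masked
  r3 <- reconstruct("A", "A", 0.63, 0.63, overlap = 1,
                    masked_fwd = TRUE, masked_rev = TRUE)
  expect_equal(r3$probs, 0.25)
})

test_that("unpaired flanks are copied with p = 1 - eps and primers clipped", {
  # fwd = ppAAC, rev_rc = ACGGq layout: template AACGG with 2-base fwd primer
  # region and 1-base rev primer region; overlap c = 2 over "AC"
  fwd <- "GGAAC"; rvc <- "ACGGT"
  ef <- c(0.01, 0.01, 1e-4, 1e-4, 1e-4)
  er <- c(1e-3, 1e-3, 1e-3, 1e-3, 0.02)
  r <- reconstruct(fwd, rvc, ef, er, overlap = 2,
                   fwd_primer_end = 2, rev_primer_end = 1)
  expect_equal(r$sequence, "AACGG")
  pe <- prob_match_given_equal
  expect_equal(r$probs, c(1 - 1e-4, pe(1e-4, 1e-3), pe(1e-4, 1e-3),
                          1 - 1e-3, 1 - 1e-3))
  # clipping everything leaves an empty assembly
  r0 <- reconstruct(fwd, rvc, ef, er, overlap = 2,
                    fwd_primer_end = 5, rev_primer_end = 5)
  expect_equal(r0$sequence, "")
})

test_that("overall quality is the geometric mean of per-base probabilities", {
  expect_equal(overall_quality(c(1, 1, 1)), 1.0)
  expect_equal(overall_quality(0.25), 0.25)
  expect_equal(overall_quality(c(1, 1, 0.25)), 0.25^(1 / 3))
  expect_equal(overall_quality(c(0.5, 0)), 0)
  expect_error(overall_quality(numeric(0)), "empty")
  # bounded below by the minimum: all p > t implies quality > t
  set.seed(11)
  for (i in 1:20) {
    p <- runif(30, 0.901, 1)
    expect_gt(overall_quality(p), 0.9)
  }
})

test_that("validation applies rules in fixed order and keeps the first reason", {
  base <- tibble::tibble(
    id = "x", sequence = "ACGN", length = 4L, quality = 0.85,
    overlap_len = 2L, n_mismatches_resolved = 0L, n_uncalled_rescued = 0L,
    status = "ok", probs = list(rep(0.85, 4)))
  # quality fails first even though N is also present
  v <- validate_assemblies(base, min_quality = 0.9, forbid_uncalled = TRUE)
  expect_equal(v$status, "low-quality")
  v2 <- validate_assemblies(base, min_quality = 0.6, forbid_uncalled = TRUE)
  expect_equal(v2$status, "contains-N")
  v3 <- validate_assemblies(base, min_quality = 0.6, min_len = 10)
  expect_equal(v3$status, "too-short")
  v4 <- validate_assemblies(base, min_quality = 0.6, max_len = 3)
  expect_equal(v4$status, "too-long")
  v5 <- validate_assemblies(base, min_quality = 0.6)
  expect_equal(v5$status, "ok")
})

test_that("user hooks run after built-ins and stamp their name as the reason", {
  base <- tibble::tibble(
    id = c("x", "y"), sequence = c("ACGT", "AAAA"), length = 4L,
    quality = 0.99, overlap_len = 2L, n_mismatches_resolved = 0L,
    n_uncalled_rescued = 0L, status = "ok",
    probs = list(rep(0.99, 4), rep(0.99, 4)))
  v <- validate_assemblies(base, hooks = list(
    "homopolymer" = function(seq, probs) length(unique(strsplit(seq, "")[[1]])) > 1))
  expect_equal(v$status, c("ok", "homopolymer"))
})
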