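test_that("orientation reverse-complements and reverses metadata in lockstep", {
  expect_equal(orient_read("ACGT")$sequence, "ACGT")  # palindromic complement
  o <- orient_read("AAAC", eps = c(0.1, 0.2, 0.3, 0.4),
                   masked = c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(o$sequence, "GTTT")
  expect_equal(o$eps, c(0.4, 0.3, 0.2, 0.1))
  expect_equal(o$masked, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(orient_read("N")$sequence, "N")
})

test_that("overlap scores evaluate the fixed-eps likelihood", {
  e <- 0.01
  pe <- prob_match_given_equal(e, e)
  pu <- prob_match_given_unequal(e, e)
  # full overlap of identical 4-mers: f = r = 0, four agreeing positions
  expect_equal(overlap_log_score("ACGT", "ACGT", 4, e), 4 * log(pe))
  # c = 2 with both aligned bases mismatching: ACGT vs GTAC aligned GT|GT? ->
  # fwd suffix "GT" vs rev_rc prefix: construct an explicit full mismatch
  expect_equal(overlap_log_score("AACC", "GGTT", 2, e),
               4 * log(0.25) + 2 * log(pu))
  # every overlap base uncalled on one side scores the uniform prior
  expect_equal(overlap_log_score("AANN", "NNTT", 4, e), 4 * log(0.25))
  expect_error(overlap_log_score("ACGT", "ACGT", 5), "outside")
})

test_that("best_overlap prefers full overlap for identical reads", {
  set.seed(7)
  s <- rand_seq(20)
  ch <- best_overlap(s, s, eps_fixed = 0.01)
  expect_equal(ch$c, 20L)
  expect_equal(ch$f, 0L)
  expect_equal(ch$r, 0L)
})

test_that("best_overlap recovers a known suffix/prefix overlap", {
  set.seed(8)
  tpl <- rand_seq(32)
  ch <- best_overlap(substr(tpl, 1, 20), substr(tpl, 13, 32))
  expect_equal(ch$c, 8L)
})

test_that("reads shorter than min_overlap yield no suitable overlap", {
  ch <- best_overlap("ACG", "ACG", min_overlap = 5)
  expect_equal(nrow(ch), 0L)
})

test_that("best_overlap matches the exhaustive oracle on random pairs", {
  set.seed(9)
  for (i in 1:200) {
    if (i %% 2 == 0) {
      p <- overlapping_pair(sample(8:15, 1), sample(3:8, 1))
      fwd <- p$fwd; rvc <- p$rev_rc
    } else {
      fwd <- rand_seq(sample(3:30, 1), alphabet = c("A", "C", "G", "T", "N"))
      rvc <- rand_seq(sample(3:30, 1), alphabet = c("A", "C", "G", "T", "N"))
    }
    got <- best_overlap(fwd, rvc)
    want <- oracle_best_overlap(fwd, rvc)
    expect_equal(got$c, want$c)
    expect_equal(got$log_score, want$log_score, tolerance = 1e-12)
  }
})

test_that("score is invariant under swapping read roles with mirrored alignment", {
  set.seed(10)
  for (i in 1:20) {
    fwd <- rand_seq(15); rvc <- rand_seq(12)
    c <- sample(1:12, 1)
    # mirror: reverse both reads and swap; aligned base pairs are preserved
    mirror_f <- paste(rev(strsplit(rvc, "")[[1]]), collapse = "")
    mirror_r <- paste(rev(strsplit(fwd, "")[[1]]), collapse = "")
    expect_equal(overlap_log_score(fwd, rvc, c),
                 overlap_log_score(mirror_f, mirror_r, c))
  }
})
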