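test_that("layout arithmetic: 135-base template, 108-base reads overlap by 81", {
  sim <- simulate_pairs(3, seed = 1)
  expect_equal(sim$true_overlap, rep(81L, 3))
  expect_equal(nchar(sim$seq_fwd), rep(108L, 3))
  expect_equal(nchar(sim$qual_rev), rep(108L, 3))
})

test_that("error-free reads are exact substrings with empty truth lists", {
  sim <- simulate_pairs(20, seed = 2, errors = FALSE)
  tpl <- attr(sim, "template")
  expect_true(all(sim$seq_fwd == substr(tpl, 1, 108)))
  rc_tpl <- orient_read(tpl)$sequence
  expect_true(all(sim$seq_rev == substr(rc_tpl, 1, 108)))
  expect_true(all(lengths(sim$err_fwd) == 0))
  expect_true(all(lengths(sim$err_rev) == 0))
})

test_that("simulation is deterministic given a seed", {
  a <- simulate_pairs(50, seed = 33)
  b <- simulate_pairs(50, seed = 33)
  expect_identical(a, b)
  m1 <- merge_pairs(a)
  m2 <- merge_pairs(b)
  expect_identical(tibble::as_tibble(m1), tibble::as_tibble(m2))
})

test_that("truth lists the template positions where reads deviate", {
  sim <- simulate_pairs(300, seed = 3)
  tpl_codes <- strsplit(attr(sim, "template"), "")[[1]]
  for (i in sample(nrow(sim), 25)) {
    fwd <- strsplit(sim$seq_fwd[i], "")[[1]]
    # forward read position j covers template position j (no primers)
    mism <- which(fwd != tpl_codes[seq_along(fwd)])
    expect_identical(sim$err_fwd[[i]], as.integer(mism))
    rev_rc <- strsplit(orient_read(sim$seq_rev[i])$sequence, "")[[1]]
    # oriented reverse read covers the template suffix
    off <- 135 - 108
    mism_r <- which(rev_rc != tpl_codes[off + seq_along(rev_rc)])
    expect_identical(sim$err_rev[[i]], as.integer(sort(off + mism_r)))
  }
})

test_that("masked tails are forced to phred 2 and Ns carry the lowest score", {
  sim <- simulate_pairs(400, seed = 4, masked_tail_prob = 1, masked_tail_max = 10)
  tails <- vapply(sim$qual_fwd,
                  function(q) sum(detect_masked_tail(q, 33)), numeric(1))
  expect_true(all(tails >= 1))
  has_n <- grepl("N", sim$seq_fwd, fixed = TRUE)
  expect_true(any(has_n))  # masked tails at eps 0.63 plus n_rate produce Ns
  for (i in which(has_n)[1:5]) {
    npos <- which(strsplit(sim$seq_fwd[i], "")[[1]] == "N")
    qc <- strsplit(sim$qual_fwd[i], "")[[1]][npos]
    expect_true(all(error_prob_from_char(paste(qc, collapse = ""), 33) >
                      0.6))  # phred 2
  }
})

test_that("mask transplanting yields error-free bases under given qualities", {
  tpl <- "ACGGTTCACGATTGCCAGTA"  # 20 bases, no internal repeat
  qf <- c("IIIIIIIIIIII###", "IIIIIIIIIIIIIII")  # 15-base reads, one masked
  qr <- c("IIIIIIIIIIIIIII", "IIIIIIIIIII####")
  tp <- transplant_masks(tpl, qf, qr)
  expect_equal(tp$seq_fwd, rep(substr(tpl, 1, 15), 2))
  expect_equal(tp$qual_fwd, qf)
  expect_equal(tp$true_overlap, rep(10L, 2))
  m <- merge_pairs(tp, min_quality = 0)
  expect_equal(m$sequence, rep(tpl, 2))
  expect_equal(transplant_masks(tpl, character(0), character(0)) |> nrow(), 0L)
})

test_that("FASTQ + truth files round-trip through the readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_pairs(25, seed = 5)
  write_sim_fastq(sim, file.path(dir, "f.fastq"), file.path(dir, "r.fastq"),
                  truth = file.path(dir, "truth.tsv"))
  pairs <- read_fastq_pairs(file.path(dir, "f.fastq"), file.path(dir, "r.fastq"))
  expect_equal(pairs$id, sim$id)
  expect_equal(pairs$seq_fwd, sim$seq_fwd)
  expect_equal(pairs$qual_rev, sim$qual_rev)
  tr <- read_sim_truth(file.path(dir, "truth.tsv"))
  expect_equal(attr(tr, "template"), attr(sim, "template"))
  expect_equal(tr$true_overlap, sim$true_overlap)
  expect_identical(tr$err_fwd, unname(sim$err_fwd))
  expect_identical(tr$err_rev, unname(sim$err_rev))
})

test_that("evaluator categories partition the evaluated assemblies", {
  sim <- simulate_pairs(500, seed = 6)
  m <- merge_pairs(sim, min_quality = 0.9)
  ev <- evaluate_assemblies(m, sim)
  g <- glance(ev)
  expect_equal(g$error_free + g$errors_retained + g$errors_reduced +
                 g$errors_introduced, g$n)
  expect_equal(g$n, sum(m$status == "ok"))
})

test_that("error-free input lands entirely in the error-free category", {
  sim <- simulate_pairs(100, seed = 7, errors = FALSE)
  m <- merge_pairs(sim, min_quality = 0)
  ev <- evaluate_assemblies(m, sim)
  g <- glance(ev)
  expect_equal(g$error_free, 100L)
  expect_equal(g$errors_retained + g$errors_reduced + g$errors_introduced, 0L)
  expect_true(all(ev$correct_overlap))
})

test_that("hand-built cases hit the reduced and introduced categories", {
  tpl <- "ACGTTGCAACGTTGCA"  # 16 bases, reads of 12, true overlap 8
  sim <- transplant_masks(tpl, strrep("I", 12), strrep("I", 12))
  # corrupt one forward base inside the overlap; mate quality wins -> reduced
  s <- sim
  seqs <- strsplit(s$seq_fwd, "")[[1]]
  seqs[10] <- if (seqs[10] == "A") "C" else "A"
  s$seq_fwd <- paste(seqs, collapse = "")
  qf <- strsplit(s$qual_fwd, "")[[1]]; qf[10] <- "#"
  s$qual_fwd <- paste(qf, collapse = "")
  s$err_fwd <- list(10L)
  m <- merge_pairs(s, min_quality = 0)
  ev <- evaluate_assemblies(m, s)
  expect_equal(as.character(ev$category), "errors_reduced")
  expect_equal(ev$input_errors, 1L)
  expect_equal(ev$output_errors, 0L)
  # an error in a single-coverage region has no mate to correct it:
  # reverse-read position 3 covers template position 14, outside the overlap
  s2 <- sim
  seqs2 <- strsplit(s2$seq_rev, "")[[1]]
  seqs2[3] <- if (seqs2[3] == "A") "C" else "A"
  s2$seq_rev <- paste(seqs2, collapse = "")
  s2$err_rev <- list(14L)
  m2 <- merge_pairs(s2, min_quality = 0)
  ev2 <- evaluate_assemblies(m2, s2)
  expect_equal(as.character(ev2$category), "errors_retained")
  # unjoinable identifier errors out by name
  bad <- m; bad$id <- "ghost"
  expect_error(evaluate_assemblies(bad, s), "ghost")
})

test_that("the naive baseline rejects pairs with Ns or overlap mismatches", {
  tpl <- "ACGGTTCACGATTGCCAGTAACGTGCATCA"  # 30 bases
  sim <- transplant_masks(tpl, strrep("I", 20), strrep("I", 20))
  nv0 <- naive_merge_pairs(sim)
  expect_true(nv0$accepted)
  expect_equal(nv0$overlap_len, 10L)  # 2*20 - 30
  withN <- sim; withN$seq_fwd <- sub("^.", "N", withN$seq_fwd)
  expect_false(naive_merge_pairs(withN)$accepted)
  # a low-quality miscall inside the true overlap: naive merging can no
  # longer accept the true overlap, while the probabilistic assembler
  # corrects the base from the mate and recovers the template
  mm <- sim
  seqs <- strsplit(mm$seq_fwd, "")[[1]]
  seqs[15] <- if (seqs[15] == "A") "C" else "A"
  mm$seq_fwd <- paste(seqs, collapse = "")
  qf <- strsplit(mm$qual_fwd, "")[[1]]; qf[15] <- "+"  # phred 10
  mm$qual_fwd <- paste(qf, collapse = "")
  nv <- naive_merge_pairs(mm, min_overlap = 5)
  expect_false(nv$accepted && nv$overlap_len == 10L)
  m <- merge_pairs(mm, min_quality = 0)
  expect_equal(m$sequence, tpl)
})
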