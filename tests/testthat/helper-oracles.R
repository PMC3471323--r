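# Shared helpers: random sequence generators and independent brute-force
# oracles the implementation is checked against.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s) {
  paste(rev(chartr("ACGTN", "TGCAN", strsplit(s, "")[[1]])), collapse = "")
}

# Exhaustive overlap argmax, written against the closed-form match
# probabilities directly (no package scoring code): for each candidate c,
# count agreeing / disagreeing / uncalled aligned positions and combine.
# Ties broken toward larger c by scanning c upward with >=.
oracle_best_overlap <- function(fwd, rev_rc, min_overlap = 1,
                                eps_fixed = 0.01) {
  f <- strsplit(fwd, "")[[1]]
  r <- strsplit(rev_rc, "")[[1]]
  lf <- length(f); lr <- length(r)
  cmax <- min(lf, lr)
  if (cmax < min_overlap) return(NULL)
  e <- eps_fixed
  log_pe <- log((1 - e) * (1 - e) + e * e / 3)
  log_pu <- log(2 * (1 - e) * e / 3 + 2 / 9 * e * e)
  log_q <- log(0.25)
  best <- NULL
  for (c in min_overlap:cmax) {
    x <- f[(lf - c + 1):lf]
    y <- r[1:c]
    n_n <- sum(x == "N" | y == "N")
    n_eq <- sum(x == y & x != "N")
    n_ne <- c - n_n - n_eq
    s <- (lf - c + lr - c) * log_q + n_eq * log_pe + n_ne * log_pu + n_n * log_q
    if (is.null(best) || s >= best$log_score) {
      best <- list(c = c, log_score = s)
    }
  }
  best
}

# a pair of reads sharing a true suffix/prefix overlap of length c_true
overlapping_pair <- function(read_len, c_true) {
  tpl <- rand_seq(2 * read_len - c_true)
  list(fwd = substr(tpl, 1, read_len),
       rev_rc = substr(tpl, read_len - c_true + 1, nchar(tpl)),
       c_true = c_true)
}

# argfirst primer offset by scanning every window, independent of
# locate_primer()'s early-exit loop
oracle_locate_primer <- function(sequence, eps, primer, max_offset,
                                 threshold) {
  np <- nchar(primer)
  hits <- integer(0)
  for (x in 0:min(max_offset, nchar(sequence) - np)) {
    gm <- exp(primer_offset_score(sequence, eps, primer, x) / np)
    if (gm >= threshold) hits <- c(hits, x)
  }
  if (length(hits) == 0) NA_integer_ else hits[1]
}

# write a pairs tibble to two FASTQ files in a fresh temp dir
write_pair_files <- function(pairs, dir = withr::local_tempdir(.local_envir =
                                                 parent.frame())) {
  fq1 <- file.path(dir, "r1.fastq")
  fq2 <- file.path(dir, "r2.fastq")
  writeLines(as.vector(rbind(paste0("@", pairs$id, "/1"), pairs$seq_fwd,
                             "+", pairs$qual_fwd)), fq1)
  writeLines(as.vector(rbind(paste0("@", pairs$id, "/2"), pairs$seq_rev,
                             "+", pairs$qual_rev)), fq2)
  list(fwd = fq1, rev = fq2, dir = dir)
}
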