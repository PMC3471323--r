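# Reconstruction of the full amplicon from a chosen overlap, per-base
# probability assignment, primer clipping, geometric-mean quality, and
# validation against user criteria.

# Core reconstruction on code/probability vectors. Rules, per overlap
# position pairing fwd[f+i] with rev_rc[i]:
#   - both uncalled            -> N,            p = 1/4
#   - exactly one uncalled     -> called base,  p = 1/4          (rescued)
#   - either masked (called)   -> prob_pair_masked; base chosen as below
#   - agree (called, unmasked) -> that base,    p = Pr[match | agree]
#   - disagree                 -> base with the smaller eps (tie: forward),
#                                 p = Pr[match | disagree]       (resolved)
# Unpaired positions copy the only available strand with p = 1 - eps.
# fwd_clip/rev_clip positions (located primer regions) are then removed
# from the head/tail of the assembly.
.reconstruct_core <- function(fc, fe, fm, rc, re, rm, c,
                              fwd_clip = 0L, rev_clip = 0L) {
  lf <- length(fc); lr <- length(rc)
  f <- lf - c; r <- lr - c
  x <- fc[f + seq_len(c)]; y <- rc[seq_len(c)]
  ex <- fe[f + seq_len(c)]; ey <- re[seq_len(c)]
  mx <- fm[f + seq_len(c)]; my <- rm[seq_len(c)]
  xN <- x == 5L; yN <- y == 5L
  anyN <- xN | yN
  eq <- !anyN & x == y
  ne <- !anyN & !eq

  base <- x
  take_y <- (ne & ey < ex) | (xN & !yN)
  base[take_y] <- y[take_y]

  p <- numeric(c)
  p[anyN] <- 0.25
  msk <- (mx | my) & !anyN
  if (any(msk)) {
    p[msk] <- prob_pair_masked(x[msk], y[msk], ex[msk], ey[msk],
                               mx[msk], my[msk])
  }
  plain_eq <- eq & !msk
  plain_ne <- ne & !msk
  p[plain_eq] <- prob_match_given_equal(ex[plain_eq], ey[plain_eq])
  p[plain_ne] <- prob_match_given_unequal(ex[plain_ne], ey[plain_ne])

  codes <- c(fc[seq_len(f)], base, if (r > 0) rc[(c + 1):lr])
  probs <- c(1 - fe[seq_len(f)], p, if (r > 0) 1 - re[(c + 1):lr])
  n <- length(codes)
  keep_from <- fwd_clip + 1L
  keep_to <- n - rev_clip
  if (keep_from > keep_to) {
    codes <- integer(0); probs <- numeric(0)
  } else {
    codes <- codes[keep_from:keep_to]
    probs <- probs[keep_from:keep_to]
  }
  list(codes = codes, probs = probs,
       n_mismatches_resolved = sum(ne),
       n_uncalled_rescued = sum(anyN))
}

#' Reconstruct an assembled sequence from an oriented pair
#'
#' Applies the per-position reconstruction rules over the `f` forward-only,
#' `c` overlapping and `r` reverse-only positions: unpaired positions are
#' copied from the available strand with probability \eqn{1 - \epsilon};
#' agreeing overlap bases keep the base with [prob_match_given_equal()];
#' disagreeing bases keep the higher-quality (smaller \eqn{\epsilon}) base
#' with [prob_match_given_unequal()] (ties go to the forward base); pairs
#' with an uncalled base keep the called base at probability 1/4; pairs with
#' a masked base use [prob_pair_masked()]. Located primer regions are then
#' clipped from the assembly.
#'
#' @param fwd,rev_rc Forward and oriented reverse sequences (strings).
#' @param eps_fwd,eps_rev Per-base error probabilities (oriented for
#'   `rev_rc`, i.e. already reversed).
#' @param overlap One row of [best_overlap()], or an overlap length.
#' @param masked_fwd,masked_rev Optional logical masked flags (default none).
#' @param fwd_primer_end,rev_primer_end Number of leading positions of each
#'   read (in its own orientation) belonging to a located primer; these are
#'   removed from the assembly. 0 means no clipping.
#' @return A list with `sequence`, `probs`, `quality` (geometric mean),
#'   `overlap_len`, `n_mismatches_resolved`, `n_uncalled_rescued`.
#' @export
reconstruct <- function(fwd, rev_rc, eps_fwd, eps_rev, overlap,
                        masked_fwd = NULL, masked_rev = NULL,
                        fwd_primer_end = 0, rev_primer_end = 0) {
  fc <- .s2codes(toupper(fwd)); rc <- .s2codes(toupper(rev_rc))
  c <- if (is.data.frame(overlap)) overlap$c[1L] else as.integer(overlap)
  if (is.null(masked_fwd)) masked_fwd <- rep(FALSE, length(fc))
  if (is.null(masked_rev)) masked_rev <- rep(FALSE, length(rc))
  stopifnot(length(eps_fwd) == length(fc), length(eps_rev) == length(rc))
  res <- .reconstruct_core(fc, eps_fwd, masked_fwd, rc, eps_rev, masked_rev,
                           c, as.integer(fwd_primer_end),
                           as.integer(rev_primer_end))
  list(sequence = .codes2s(res$codes),
       probs = res$probs,
       quality = if (length(res$probs)) overall_quality(res$probs) else NA_real_,
       overlap_len = c,
       n_mismatches_resolved = res$n_mismatches_resolved,
       n_uncalled_rescued = res$n_uncalled_rescued)
}

#' Geometric-mean quality of an assembly
#'
#' The overall quality is the geometric mean of the per-base correctness
#' probabilities, `exp(mean(log(p)))`, which makes scores comparable across
#' assemblies of different lengths.
#'
#' @param probs Non-empty numeric vector of per-base probabilities.
#' @return A probability; 0 if any element is 0.
#' @examples
#' overall_quality(c(1, 1, 0.25))  # cube root of 0.25
#' @export
overall_quality <- function(probs) {
  if (length(probs) == 0L) stop("no sequence: empty probability vector",
                                call. = FALSE)
  if (any(probs == 0)) return(0)
  exp(mean(log(probs)))
}

#' Validate assemblies against user criteria
#'
#' Applies the rejection rules in fixed order — low quality, too short, too
#' long, contains an uncalled base — and sets `status` to the first failing
#' rule (only the first reason is recorded). User-supplied hook predicates
#' run after the built-ins: each is a function of `(sequence, probs)`
#' returning `TRUE` to keep the assembly; a failing hook sets `status` to
#' the hook's name.
#'
#' @param results A [merge_pairs()]-shaped tibble; only rows whose current
#'   status is `"ok"` are re-examined.
#' @param min_quality Geometric-mean quality threshold in \[0, 1\]
#'   (default 0.6; 0.9 is the conservative alternative).
#' @param min_len,max_len Length bounds on the assembled sequence.
#' @param forbid_uncalled Reject assemblies containing N?
#' @param hooks Named list of predicates, or `NULL`.
#' @return The tibble with `status` updated.
#' @export
validate_assemblies <- function(results, min_quality = 0.6, min_len = 1,
                                max_len = Inf, forbid_uncalled = FALSE,
                                hooks = NULL) {
  stopifnot(min_len <= max_len, min_quality >= 0, min_quality <= 1)
  ok <- results$status == "ok"
  len <- nchar(results$sequence)
  set <- function(cur, cond, reason) ifelse(ok & cur == "ok" & cond,
                                            reason, cur)
  st <- results$status
  st <- set(st, !is.na(results$quality) & results$quality < min_quality,
            "low-quality")
  st <- set(st, len < min_len, "too-short")
  st <- set(st, len > max_len, "too-long")
  if (forbid_uncalled) st <- set(st, grepl("N", results$sequence, fixed = TRUE),
                                 "contains-N")
  if (!is.null(hooks)) {
    stopifnot(is.list(hooks), !is.null(names(hooks)), all(nzchar(names(hooks))))
    for (nm in names(hooks)) {
      keep <- vapply(seq_len(nrow(results)), function(i) {
        if (!(ok[i] && st[i] == "ok")) return(TRUE)
        isTRUE(hooks[[nm]](results$sequence[i], results$probs[[i]]))
      }, logical(1))
      st <- set(st, !keep, nm)
    }
  }
  results$status <- st
  results
}
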