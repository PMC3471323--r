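# Overlap selection: orient the reverse read into forward coordinates and
# pick the overlap length c maximising the pair likelihood
#   Pr[F,R|c] = prod_unpaired 1/4 * prod_overlap Pr[match | agree/disagree]
# with the error rate fixed at eps_fixed for every overlap position. The
# c-scan is exhaustive (compiled kernel); masked flags do not enter this
# stage, only reconstruction.

#' Orient a reverse read into forward-read coordinates
#'
#' Reverse-complements the reverse read (A<->T, C<->G, N->N) and reverses
#' its per-base error probabilities and masked flags in lockstep, so that
#' overlap position `i` of the oriented read aligns with forward position
#' `f + i`.
#'
#' @param sequence Reverse read sequence as sequenced.
#' @param eps Optional numeric vector of per-base error probabilities.
#' @param masked Optional logical vector of masked flags.
#' @return A list with `sequence` (reverse-complemented string) and, when
#'   supplied, reversed `eps` and `masked`.
#' @examples
#' orient_read("AAAC")$sequence  # "GTTT"
#' @export
orient_read <- function(sequence, eps = NULL, masked = NULL) {
  out <- list(sequence = .rc_string(toupper(sequence)))
  if (!is.null(eps)) out$eps <- rev(eps)
  if (!is.null(masked)) out$masked <- rev(masked)
  out
}

# the three per-position log terms used by the fixed-eps overlap score
.overlap_logs <- function(eps_fixed) {
  list(pe = log(prob_match_given_equal(eps_fixed, eps_fixed)),
       pu = log(prob_match_given_unequal(eps_fixed, eps_fixed)),
       q = log(0.25))
}

#' Log-likelihood of a candidate overlap length
#'
#' For overlap length `c`, the `|F| - c` forward-only and `|R| - c`
#' reverse-only positions each contribute the uniform prior log(1/4); each
#' of the `c` overlapping positions contributes the log match probability at
#' the fixed error rate `eps_fixed` — agreeing bases score
#' [prob_match_given_equal()], disagreeing bases
#' [prob_match_given_unequal()], and pairs with an uncalled base log(1/4).
#'
#' @param fwd Forward read sequence.
#' @param rev_rc Reverse read sequence, already reverse-complemented (see
#'   [orient_read()]).
#' @param c Candidate overlap length, between 1 and `min(|F|, |R|)`.
#' @param eps_fixed Fixed per-base error rate for overlap scoring
#'   (default 0.01, an estimate of the platform's average error rate; the
#'   overlap choice is insensitive to its exact value).
#' @return A single log probability.
#' @export
overlap_log_score <- function(fwd, rev_rc, c, eps_fixed = 0.01) {
  fc <- .s2codes(toupper(fwd))
  rc <- .s2codes(toupper(rev_rc))
  cmax <- min(length(fc), length(rc))
  if (c < 1 || c > cmax) {
    stop("overlap length c = ", c, " outside [1, ", cmax, "]", call. = FALSE)
  }
  lg <- .overlap_logs(eps_fixed)
  # the kernel scores c..cmax; keep only the requested c
  overlap_scan_cpp(fc, rc, as.integer(c), lg$pe, lg$pu, lg$q)[1L]
}

#' Choose the most likely overlap length for an oriented pair
#'
#' Scores every candidate `c` in `[min_overlap, min(|F|, |R|)]` with
#' [overlap_log_score()] and returns the maximiser, breaking ties toward
#' larger `c` (the shorter assembly, which explains more observed data as
#' overlap). The scan covers the entire reads, including any primer regions.
#'
#' @inheritParams overlap_log_score
#' @param min_overlap Smallest overlap considered (default 1).
#' @return A one-row tibble with columns `c`, `log_score`, and the unpaired
#'   forward/reverse lengths `f` and `r`, or a zero-row tibble when the
#'   reads are shorter than `min_overlap` (no suitable overlap).
#' @export
best_overlap <- function(fwd, rev_rc, min_overlap = 1, eps_fixed = 0.01) {
  fc <- .s2codes(toupper(fwd))
  rc <- .s2codes(toupper(rev_rc))
  ch <- .best_overlap_codes(fc, rc, as.integer(min_overlap), eps_fixed)
  if (is.null(ch)) {
    return(tibble::tibble(c = integer(0), log_score = numeric(0),
                          f = integer(0), r = integer(0)))
  }
  tibble::tibble(c = ch$c, log_score = ch$log_score, f = ch$f, r = ch$r)
}

# hot-path version on nucleotide code vectors; NULL when no candidate exists
.best_overlap_codes <- function(fc, rc, min_overlap, eps_fixed,
                                logs = .overlap_logs(eps_fixed)) {
  scores <- overlap_scan_cpp(fc, rc, min_overlap, logs$pe, logs$pu, logs$q)
  if (length(scores) == 0L) return(NULL)
  best <- max(which(scores == max(scores)))  # tie -> larger c
  c <- min_overlap + best - 1L
  list(c = c, log_score = scores[best],
       f = length(fc) - c, r = length(rc) - c)
}
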