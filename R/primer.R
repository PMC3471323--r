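# Probabilistic primer location. The primer is assumed to carry the
# platform's best error rate per base (eps_P = 10^-4.1); a read base inside
# the primer symbol's IUPAC set scores as an agreeing pair, outside it as a
# disagreeing pair, and an uncalled read base scores the uniform 1/4.

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# membership matrix: rows IUPAC codes, cols nucleotide codes 1..4
.IUPAC_MEMBER <- local({
  m <- matrix(FALSE, nrow = length(.IUPAC_SETS), ncol = 4,
              dimnames = list(names(.IUPAC_SETS), c("A", "C", "G", "T")))
  for (nm in names(.IUPAC_SETS)) m[nm, .IUPAC_SETS[[nm]]] <- TRUE
  m
})

.check_primer <- function(primer) {
  primer <- toupper(primer)
  if (nchar(primer) == 0L) stop("primer sequence is empty", call. = FALSE)
  chars <- strsplit(primer, "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(.IUPAC_SETS))
  if (length(bad) > 0L) {
    stop("invalid IUPAC code '", bad[1L], "' in primer", call. = FALSE)
  }
  primer
}

# logical: does read code (1..5) fall in the primer character's set?
# returns NA for uncalled read bases (handled by the 1/4 rule)
.primer_hits <- function(read_codes, primer_chars) {
  n <- read_codes == 5L
  hit <- logical(length(read_codes))
  rows <- match(primer_chars, rownames(.IUPAC_MEMBER))
  hit[!n] <- .IUPAC_MEMBER[cbind(rows[!n], read_codes[!n])]
  hit[n] <- NA
  hit
}

#' Log-probability that a primer sits at a given read offset
#'
#' Sums, over primer positions, the log probability that the read base and
#' primer base agree: [prob_match_given_equal()] of the read base's error
#' probability and `eps_primer` when the read base belongs to the primer
#' symbol's IUPAC set, [prob_match_given_unequal()] otherwise, and log(1/4)
#' for an uncalled read base.
#'
#' @param sequence Read sequence (A/C/G/T/N string).
#' @param eps Numeric vector of per-base error probabilities, same length.
#' @param primer IUPAC primer string.
#' @param offset 0-based offset of the primer window in the read;
#'   `offset + nchar(primer)` must not exceed the read length.
#' @param eps_primer Per-base error probability assumed for the primer
#'   (default `10^-4.1`, the platform's best score).
#' @return A single log probability.
#' @export
primer_offset_score <- function(sequence, eps, primer, offset,
                                eps_primer = 10^-4.1) {
  primer <- .check_primer(primer)
  np <- nchar(primer)
  codes <- .s2codes(toupper(sequence))
  stopifnot(length(eps) == length(codes))
  if (offset < 0 || offset + np > length(codes)) {
    stop("primer window [", offset, ", ", offset + np,
         ") exceeds the read", call. = FALSE)
  }
  idx <- offset + seq_len(np)
  hit <- .primer_hits(codes[idx], strsplit(primer, "", fixed = TRUE)[[1]])
  e <- eps[idx]
  p <- ifelse(is.na(hit), 0.25,
              ifelse(hit, prob_match_given_equal(e, eps_primer),
                     prob_match_given_unequal(e, eps_primer)))
  sum(log(p))
}

#' Locate a primer near the start of a read
#'
#' Scans offsets 0..`max_offset` left to right and returns the first offset
#' whose per-base geometric-mean agreement probability reaches `threshold`;
#' the primer region is then `[offset, offset + nchar(primer))` and
#' everything before its end is excluded from the assembly.
#'
#' @inheritParams primer_offset_score
#' @param max_offset Largest offset tried (default 5; reduced automatically
#'   if the read is short).
#' @param threshold Geometric-mean agreement probability required for a
#'   window to qualify (default 0.75).
#' @return The 0-based offset, or `NA_integer_` when no window qualifies.
#' @export
locate_primer <- function(sequence, eps, primer, max_offset = 5,
                          threshold = 0.75, eps_primer = 10^-4.1) {
  primer <- .check_primer(primer)
  np <- nchar(primer)
  L <- nchar(sequence)
  max_offset <- min(max_offset, L - np)
  if (max_offset < 0) return(NA_integer_)
  for (x in 0:max_offset) {
    gm <- exp(primer_offset_score(sequence, eps, primer, x, eps_primer) / np)
    if (gm >= threshold) return(as.integer(x))
  }
  NA_integer_
}
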