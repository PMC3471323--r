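#' Phred quality encodings
#'
#' Illumina pipelines have used two ASCII encodings for per-base quality:
#' offset 64 in analysis pipelines before CASAVA 1.8 and offset 33 from
#' CASAVA 1.8 onward. A quality character with ASCII value \eqn{A} encodes
#' phred score \eqn{A - \mathrm{offset}}.
#'
#' @param ascii_offset 33 or 64.
#' @return A `phred_encoding` object with fields `ascii_offset` and `name`.
#' @examples
#' phred_encoding(33)
#' @export
phred_encoding <- function(ascii_offset = 33) {
  ascii_offset <- as.integer(ascii_offset)
  if (!ascii_offset %in% c(33L, 64L)) {
    stop("`ascii_offset` must be 33 or 64", call. = FALSE)
  }
  structure(
    list(ascii_offset = ascii_offset,
         name = if (ascii_offset == 33L) "casava-1.8" else "pre-1.8"),
    class = "phred_encoding"
  )
}

#' @export
print.phred_encoding <- function(x, ...) {
  cat("<phred_encoding> offset", x$ascii_offset, paste0("(", x$name, ")\n"))
  invisible(x)
}

#' Error probability from a quality character
#'
#' Converts quality characters to the per-base miscall probability
#' \eqn{\epsilon = 10^{-(A - \mathrm{offset})/10}}, where \eqn{A} is the
#' character's ASCII value. Probabilities are clamped to a floor of
#' \eqn{10^{-4.1}} (phred 41, the platform's highest assigned score) so no
#' base is ever treated as error-free.
#'
#' @param ch Character vector; each element may hold one or more quality
#'   characters (a whole quality string is fine).
#' @param encoding A [phred_encoding()] or a bare offset (33/64).
#' @return Numeric vector of error probabilities, one per character.
#' @examples
#' error_prob_from_char("!", 33)  # phred 0 -> 1
#' error_prob_from_char("I", 33)  # phred 40 -> 1e-4
#' @export
error_prob_from_char <- function(ch, encoding = phred_encoding(33)) {
  offset <- .enc_offset(encoding)
  .q2eps(paste(ch, collapse = ""), offset)
}

#' Probability the true bases match, given the sequenced bases agree
#'
#' For observed bases X and Y with miscall probabilities `eps_x` and `eps_y`,
#' returns \eqn{\Pr[\hat X = \hat Y \mid X = Y] =
#' (1-\epsilon_X)(1-\epsilon_Y) + \epsilon_X \epsilon_Y / 3}, under a uniform
#' prior over nucleotides and errors equiprobable over the other three bases.
#'
#' @param eps_x,eps_y Error probabilities in \[0, 1\] (vectorised).
#' @return Probabilities in \[0, 1\].
#' @seealso [prob_match_given_unequal()], [prob_match_uncalled()]
#' @examples
#' prob_match_given_equal(0.1, 0.2)
#' @export
prob_match_given_equal <- function(eps_x, eps_y) {
  (1 - eps_x) * (1 - eps_y) + eps_x * eps_y / 3
}

#' Probability the true bases match, given the sequenced bases disagree
#'
#' Returns \eqn{\Pr[\hat X = \hat Y \mid X \neq Y] =
#' \frac13(1-\epsilon_X)\epsilon_Y + \frac13(1-\epsilon_Y)\epsilon_X +
#' \frac29 \epsilon_X \epsilon_Y}.
#'
#' @inheritParams prob_match_given_equal
#' @return Probabilities in \[0, 1\].
#' @examples
#' prob_match_given_unequal(0.1, 0.2)
#' @export
prob_match_given_unequal <- function(eps_x, eps_y) {
  (1 - eps_x) * eps_y / 3 + (1 - eps_y) * eps_x / 3 + 2 / 9 * eps_x * eps_y
}

#' Match probability when a base is uncalled
#'
#' When either base of an aligned pair is an uncalled N the bases are taken
#' to match with the uniform prior 1/4, irrespective of the partner's
#' quality. (Base callers always attach the lowest quality score to N.)
#'
#' @return 0.25.
#' @export
prob_match_uncalled <- function() 0.25

#' Match probability when a base lies in a quality-masked tail
#'
#' Pipelines may mask the trailing low-confidence portion of a read by
#' overwriting its quality scores with the lowest value. For an aligned pair
#' where at least one base is masked: if exactly one is masked and the bases
#' agree, the unmasked base's own correctness probability
#' \eqn{1 - \epsilon} is used; if they disagree, or both are masked, the
#' uniform 1/4 applies.
#'
#' @param base_x,base_y Single-character bases (vectorised).
#' @param eps_x,eps_y Their error probabilities.
#' @param masked_x,masked_y Logical; at least one must be `TRUE` per element.
#' @return Probabilities in \[0, 1\].
#' @export
prob_pair_masked <- function(base_x, base_y, eps_x, eps_y, masked_x, masked_y) {
  if (any(!masked_x & !masked_y)) {
    stop("prob_pair_masked() requires at least one masked base per pair",
         call. = FALSE)
  }
  eq <- base_x == base_y
  both <- masked_x & masked_y
  other_eps <- ifelse(masked_x, eps_y, eps_x)
  ifelse(both | !eq, 0.25, 1 - other_eps)
}
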