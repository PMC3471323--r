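# Truth-based accounting of assembly outcomes, in the categories used for
# error-correction validation: error-free input and output; all errors
# retained; input errors reduced; errors introduced — plus correct-overlap
# counting. The four categories partition the evaluated assemblies.

#' Classify assemblies against simulation truth
#'
#' Joins assemblies to their truth records and compares each output
#' sequence to the (primer-clipped) template. With per-pair input error
#' positions \eqn{I} (template positions where either read deviates from
#' the truth) and output error positions \eqn{O}:
#' \describe{
#'   \item{error_free}{\eqn{I = \emptyset} and \eqn{O = \emptyset}.}
#'   \item{errors_introduced}{some output error at a position where both
#'     inputs were correct (\eqn{O \not\subseteq I}), including
#'     length-mismatched assemblies (a mis-chosen overlap).}
#'   \item{errors_reduced}{\eqn{|O| < |I|}.}
#'   \item{errors_retained}{\eqn{|O| = |I| > 0}.}
#' }
#' `correct_overlap` records whether the assembled overlap length equals
#' the truth.
#'
#' @param merged An `amplimerge_merged` tibble ([merge_pairs()]).
#' @param truth An `amplimerge_sim` tibble ([simulate_pairs()]) or a tibble
#'   from [read_sim_truth()], carrying a `"template"` attribute.
#' @param statuses Which assembly statuses to evaluate (default `"ok"`,
#'   i.e. the accepted output).
#' @return A tibble of class `amplimerge_eval`, one row per evaluated
#'   assembly: `id`, `status`, `input_errors`, `output_errors`,
#'   `correct_overlap`, `category`.
#' @export
evaluate_assemblies <- function(merged, truth, statuses = "ok") {
  template <- attr(truth, "template")
  if (is.null(template)) {
    stop("`truth` carries no \"template\" attribute", call. = FALSE)
  }
  keep <- merged[merged$status %in% statuses, ]
  missing <- setdiff(keep$id, truth$id)
  if (length(missing) > 0L) {
    stop("assembly '", missing[1L], "' has no truth record", call. = FALSE)
  }
  tr <- truth[match(keep$id, truth$id), ]
  tc <- .s2codes(toupper(template))
  lt <- length(tc)

  n <- nrow(keep)
  input_errors <- integer(n)
  output_errors <- integer(n)
  introduced <- logical(n)
  for (i in seq_len(n)) {
    ipos <- sort(unique(c(tr$err_fwd[[i]], tr$err_rev[[i]])))
    input_errors[i] <- length(ipos)
    oc <- .s2codes(keep$sequence[i])
    if (length(oc) == lt) {
      opos <- which(oc != tc)
      output_errors[i] <- length(opos)
      introduced[i] <- length(setdiff(opos, ipos)) > 0L
    } else {
      m <- min(length(oc), lt)
      output_errors[i] <- sum(oc[seq_len(m)] != tc[seq_len(m)]) +
        abs(length(oc) - lt)
      introduced[i] <- TRUE
    }
  }
  category <- dplyr::case_when(
    input_errors == 0L & output_errors == 0L ~ "error_free",
    introduced ~ "errors_introduced",
    output_errors < input_errors ~ "errors_reduced",
    TRUE ~ "errors_retained"
  )
  out <- tibble::tibble(
    id = keep$id, status = keep$status,
    input_errors = input_errors, output_errors = output_errors,
    correct_overlap = keep$overlap_len == tr$true_overlap,
    category = factor(category,
                      levels = c("error_free", "errors_retained",
                                 "errors_reduced", "errors_introduced"))
  )
  class(out) <- c("amplimerge_eval", class(out))
  attr(out, "template") <- template
  out
}

#' @describeIn evaluate_assemblies Category counts in long form.
#' @param x An `amplimerge_eval` tibble.
#' @param ... Unused.
#' @method tidy amplimerge_eval
#' @export
tidy.amplimerge_eval <- function(x, ...) {
  tibble::tibble(
    category = levels(x$category),
    n = as.integer(table(x$category))
  )
}

#' @describeIn evaluate_assemblies One-row summary: total evaluated,
#'   category counts, correct-overlap count, and mean input/output errors
#'   per evaluated assembly.
#' @method glance amplimerge_eval
#' @export
glance.amplimerge_eval <- function(x, ...) {
  counts <- table(x$category)
  tibble::tibble(
    n = nrow(x),
    error_free = as.integer(counts[["error_free"]]),
    errors_retained = as.integer(counts[["errors_retained"]]),
    errors_reduced = as.integer(counts[["errors_reduced"]]),
    errors_introduced = as.integer(counts[["errors_introduced"]]),
    correct_overlap = sum(x$correct_overlap, na.rm = TRUE),
    mean_input_errors = mean(x$input_errors),
    mean_output_errors = mean(x$output_errors)
  )
}

#' @describeIn evaluate_assemblies Bar chart of the category counts.
#' @param object An `amplimerge_eval` tibble.
#' @method autoplot amplimerge_eval
#' @export
autoplot.amplimerge_eval <- function(object, ...) {
  df <- tidy.amplimerge_eval(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "assemblies") +
    ggplot2::theme_minimal()
}

#' Naive perfect-match merging baseline
#'
#' Accepts a pair only if neither read contains an uncalled base and some
#' overlap length aligns the reads with an exact nucleotide match at every
#' position (the largest such length is reported). This is the
#' quality-blind strategy the probabilistic assembler improves on.
#'
#' @param pairs A pairs tibble (see [merge_pairs()]).
#' @param min_overlap Smallest overlap length considered.
#' @return A tibble with `id`, `accepted`, `overlap_len` (0 when rejected).
#' @export
naive_merge_pairs <- function(pairs, min_overlap = 1) {
  n <- nrow(pairs)
  ov <- integer(n)
  for (i in seq_len(n)) {
    fc <- .s2codes(pairs$seq_fwd[i])
    rc <- .rc_codes(.s2codes(pairs$seq_rev[i]))
    if (any(fc == 5L) || any(rc == 5L)) next
    ov[i] <- exact_overlap_cpp(fc, rc, as.integer(min_overlap))
  }
  tibble::tibble(id = pairs$id, accepted = ov > 0L, overlap_len = ov)
}
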