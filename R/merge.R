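#' Assemble paired-end amplicon reads
#'
#' The package's main verb. For each read pair: locates forward/reverse
#' primers if supplied (pairs missing a specified primer are rejected with
#' reason `"primer-missing"`), orients the reverse read, chooses the overlap
#' length maximising the pair likelihood ([best_overlap()]; no candidate in
#' range rejects with `"no-overlap"`), reconstructs the full sequence with
#' quality-aware error correction ([reconstruct()]), clips primer regions,
#' scores the assembly by geometric-mean quality, and validates it
#' ([validate_assemblies()]).
#'
#' @param pairs A tibble from [read_fastq_pairs()] or [simulate_pairs()]
#'   (columns `id`, `seq_fwd`, `qual_fwd`, `seq_rev`, `qual_rev`).
#' @param fwd_primer,rev_primer `NULL` (none), an IUPAC sequence to locate
#'   probabilistically, or an integer number of bases to strip blindly
#'   (for pre-trimmed or unsequenced-primer data).
#' @param min_quality,min_len,max_len,forbid_uncalled,hooks Validation
#'   criteria, see [validate_assemblies()].
#' @param min_overlap Smallest overlap length considered (default 1).
#' @param eps_fixed Fixed error rate for overlap scoring (default 0.01).
#' @param max_primer_offset,primer_threshold Primer search window and
#'   qualification threshold, see [locate_primer()].
#' @param encoding Overrides the `"encoding"` attribute of `pairs`
#'   (default: that attribute, else phred+33).
#' @return A tibble of class `amplimerge_merged`, one row per input pair:
#'   `id`, `sequence`, `length`, `quality`, `overlap_len`,
#'   `n_mismatches_resolved`, `n_uncalled_rescued`, `status`, and a `probs`
#'   list-column of per-base probabilities. Attributes record the run
#'   parameters. Input order is preserved.
#' @examples
#' sim <- simulate_pairs(5, seed = 1)
#' merged <- merge_pairs(sim, min_quality = 0.9)
#' glance(merged)
#' @export
merge_pairs <- function(pairs, fwd_primer = NULL, rev_primer = NULL,
                        min_quality = 0.6, min_len = 1, max_len = Inf,
                        forbid_uncalled = FALSE, min_overlap = 1,
                        eps_fixed = 0.01, max_primer_offset = 5,
                        primer_threshold = 0.75, encoding = NULL,
                        hooks = NULL) {
  stopifnot(all(c("id", "seq_fwd", "qual_fwd", "seq_rev", "qual_rev")
                %in% names(pairs)))
  enc <- encoding %||% attr(pairs, "encoding") %||% phred_encoding(33)
  offset <- .enc_offset(enc)
  n <- nrow(pairs)
  min_overlap <- as.integer(min_overlap)
  logs <- .overlap_logs(eps_fixed)

  pf <- .primer_mode(fwd_primer)
  pr <- .primer_mode(rev_primer)

  sequence <- rep(NA_character_, n)
  quality <- rep(NA_real_, n)
  overlap_len <- rep(NA_integer_, n)
  n_mm <- rep(NA_integer_, n)
  n_un <- rep(NA_integer_, n)
  status <- rep("ok", n)
  probs <- vector("list", n)

  for (i in seq_len(n)) {
    fc <- .s2codes(pairs$seq_fwd[i])
    rc0 <- .s2codes(pairs$seq_rev[i])
    fa <- utf8ToInt(pairs$qual_fwd[i])
    ra <- utf8ToInt(pairs$qual_rev[i])
    fe <- .eps_tab(offset)[fa + 1L]
    re <- .eps_tab(offset)[ra + 1L]
    if (anyNA(fe) || anyNA(re)) {
      stop("malformed quality in record '", pairs$id[i], "'", call. = FALSE)
    }
    fm <- .masked_tail_ascii(fa, offset)
    rm0 <- .masked_tail_ascii(ra, offset)

    fwd_clip <- .clip_len(pf, pairs$seq_fwd[i], fe,
                          max_primer_offset, primer_threshold)
    rev_clip <- .clip_len(pr, pairs$seq_rev[i], re,
                          max_primer_offset, primer_threshold)
    if (is.na(fwd_clip) || is.na(rev_clip)) {
      status[i] <- "primer-missing"
      next
    }

    rc <- .COMP[rev(rc0)]
    ch <- .best_overlap_codes(fc, rc, min_overlap, eps_fixed, logs)
    if (is.null(ch)) {
      status[i] <- "no-overlap"
      next
    }

    res <- .reconstruct_core(fc, fe, fm, rc, rev(re), rev(rm0),
                             ch$c, fwd_clip, rev_clip)
    sequence[i] <- .codes2s(res$codes)
    probs[[i]] <- res$probs
    quality[i] <- if (length(res$probs)) overall_quality(res$probs) else NA_real_
    overlap_len[i] <- ch$c
    n_mm[i] <- res$n_mismatches_resolved
    n_un[i] <- res$n_uncalled_rescued
  }

  out <- tibble::tibble(
    id = pairs$id, sequence = sequence, length = nchar(sequence),
    quality = quality, overlap_len = overlap_len,
    n_mismatches_resolved = n_mm, n_uncalled_rescued = n_un,
    status = status, probs = probs
  )
  out <- validate_assemblies(out, min_quality = min_quality,
                             min_len = min_len, max_len = max_len,
                             forbid_uncalled = forbid_uncalled, hooks = hooks)
  class(out) <- c("amplimerge_merged", class(out))
  attr(out, "encoding") <- if (inherits(enc, "phred_encoding")) enc
                           else phred_encoding(enc)
  attr(out, "params") <- list(
    fwd_primer = fwd_primer, rev_primer = rev_primer,
    min_quality = min_quality, min_len = min_len, max_len = max_len,
    forbid_uncalled = forbid_uncalled, min_overlap = min_overlap,
    eps_fixed = eps_fixed, max_primer_offset = max_primer_offset,
    primer_threshold = primer_threshold
  )
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.primer_mode <- function(primer) {
  if (is.null(primer)) return(list(mode = "none"))
  if (is.numeric(primer)) {
    return(list(mode = "fixed", len = as.integer(primer)))
  }
  list(mode = "search", seq = .check_primer(primer))
}

# positions to clip from a read's start: 0 (no primer), fixed length, or
# located primer end; NA when a searched-for primer is absent
.clip_len <- function(pm, seq, eps, max_offset, threshold) {
  switch(pm$mode,
         none = 0L,
         fixed = pm$len,
         search = {
           x <- locate_primer(seq, eps, pm$seq, max_offset, threshold)
           if (is.na(x)) NA_integer_ else x + nchar(pm$seq)
         })
}

.REASONS <- c("low-quality", "too-short", "too-long", "contains-N",
              "no-overlap", "primer-missing")

#' @describeIn merge_pairs One row per rejection reason with its count
#'   (reasons with zero counts included; hook rejections appear under their
#'   hook name).
#' @param x An `amplimerge_merged` tibble.
#' @param ... Unused.
#' @method tidy amplimerge_merged
#' @export
tidy.amplimerge_merged <- function(x, ...) {
  reasons <- union(.REASONS, setdiff(unique(x$status), "ok"))
  tibble::tibble(
    reason = reasons,
    n = vapply(reasons, function(r) sum(x$status == r), integer(1))
  )
}

#' @describeIn merge_pairs One-row run summary: pairs in, assembled, counts
#'   per rejection reason, and the main parameters.
#' @method glance amplimerge_merged
#' @export
glance.amplimerge_merged <- function(x, ...) {
  p <- attr(x, "params")
  counts <- tidy.amplimerge_merged(x)
  wide <- stats::setNames(as.list(counts$n),
                          gsub("-", "_", counts$reason, fixed = TRUE))
  tibble::as_tibble(c(
    list(pairs = nrow(x), assembled = sum(x$status == "ok")),
    wide,
    list(min_quality = p$min_quality, min_overlap = p$min_overlap,
         eps_fixed = p$eps_fixed)
  ))
}

#' Histogram of assembly quality scores
#'
#' Plots the distribution of geometric-mean quality scores of the
#' reconstructed sequences, filled by validation status, with the quality
#' threshold marked.
#'
#' @param object An `amplimerge_merged` tibble.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot amplimerge_merged
#' @export
autoplot.amplimerge_merged <- function(object, bins = 50, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$quality))
  thr <- attr(object, "params")$min_quality
  ggplot2::ggplot(df, ggplot2::aes(x = .data$quality, fill = .data$status)) +
    ggplot2::geom_histogram(bins = bins, boundary = 1) +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::labs(x = "geometric-mean assembly quality", y = "assemblies",
                  fill = "status") +
    ggplot2::theme_minimal()
}
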