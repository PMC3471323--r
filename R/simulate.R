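# Synthetic paired-end amplicon reads with truth records. The generator
# emulates the features the assembler must cope with: a quality profile
# declining along the read, quality-masked (phred 2) tails, uncalled bases,
# and substitution errors drawn at the quality-implied rate, uniform over
# the other three nucleotides. Error-free mode reproduces the
# "real masks on error-free sequence" validation design.

.concretize_iupac <- function(primer, sample_bases = TRUE) {
  if (nchar(primer) == 0L) return("")
  chars <- strsplit(.check_primer(primer), "", fixed = TRUE)[[1]]
  conc <- vapply(chars, function(ch) {
    set <- .IUPAC_SETS[[ch]]
    if (length(set) == 1L) set
    else if (sample_bases) sample(set, 1L)
    else set[1L]
  }, character(1))
  paste(conc, collapse = "")
}

.random_template <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Simulate paired-end amplicon reads with truth records
#'
#' Lays out an amplicon `fwd_primer + template + revcomp(rev_primer)`; the
#' forward read is its prefix and the reverse read the reverse complement of
#' its suffix, each truncated to `read_len`. Per-base phred scores decline
#' linearly from `phred_start` to `phred_end`; with probability
#' `masked_tail_prob` a read's tail of uniform length 1..`masked_tail_max`
#' is quality-masked to phred 2. When `errors = TRUE`, substitutions are
#' drawn independently per base with the quality-implied probability
#' \eqn{10^{-\mathrm{phred}/10}} (uniform over the other three
#' nucleotides), and bases with phred \eqn{\le} `n_phred_max` become
#' uncalled (N, at phred 2) with probability `n_rate`. Degenerate IUPAC
#' primer positions are concretised once per call. Optional per-pair spacer
#' bases shift the primer away from the read start.
#'
#' @param n_pairs Number of read pairs.
#' @param template Template sequence between the primers, or `NULL` to draw
#'   a random one of length `template_len`.
#' @param template_len Length of the random template (default 135, a 16S
#'   rRNA V3-region size).
#' @param fwd_primer,rev_primer IUPAC primer sequences (`""` for none).
#' @param read_len Read length (default 108).
#' @param phred_start,phred_end Endpoints of the linear quality decline.
#' @param masked_tail_prob,masked_tail_max Masked-tail frequency and
#'   maximal length.
#' @param n_rate,n_phred_max Uncalled-base rate among low-quality bases.
#' @param errors `FALSE` for error-free reads (quality profile and masks
#'   still applied).
#' @param fwd_spacer,rev_spacer Integer spacer lengths before each read's
#'   primer (recycled across pairs); spacer bases are random.
#' @param seed Integer seed; given the same seed the output is identical.
#' @return A tibble of class `amplimerge_sim` with columns `id`, `seq_fwd`,
#'   `qual_fwd`, `seq_rev`, `qual_rev`, `true_overlap`, and list-columns
#'   `err_fwd`/`err_rev` of template positions (1-based) where each read
#'   deviates from the truth. Attributes: `template`, concretised primers,
#'   `encoding` (phred+33), `seed`, and the full parameter list.
#' @examples
#' sim <- simulate_pairs(3, seed = 42)
#' sim$true_overlap[1]  # 2*108 - 135 = 81
#' @export
simulate_pairs <- function(n_pairs, template = NULL, template_len = 135,
                           fwd_primer = "", rev_primer = "", read_len = 108,
                           phred_start = 40, phred_end = 15,
                           masked_tail_prob = 0.2, masked_tail_max = 15,
                           n_rate = 0.02, n_phred_max = 15, errors = TRUE,
                           fwd_spacer = 0, rev_spacer = 0, seed = NULL) {
  run <- function() {
    .simulate_pairs_impl(n_pairs, template, template_len, fwd_primer,
                         rev_primer, read_len, phred_start, phred_end,
                         masked_tail_prob, masked_tail_max, n_rate,
                         n_phred_max, errors, fwd_spacer, rev_spacer, seed)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

.simulate_pairs_impl <- function(n_pairs, template, template_len, fwd_primer,
                                 rev_primer, read_len, phred_start, phred_end,
                                 masked_tail_prob, masked_tail_max, n_rate,
                                 n_phred_max, errors, fwd_spacer, rev_spacer,
                                 seed) {
  if (is.null(template)) template <- .random_template(template_len)
  template <- toupper(template)
  cf <- .concretize_iupac(fwd_primer)
  cr <- .concretize_iupac(rev_primer)
  amplicon <- paste0(cf, template, .rc_string(cr))
  la <- nchar(amplicon)
  lt <- nchar(template)
  pf <- nchar(cf)
  sf <- as.integer(rep_len(fwd_spacer, n_pairs))
  sr <- as.integer(rep_len(rev_spacer, n_pairs))
  if (any(read_len > la + sf) || any(read_len > la + sr)) {
    stop("template shorter than required: reads of length ", read_len,
         " cannot be drawn from a ", la, "-base amplicon", call. = FALSE)
  }
  ac <- .s2codes(amplicon)
  ac_rc <- .rc_codes(ac)
  prof <- as.integer(round(seq(phred_start, phred_end, length.out = read_len)))
  # template position covered by forward/reverse read position j (spacer s)
  fwd_map <- function(s) {
    tp <- seq_len(read_len) - s - pf
    tp[tp < 1 | tp > lt] <- NA_integer_
    tp
  }
  rev_map <- function(s) {
    tp <- la - (seq_len(read_len) - s) + 1L - pf
    tp[seq_len(read_len) <= s] <- NA_integer_
    tp[!is.na(tp) & (tp < 1 | tp > lt)] <- NA_integer_
    tp
  }

  sim_side <- function(true_codes_fn, s) {
    codes <- matrix(0L, n_pairs, read_len)
    for (i in seq_len(n_pairs)) codes[i, ] <- true_codes_fn(s[i])
    phred <- matrix(rep(prof, each = n_pairs), n_pairs, read_len)
    tail_on <- runif(n_pairs) < masked_tail_prob
    tail_len <- integer(n_pairs)
    tail_len[tail_on] <- sample.int(masked_tail_max, sum(tail_on),
                                    replace = TRUE)
    for (i in which(tail_on)) {
      phred[i, (read_len - tail_len[i] + 1L):read_len] <- 2L
    }
    err <- matrix(FALSE, n_pairs, read_len)
    if (errors) {
      eps <- 10^(-phred / 10)
      sub <- matrix(runif(n_pairs * read_len), n_pairs, read_len) < eps
      ncall <- matrix(runif(n_pairs * read_len), n_pairs, read_len) < n_rate &
        phred <= n_phred_max
      wsub <- which(sub & !ncall)
      if (length(wsub)) {
        codes[wsub] <- ((codes[wsub] - 1L +
                           sample.int(3L, length(wsub), replace = TRUE)) %% 4L) + 1L
      }
      wn <- which(ncall)
      if (length(wn)) {
        codes[wn] <- 5L
        phred[wn] <- 2L
      }
      err <- sub | ncall
    }
    seqs <- vapply(seq_len(n_pairs),
                   function(i) .codes2s(codes[i, ]), character(1))
    quals <- vapply(seq_len(n_pairs),
                    function(i) intToUtf8(phred[i, ] + 33L), character(1))
    list(seqs = seqs, quals = quals, err = err)
  }

  fwd_true <- function(s) {
    c(if (s > 0) sample.int(4L, s, replace = TRUE),
      ac)[seq_len(read_len)]
  }
  rev_true <- function(s) {
    c(if (s > 0) sample.int(4L, s, replace = TRUE),
      ac_rc)[seq_len(read_len)]
  }
  fside <- sim_side(fwd_true, sf)
  rside <- sim_side(rev_true, sr)

  err_to_template <- function(err, maps) {
    w <- which(err, arr.ind = TRUE)
    out <- rep(list(integer(0)), n_pairs)
    if (nrow(w) > 0) {
      tp <- mapply(function(row, col) maps[[row]][col], w[, 1], w[, 2])
      keep <- !is.na(tp)
      sp <- split(as.integer(tp[keep]), w[keep, 1])
      out[as.integer(names(sp))] <- lapply(sp, function(v) sort(unique(v)))
    }
    out
  }
  fmaps <- lapply(sf, fwd_map)
  rmaps <- lapply(sr, rev_map)

  true_overlap <- ifelse(sf == 0 & sr == 0 & 2L * read_len - la >= 1L,
                         2L * read_len - la, NA_integer_)

  out <- tibble::tibble(
    id = sprintf("sim%06d", seq_len(n_pairs)),
    seq_fwd = fside$seqs, qual_fwd = fside$quals,
    seq_rev = rside$seqs, qual_rev = rside$quals,
    true_overlap = as.integer(true_overlap),
    err_fwd = err_to_template(fside$err, fmaps),
    err_rev = err_to_template(rside$err, rmaps)
  )
  class(out) <- c("amplimerge_sim", class(out))
  attr(out, "template") <- template
  attr(out, "fwd_primer") <- cf
  attr(out, "rev_primer") <- cr
  attr(out, "encoding") <- phred_encoding(33)
  attr(out, "seed") <- seed
  attr(out, "params") <- list(
    read_len = read_len, phred_start = phred_start, phred_end = phred_end,
    masked_tail_prob = masked_tail_prob, masked_tail_max = masked_tail_max,
    n_rate = n_rate, n_phred_max = n_phred_max, errors = errors
  )
  out
}

#' Error-free reads under supplied quality masks
#'
#' Reproduces the "real masks on error-free sequence" design: each read
#' carries the exact template-derived bases, while its quality string is
#' taken verbatim from the supplied masks (e.g. quality strings harvested
#' from a real run). Read lengths follow the mask lengths.
#'
#' @param template Template sequence between the primers.
#' @param qual_fwd,qual_rev Character vectors of quality strings (phred+33),
#'   one pair per element; each must be no longer than the amplicon.
#' @param fwd_primer,rev_primer Primer sequences (non-degenerate; degenerate
#'   codes are concretised to their first member).
#' @return An `amplimerge_sim` tibble as from [simulate_pairs()] with empty
#'   error lists.
#' @export
transplant_masks <- function(template, qual_fwd, qual_rev,
                             fwd_primer = "", rev_primer = "") {
  stopifnot(length(qual_fwd) == length(qual_rev))
  template <- toupper(template)
  cf <- .concretize_iupac(fwd_primer, sample_bases = FALSE)
  cr <- .concretize_iupac(rev_primer, sample_bases = FALSE)
  amplicon <- paste0(cf, template, .rc_string(cr))
  la <- nchar(amplicon)
  rc_amp <- .rc_string(amplicon)
  n <- length(qual_fwd)
  lf <- nchar(qual_fwd)
  lr <- nchar(qual_rev)
  if (any(lf > la) || any(lr > la)) {
    stop("mask longer than the amplicon (", la, " bases)", call. = FALSE)
  }
  ov <- lf + lr - la
  out <- tibble::tibble(
    id = sprintf("mask%06d", seq_len(n)),
    seq_fwd = substr(rep(amplicon, n), 1, lf), qual_fwd = qual_fwd,
    seq_rev = substr(rep(rc_amp, n), 1, lr), qual_rev = qual_rev,
    true_overlap = ifelse(ov >= 1L, as.integer(ov), NA_integer_),
    err_fwd = rep(list(integer(0)), n),
    err_rev = rep(list(integer(0)), n)
  )
  class(out) <- c("amplimerge_sim", class(out))
  attr(out, "template") <- template
  attr(out, "fwd_primer") <- cf
  attr(out, "rev_primer") <- cr
  attr(out, "encoding") <- phred_encoding(33)
  out
}

#' Write simulated pairs as FASTQ plus a truth table
#'
#' Mate files carry `/1` and `/2` identifier suffixes. The truth file is
#' tab-separated (`id`, `true_overlap`, comma-joined `err_fwd`/`err_rev`
#' template positions) with a header comment recording the seed and
#' template.
#'
#' @param sim An `amplimerge_sim` tibble.
#' @param forward,reverse,truth Output paths (`truth = NULL` to skip).
#' @return `sim`, invisibly.
#' @export
write_sim_fastq <- function(sim, forward, reverse, truth = NULL) {
  .write_fastq(paste0(sim$id, "/1"), sim$seq_fwd, sim$qual_fwd, forward)
  .write_fastq(paste0(sim$id, "/2"), sim$seq_rev, sim$qual_rev, reverse)
  if (!is.null(truth)) {
    join <- function(v) vapply(v, function(x) paste(x, collapse = ","),
                               character(1))
    hdr <- paste0("# amplimerge-sim seed=",
                  attr(sim, "seed") %||% "NA",
                  " template=", attr(sim, "template"))
    writeLines(hdr, truth)
    readr::write_tsv(
      tibble::tibble(id = sim$id, true_overlap = sim$true_overlap,
                     err_fwd = join(sim$err_fwd), err_rev = join(sim$err_rev)),
      truth, append = TRUE, col_names = TRUE)
  }
  invisible(sim)
}

#' Read back a truth table written by [write_sim_fastq()]
#'
#' @param path Truth file path.
#' @return A tibble with `id`, `true_overlap` and integer list-columns
#'   `err_fwd`, `err_rev`; the template is restored as an attribute.
#' @export
read_sim_truth <- function(path) {
  first <- readLines(path, n = 1L)
  template <- sub("^.* template=", "", first)
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       col_types = readr::cols(
                         id = readr::col_character(),
                         true_overlap = readr::col_integer(),
                         err_fwd = readr::col_character(),
                         err_rev = readr::col_character()))
  unjoin <- function(v) {
    lapply(v, function(s) {
      if (is.na(s) || !nzchar(s)) integer(0)
      else as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
    })
  }
  out <- tibble::tibble(
    id = x$id,
    true_overlap = as.integer(x$true_overlap),
    err_fwd = unjoin(as.character(x$err_fwd)),
    err_rev = unjoin(as.character(x$err_rev))
  )
  attr(out, "template") <- template
  out
}
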