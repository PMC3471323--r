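# Internal sequence/quality encodings shared across modules.
# Nucleotide codes 1..5 = A,C,G,T,N; coordinates 0-based half-open at module
# boundaries, 1-based only inside R vector arithmetic.

.NUC <- c("A", "C", "G", "T", "N")
.NUC_ASCII <- utf8ToInt("ACGTN")
.COMP <- c(4L, 3L, 2L, 1L, 5L)

# error probabilities never below the platform cap (phred 41)
.EPS_FLOOR <- 10^-4.1

.code_tab <- local({
  tab <- rep(NA_integer_, 256L)
  tab[.NUC_ASCII + 1L] <- 1:5
  tab
})

.s2codes <- function(s) {
  a <- utf8ToInt(s)
  cd <- .code_tab[a + 1L]
  if (anyNA(cd)) {
    bad <- which(is.na(cd))[1L]
    stop("invalid nucleotide symbol '", substr(s, bad, bad),
         "' at position ", bad, " (allowed: A, C, G, T, N)", call. = FALSE)
  }
  cd
}

.codes2s <- function(codes) {
  if (length(codes) == 0L) return("")
  intToUtf8(.NUC_ASCII[codes])
}

.rc_codes <- function(codes) .COMP[rev(codes)]

.rc_string <- function(s) .codes2s(.rc_codes(.s2codes(s)))

# ascii -> error probability lookup, one table per offset, clamped to the floor
.eps_tab <- local({
  cache <- list()
  function(offset) {
    key <- as.character(offset)
    if (is.null(cache[[key]])) {
      a <- 0:255
      q <- a - offset
      eps <- pmax(10^(-q / 10), .EPS_FLOOR)
      eps[q < 0] <- NA_real_
      cache[[key]] <<- eps
    }
    cache[[key]]
  }
})

.q2eps <- function(qual, offset) {
  a <- utf8ToInt(qual)
  eps <- .eps_tab(offset)[a + 1L]
  if (anyNA(eps)) {
    bad <- which(is.na(eps))[1L]
    stop("malformed quality character '", substr(qual, bad, bad),
         "' (ASCII ", a[bad], ") at position ", bad,
         ": below encoding offset ", offset, call. = FALSE)
  }
  eps
}

# trailing run of phred <= 2 (the pipelines' quality-masking convention)
.masked_tail_ascii <- function(a, offset) {
  low <- a <= offset + 2L
  if (length(low) == 0L) return(logical(0))
  rev(cumprod(rev(low)) > 0)
}

.enc_offset <- function(encoding) {
  if (inherits(encoding, "phred_encoding")) return(encoding$ascii_offset)
  if (is.numeric(encoding) && encoding %in% c(33, 64)) return(as.integer(encoding))
  stop("`encoding` must be a phred_encoding object or 33/64", call. = FALSE)
}
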