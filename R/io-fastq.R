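# Paired FASTQ ingest/output. Parsing and serialisation are delegated to
# Biostrings; pairing, identifier normalisation, encoding detection and
# masked-tail calling are package logic.

# strip mate designators: "/1"-"/2" suffixes and CASAVA 1.8 " 1:..."/" 2:..."
# comment fields; the identifier proper is the first whitespace token.
.norm_read_id <- function(id) {
  id <- sub("\\s.*$", "", id)
  sub("/[12]$", "", id)
}

.read_fastq_side <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble::tibble(
    id = names(x),
    seq = unname(toupper(as.character(x))),
    qual = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' Read synchronized paired FASTQ files
#'
#' Streams the forward and reverse mate files (plain or gzip) into a tibble
#' of read pairs, one row per pair. Mates are paired positionally, as
#' Illumina mate files are written, and identifiers are verified to agree
#' after mate-designator normalisation ("/1"/"/2" suffixes and CASAVA-1.8
#' comment fields are stripped). Sequences are upper-cased; symbols outside
#' A/C/G/T/N are rejected.
#'
#' @param forward,reverse Paths to the mate-1 and mate-2 FASTQ files.
#' @param encoding `"auto"` (default) to detect the quality encoding from the
#'   first reads, or a [phred_encoding()]/offset to force one.
#' @param sample_n Number of leading records inspected by auto-detection.
#' @return A tibble with columns `id`, `seq_fwd`, `qual_fwd`, `seq_rev`,
#'   `qual_rev` and a `"encoding"` attribute holding the [phred_encoding()].
#' @export
read_fastq_pairs <- function(forward, reverse, encoding = "auto",
                             sample_n = 100) {
  f <- .read_fastq_side(forward)
  r <- .read_fastq_side(reverse)
  if (nrow(f) != nrow(r)) {
    stop("mate files desynchronized: ", nrow(f), " forward vs ",
         nrow(r), " reverse records", call. = FALSE)
  }
  idf <- .norm_read_id(f$id)
  idr <- .norm_read_id(r$id)
  bad <- which(idf != idr)
  if (length(bad) > 0L) {
    k <- bad[1L]
    stop("mate files desynchronized at record ", k, ": '", f$id[k],
         "' vs '", r$id[k], "'", call. = FALSE)
  }
  for (s in c(f$seq, r$seq)) {
    if (grepl("[^ACGTN]", s)) .s2codes(s)  # raises a precise error
  }
  if (any(nchar(f$seq) != nchar(f$qual)) || any(nchar(r$seq) != nchar(r$qual))) {
    stop("malformed record: sequence/quality length mismatch", call. = FALSE)
  }
  enc <- if (identical(encoding, "auto")) {
    if (nrow(f) == 0L) phred_encoding(33)
    else detect_encoding(utils::head(c(f$qual, r$qual), sample_n))
  } else if (inherits(encoding, "phred_encoding")) {
    encoding
  } else {
    phred_encoding(encoding)
  }
  out <- tibble::tibble(
    id = idf,
    seq_fwd = f$seq, qual_fwd = f$qual,
    seq_rev = r$seq, qual_rev = r$qual
  )
  attr(out, "encoding") <- enc
  out
}

#' Detect the phred encoding of quality strings
#'
#' Heuristic over a sample of quality strings: any character below ASCII 59
#' implies offset 33 (such characters cannot occur in phred+64 data); a
#' sample lying entirely at or above ASCII 64 with at least one character
#' above 74 implies offset 64. Ambiguous samples default to offset 33 with a
#' warning; an explicit encoding argument elsewhere overrides detection.
#'
#' @param qualities Character vector of quality strings.
#' @return A [phred_encoding()].
#' @export
detect_encoding <- function(qualities) {
  stopifnot(length(qualities) > 0L)
  a <- utf8ToInt(paste(qualities, collapse = ""))
  if (length(a) == 0L) {
    warning("empty quality sample; defaulting to phred+33", call. = FALSE)
    return(phred_encoding(33))
  }
  if (any(a < 59)) return(phred_encoding(33))
  if (all(a >= 64) && any(a > 74)) return(phred_encoding(64))
  warning("ambiguous quality encoding; defaulting to phred+33", call. = FALSE)
  phred_encoding(33)
}

#' Flag the quality-masked tail of a read
#'
#' CASAVA-style pipelines mask the unreliable end of a read by overwriting
#' trailing quality scores with the lowest value (phred 2: `#` in phred+33,
#' `B` in phred+64). Returns `TRUE` exactly for the maximal contiguous
#' suffix with phred \eqn{\le} 2; interior low-quality runs not connected to
#' the suffix are not masked.
#'
#' @param qual_chars A quality string.
#' @param encoding A [phred_encoding()] or offset.
#' @return Logical vector, one element per base.
#' @examples
#' detect_masked_tail("IIIII###", 33)
#' @export
detect_masked_tail <- function(qual_chars, encoding = phred_encoding(33)) {
  offset <- .enc_offset(encoding)
  .masked_tail_ascii(utf8ToInt(qual_chars), offset)
}

# internal: write id/seq/qual vectors as 4-line FASTQ records (a bare "+"
# separator, so records survive a read/write cycle byte-for-byte)
.write_fastq <- function(ids, seqs, quals, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (length(ids) > 0) {
    writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), con)
  }
  invisible(length(ids))
}

# per-base correctness probability -> phred character at offset 33, cap 41
.p2qchar <- function(p) {
  q <- round(-10 * log10(pmax(1 - p, 0)))
  q[!is.finite(q)] <- 41
  q <- pmin(pmax(q, 0), 41)
  intToUtf8(q + 33L, multiple = FALSE)
}

#' Write assembled sequences to FASTA or FASTQ
#'
#' FASTA headers carry `id:overlap_length:quality` with the geometric-mean
#' quality printed to six decimals. FASTQ output re-encodes each base's
#' correctness probability `p` as phred `round(-10 log10(1 - p))`, clamped
#' to \[0, 41\] at offset 33.
#'
#' @param results A [merge_pairs()] result; every row must have passed
#'   validation (`status == "ok"`).
#' @param dest Output path (`.gz` for compressed output).
#' @param format `"fasta"` (default) or `"fastq"`.
#' @return The number of records written, invisibly.
#' @export
write_assemblies <- function(results, dest, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (nrow(results) > 0 && !all(results$status == "ok")) {
    stop("write_assemblies() expects validated results (status == \"ok\"); ",
         "filter first", call. = FALSE)
  }
  headers <- if (nrow(results) == 0) character(0) else {
    paste(results$id, results$overlap_len,
          sprintf("%.6f", results$quality), sep = ":")
  }
  x <- Biostrings::DNAStringSet(results$sequence)
  names(x) <- headers
  compress <- grepl("\\.gz$", dest)
  if (format == "fasta") {
    Biostrings::writeXStringSet(x, dest, format = "fasta", compress = compress)
  } else {
    quals <- vapply(results$probs, .p2qchar, character(1))
    .write_fastq(headers, results$sequence, quals, dest)
  }
  invisible(nrow(results))
}
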