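#' Amplicon read sets
#'
#' A lightweight container for a set of amplicon reads: identifiers, DNA
#' sequences over `{A,C,G,T,N}`, optional per-base error probabilities
#' (derived from Phred scores for FASTQ input, absent for FASTA), and a
#' sample label per read.
#'
#' @param id character vector of read identifiers.
#' @param seq character vector of DNA sequences (upper-cased on input).
#' @param qual `NULL`, or a list of numeric vectors of per-base error
#'   probabilities in `[0, 1]`, one per read, each the same length as its
#'   sequence.
#' @param sample character vector (or scalar, recycled) of sample labels.
#' @return An object of class `amplicon_reads`: a list with elements `id`,
#'   `seq`, `qual` and `sample`.
#' @examples
#' rs <- amplicon_reads("r1", "ACGT", list(rep(0.01, 4)), "S1")
#' length(rs)
#' @export
amplicon_reads <- function(id, seq, qual = NULL, sample = "sample1") {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  n <- length(seq)
  if (length(id) != n) stop("`id` and `seq` lengths differ", call. = FALSE)
  sample <- rep_len(as.character(sample), n)
  if (!is.null(qual)) {
    if (!is.list(qual) || length(qual) != n)
      stop("`qual` must be a list with one numeric vector per read",
           call. = FALSE)
    ok <- vapply(seq_len(n), function(i) {
      q <- qual[[i]]
      is.numeric(q) && length(q) == nchar(seq[i]) && all(q >= 0 & q <= 1)
    }, logical(1))
    if (n > 0 && !all(ok))
      stop("per-base error probabilities must match sequence lengths and lie in [0, 1]; first offending read: ",
           id[which(!ok)[1]], call. = FALSE)
  }
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad))
    stop("sequences contain characters outside {A,C,G,T,N}; first offending read: ",
         id[which(bad)[1]], call. = FALSE)
  structure(list(id = id, seq = seq, qual = qual, sample = sample),
            class = "amplicon_reads")
}

#' @export
length.amplicon_reads <- function(x) length(x$seq)

#' @export
`[.amplicon_reads` <- function(x, i) {
  amplicon_reads(x$id[i], x$seq[i],
                 if (!is.null(x$qual)) x$qual[i] else NULL,
                 x$sample[i])
}

#' @export
c.amplicon_reads <- function(...) {
  parts <- list(...)
  quals <- lapply(parts, `[[`, "qual")
  have_q <- !vapply(quals, is.null, logical(1))
  qual <- if (any(have_q)) {
    do.call(c, lapply(seq_along(parts), function(i) {
      quals[[i]] %||% rep(list(NULL), length(parts[[i]]))
    }))
  } else NULL
  amplicon_reads(unlist(lapply(parts, `[[`, "id")),
                 unlist(lapply(parts, `[[`, "seq")),
                 qual,
                 unlist(lapply(parts, `[[`, "sample")))
}

#' @export
print.amplicon_reads <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<amplicon_reads> %d read%s, %d sample%s, %s\n",
              n, if (n == 1) "" else "s",
              length(unique(x$sample)),
              if (length(unique(x$sample)) == 1) "" else "s",
              if (is.null(x$qual)) "no qualities" else "with qualities"))
  if (n > 0) {
    ln <- nchar(x$seq)
    cat(sprintf("  lengths: %d-%d (median %g)\n",
                min(ln), max(ln), stats::median(ln)))
    show <- utils::head(seq_len(n), 3L)
    for (i in show)
      cat(sprintf("  %s [%s] %s%s\n", x$id[i], x$sample[i],
                  substr(x$seq[i], 1, 40),
                  if (nchar(x$seq[i]) > 40) "..." else ""))
    if (n > 3) cat("  ...\n")
  }
  invisible(x)
}

#' Read amplicon sequences from FASTA or FASTQ
#'
#' FASTQ Phred scores (Sanger, Phred+33) are converted to per-base error
#' probabilities `p = 10^(-Q/10)`; FASTA reads carry no qualities.
#'
#' @param path path to the sequence file.
#' @param format `"fasta"` or `"fastq"`; default guessed from the file
#'   extension (`.fq`/`.fastq` imply FASTQ).
#' @param sample sample label attached to every read in the file.
#' @return An [amplicon_reads] object. An empty file yields an empty read
#'   set with a warning.
#' @export
read_amplicons <- function(path, format = c("auto", "fasta", "fastq"),
                           sample = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sample <- sample %||% sub("\\.[^.]*$", "", basename(path))
  if (format == "fastq") {
    # validate the 4-line record structure up front: the XString FASTQ
    # parser does not reliably report a quality/sequence length mismatch
    lines <- readLines(path)
    if (length(lines) %% 4L != 0L)
      stop("malformed FASTQ in ", path, ": truncated record near line ",
           4L * (length(lines) %/% 4L) + 1L, call. = FALSE)
    if (length(lines)) {
      sl <- nchar(lines[seq(2L, length(lines), by = 4L)])
      ql <- nchar(lines[seq(4L, length(lines), by = 4L)])
      if (any(sl != ql)) {
        rec <- which(sl != ql)[1]
        stop("malformed FASTQ in ", path,
             ": quality length differs from sequence length at line ",
             4L * (rec - 1L) + 4L, call. = FALSE)
      }
    }
    x <- tryCatch(
      suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path)),
      error = function(e) stop("malformed FASTQ in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    if (length(x) == 0L) {
      warning("no records in ", path)
      return(amplicon_reads(character(0), character(0),
                            list(), sample))
    }
    q <- methods::as(Biostrings::quality(x), "IntegerList")
    qual <- lapply(as.list(q), function(Q) 10^(-Q / 10))
    amplicon_reads(names(x) %||% paste0("read", seq_along(x)),
                   as.character(x), qual, sample)
  } else {
    x <- tryCatch(
      Biostrings::readDNAStringSet(path),
      error = function(e) stop("malformed FASTA in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    if (length(x) == 0L) {
      warning("no records in ", path)
      return(amplicon_reads(character(0), character(0), NULL, sample))
    }
    ids <- names(x) %||% paste0("read", seq_along(x))
    ids <- sub("\\s.*$", "", ids)
    amplicon_reads(ids, as.character(x), NULL, sample)
  }
}

#' Write an amplicon read set to FASTA or FASTQ
#'
#' FASTQ output encodes error probabilities back to Phred+33 characters
#' (`Q = round(-10 log10 p)`, capped at 93); reads without qualities can only
#' be written as FASTA.
#'
#' @param reads an [amplicon_reads] object.
#' @param path output file path.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_amplicons <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "fasta") {
    x <- Biostrings::DNAStringSet(reads$seq)
    names(x) <- reads$id
    Biostrings::writeXStringSet(x, path)
  } else {
    if (is.null(reads$qual))
      stop("reads carry no qualities; write FASTA instead", call. = FALSE)
    qchr <- vapply(reads$qual, function(p) {
      Q <- pmin(93L, pmax(0L, as.integer(round(-10 * log10(pmax(p, 1e-10))))))
      intToUtf8(Q + 33L)
    }, "")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", qchr), con)
  }
  invisible(path)
}
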