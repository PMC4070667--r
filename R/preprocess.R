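#' Filtering configuration for amplicon preprocessing
#'
#' Bundles the read-cleaning thresholds: at most `max_ambiguous` ambiguous
#' bases per read, modified-Mott quality trimming at error-probability
#' `quality_limit`, and a minimum read length of `min_length` nucleotides,
#' together with the amplicon primer pair.
#'
#' Defaults follow common 454 amplicon practice for the V3-V4 region:
#' `max_ambiguous = 2`, `quality_limit = 0.05`, `min_length = 300`, and the
#' V3-V4 primer pair used throughout this package.
#'
#' @param max_ambiguous maximum number of ambiguous (`N`) bases tolerated.
#' @param quality_limit error-probability threshold for Mott trimming.
#' @param min_length minimum read length in nucleotides (before primer
#'   removal by default; see [preprocess_reads]).
#' @param fwd_primer,rev_primer forward and reverse primer sequences
#'   (5'->3' on their respective strands).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(max_ambiguous = 2L,
                          quality_limit = 0.05,
                          min_length = 300L,
                          fwd_primer = "TCCTACGGGAGGCAGCAGT",
                          rev_primer = "GGACTACCAGGGTATCTAATCCTGTT") {
  stopifnot_scalar_prob(quality_limit, "quality_limit")
  if (min_length < 3) stop("`min_length` must be at least 3", call. = FALSE)
  if (max_ambiguous < 0) stop("`max_ambiguous` must be non-negative",
                              call. = FALSE)
  structure(list(max_ambiguous = as.integer(max_ambiguous),
                 quality_limit = quality_limit,
                 min_length = as.integer(min_length),
                 fwd_primer = toupper(fwd_primer),
                 rev_primer = toupper(rev_primer)),
            class = "filter_config")
}

# Leftmost maximum-score contiguous segment of `score`; returns c(start, end)
# (1-based, inclusive) or c(0L, -1L) when every segment scores <= 0.
.best_segment <- function(score) {
  best <- 0
  bs <- 0L; be <- -1L
  cur <- 0
  cs <- 1L
  for (i in seq_along(score)) {
    cur <- cur + score[i]
    if (cur > best) {
      best <- cur
      bs <- cs; be <- i
    }
    if (cur <= 0) {
      cur <- 0
      cs <- i + 1L
    }
  }
  c(bs, be)
}

#' Quality-trim reads with the modified-Mott algorithm
#'
#' Keeps, for each read, the contiguous subsequence maximizing
#' `sum(limit - p_i)` over its per-base error probabilities `p_i`; the read
#' becomes empty when every segment scores non-positive. Among equal-scoring
#' segments the leftmost (earliest-ending) one is kept. Reads without
#' qualities pass through untrimmed with a warning.
#'
#' @param reads an [amplicon_reads] object.
#' @param limit error-probability threshold (default 0.05).
#' @return An [amplicon_reads] object of the same length with trimmed
#'   sequences and qualities.
#' @examples
#' r <- amplicon_reads("r", "AACCGGTT",
#'                     list(c(.2, .01, .01, .01, .01, .01, .2, .2)))
#' mott_trim(r)$seq
#' @export
mott_trim <- function(reads, limit = 0.05) {
  stopifnot_scalar_prob(limit, "limit")
  if (is.null(reads$qual)) {
    warning("reads carry no qualities; returned untrimmed")
    return(reads)
  }
  n <- length(reads)
  seq2 <- character(n)
  qual2 <- vector("list", n)
  for (i in seq_len(n)) {
    p <- reads$qual[[i]]
    seg <- .best_segment(limit - p)
    if (seg[2] < seg[1]) {
      seq2[i] <- ""
      qual2[[i]] <- numeric(0)
    } else {
      seq2[i] <- substr(reads$seq[i], seg[1], seg[2])
      qual2[[i]] <- p[seg[1]:seg[2]]
    }
  }
  structure(list(id = reads$id, seq = seq2, qual = qual2,
                 sample = reads$sample),
            class = "amplicon_reads")
}

#' Filter reads on ambiguity and length
#'
#' Keeps reads with at most `max_ambiguous` ambiguous bases and length at
#' least `min_length`; both boundaries are inclusive. Input order is
#' preserved. Rejections are reported per rule in the `"filter_report"`
#' attribute of the result (a data frame with columns `id`, `sample`,
#' `rule`).
#'
#' @param reads an [amplicon_reads] object.
#' @param cfg a [filter_config]; only `max_ambiguous` and `min_length` are
#'   used here.
#' @return The kept reads, with attribute `filter_report`.
#' @export
filter_reads <- function(reads, cfg = filter_config()) {
  n_amb <- count_ambiguous(reads$seq)
  len <- nchar(reads$seq)
  too_amb <- n_amb > cfg$max_ambiguous
  too_short <- !too_amb & len < cfg$min_length
  keep <- !too_amb & !too_short
  report <- data.frame(
    id = reads$id[!keep],
    sample = reads$sample[!keep],
    rule = ifelse(too_amb[!keep], "max_ambiguous", "min_length"),
    stringsAsFactors = FALSE)
  out <- reads[keep]
  attr(out, "filter_report") <- report
  out
}

# Locate an exact occurrence of `pattern` in `s` starting at a 1-based
# position in `starts`; returns the first matching start or 0L.
.anchored_match <- function(s, pattern, starts) {
  np <- nchar(pattern)
  for (st in starts) {
    if (st < 1L || st + np - 1L > nchar(s)) next
    if (substr(s, st, st + np - 1L) == pattern) return(st)
  }
  0L
}

# Try to strip primers from one oriented sequence; returns c(start, end) of
# the insert (1-based, inclusive) or NULL.
.find_insert <- function(s, fwd, rcrev, anchor) {
  f <- .anchored_match(s, fwd, seq_len(anchor + 1L))
  if (f == 0L) return(NULL)
  L <- nchar(s); nr <- nchar(rcrev)
  ends <- L - (0:anchor)                      # allowed end positions of rcrev
  r <- 0L
  for (e in ends) {
    st <- e - nr + 1L
    if (st < 1L) next
    if (substr(s, st, e) == rcrev) { r <- st; break }
  }
  if (r == 0L) return(NULL)
  ins_start <- f + nchar(fwd)
  ins_end <- r - 1L
  if (ins_end < ins_start) return(NULL)
  c(ins_start, ins_end)
}

#' Strip primers and orient reads
#'
#' Requires an exact (0-mismatch) occurrence of the forward primer near the
#' 5' end and of the reverse complement of the reverse primer near the 3'
#' end. Both the read as given and its reverse complement are tested; the
#' matching orientation is kept and the insert between the primers returned,
#' always oriented forward-primer-first. Primer matches are anchored: the
#' forward primer must start within the first `anchor + 1` bases and the
#' reverse-primer complement must end within the last `anchor + 1` bases
#' (allowing small key/adapter remnants).
#'
#' Reads failing the match are rejected with rule `"primer_mismatch"`;
#' degenerate reads matching in both orientations are rejected with rule
#' `"ambiguous_orientation"`.
#'
#' @param reads an [amplicon_reads] object.
#' @param fwd,rev primer sequences (5'->3' on their respective strands).
#' @param anchor maximum offset of the primer from the read end (default 5).
#' @return The primer-stripped inserts as [amplicon_reads], with attribute
#'   `filter_report` listing rejections.
#' @export
strip_primers <- function(reads, fwd, rev, anchor = 5L) {
  if (!nzchar(fwd) || !nzchar(rev))
    stop("primers must be non-empty", call. = FALSE)
  fwd <- toupper(fwd); rev <- toupper(rev)
  rcrev <- revcomp(rev)
  n <- length(reads)
  seq2 <- character(n); qual2 <- vector("list", n)
  status <- character(n)
  have_q <- !is.null(reads$qual)
  for (i in seq_len(n)) {
    s <- reads$seq[i]
    rc <- revcomp(s)
    a <- .find_insert(s, fwd, rcrev, anchor)
    b <- .find_insert(rc, fwd, rcrev, anchor)
    if (!is.null(a) && !is.null(b)) {
      status[i] <- "ambiguous_orientation"
    } else if (is.null(a) && is.null(b)) {
      status[i] <- "primer_mismatch"
    } else {
      status[i] <- "ok"
      if (!is.null(a)) {
        seq2[i] <- substr(s, a[1], a[2])
        if (have_q) qual2[[i]] <- reads$qual[[i]][a[1]:a[2]]
      } else {
        seq2[i] <- substr(rc, b[1], b[2])
        if (have_q) {
          q <- rev(reads$qual[[i]])          # qualities follow the flip
          qual2[[i]] <- q[b[1]:b[2]]
        }
      }
    }
  }
  keep <- status == "ok"
  out <- structure(list(id = reads$id[keep], seq = seq2[keep],
                        qual = if (have_q) qual2[keep] else NULL,
                        sample = reads$sample[keep]),
                   class = "amplicon_reads")
  attr(out, "filter_report") <- data.frame(
    id = reads$id[!keep], sample = reads$sample[!keep],
    rule = status[!keep], stringsAsFactors = FALSE)
  out
}

#' Subsample each sample to equal depth
#'
#' Uniform sampling without replacement within each sample, so that every
#' sample retains exactly `depth` reads (`depth = "min"` uses the smallest
#' sample size). Deterministic for a given `seed`.
#'
#' @param reads an [amplicon_reads] object covering one or more samples.
#' @param depth integer target depth, or `"min"`.
#' @param seed integer RNG seed (default 1).
#' @return An [amplicon_reads] object with `depth` reads per sample.
#' @export
subsample_reads <- function(reads, depth = "min", seed = 1L) {
  sizes <- table(reads$sample)
  if (identical(depth, "min")) depth <- min(sizes)
  depth <- as.integer(depth)
  small <- names(sizes)[sizes < depth]
  if (length(small))
    stop("sample(s) smaller than requested depth ", depth, ": ",
         paste(small, collapse = ", "), call. = FALSE)
  idx <- with_seed(seed, {
    unlist(lapply(split(seq_along(reads$sample), reads$sample), function(ii) {
      sort(sample(ii, depth))
    }), use.names = FALSE)
  })
  reads[sort(idx)]
}

#' Run the full read-preparation pipeline
#'
#' Quality trimming (FASTQ input only), ambiguity/length filtering, primer
#' stripping and orientation, and depth normalization, in that order. The
#' length filter is applied to the read before primer removal by default
#' (`length_filter = "pre_primer"`); set `length_filter = "post_primer"` to
#' apply the cutoff to the primer-stripped insert instead.
#'
#' @param reads an [amplicon_reads] object (all samples pooled).
#' @param cfg a [filter_config].
#' @param depth subsampling depth per sample, `"min"`, or `NULL` to skip
#'   depth normalization.
#' @param seed RNG seed for subsampling.
#' @param length_filter when the minimum-length rule applies (see above).
#' @return Primer-stripped, depth-normalized [amplicon_reads]; attribute
#'   `prep_log` summarizes counts per stage and rejections per rule.
#' @export
preprocess_reads <- function(reads, cfg = filter_config(), depth = "min",
                             seed = 1L,
                             length_filter = c("pre_primer", "post_primer")) {
  length_filter <- match.arg(length_filter)
  log <- list(input = length(reads))
  if (!is.null(reads$qual)) {
    reads <- mott_trim(reads, cfg$quality_limit)
    log$trimmed <- length(reads)
  }
  pre_cfg <- cfg
  if (length_filter == "post_primer") pre_cfg$min_length <- 3L
  reads <- filter_reads(reads, pre_cfg)
  rej <- attr(reads, "filter_report")
  log$after_filter <- length(reads)
  reads <- strip_primers(reads, cfg$fwd_primer, cfg$rev_primer)
  rej <- rbind(rej, attr(reads, "filter_report"))
  log$after_primers <- length(reads)
  if (length_filter == "post_primer") {
    post_cfg <- cfg
    post_cfg$max_ambiguous <- .Machine$integer.max
    reads <- filter_reads(reads, post_cfg)
    rej <- rbind(rej, attr(reads, "filter_report"))
    log$after_length <- length(reads)
  }
  if (!is.null(depth) && length(reads) > 0) {
    reads <- subsample_reads(reads, depth, seed)
    log$after_subsample <- length(reads)
  }
  log$rejections <- rej
  attr(reads, "prep_log") <- log
  reads
}
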