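#' Assign reads to OTNs and build the binary matrix
#'
#' Every occurrence of trinucleotide `t` at offset `p` in a read marks the
#' OTN `(t, bin containing p)` present for that read. After marking, the
#' multiplicity-discharge rule removes, globally, every OTN for which at
#' least one read carried two or more occurrences of `t` inside the same
#' bin — the signature of homopolymeric tracts, whose high indel error rate
#' would otherwise inflate distances. Occurrences of a trinucleotide with no
#' bins (no detected peak) carry no information and are ignored (counted in
#' the summary).
#'
#' @param reads an [amplicon_reads] object (primer-stripped inserts).
#' @param peaks an `otn_peaks` object built from the same read universe (or
#'   a superset).
#' @return An object of class `otn_matrix`: list with
#'   \describe{
#'     \item{matrix}{reads x OTNs binary integer matrix; row names read ids,
#'       column names `"TTT@bin3"`-style OTN ids (bins 1-based per
#'       trinucleotide).}
#'     \item{sample}{sample label per row.}
#'     \item{discharged}{character vector of OTN ids removed by the
#'       multiplicity rule.}
#'     \item{n_ignored}{occurrences falling outside every bin of their
#'       trinucleotide.}
#'   }
#' @export
assign_otns <- function(reads, peaks) {
  n <- length(reads)
  if (n == 0L) stop("empty read set", call. = FALSE)
  nbins <- vapply(peaks$breaks, function(b) max(0L, length(b) - 1L),
                  integer(1))
  col_tri <- rep(seq_len(64L), nbins)
  col_bin <- unlist(lapply(nbins, seq_len), use.names = FALSE)
  ncols <- length(col_tri)
  col_ids <- paste0(TRINUCLEOTIDES[col_tri], "@bin", col_bin)
  # column index lookup per (trinucleotide, bin): offset into col_ids
  col_offset <- c(0L, cumsum(nbins))
  n_ignored <- 0L
  ri <- vector("list", n); ci <- vector("list", n); dup <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- tri_indices(reads$seq[i])
    off <- which(!is.na(idx)) - 1L           # 0-based offsets
    tri <- idx[off + 1L]
    if (!length(off)) next
    cols <- rep(NA_integer_, length(off))
    for (t in unique(tri)) {
      br <- peaks$breaks[[t]]
      if (length(br) < 2L) next
      sel <- which(tri == t)
      b <- findInterval(off[sel], br)
      valid <- b >= 1L & b <= length(br) - 1L & off[sel] < br[length(br)]
      cols[sel[valid]] <- col_offset[t] + b[valid]
    }
    n_ignored <- n_ignored + sum(is.na(cols))
    cols <- cols[!is.na(cols)]
    if (!length(cols)) next
    tab <- tabulate(cols, nbins = ncols)
    hit <- which(tab > 0L)
    ri[[i]] <- rep.int(i, length(hit))
    ci[[i]] <- hit
    dup[[i]] <- which(tab > 1L)
  }
  rows <- unlist(ri, use.names = FALSE)
  cols <- unlist(ci, use.names = FALSE)
  discharged_idx <- sort(unique(unlist(dup, use.names = FALSE)))
  m <- matrix(0L, nrow = n, ncol = ncols,
              dimnames = list(reads$id, col_ids))
  if (length(rows)) m[cbind(rows, cols)] <- 1L
  discharged <- col_ids[discharged_idx]
  if (length(discharged_idx)) m <- m[, -discharged_idx, drop = FALSE]
  structure(list(matrix = m, sample = reads$sample,
                 discharged = discharged, n_ignored = n_ignored),
            class = "otn_matrix")
}

#' @export
print.otn_matrix <- function(x, ...) {
  cat(sprintf("<otn_matrix> %d reads x %d OTNs (%d discharged, %d occurrences outside bins)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$discharged),
              x$n_ignored))
  invisible(x)
}

#' Collapse identical OTN patterns into OTUs
#'
#' Reads with identical OTN presence/absence bit-vectors are merged into one
#' pattern; patterns play the role of operational taxonomic units (100%
#' identity). Counts are split by sample. With `drop_singletons` (the
#' default, mirroring the treatment of likely sequencing errors and
#' chimeras) patterns observed exactly once across all samples are removed.
#'
#' @param x an `otn_matrix` (or a binary matrix with a `sample` attribute).
#' @param drop_singletons drop patterns with total count 1?
#' @return An object of class `otn_patterns`: list with
#'   \describe{
#'     \item{counts}{patterns x samples integer matrix of read counts.}
#'     \item{patterns}{patterns x OTNs binary matrix (one representative
#'       bit-vector per row).}
#'     \item{singleton_filtered}{logical flag.}
#'     \item{singleton_fraction}{fraction of patterns that were singletons
#'       before filtering.}
#'     \item{accuracy_estimate}{heuristic per-position accuracy: treating
#'       every singleton read as carrying at least one error,
#'       `(1 - singleton_reads/total_reads)^(1/mean_pattern_length)`.}
#'   }
#' @export
collapse_patterns <- function(x, drop_singletons = TRUE) {
  m <- x$matrix
  samp <- x$sample
  if (!all(m %in% c(0L, 1L))) stop("matrix is not binary", call. = FALSE)
  key <- apply(m, 1L, paste, collapse = "")
  if (nrow(m) > 0 && ncol(m) == 0L) key <- rep("", nrow(m))
  samples <- sort(unique(samp))
  tab <- table(factor(key), factor(samp, levels = samples))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), samples))
  first <- match(rownames(tab), key)
  patterns <- m[first, , drop = FALSE]
  rownames(patterns) <- rownames(counts) <-
    paste0("pattern", seq_len(nrow(counts)))
  totals <- rowSums(counts)
  n_singleton <- sum(totals == 1L)
  singleton_fraction <- if (nrow(counts)) n_singleton / nrow(counts) else 0
  total_reads <- sum(totals)
  L <- max(1, ncol(m))
  accuracy <- if (total_reads > 0)
    (1 - n_singleton / total_reads)^(1 / L) else NA_real_
  if (drop_singletons) {
    keep <- totals >= 2L
    counts <- counts[keep, , drop = FALSE]
    patterns <- patterns[keep, , drop = FALSE]
  }
  structure(list(counts = counts, patterns = patterns,
                 singleton_filtered = drop_singletons,
                 singleton_fraction = singleton_fraction,
                 accuracy_estimate = accuracy),
            class = "otn_patterns")
}

#' @export
print.otn_patterns <- function(x, ...) {
  cat(sprintf("<otn_patterns> %d pattern%s x %d sample%s (%d reads)%s\n",
              nrow(x$counts), if (nrow(x$counts) == 1) "" else "s",
              ncol(x$counts), if (ncol(x$counts) == 1) "" else "s",
              sum(x$counts),
              if (x$singleton_filtered) ", singletons removed" else ""))
  cat(sprintf("  singleton fraction %.3f; per-position accuracy estimate %.4f\n",
              x$singleton_fraction, x$accuracy_estimate))
  invisible(x)
}

#' Fit the OTN semi-alignment to a prepared read set
#'
#' The central fitting step: builds the pooled positional trinucleotide
#' histogram, detects peaks and bins, assigns reads to OTNs under the
#' multiplicity-discharge rule, and collapses identical patterns into OTUs.
#'
#' @param reads primer-stripped, depth-normalized [amplicon_reads] (see
#'   [preprocess_reads]).
#' @param delta,min_peak_freq,delta_mode,boundary passed to [detect_peaks].
#' @param drop_singletons passed to [collapse_patterns].
#' @return An object of class `otn_fit` bundling `histogram`, `peaks`,
#'   `profile` (the `otn_matrix`) and `patterns`, with `print`, `summary`
#'   and `plot` methods.
#' @examples
#' reads <- amplicon_reads(c("a", "b", "c", "d"),
#'                         c("ACGTACCA", "ACGTACCA", "ACGAACCA", "ACGAACCA"))
#' fit <- otn_semialign(reads, min_peak_freq = 0, drop_singletons = FALSE)
#' fit
#' @export
otn_semialign <- function(reads, delta = 0.1, min_peak_freq = 0.01,
                          delta_mode = c("relative", "absolute"),
                          boundary = c("midpoint", "valley"),
                          drop_singletons = TRUE) {
  hist <- build_histogram(reads)
  peaks <- detect_peaks(hist, delta = delta, min_peak_freq = min_peak_freq,
                        delta_mode = match.arg(delta_mode),
                        boundary = match.arg(boundary))
  profile <- assign_otns(reads, peaks)
  patterns <- collapse_patterns(profile, drop_singletons = drop_singletons)
  structure(list(histogram = hist, peaks = peaks, profile = profile,
                 patterns = patterns, call = match.call()),
            class = "otn_fit")
}

#' @export
print.otn_fit <- function(x, ...) {
  cat("OTN semi-alignment fit\n")
  cat(sprintf("  reads: %d   positions: %d\n",
              x$histogram$n_reads, ncol(x$histogram$counts)))
  cat(sprintf("  peaks: %d   OTNs kept: %d   discharged: %d\n",
              x$peaks$n_peaks, ncol(x$profile$matrix),
              length(x$profile$discharged)))
  cat(sprintf("  patterns (OTUs): %d across %d sample(s)\n",
              nrow(x$patterns$counts), ncol(x$patterns$counts)))
  invisible(x)
}

#' @export
summary.otn_fit <- function(object, ...) {
  pat <- object$patterns
  per_sample <- colSums(pat$counts)
  out <- list(
    n_reads = object$histogram$n_reads,
    n_positions = ncol(object$histogram$counts),
    n_peaks = object$peaks$n_peaks,
    n_otns = ncol(object$profile$matrix),
    n_discharged = length(object$profile$discharged),
    n_patterns = nrow(pat$counts),
    reads_per_sample = per_sample,
    singleton_fraction = pat$singleton_fraction,
    accuracy_estimate = pat$accuracy_estimate)
  class(out) <- "summary.otn_fit"
  out
}

#' @export
print.summary.otn_fit <- function(x, ...) {
  cat("OTN semi-alignment summary\n")
  cat(sprintf("  reads %d, positions %d\n", x$n_reads, x$n_positions))
  cat(sprintf("  peaks %d -> OTNs kept %d (discharged %d)\n",
              x$n_peaks, x$n_otns, x$n_discharged))
  cat(sprintf("  unique patterns %d; singleton fraction %.3f; accuracy est. %.4f\n",
              x$n_patterns, x$singleton_fraction, x$accuracy_estimate))
  cat("  reads per sample after pattern filtering:\n")
  print(x$reads_per_sample)
  invisible(x)
}

#' @export
plot.otn_fit <- function(x, ...) {
  plot(x$histogram, ...)
  invisible(x)
}
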