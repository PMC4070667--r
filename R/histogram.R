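#' Positional trinucleotide histogram
#'
#' Counts, over the pooled primer-stripped read set, the occurrences of each
#' of the 64 trinucleotides at every start offset along the read coordinate.
#' Offsets are 0-based within the insert; a read of length `L` contributes
#' offsets `0 .. L-3`. Windows containing an ambiguous base are skipped and
#' do not enter the coverage either, so the column sums of `counts` equal
#' `coverage` exactly.
#'
#' @param reads an [amplicon_reads] object (pooled across all samples).
#' @return An object of class `otn_histogram`: list with
#'   \describe{
#'     \item{counts}{64 x P integer matrix, rows the trinucleotides in
#'       lexicographic order, column `p+1` the 0-based offset `p`;
#'       `P = Lmax - 2`.}
#'     \item{coverage}{integer vector of length P; `coverage[p+1]` is the
#'       number of reads contributing an unambiguous window at offset `p`.}
#'     \item{n_reads}{number of reads used.}
#'   }
#' @export
build_histogram <- function(reads) {
  if (length(reads) == 0L) stop("empty read set", call. = FALSE)
  lens <- nchar(reads$seq)
  lmax <- max(lens)
  if (lmax < 3L) stop("no read is long enough to hold a trinucleotide",
                      call. = FALSE)
  P <- lmax - 2L
  keys <- lapply(reads$seq, function(s) {
    idx <- tri_indices(s)
    off <- which(!is.na(idx))               # 1-based offset+1
    if (!length(off)) return(integer(0))
    (off - 1L) * 64L + idx[off]             # combined key, 1-based
  })
  allk <- unlist(keys, use.names = FALSE)
  counts <- matrix(tabulate(allk, nbins = 64L * P), nrow = 64L,
                   dimnames = list(TRINUCLEOTIDES, NULL))
  coverage <- as.integer(colSums(counts))
  structure(list(counts = counts, coverage = coverage,
                 n_reads = length(reads)),
            class = "otn_histogram")
}

#' @export
print.otn_histogram <- function(x, ...) {
  cat(sprintf("<otn_histogram> %d reads, %d positions, %d occurrences\n",
              x$n_reads, ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' @export
plot.otn_histogram <- function(x, trinucleotides = c("ACG", "GCA", "TAC"),
                               relative = TRUE, ...) {
  sel <- match(trinucleotides, TRINUCLEOTIDES)
  y <- x$counts[sel, , drop = FALSE]
  if (relative) {
    denom <- pmax(x$coverage, 1L)
    y <- sweep(y, 2, denom, "/")
  }
  graphics::matplot(0:(ncol(y) - 1L), t(y), type = "l", lty = 1,
                    xlab = "offset in insert (0-based)",
                    ylab = if (relative) "relative frequency" else "count",
                    ...)
  graphics::legend("topright", legend = trinucleotides, lty = 1,
                   col = seq_along(sel), bty = "n")
  invisible(x)
}

#' Detect peaks in a 1-D series by delta prominence
#'
#' Alternating maxima/minima scan: a candidate maximum is emitted once the
#' series has subsequently dropped by at least `delta` below the running
#' maximum, and symmetrically a candidate minimum once the series has risen
#' by at least `delta` above the running minimum. Equal-height candidates
#' keep the earliest position.
#'
#' @param series numeric vector, finite.
#' @param delta positive prominence threshold.
#' @return list with integer vectors `maxima` and `minima` of 1-based
#'   indices into `series`.
#' @examples
#' peakdet(c(0, 3, 1, 4, 0), 2)$maxima  # indices 2 and 4
#' @export
peakdet <- function(series, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta <= 0)
    stop("`delta` must be a single positive number", call. = FALSE)
  if (any(!is.finite(series))) stop("`series` must be finite", call. = FALSE)
  maxima <- integer(0); minima <- integer(0)
  mx <- -Inf; mn <- Inf
  mxpos <- 0L; mnpos <- 0L
  lookformax <- TRUE
  for (i in seq_along(series)) {
    v <- series[i]
    if (v > mx) { mx <- v; mxpos <- i }
    if (v < mn) { mn <- v; mnpos <- i }
    if (lookformax) {
      if (v <= mx - delta) {
        maxima <- c(maxima, mxpos)
        mn <- v; mnpos <- i
        lookformax <- FALSE
      }
    } else {
      if (v >= mn + delta) {
        minima <- c(minima, mnpos)
        mx <- v; mxpos <- i
        lookformax <- TRUE
      }
    }
  }
  list(maxima = maxima, minima = minima)
}

# Half-open bin breaks (0-based) for peak offsets `peaks0` on [0, P):
# boundaries at ceiling of midpoints between consecutive peaks, so an
# integer position equidistant from two peaks falls in the left bin when the
# midpoint is fractional, and exactly on the boundary (right bin) when the
# midpoint is integer.
.bin_breaks <- function(peaks0, P) {
  if (!length(peaks0)) return(numeric(0))
  if (length(peaks0) == 1L) return(c(0, P))
  mids <- ceiling((utils::head(peaks0, -1) + utils::tail(peaks0, -1)) / 2)
  c(0, mids, P)
}

#' Detect per-trinucleotide histogram peaks and derive OTN bins
#'
#' For each trinucleotide row the relative frequency series
#' `counts[t, ] / coverage` (0 where coverage is 0) is scanned with
#' [peakdet]; the prominence threshold is `delta` times the row maximum
#' (`delta_mode = "relative"`, the default) or `delta` itself
#' (`delta_mode = "absolute"`). Peaks with relative frequency below
#' `min_peak_freq` are dropped. Each trinucleotide's bins are half-open
#' windows `[start, end)` partitioning `[0, P)` with boundaries at midpoints
#' between consecutive peaks (`boundary = "midpoint"`) or at the deepest
#' detected valley between them (`boundary = "valley"`, midpoint fallback).
#'
#' @param hist an `otn_histogram` from [build_histogram].
#' @param delta prominence threshold (fraction of the row maximum by
#'   default); default 0.1.
#' @param min_peak_freq minimum relative frequency for an accepted peak;
#'   default 0.01.
#' @param delta_mode `"relative"` or `"absolute"`.
#' @param boundary `"midpoint"` or `"valley"`.
#' @return An object of class `otn_peaks`: list with `peaks` (per
#'   trinucleotide, 0-based peak offsets), `breaks` (per trinucleotide,
#'   numeric break vector of its bins), `n_peaks` (total peak count), and
#'   the configuration used.
#' @export
detect_peaks <- function(hist, delta = 0.1, min_peak_freq = 0.01,
                         delta_mode = c("relative", "absolute"),
                         boundary = c("midpoint", "valley")) {
  delta_mode <- match.arg(delta_mode)
  boundary <- match.arg(boundary)
  if (delta <= 0) stop("`delta` must be positive", call. = FALSE)
  P <- ncol(hist$counts)
  denom <- ifelse(hist$coverage > 0, hist$coverage, 1L)
  peaks <- vector("list", 64L); names(peaks) <- TRINUCLEOTIDES
  breaks <- vector("list", 64L); names(breaks) <- TRINUCLEOTIDES
  for (t in seq_len(64L)) {
    rel <- hist$counts[t, ] / denom
    rmax <- max(rel)
    if (rmax <= 0) { peaks[[t]] <- integer(0); breaks[[t]] <- numeric(0); next }
    d <- if (delta_mode == "relative") delta * rmax else delta
    pd <- peakdet(rel, d)
    pk <- pd$maxima
    pk <- pk[rel[pk] >= min_peak_freq]
    pk0 <- pk - 1L                           # 0-based offsets
    if (boundary == "valley" && length(pk0) > 1L) {
      br <- numeric(length(pk0) + 1L)
      br[1] <- 0; br[length(br)] <- P
      for (j in seq_len(length(pk0) - 1L)) {
        between <- pd$minima[pd$minima > pk[j] & pd$minima < pk[j + 1L]]
        br[j + 1L] <- if (length(between)) {
          between[which.min(rel[between])] - 1L
        } else ceiling((pk0[j] + pk0[j + 1L]) / 2)
      }
      breaks[[t]] <- br
    } else {
      breaks[[t]] <- .bin_breaks(pk0, P)
    }
    peaks[[t]] <- pk0
  }
  structure(list(peaks = peaks, breaks = breaks,
                 n_peaks = sum(lengths(peaks)), P = P,
                 delta = delta, min_peak_freq = min_peak_freq,
                 delta_mode = delta_mode, boundary = boundary),
            class = "otn_peaks")
}

#' Construct a peak table directly
#'
#' Builds an `otn_peaks` object from explicitly given peak offsets, mainly
#' for tests and micro-fixtures where the binning is known a priori.
#'
#' @param peaks named list mapping trinucleotides to 0-based peak offsets.
#' @param P number of positions (offsets run over `[0, P)`).
#' @return An `otn_peaks` object with midpoint bins.
#' @export
peak_table <- function(peaks, P) {
  full <- stats::setNames(vector("list", 64L), TRINUCLEOTIDES)
  for (t in TRINUCLEOTIDES) full[[t]] <- integer(0)
  bad <- setdiff(names(peaks), TRINUCLEOTIDES)
  if (length(bad)) stop("unknown trinucleotides: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  for (t in names(peaks)) full[[t]] <- sort(as.integer(peaks[[t]]))
  breaks <- lapply(full, .bin_breaks, P = P)
  structure(list(peaks = full, breaks = breaks,
                 n_peaks = sum(lengths(full)), P = P,
                 delta = NA_real_, min_peak_freq = NA_real_,
                 delta_mode = "manual", boundary = "midpoint"),
            class = "otn_peaks")
}

#' @export
print.otn_peaks <- function(x, ...) {
  occupied <- sum(lengths(x$peaks) > 0)
  cat(sprintf("<otn_peaks> %d peaks over %d/64 trinucleotides, %d positions\n",
              x$n_peaks, occupied, x$P))
  cat(sprintf("  delta=%s (%s), min_peak_freq=%s, %s bins\n",
              format(x$delta), x$delta_mode, format(x$min_peak_freq),
              x$boundary))
  invisible(x)
}

#' @export
as.data.frame.otn_peaks <- function(x, ...) {
  rows <- lapply(TRINUCLEOTIDES, function(t) {
    pk <- x$peaks[[t]]
    if (!length(pk)) return(NULL)
    br <- x$breaks[[t]]
    data.frame(trinucleotide = t, bin = seq_along(pk), peak = pk,
               start = utils::head(br, -1), end = utils::tail(br, -1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows) %||% data.frame(trinucleotide = character(0),
                                       bin = integer(0), peak = integer(0),
                                       start = numeric(0), end = numeric(0))
}
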