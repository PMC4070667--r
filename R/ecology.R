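#' Shannon-Wiener diversity (natural log)
#'
#' `H = -sum(p_i log p_i)` over the non-zero relative abundances
#' `p_i = c_i / sum(c)`, in nats.
#'
#' @param counts non-negative abundance vector with positive sum.
#' @return `H` in nats; `0 <= H <= log(richness)`.
#' @examples
#' shannon(c(1, 1, 1, 1))  # log(4)
#' @export
shannon <- function(counts) {
  p <- .check_counts(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Inverse Simpson diversity
#'
#' `D = 1 / sum(p_i^2)`, the effective number of equally abundant OTUs;
#' `D >= 1` for any non-empty sample. (The inverse form is used because the
#' 0-1 complement form cannot reach the magnitudes typical of diverse
#' amplicon libraries.)
#'
#' @inheritParams shannon
#' @return `D >= 1`.
#' @examples
#' inverse_simpson(c(1, 1, 1, 1))  # 4
#' @export
inverse_simpson <- function(counts) {
  p <- .check_counts(counts)
  1 / sum(p^2)
}

.check_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative", call. = FALSE)
  s <- sum(counts)
  if (s <= 0) stop("counts sum to zero", call. = FALSE)
  counts / s
}

#' Exact Mann-Whitney U test by full enumeration
#'
#' Computes the rank-sum U statistic of `x` (group A) against `y` (group B)
#' with midranks for ties, and an exact permutation p-value over all
#' `choose(nA+nB, nA)` relabelings. For complete one-sided separation of
#' triplicates this gives `p = 1/C(6,3) = 0.05` exactly. Enumeration is used
#' up to `choose(n, nA) <= max_enum` labelings; beyond that a normal
#' approximation with tie correction is substituted (with a message).
#'
#' @param x,y numeric vectors (group A and group B), each non-empty.
#' @param alternative `"greater"` (A tends larger than B), `"less"`, or
#'   `"two.sided"`.
#' @param max_enum largest number of labelings enumerated exactly.
#' @return An object of class `htest` with the U statistic for group A and
#'   the exact p-value.
#' @examples
#' mann_whitney_exact(c(4, 5, 6), c(1, 2, 3), alternative = "greater")
#' @export
mann_whitney_exact <- function(x, y,
                               alternative = c("two.sided", "greater",
                                               "less"),
                               max_enum = 5e5) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("empty group", call. = FALSE)
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)                          # midranks
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  n <- nx + ny
  exact <- choose(n, nx) <= max_enum
  if (exact) {
    combs <- utils::combn(n, nx)
    u_perm <- colSums(matrix(r[combs], nrow = nx)) - nx * (nx + 1) / 2
    p <- switch(alternative,
                greater = mean(u_perm >= u_obs),
                less = mean(u_perm <= u_obs),
                two.sided = mean(abs(u_perm - mu) >= abs(u_obs - mu)))
    method <- "Exact Mann-Whitney U test (full enumeration)"
  } else {
    message("enumeration too large; using normal approximation")
    ties <- table(r)
    sigma2 <- nx * ny / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u_obs - mu) / sqrt(sigma2)
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two.sided = 2 * stats::pnorm(-abs(z)))
    method <- "Mann-Whitney U test (normal approximation, tie-corrected)"
  }
  structure(list(statistic = c(U = u_obs), p.value = min(p, 1),
                 alternative = alternative, method = method,
                 data.name = paste(deparse(substitute(x)), "and",
                                   deparse(substitute(y)))),
            class = "htest")
}

#' Chord distance between abundance vectors
#'
#' Euclidean distance between the vectors after scaling each to unit norm;
#' scale-invariant, ranging from 0 (proportional vectors) to `sqrt(2)`
#' (disjoint supports).
#'
#' @param x a non-zero abundance vector, or a samples-x-OTUs matrix when
#'   `y` is `NULL`.
#' @param y a non-zero abundance vector of the same length, or `NULL`.
#' @return A single distance, or a `dist` object over the rows of `x`.
#' @examples
#' chord_distance(c(1, 0), c(1, 1))  # sqrt(2 - sqrt(2))
#' @export
chord_distance <- function(x, y = NULL) {
  if (is.null(y)) {
    m <- as.matrix(x)
    nrm <- sqrt(rowSums(m^2))
    if (any(nrm == 0)) stop("zero abundance vector", call. = FALSE)
    return(stats::dist(m / nrm))
  }
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("zero abundance vector", call. = FALSE)
  sqrt(sum((x / nx - y / ny)^2))
}

#' PCA ordination of an OTN pattern or abundance table
#'
#' Column-mean centering followed by singular value decomposition; the
#' number of retained components is the smallest `k` whose cumulative
#' explained variance reaches `var_target` (default 50%). Component signs
#' are fixed by the convention that the largest-magnitude loading of each
#' component is positive.
#'
#' @param table numeric matrix, objects in rows (e.g. samples x OTUs counts
#'   or patterns x OTNs bits).
#' @param var_target cumulative explained-variance fraction to cover.
#' @return An object of class `otn_pca`: list with `scores` (objects x all
#'   components), `loadings`, `explained` (variance fractions), and
#'   `retained` (number of components kept).
#' @export
pca_ordination <- function(table, var_target = 0.5) {
  m <- as.matrix(table)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least 2 objects and 2 variables", call. = FALSE)
  if (all(apply(m, 2, stats::var) == 0))
    stop("constant matrix has no variance", call. = FALSE)
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  for (j in seq_len(ncol(pc$rotation))) {
    if (pc$rotation[which.max(abs(pc$rotation[, j])), j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  retained <- which(cumsum(explained) >= var_target)[1]
  structure(list(scores = pc$x, loadings = pc$rotation,
                 center = pc$center,
                 explained = explained, retained = retained,
                 var_target = var_target),
            class = "otn_pca")
}

#' @export
print.otn_pca <- function(x, ...) {
  cat(sprintf("<otn_pca> %d objects, %d components; %d retained (%.1f%% of variance at target %.0f%%)\n",
              nrow(x$scores), length(x$explained), x$retained,
              100 * sum(x$explained[seq_len(x$retained)]),
              100 * x$var_target))
  invisible(x)
}

#' @export
plot.otn_pca <- function(x, ...) {
  graphics::plot(x$scores[, 1], x$scores[, 2],
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained[2]), ...)
  invisible(x)
}

#' Alpha-diversity report for an OTN pattern table
#'
#' Per-sample Shannon-Wiener `H` (nats) and inverse Simpson `D` over the
#' pattern counts, with an optional exact Mann-Whitney comparison between
#' two groups of samples.
#'
#' @param patterns an `otn_patterns` object (or a patterns x samples count
#'   matrix).
#' @param groups optional named character/factor assigning each sample to a
#'   group; with exactly two groups the H and D columns are compared.
#' @param alternative passed to [mann_whitney_exact]; interpreted as the
#'   first group level versus the second.
#' @return A data frame (sample, group, H, D) with attribute `tests` (list
#'   of `htest`) when a comparison was made.
#' @export
diversity_report <- function(patterns, groups = NULL,
                             alternative = "two.sided") {
  counts <- if (inherits(patterns, "otn_patterns")) patterns$counts
  else as.matrix(patterns)
  samples <- colnames(counts) %||% paste0("sample", seq_len(ncol(counts)))
  H <- apply(counts, 2, shannon)
  D <- apply(counts, 2, inverse_simpson)
  grp <- if (is.null(groups)) rep(NA_character_, length(samples))
  else if (!is.null(names(groups))) as.character(groups[samples])
  else as.character(rep_len(groups, length(samples)))
  out <- data.frame(sample = samples, group = grp, H = H, D = D,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    lv <- unique(stats::na.omit(out$group))
    if (length(lv) == 2L) {
      tests <- list(
        H = mann_whitney_exact(out$H[out$group == lv[1]],
                               out$H[out$group == lv[2]],
                               alternative = alternative),
        D = mann_whitney_exact(out$D[out$group == lv[1]],
                               out$D[out$group == lv[2]],
                               alternative = alternative))
      attr(out, "tests") <- tests
      attr(out, "group_order") <- lv
    }
  }
  out
}
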