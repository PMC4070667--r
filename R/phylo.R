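#' Parameters of the exponential-decay generation distance
#'
#' The model assumes each OTN character mutates independently at a constant
#' probability per generation, so the expected fraction of shared OTNs
#' between two lineages decays as `(1 - rate)^gen`. Inverting gives the
#' number of generations separating two profiles from their shared-OTN
#' fraction.
#'
#' The default rate is `0.5e-9` per position per generation, a neutral-rate
#' estimate for the 16S rRNA gene. Because a trinucleotide spans three
#' positions, `rate_mode = "per_position_x3"` triples the rate
#' (`1.5e-9` per trinucleotide per generation) for users who read the rate
#' as strictly per nucleotide position; the default `"per_trinucleotide"`
#' uses the printed value unchanged.
#'
#' @param rate mutation probability per generation (default `0.5e-9`).
#' @param rate_mode `"per_trinucleotide"` or `"per_position_x3"`.
#' @param shared_convention `"symmetric"` (shared counted once per profile:
#'   `shared = 2 |A ∩ B|`, `total = |A| + |B|`, so identical profiles are at
#'   0 generations) or `"literal"` (`shared = |A ∩ B|`), kept for
#'   comparability.
#' @return A list of class `gen_params`.
#' @export
gen_params <- function(rate = 0.5e-9,
                       rate_mode = c("per_trinucleotide", "per_position_x3"),
                       shared_convention = c("symmetric", "literal")) {
  rate_mode <- match.arg(rate_mode)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0 || rate >= 1)
    stop("`rate` must lie strictly between 0 and 1", call. = FALSE)
  eff <- if (rate_mode == "per_position_x3") 3 * rate else rate
  structure(list(rate = rate, rate_mode = rate_mode, effective_rate = eff,
                 shared_convention = match.arg(shared_convention)),
            class = "gen_params")
}

#' Generations separating two binary OTN profiles
#'
#' Under exponential decay of shared OTNs,
#' `gen = (ln(shared) - ln(total)) / ln(1 - rate)`, with
#' `shared = 2 |A ∩ B|` and `total = |A| + |B|` (symmetric convention), so
#' `gen(a, a) = 0` and `gen` grows as the shared fraction shrinks.
#' `log1p(-rate)` is used for numerical accuracy at biologically small
#' rates.
#'
#' @param a,b binary (0/1 or logical) vectors over the same OTN column set.
#' @param params a [gen_params] object.
#' @return Non-negative number of generations; `NA` (undefined/infinite)
#'   when the profiles share no OTN.
#' @examples
#' a <- c(rep(1, 100), rep(0, 10))
#' b <- c(rep(1, 90), rep(0, 10), rep(1, 10))
#' pairwise_generations(a, b)  # ~ 2.107e8
#' @export
pairwise_generations <- function(a, b, params = gen_params()) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b))
    stop("profiles must be over the same OTN column set", call. = FALSE)
  na <- sum(a); nb <- sum(b)
  if (na == 0L || nb == 0L) stop("empty OTN profile", call. = FALSE)
  i <- sum(a & b)
  if (i == 0L) return(NA_real_)
  shared <- if (params$shared_convention == "symmetric") 2 * i else i
  total <- na + nb
  (log(shared) - log(total)) / log1p(-params$effective_rate)
}

#' Pairwise generation distance matrix
#'
#' Applies [pairwise_generations] to every pair of rows of a binary matrix
#' (reads or collapsed patterns). Pairs sharing no OTN are undefined; by
#' default their presence is an error listing the pairs, or they can be
#' capped at 1.1 times the largest finite distance for exploratory trees.
#'
#' @param x an `otn_matrix`, `otn_patterns`, `otn_fit`, or a binary matrix
#'   with row names.
#' @param params a [gen_params] object.
#' @param on_undefined `"error"` or `"cap"`.
#' @return A symmetric matrix of class `gen_dist` with zero diagonal, the
#'   taxa as dimnames and attributes `rate`, `max_finite` and
#'   `undefined_pairs`.
#' @export
generation_dist <- function(x, params = gen_params(),
                            on_undefined = c("error", "cap")) {
  on_undefined <- match.arg(on_undefined)
  m <- profile_matrix(x)
  if (nrow(m) < 2L) stop("need at least 2 profiles", call. = FALSE)
  sizes <- rowSums(m)
  if (any(sizes == 0L))
    stop("empty OTN profile(s): ",
         paste(rownames(m)[sizes == 0], collapse = ", "), call. = FALSE)
  inter <- tcrossprod(m)
  tot <- outer(sizes, sizes, "+")
  shared <- if (params$shared_convention == "symmetric") 2 * inter else inter
  d <- (log(shared) - log(tot)) / log1p(-params$effective_rate)
  d[inter == 0L] <- NA_real_
  diag(d) <- 0
  undef <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
  pairs <- if (nrow(undef))
    paste(rownames(m)[undef[, 1]], rownames(m)[undef[, 2]], sep = " / ")
  else character(0)
  if (length(pairs)) {
    if (on_undefined == "error")
      stop("pairs share no OTN (undefined distance): ",
           paste(pairs, collapse = "; "), call. = FALSE)
    cap <- 1.1 * max(d[is.finite(d)])
    d[is.na(d)] <- cap
    diag(d) <- 0
  }
  structure(d, class = c("gen_dist", "matrix"),
            rate = params$effective_rate,
            max_finite = max(d[is.finite(d)]),
            undefined_pairs = pairs)
}

# Extract the binary profile matrix from any of the accepted inputs.
profile_matrix <- function(x) {
  m <- if (inherits(x, "otn_fit")) x$patterns$patterns
  else if (inherits(x, "otn_patterns")) x$patterns
  else if (inherits(x, "otn_matrix")) x$matrix
  else x
  m <- as.matrix(m)
  if (!all(m %in% c(0, 1))) stop("profiles must be binary", call. = FALSE)
  storage.mode(m) <- "integer"
  if (is.null(rownames(m))) rownames(m) <- paste0("t", seq_len(nrow(m)))
  m
}

#' @export
print.gen_dist <- function(x, ...) {
  cat(sprintf("<gen_dist> %d taxa; max distance %.4g generations (rate %.3g)\n",
              nrow(x), attr(x, "max_finite"), attr(x, "rate")))
  if (length(attr(x, "undefined_pairs")))
    cat("  capped undefined pairs:",
        length(attr(x, "undefined_pairs")), "\n")
  invisible(x)
}

#' Neighbor-joining tree from a generation distance matrix
#'
#' Standard agglomerative neighbor joining; negative branch lengths (an
#' artifact of non-additive noise) are clamped to zero, with a message
#' reporting how many edges were clamped.
#'
#' @param d a `gen_dist` matrix (or any symmetric matrix / `dist`).
#' @return An [ape::nj] `phylo` tree with branch lengths in generations.
#' @export
nj_tree <- function(d) {
  m <- unclass(as.matrix(d))
  if (!isSymmetric(m, check.attributes = FALSE))
    stop("distance matrix is not symmetric", call. = FALSE)
  if (any(!is.finite(m)))
    stop("distance matrix has non-finite entries", call. = FALSE)
  if (nrow(m) < 3L) stop("need at least 3 taxa", call. = FALSE)
  tr <- ape::nj(stats::as.dist(m))
  nneg <- sum(tr$edge.length < 0)
  if (nneg > 0) {
    message(nneg, " negative branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Column-bootstrap support for the OTN neighbor-joining tree
#'
#' Resamples OTN columns with replacement (the characters of the binary
#' matrix), recomputes the generation distances and NJ tree per replicate,
#' and reports, for each internal edge of the full-data tree, the percentage
#' of replicates whose tree contains the same bipartition. Replicates in
#' which some pair shares no OTN are dropped; more than `max_drop_frac`
#' dropped replicates is an error.
#'
#' @param x an `otn_matrix`, `otn_patterns`, `otn_fit` or binary matrix
#'   (rows taxa, columns OTNs).
#' @param replicates number of bootstrap replicates (default 100).
#' @param params a [gen_params].
#' @param seed RNG seed (default 1).
#' @param max_drop_frac maximum tolerated fraction of dropped replicates.
#' @return The full-data `phylo` tree with bootstrap percentages in
#'   `node.label` (root label empty) and attributes `n_kept`, `n_dropped`.
#' @export
bootstrap_support <- function(x, replicates = 100L, params = gen_params(),
                              seed = 1L, max_drop_frac = 0.2) {
  m <- profile_matrix(x)
  if (nrow(m) < 4L) stop("need at least 4 taxa", call. = FALSE)
  full <- nj_tree(generation_dist(m, params))
  reps <- with_seed(seed, {
    lapply(seq_len(replicates), function(r) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      mm <- m[, cols, drop = FALSE]
      if (any(rowSums(mm) == 0L)) return(NULL)
      d <- tryCatch(generation_dist(mm, params), error = function(e) NULL)
      if (is.null(d)) return(NULL)
      suppressMessages(nj_tree(d))
    })
  })
  kept <- reps[!vapply(reps, is.null, logical(1))]
  n_drop <- replicates - length(kept)
  if (n_drop > max_drop_frac * replicates)
    stop(sprintf("%d/%d bootstrap replicates dropped (undefined pairs)",
                 n_drop, replicates), call. = FALSE)
  counts <- ape::prop.clades(full, kept, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / length(kept))
  full$node.label <- as.character(support)
  full$node.label[1] <- ""                   # root of the unrooted tree
  attr(full, "n_kept") <- length(kept)
  attr(full, "n_dropped") <- n_drop
  full
}
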