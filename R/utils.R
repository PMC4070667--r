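## Internal helpers shared across modules.

# The 64 trinucleotides in lexicographic order (A < C < G < T); OTN row order.
TRINUCLEOTIDES <- {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(third = b, second = b, first = b,
                   stringsAsFactors = FALSE)
  paste0(g$first, g$second, g$third)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package operations do not
#' disturb the caller's random number stream.
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Reverse complement of DNA strings
#'
#' Vectorized over a character vector; `N` maps to `N`.
#'
#' @param x character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, NULL), function(s) paste(rev(s), collapse = ""), "")
}

# Map a DNA string to the integer codes A=0, C=1, G=2, T=3 (NA for anything
# else, in particular N).  Returns an integer vector of length nchar(s).
.base_codes <- local({
  tab <- rep(NA_integer_, 256)
  tab[utf8ToInt("A") + 1L] <- 0L
  tab[utf8ToInt("C") + 1L] <- 1L
  tab[utf8ToInt("G") + 1L] <- 2L
  tab[utf8ToInt("T") + 1L] <- 3L
  tab
})

dna_codes <- function(s) .base_codes[utf8ToInt(s) + 1L]

# Trinucleotide indices (1..64, lexicographic) at every 0-based start offset
# of a sequence; NA where the window contains a non-ACGT base.  Length
# nchar(s) - 2 (empty for sequences shorter than 3).
tri_indices <- function(s) {
  v <- dna_codes(s)
  n <- length(v)
  if (n < 3L) return(integer(0))
  16L * v[1:(n - 2L)] + 4L * v[2:(n - 1L)] + v[3:n] + 1L
}

# Count of ambiguous (non-ACGT) bases per sequence.
count_ambiguous <- function(seqs) {
  vapply(seqs, function(s) sum(is.na(dna_codes(s))), integer(1),
         USE.NAMES = FALSE)
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
}
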