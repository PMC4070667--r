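# Independent brute-force oracles and fixture builders used across tests.

# Exhaustive maximum-score contiguous segment: returns c(start, end)
# (1-based inclusive) of the best-scoring segment, or c(0, -1) if every
# segment scores <= 0.  O(n^2) over all segments; ties resolved to the
# segment found first scanning starts then ends (leftmost, then shortest).
segment_oracle <- function(score) {
  n <- length(score)
  best <- 0; bs <- 0L; be <- -1L
  for (i in seq_len(n)) {
    s <- 0
    for (j in i:n) {
      s <- s + score[j]
      if (s > best) { best <- s; bs <- i; be <- j }
    }
  }
  c(bs, be)
}

# Alternating extremum detection by explicit range rescans (O(n^2)); same
# semantics as the package scan but mechanically different: each candidate
# emission re-derives the running extremum with max()/min() over the whole
# segment since the previous emission.
peakdet_oracle <- function(v, delta) {
  maxima <- integer(0); minima <- integer(0)
  n <- length(v); s <- 1L; lookmax <- TRUE
  repeat {
    found <- FALSE
    for (j in s:n) {
      w <- v[s:j]
      if (lookmax && max(w) - v[j] >= delta) {
        maxima <- c(maxima, s + which.max(w) - 1L)
        s <- j; lookmax <- FALSE; found <- TRUE; break
      }
      if (!lookmax && v[j] - min(w) >= delta) {
        minima <- c(minima, s + which.min(w) - 1L)
        s <- j; lookmax <- TRUE; found <- TRUE; break
      }
    }
    if (!found) break
  }
  list(maxima = maxima, minima = minima)
}

# Sort-and-group pattern oracle: multiset of (pattern, per-sample counts).
pattern_oracle <- function(m, samples) {
  key <- apply(m, 1, paste, collapse = "")
  tab <- table(key, samples)
  tab[order(rownames(tab)), , drop = FALSE]
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), "")
}

# Naive per-read, per-offset trinucleotide recount (the histogram oracle).
naive_histogram <- function(seqs) {
  lmax <- max(nchar(seqs))
  P <- lmax - 2L
  counts <- matrix(0L, 64L, P, dimnames = list(otnsa:::TRINUCLEOTIDES, NULL))
  coverage <- integer(P)
  for (s in seqs) {
    for (p in seq_len(max(0L, nchar(s) - 2L))) {
      w <- substr(s, p, p + 2)
      if (grepl("N", w, fixed = TRUE)) next
      counts[w, p] <- counts[w, p] + 1L
      coverage[p] <- coverage[p] + 1L
    }
  }
  list(counts = counts, coverage = coverage)
}

# Two-clade binary profile fixture: two groups of identical profiles with
# 50% sharing between groups.
two_clade_profiles <- function(per_clade = 3L, n_shared = 50L,
                               n_private = 50L) {
  a <- c(rep(1L, n_shared + n_private), rep(0L, n_private))
  b <- c(rep(1L, n_shared), rep(0L, n_private), rep(1L, n_private))
  m <- rbind(matrix(rep(a, per_clade), nrow = per_clade, byrow = TRUE),
             matrix(rep(b, per_clade), nrow = per_clade, byrow = TRUE))
  rownames(m) <- c(paste0("A", seq_len(per_clade)),
                   paste0("B", seq_len(per_clade)))
  m
}

# A 6-taxon two-clade tree with edge lengths in generations.
two_clade_tree <- function(within = 2e8, central = 4e8) {
  txt <- sprintf("((A:%g,B:%g,C:%g):%g,(D:%g,E:%g,F:%g):%g);",
                 within, within, within, central,
                 within, within, within, central)
  ape::read.tree(text = txt)
}

# Fully bifurcating variant for topology-recovery checks (NJ always returns
# a binary tree, so the reference must be binary too).
binary_two_clade_tree <- function() {
  ape::read.tree(text = paste0(
    "(((A:1e8,B:1e8):1e8,C:2e8):4e8,",
    "((D:1e8,E:1e8):1e8,F:2e8):4e8);"))
}

# Published alpha-diversity index values for the six soil libraries
# (triplicates with and without earthworms).
soil_alpha_table <- function() {
  utils::read.delim(system.file("extdata", "soil_alpha_diversity.tsv",
                                package = "otnsa"))
}
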