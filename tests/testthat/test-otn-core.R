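test_that("positional histogram counts trinucleotides at 0-based offsets", {
  h <- build_histogram(amplicon_reads("r", "AAAA"))
  expect_equal(dim(h$counts), c(64L, 2L))
  expect_equal(h$counts["AAA", ], c(1L, 1L))
  expect_equal(sum(h$counts), 2L)
  expect_equal(h$coverage, c(1L, 1L))

  h2 <- build_histogram(amplicon_reads(c("a", "b"), c("ACGT", "ACGT")))
  expect_equal(unname(h2$counts["ACG", 1]), 2L)
  expect_equal(unname(h2$counts["CGT", 2]), 2L)
  expect_equal(sum(h2$counts), 4L)
  expect_equal(h2$coverage, c(2L, 2L))

  expect_error(build_histogram(amplicon_reads(character(0), character(0))),
               "empty")
})

test_that("histogram matches a naive double-loop recount and conserves coverage", {
  set.seed(31)
  lens <- sample(10:60, 100, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    s <- sample(c("A", "C", "G", "T", "N"), L, replace = TRUE,
                prob = c(.24, .24, .24, .24, .04))
    paste(s, collapse = "")
  }, "")
  rs <- amplicon_reads(paste0("r", 1:100), seqs)
  h <- build_histogram(rs)
  oracle <- naive_histogram(seqs)
  expect_equal(unname(h$counts), unname(oracle$counts))
  expect_equal(h$coverage, oracle$coverage)
  expect_equal(colSums(h$counts), as.numeric(h$coverage))
})

test_that("peakdet finds delta-prominent alternating extrema", {
  expect_equal(peakdet(c(0, 3, 1, 4, 0), 2)$maxima, c(2L, 4L))
  expect_equal(peakdet(rep(2, 10), 0.5)$maxima, integer(0))
  expect_equal(peakdet(c(0, 5, 0), 1)$maxima, 2L)
  expect_error(peakdet(c(0, 1), 0), "positive")
  expect_error(peakdet(c(0, NA), 1), "finite")
})

test_that("peakdet agrees with the brute-force rescan oracle", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(5:80, 1)
    v <- stats::runif(n)
    delta <- stats::runif(1, 0.05, 0.8)
    got <- peakdet(v, delta)
    want <- peakdet_oracle(v, delta)
    expect_identical(got$maxima, want$maxima)
    expect_identical(got$minima, want$minima)
  }
})

test_that("bin boundaries fall at midpoints between peaks", {
  # single clean peak -> one bin spanning the full coordinate range
  counts <- matrix(0L, 64, 40, dimnames = list(otnsa:::TRINUCLEOTIDES, NULL))
  counts["ACG", 21] <- 10L
  h <- structure(list(counts = counts, coverage = rep(10L, 40),
                      n_reads = 10L), class = "otn_histogram")
  pk <- detect_peaks(h, min_peak_freq = 0)
  expect_equal(pk$peaks[["ACG"]], 20L)          # 0-based offset
  expect_equal(pk$breaks[["ACG"]], c(0, 40))

  # peaks at offsets 10 and 20 -> bins [0,15) and [15,P)
  counts2 <- counts; counts2["ACG", ] <- 0L
  counts2["ACG", c(11, 21)] <- 10L
  h2 <- structure(list(counts = counts2, coverage = rep(10L, 40),
                       n_reads = 10L), class = "otn_histogram")
  pk2 <- detect_peaks(h2, min_peak_freq = 0)
  expect_equal(pk2$peaks[["ACG"]], c(10L, 20L))
  expect_equal(pk2$breaks[["ACG"]], c(0, 15, 40))

  # unobserved trinucleotide -> zero peaks, not an error
  expect_equal(pk2$peaks[["TTT"]], integer(0))
})

test_that("planted conserved positions are recovered exactly against noise", {
  set.seed(7)
  P <- 100L
  planted <- c(10L, 45L, 80L)                  # 0-based offsets
  coverage <- rep(1000L, P)
  counts <- matrix(0L, 64, P, dimnames = list(otnsa:::TRINUCLEOTIDES, NULL))
  # uniform noise well below delta * row max, signal at the planted offsets
  counts["GCA", ] <- sample(0:30, P, replace = TRUE)
  counts["GCA", planted + 1L] <- 800L
  h <- structure(list(counts = counts, coverage = coverage, n_reads = 1000L),
                 class = "otn_histogram")
  pk <- detect_peaks(h, delta = 0.1, min_peak_freq = 0.05)
  expect_equal(pk$peaks[["GCA"]], planted)
  expect_equal(pk$n_peaks, 3L)
})

test_that("homopolymer multiplicity discharges the OTN globally", {
  # "AAAA" has AAA at offsets 0 and 1, in one bin spanning everything
  pk <- peak_table(list(AAA = 1L), P = 2L)
  rs <- amplicon_reads(c("hp", "other"), c("AAAA", "AAGG"))
  m <- assign_otns(rs, pk)
  expect_equal(m$discharged, "AAA@bin1")
  expect_equal(ncol(m$matrix), 0L)

  # corrected hand enumeration: single occurrences never discharge
  pk2 <- peak_table(list(ACG = 1L, TTT = 1L, CGT = 1L, GTT = 1L,
                         TTA = 1L, TAC = 1L), P = 4L)
  rs2 <- amplicon_reads(c("a", "b"), c("ACGTTT", "TTTACG"))
  m2 <- assign_otns(rs2, pk2)
  expect_equal(m2$discharged, character(0))
  expect_equal(m2$matrix["a", "ACG@bin1"], 1L)
  expect_equal(m2$matrix["b", "TTT@bin1"], 1L)
  expect_equal(m2$matrix["a", "TTA@bin1"], 0L)  # absent occurrence -> 0

  # a read with a doubled trinucleotide discharges it for everyone
  rs3 <- amplicon_reads(c("a", "b", "hp"), c("ACGTTT", "TTTACG", "TTTT"))
  pk3 <- peak_table(list(ACG = 1L, TTT = 1L, CGT = 1L, GTT = 1L,
                         TTA = 1L, TAC = 1L), P = 4L)
  m3 <- assign_otns(rs3, pk3)
  expect_equal(m3$discharged, "TTT@bin1")
  expect_false("TTT@bin1" %in% colnames(m3$matrix))
})

test_that("occurrences outside every bin are ignored, not errors", {
  pk <- peak_table(list(ACG = 0L), P = 2L)     # only ACG has a bin
  rs <- amplicon_reads("r", "ACGT")            # CGT has no bin
  m <- assign_otns(rs, pk)
  expect_equal(colnames(m$matrix), "ACG@bin1")
  expect_equal(m$n_ignored, 1L)
})

test_that("adding reads can only grow the discharged set", {
  set.seed(13)
  pool <- amplicon_reads(paste0("r", 1:30), random_dna(30, 40))
  pk <- detect_peaks(build_histogram(pool), min_peak_freq = 0)
  prev <- character(0)
  for (n in c(5, 10, 20, 30)) {
    d <- assign_otns(pool[seq_len(n)], pk)$discharged
    expect_true(all(prev %in% d))
    prev <- d
  }
})

test_that("identical reads produce identical OTN patterns", {
  set.seed(17)
  template <- random_dna(3, 50)
  rs <- amplicon_reads(paste0("r", 1:12), rep(template, each = 4),
                       sample = rep(c("S1", "S2"), 6))
  fit <- otn_semialign(rs, min_peak_freq = 0, drop_singletons = FALSE)
  expect_equal(nrow(fit$patterns$counts), 3L)
  expect_equal(unname(rowSums(fit$patterns$counts)), rep(4, 3))
})

test_that("small indels far from bin boundaries preserve shared OTNs", {
  set.seed(19)
  template <- random_dna(1, 60)
  # one wide bin per trinucleotide keeps every occurrence binnable
  pool <- amplicon_reads("t", template)
  h <- build_histogram(amplicon_reads(paste0("c", 1:5), rep(template, 5)))
  pk <- peak_table(stats::setNames(as.list(rep(29L, 64)),
                                   otnsa:::TRINUCLEOTIDES), P = 58L)
  # plant a single-base deletion in the middle; bin width 58 >> shift 1
  mutated <- paste0(substr(template, 1, 29), substr(template, 31, 60))
  both <- amplicon_reads(c("orig", "indel"), c(template, mutated))
  m <- assign_otns(both, pk)
  shared <- sum(m$matrix["orig", ] & m$matrix["indel", ])
  total_orig <- sum(m$matrix["orig", ])
  # occurrences whose offsets stay inside the single full-width bin remain
  # shared; only trinucleotides destroyed at the indel site may differ
  expect_gte(shared / total_orig, 0.9)
})

test_that("pattern collapse matches the sort-and-group oracle", {
  rs_m <- matrix(c(1, 0, 1,
                   1, 0, 1,
                   1, 0, 1), nrow = 3, byrow = TRUE)
  x <- list(matrix = rs_m, sample = rep("S", 3))
  pat <- collapse_patterns(x, drop_singletons = FALSE)
  expect_equal(nrow(pat$counts), 1L)
  expect_equal(pat$counts[1, "S"], 3L)

  # counts {3,1,1} with singleton filtering -> 1 pattern retained
  m2 <- rbind(matrix(rep(c(1, 1, 0), 3), 3, byrow = TRUE),
              c(0, 1, 1), c(1, 0, 0))
  x2 <- list(matrix = m2, sample = rep("S", 5))
  pat2 <- collapse_patterns(x2, drop_singletons = TRUE)
  expect_equal(nrow(pat2$counts), 1L)
  expect_equal(pat2$singleton_fraction, 2 / 3)

  set.seed(23)
  base <- matrix(rbinom(40 * 12, 1, 0.4), 40, 12)
  m3 <- base[sample(40, 100, replace = TRUE), ]
  samples <- sample(c("S1", "S2"), 100, replace = TRUE)
  x3 <- list(matrix = m3, sample = samples)
  pat3 <- collapse_patterns(x3, drop_singletons = FALSE)
  oracle <- pattern_oracle(m3, samples)
  got <- pat3$counts[order(apply(pat3$patterns, 1, paste, collapse = "")),
                     colnames(oracle), drop = FALSE]
  expect_equal(unname(got), unname(as.matrix(unclass(oracle))))
  expect_equal(sum(pat3$counts), 100L)
})
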