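test_that("diversity indices match closed forms and invariances", {
  expect_equal(shannon(5), 0)
  expect_equal(shannon(c(1, 1, 1, 1)), log(4), tolerance = 1e-12)
  expect_equal(inverse_simpson(5), 1)
  expect_equal(inverse_simpson(c(1, 1, 1, 1)), 4, tolerance = 1e-12)

  set.seed(61)
  counts <- rpois(30, 10) + 1
  perm <- sample(counts)
  expect_equal(shannon(perm), shannon(counts))
  expect_equal(inverse_simpson(perm), inverse_simpson(counts))
  # zero-count OTUs contribute nothing
  expect_equal(shannon(c(counts, 0, 0)), shannon(counts))
  expect_equal(inverse_simpson(c(counts, 0, 0)), inverse_simpson(counts))
  # bounds: H <= log(richness); D >= 1
  expect_lte(shannon(counts), log(length(counts)))
  expect_gte(inverse_simpson(counts), 1)
  # merging two equal-abundance OTUs strictly decreases D
  eq <- c(4, 4, 2)
  expect_lt(inverse_simpson(c(8, 2)), inverse_simpson(eq))

  expect_error(shannon(c(0, 0)), "zero")
  expect_error(inverse_simpson(numeric(0)), "zero")
})

test_that("diversity indices agree with vegan", {
  skip_if_not_installed("vegan")
  set.seed(67)
  for (i in 1:20) {
    counts <- rpois(50, 5)
    counts[1] <- counts[1] + 1
    expect_equal(shannon(counts),
                 unname(vegan::diversity(counts, "shannon")),
                 tolerance = 1e-12)
    expect_equal(inverse_simpson(counts),
                 unname(vegan::diversity(counts, "invsimpson")),
                 tolerance = 1e-12)
  }
})

test_that("exact Mann-Whitney enumerates the permutation distribution", {
  res <- mann_whitney_exact(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p.value, 0.05)

  # identical multisets, two-sided -> p = 1
  res2 <- mann_whitney_exact(c(2, 5, 7), c(2, 5, 7))
  expect_equal(res2$p.value, 1)

  # tie-free data matches wilcox.test's exact p-values
  set.seed(71)
  for (i in 1:20) {
    a <- stats::rnorm(sample(3:6, 1))
    b <- stats::rnorm(sample(3:6, 1))
    for (alt in c("two.sided", "greater", "less")) {
      mine <- mann_whitney_exact(a, b, alternative = alt)
      ref <- stats::wilcox.test(a, b, alternative = alt, exact = TRUE)
      expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
      expect_equal(unname(mine$statistic), unname(ref$statistic))
    }
  }

  # one-sided p-values sum to 1 + P(U = u) over the two directions
  a <- c(1.2, 3.4, 2.2); b <- c(0.5, 2.8, 4.1, 1.9)
  pg <- mann_whitney_exact(a, b, "greater")$p.value
  pl <- mann_whitney_exact(a, b, "less")$p.value
  expect_gte(pg + pl, 1)

  expect_error(mann_whitney_exact(numeric(0), 1), "empty")
})

test_that("published soil alpha-diversity values give one-sided p = 0.05", {
  tab <- soil_alpha_table()
  worm <- tab$earthworm == "yes"
  for (col in c("otn_shannon", "otn_simpson", "otu_shannon",
                "otu_simpson")) {
    res <- mann_whitney_exact(tab[[col]][!worm], tab[[col]][worm],
                              alternative = "greater")
    expect_equal(res$p.value, 0.05)
  }
})

test_that("chord distance has the closed forms and metric properties", {
  expect_equal(chord_distance(c(1, 2, 3), c(2, 4, 6)), 0)
  expect_equal(chord_distance(c(1, 1, 0, 0), c(0, 0, 2, 5)), sqrt(2),
               tolerance = 1e-12)
  expect_equal(chord_distance(c(1, 0), c(1, 1)), sqrt(2 - sqrt(2)),
               tolerance = 1e-12)
  expect_error(chord_distance(c(0, 0), c(1, 0)), "zero")

  set.seed(73)
  for (i in 1:200) {
    x <- stats::runif(6); y <- stats::runif(6); z <- stats::runif(6)
    dxy <- chord_distance(x, y)
    dyz <- chord_distance(y, z)
    dxz <- chord_distance(x, z)
    expect_lte(dxz, dxy + dyz + 1e-12)
    expect_equal(dxy, chord_distance(y, x))
    expect_lte(dxy, sqrt(2) + 1e-12)
  }
})

test_that("matrix chord distances agree with vegan's chord metric", {
  skip_if_not_installed("vegan")
  set.seed(79)
  m <- matrix(rpois(5 * 12, 4) + 1, nrow = 5)
  rownames(m) <- paste0("s", 1:5)
  mine <- as.matrix(chord_distance(m))
  ref <- as.matrix(vegan::vegdist(m, method = "chord"))
  expect_equal(unname(mine), unname(ref), tolerance = 1e-10)
})

test_that("PCA ordination centers, orders variance, and retains 50%", {
  # rank-1 matrix -> one component carries all variance
  r1 <- outer(c(1, 2, 3, 4), c(2, 1, 3))
  ord <- pca_ordination(r1)
  expect_equal(ord$retained, 1L)
  expect_equal(ord$explained[1], 1, tolerance = 1e-12)

  set.seed(83)
  m <- matrix(stats::rnorm(8 * 5), 8, 5)
  ord2 <- pca_ordination(m)
  expect_equal(sum(ord2$explained), 1, tolerance = 1e-12)
  expect_true(all(diff(ord2$explained) <= 1e-12))
  expect_gte(sum(ord2$explained[seq_len(ord2$retained)]), 0.5)
  # reconstruction identity with all components
  rec <- ord2$scores %*% t(ord2$loadings)
  expect_equal(rec + rep(ord2$center, each = 8), m, tolerance = 1e-10,
               ignore_attr = TRUE)
  # sign convention: the largest-magnitude loading of each component is
  # positive, so repeated runs cannot flip
  for (j in seq_len(ncol(ord2$loadings)))
    expect_gte(ord2$loadings[which.max(abs(ord2$loadings[, j])), j], 0)

  expect_error(pca_ordination(matrix(1, 4, 3)), "variance")
})

test_that("PC1 separates two planted binary clusters completely", {
  set.seed(89)
  n_var <- 60
  proto_a <- rbinom(n_var, 1, 0.5)
  proto_b <- 1 - proto_a                      # maximal separation
  flip <- function(v, k) { i <- sample(n_var, k); v[i] <- 1 - v[i]; v }
  m <- rbind(t(vapply(1:6, function(i) flip(proto_a, 3), numeric(n_var))),
             t(vapply(1:6, function(i) flip(proto_b, 3), numeric(n_var))))
  ord <- pca_ordination(m)
  s1 <- ord$scores[1:6, 1]; s2 <- ord$scores[7:12, 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
})

test_that("diversity report combines indices and group comparison", {
  counts <- matrix(c(10, 10, 0, 5,
                     1, 1, 1, 1,
                     8, 0, 4, 4), nrow = 4,
                   dimnames = list(NULL, c("S1", "S2", "S3")))
  groups <- c(S1 = "worm", S2 = "worm", S3 = "free")
  rep_ <- diversity_report(counts, groups)
  expect_equal(rep_$sample, c("S1", "S2", "S3"))
  expect_equal(rep_$H, apply(counts, 2, shannon), ignore_attr = TRUE)
  expect_equal(rep_$D, apply(counts, 2, inverse_simpson),
               ignore_attr = TRUE)
  tests <- attr(rep_, "tests")
  expect_s3_class(tests$H, "htest")
})
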