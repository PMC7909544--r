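test_that("rarefaction subsamples exactly to depth without replacement", {
  m <- count_table(matrix(c(3, 4, 3, 10, 0, 5), 3, 2,
                          dimnames = list(paste0("f", 1:3), c("s1", "s2"))))
  r <- rarefy(m, depth = 5, seed = 9)
  expect_equal(unname(colSums(r)), c(5, 5))
  expect_true(all(r <= m))

  # depth equal to the total leaves the column unchanged
  r2 <- rarefy(m[, 1, drop = FALSE], depth = 10, seed = 1)
  expect_equal(unclass(r2), unclass(m[, 1, drop = FALSE]))

  expect_error(rarefy(m, depth = 16), class = "depth_error")

  # same seed reproduces; the expected rarefied count is hypergeometric
  expect_equal(unclass(rarefy(m, depth = 5, seed = 4)),
               unclass(rarefy(m, depth = 5, seed = 4)))
  draws <- sapply(1:1000, function(s) rarefy(m, depth = 5, seed = s)[, "s1"])
  expect_equal(rowMeans(draws), 5 * m[, "s1"] / 10, tolerance = 0.05)
})

test_that("observed species is non-decreasing in rarefaction depth", {
  m <- random_counts(50, 4, lambda = 3, seed = 8)
  m <- count_table(m)
  depths <- c(20, 40, 60)
  obs <- sapply(depths, function(d) {
    alpha_diversity_table(rarefy(m, depth = d, seed = 11))$observed_species
  })
  for (i in seq_len(nrow(obs))) {
    expect_true(all(diff(obs[i, ]) >= 0))
  }
})

test_that("alpha diversity reproduces closed forms", {
  u <- alpha_diversity(c(1, 1, 1, 1))
  expect_equal(u$observed_species, 4)
  expect_equal(u$shannon, 2.0)      # log2(4)
  expect_equal(u$simpson, 0.75)     # 1 - 1/4

  s <- alpha_diversity(c(4, 0, 0))
  expect_equal(s$observed_species, 1)
  expect_equal(s$shannon, 0)
  expect_equal(s$simpson, 0)

  h <- alpha_diversity(c(2, 1, 1))
  expect_equal(h$shannon, 1.5)
  expect_equal(h$simpson, 0.625)

  # natural-log base is configurable
  expect_equal(alpha_diversity(c(1, 1, 1), shannon_base = exp(1))$shannon,
               log(3), tolerance = 1e-12)
  # uniform composition maximizes Shannon at log_base(S)
  expect_equal(alpha_diversity(rep(7, 16))$shannon, 4)

  expect_error(alpha_diversity(c(0, 0)), class = "degenerate_sample_error")
})

test_that("Bray-Curtis matches hand values and the double-loop oracle", {
  x <- matrix(c(1, 1, 1, 3), 2, 2, dimnames = list(NULL, c("a", "b")))
  d <- bray_curtis(x)
  expect_equal(d["a", "b"], 1 / 3, tolerance = 1e-12)
  expect_equal(diag(d), c(a = 0, b = 0))

  # disjoint supports give exactly 1
  y <- matrix(c(3, 0, 0, 5), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(bray_curtis(y)["a", "b"], 1)

  for (seed in 1:5) {
    m <- random_counts(15, 6, seed = seed)
    d <- bray_curtis(m)
    expect_equal(d, oracle_bray(m), tolerance = 1e-12)
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d, t(d))
  }
  bad <- matrix(c(1, 1, 0, 0), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(bray_curtis(bad), class = "degenerate_sample_error")
})

test_that("Mantel statistic equals the pairwise correlation oracle and a
           self-comparison is maximal", {
  set.seed(21)
  p1 <- matrix(rnorm(8), 4, 2)
  p2 <- p1 + matrix(rnorm(8, 0, 0.3), 4, 2)
  d1 <- as.matrix(dist(p1)); d2 <- as.matrix(dist(p2))
  dimnames(d1) <- dimnames(d2) <- list(letters[1:4], letters[1:4])
  r <- mantel(d1, d2, n_perm = 99, seed = 2)
  expect_equal(r$statistic, oracle_mantel_r(d1, d2), tolerance = 1e-12)

  self <- mantel(d1, d1, n_perm = 199, seed = 2)
  expect_equal(self$statistic, 1, tolerance = 1e-12)
  expect_gt(self$p_value, 0)

  # a strong match on more samples reaches the minimal attainable p
  set.seed(22)
  p <- matrix(rnorm(20), 10, 2)
  dd <- as.matrix(dist(p))
  strong <- mantel(dd, dd, n_perm = 199, seed = 5)
  expect_equal(strong$p_value, 1 / 200)

  expect_error(mantel(d1 * 0, d2), class = "degenerate_matrix_error")
  expect_error(mantel(d1[1:3, 1:3], d2[1:3, 1:3]), class = "design_error")
})

test_that("ANOSIM matches the hand-rank oracle, hits its bounds, and stays
           in [-1, 1]", {
  # perfect separation: all within distances below all between distances
  pts <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  d <- as.matrix(dist(pts))
  g <- rep(c("a", "b"), each = 3)
  r <- anosim(d, g, n_perm = 99, seed = 3)
  expect_equal(r$statistic, 1)

  for (seed in 1:5) {
    set.seed(seed)
    d6 <- as.matrix(dist(rnorm(6)))
    g6 <- sample(rep(c("x", "y"), 3))
    expect_equal(anosim(d6, g6, n_perm = 9, seed = 1)$statistic,
                 oracle_anosim_r(d6, g6), tolerance = 1e-12)
    expect_true(abs(anosim(d6, g6, n_perm = 9, seed = 1)$statistic) <= 1)
  }

  # labels unrelated to distance: permuted R centers near 0
  set.seed(30)
  d12 <- as.matrix(dist(rnorm(12)))
  g12 <- rep(c("a", "b"), 6)
  rs <- replicate(50, oracle_anosim_r(d12, sample(g12)))
  expect_lt(abs(mean(rs)), 0.1)

  expect_error(anosim(d, rep("a", 6)), class = "design_error")
})

test_that("PERMANOVA pseudo-F matches the Gower-centered oracle and
           separates distinct groups", {
  set.seed(17)
  for (seed in 1:5) {
    set.seed(seed)
    d <- as.matrix(dist(matrix(rnorm(12), 6, 2)))
    g <- sample(rep(c("x", "y"), 3))
    expect_equal(permanova(d, g, n_perm = 9, seed = 1)$statistic,
                 oracle_permanova_f(d, g), tolerance = 1e-9)
  }

  # two internally identical groups: between-distances only; with 8 + 8
  # samples essentially no label permutation preserves the partition, so p
  # reaches its (b + 1)/(n_perm + 1) floor
  m <- cbind(matrix(c(5, 0), 2, 8), matrix(c(0, 5), 2, 8))
  colnames(m) <- paste0("s", 1:16)
  d <- bray_curtis(m)
  g <- rep(c("a", "b"), each = 8)
  r <- permanova(d, g, n_perm = 199, seed = 4)
  expect_gt(r$statistic, 1e6)
  expect_equal(r$p_value, 1 / 200)

  expect_error(permanova(d, rep("a", 16)), class = "design_error")
})

test_that("vegan agrees with the first-principles implementations", {
  skip_if_not_installed("vegan")
  cm <- simulate_community_tables(seed = 3)
  bc <- bray_curtis(cm$counts)
  vd <- as.matrix(vegan::vegdist(t(unclass(cm$counts)), method = "bray"))
  expect_equal(unname(bc), unname(vd), tolerance = 1e-12)
  g <- cm$metadata$status
  expect_equal(anosim(bc, g, n_perm = 9, seed = 1)$statistic,
               unname(vegan::anosim(stats::as.dist(bc), g,
                                    permutations = 2)$statistic),
               tolerance = 1e-9)
  expect_equal(permanova(bc, g, n_perm = 9, seed = 1)$statistic,
               vegan::adonis2(stats::as.dist(bc) ~ g, permutations = 2)$F[1],
               tolerance = 1e-9)
  env <- simulate_environment(cm$truth$axis, seed = 4)
  ed <- as.matrix(dist(env$constraints))
  expect_equal(mantel(bc, ed, n_perm = 9, seed = 1)$statistic,
               unname(vegan::mantel(stats::as.dist(bc), stats::as.dist(ed),
                                    permutations = 2)$statistic),
               tolerance = 1e-9)
})
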