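toy_response <- function(seed = 7, n_feat = 8, n_samp = 5) {
  set.seed(seed)
  m <- matrix(rpois(n_feat * n_samp, 8), n_feat, n_samp,
              dimnames = list(paste0("f", seq_len(n_feat)),
                              paste0("s", seq_len(n_samp))))
  m
}

test_that("CCA eigenvalues match the dense-algebra oracle and vegan", {
  y <- toy_response()
  x <- constraint_table(matrix(rnorm(10), 5, 2,
                               dimnames = list(colnames(y), c("a", "b"))))
  fit <- cca(y, x)
  expect_equal(fit$eigenvalues, oracle_cca_eig(y, x), tolerance = 1e-9)
  expect_equal(sum(fit$eigenvalues), fit$constrained_inertia,
               tolerance = 1e-9)
  expect_true(fit$constrained_inertia <= fit$total_inertia + 1e-12)
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))

  # a 4x3 toy with one binary constraint
  y2 <- toy_response(seed = 2, n_feat = 4, n_samp = 3)
  x2 <- matrix(c(0, 1, 1), 3, 1, dimnames = list(colnames(y2), "grp"))
  fit2 <- cca(y2, x2)
  expect_equal(fit2$eigenvalues, oracle_cca_eig(y2, x2), tolerance = 1e-9)

  skip_if_not_installed("vegan")
  vfit <- vegan::cca(t(y) ~ a + b, data = as.data.frame(unclass(x)))
  expect_equal(unname(fit$eigenvalues), unname(vfit$CCA$eig),
               tolerance = 1e-9)
  expect_equal(fit$total_inertia, vfit$tot.chi, tolerance = 1e-9)
})

test_that("a saturated constraint basis explains everything, pure noise
           explains little", {
  y <- toy_response(seed = 4, n_feat = 12, n_samp = 6)
  # full indicator basis spanning all samples
  x_sat <- stats::model.matrix(~ 0 + factor(seq_len(6)))[, 1:5]
  rownames(x_sat) <- colnames(y)
  fit <- suppressWarnings(cca(y, x_sat))
  expect_equal(fit$proportion_explained, 1, tolerance = 1e-9)

  # one noise column at larger n explains a small share
  y_big <- toy_response(seed = 5, n_feat = 40, n_samp = 30)
  set.seed(6)
  x_noise <- matrix(rnorm(30), 30, 1, dimnames = list(colnames(y_big), "z"))
  expect_lt(cca(y_big, x_noise)$proportion_explained, 0.15)

  # degenerate response: explicit error, not NaN
  flat <- matrix(3, 4, 4, dimnames = list(paste0("f", 1:4), paste0("s", 1:4)))
  expect_error(cca(flat, x_sat[1:4, 1:2]), class = "degenerate_matrix_error")
})

test_that("adding a constraint never decreases constrained inertia and
           collinearity falls back to the pseudo-inverse", {
  y <- toy_response(seed = 11, n_feat = 15, n_samp = 8)
  set.seed(12)
  x <- matrix(rnorm(24), 8, 3,
              dimnames = list(colnames(y), c("a", "b", "c")))
  in1 <- cca(y, x[, 1, drop = FALSE])$constrained_inertia
  in2 <- cca(y, x[, 1:2])$constrained_inertia
  in3 <- cca(y, x)$constrained_inertia
  expect_true(in1 <= in2 + 1e-12 && in2 <= in3 + 1e-12)

  x_dup <- cbind(x, d = x[, 1])
  expect_warning(fit_dup <- cca(y, x_dup), "rank-deficient")
  expect_equal(fit_dup$constrained_inertia, in3, tolerance = 1e-9)
})

test_that("the CCA permutation test finds a planted gradient and respects
           the p-value floor", {
  cm <- simulate_community_tables(seed = 8)
  env <- simulate_environment(cm$truth$axis, noise_sd = 0.1, seed = 9)
  r <- cca_permutation_test(cm$counts, env$constraints[, "TN", drop = FALSE],
                            n_perm = 199, seed = 10)
  expect_equal(r$p_value, 1 / 200)
  expect_gt(r$statistic, 0)
  expect_lte(r$statistic, 1)
})

test_that("VIF matches the regression oracle and screening removes
           collinear variables", {
  # mutually uncorrelated (orthogonal, centered) columns: all VIF exactly 1
  q <- unclass(stats::poly(1:8, 3))
  rownames(q) <- paste0("s", 1:8)
  colnames(q) <- c("a", "b", "c")
  expect_equal(unname(vif(q)), rep(1, 3), tolerance = 1e-9)
  scr0 <- vif_screen(q)
  expect_equal(ncol(scr0$x), 3)
  expect_equal(scr0$removed, character(0))

  # duplicated column: unbounded VIF, one copy removed
  set.seed(15)
  base <- matrix(rnorm(30), 10, 3,
                 dimnames = list(paste0("s", 1:10), c("a", "b", "c")))
  dup <- cbind(base, a2 = base[, "a"])
  scr <- vif_screen(dup)
  expect_equal(ncol(scr$x), 3)
  expect_length(intersect(c("a", "a2"), colnames(scr$x)), 1)
  expect_true(all(vif(scr$x) < 20))

  # correlated variables: VIFs equal the brute-force 1/(1 - R^2)
  set.seed(16)
  z <- rnorm(12)
  xc <- cbind(a = z + rnorm(12, 0, 0.5), b = z + rnorm(12, 0, 0.5),
              c = rnorm(12))
  rownames(xc) <- paste0("s", 1:12)
  expect_equal(unname(vif(xc)), oracle_vif(xc), tolerance = 1e-9)

  expect_error(vif(xc[, 1, drop = FALSE]), class = "design_error")
})

test_that("forward selection keeps informative variables, rejects noise and
           collinear duplicates", {
  cm <- simulate_community_tables(seed = 20)
  env <- simulate_environment(
    cm$truth$axis,
    coupling = c(TN = 1, TP = 0), noise_sd = 0.2, seed = 21
  )
  sel <- forward_select(cm$counts, env$constraints, alpha = 0.05,
                        n_perm = 199, seed = 22)
  expect_true("TN" %in% sel$selected)
  expect_false("TP" %in% sel$selected)

  # near-duplicate of a selected variable: blocked by the VIF rule
  x2 <- cbind(unclass(env$constraints),
              TN2 = env$constraints[, "TN"] +
                rnorm(nrow(env$constraints), 0, 1e-4))
  sel2 <- forward_select(cm$counts, x2, alpha = 0.05, n_perm = 199,
                         seed = 23)
  expect_length(intersect(c("TN", "TN2"), sel2$selected), 1)
  blocked <- sel2$trace[sel2$trace$variable %in% c("TN", "TN2") &
                          !sel2$trace$accepted, ]
  if (nrow(blocked) > 0) expect_true(any(blocked$max_vif >= 20))

  # pure-noise candidates: usually nothing selected
  set.seed(24)
  y <- random_counts(40, 12, seed = 25)
  x_noise <- matrix(rnorm(24), 12, 2,
                    dimnames = list(colnames(y), c("u", "v")))
  sel3 <- suppressWarnings(forward_select(y, x_noise, alpha = 0.01,
                                          n_perm = 199, seed = 26))
  expect_lte(length(sel3$selected), 1)
})

test_that("variation partitioning fractions are coherent and sum to one", {
  cm <- simulate_community_tables(seed = 30)
  env <- simulate_environment(cm$truth$axis, seed = 31)
  x <- unclass(env$constraints)
  v <- variation_partition(cm$counts, x[, c("pH", "WC")],
                           x[, c("coverage", "density")])
  expect_equal(v$fraction_a + v$fraction_b + v$fraction_shared +
                 v$fraction_unexplained, 1, tolerance = 1e-9)
  expect_gte(v$fraction_a, -1e-12)
  expect_gte(v$fraction_b, -1e-12)

  # a duplicated span has no unique contribution
  x2 <- x[, c("pH", "WC")]
  colnames(x2) <- c("pH_copy", "WC_copy")
  v2 <- suppressWarnings(variation_partition(cm$counts, x[, c("pH", "WC")],
                                             x2))
  expect_equal(v2$fraction_b, 0, tolerance = 1e-9)
  expect_equal(v2$fraction_shared, v2$prop_group1, tolerance = 1e-9)
  expect_equal(v2$fraction_unexplained, 1 - v2$prop_group1, tolerance = 1e-9)

  expect_error(variation_partition(cm$counts, x[, c("pH", "WC")],
                                   x[, c("WC", "TN")]),
               class = "design_error")

  # fuzzed identity
  for (seed in 1:3) {
    y <- random_counts(20, 8, seed = seed + 50)
    set.seed(seed)
    xa <- matrix(rnorm(16), 8, 2, dimnames = list(colnames(y), c("a1", "a2")))
    xb <- matrix(rnorm(8), 8, 1, dimnames = list(colnames(y), "b1"))
    vv <- variation_partition(y, xa, xb)
    expect_equal(vv$fraction_a + vv$fraction_b + vv$fraction_shared +
                   vv$fraction_unexplained, 1, tolerance = 1e-9)
  }
})
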