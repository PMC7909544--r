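test_that("response ratio matches the hand-derived contrast values", {
  r <- response_ratio(2.0, 1.0, 0.1, 0.1, 3, 3)
  expect_equal(r$rr, log(2), tolerance = 1e-12)
  expect_equal(r$variance, 0.1^2 / (3 * 4) + 0.1^2 / (3 * 1),
               tolerance = 1e-12)
  expect_equal(r$se, 0.06454972, tolerance = 1e-7)
  expect_equal(r$ci_low, 0.5666297, tolerance = 1e-6)
  expect_equal(r$ci_high, 0.8196646, tolerance = 1e-6)
  expect_true(r$significant)
  expect_true(r$rr > 0)

  # equal means: rr 0, CI symmetric, not significant
  r0 <- response_ratio(1.5, 1.5, 0.2, 0.2, 4, 4)
  expect_equal(r0$rr, 0)
  expect_equal(r0$ci_low, -r0$ci_high)
  expect_false(r0$significant)

  expect_error(response_ratio(0, 1, 0.1, 0.1, 3, 3), class = "domain_error")
  expect_error(response_ratio(2, 1, 0, 0, 3, 3),
               class = "degenerate_variance_error")
  expect_error(response_ratio(2, 1, 0.1, 0.1, 1, 3), class = "domain_error")
})

test_that("swapping treatment and control negates rr and keeps the variance", {
  set.seed(101)
  for (i in 1:100) {
    xt <- runif(1, 0.5, 5); xc <- runif(1, 0.5, 5)
    st <- runif(1, 0.01, 1); sc <- runif(1, 0.01, 1)
    nt <- sample(2:20, 1); nc <- sample(2:20, 1)
    a <- response_ratio(xt, xc, st, sc, nt, nc)
    b <- response_ratio(xc, xt, sc, st, nc, nt)
    expect_equal(a$rr, -b$rr, tolerance = 1e-12)
    expect_equal(a$variance, b$variance, tolerance = 1e-12)
    # CI width is exactly 2 z se
    expect_equal(a$ci_high - a$ci_low, 2 * 1.96 * a$se, tolerance = 1e-12)
  }
})

test_that("weighted RR is the inverse-variance mean with se sqrt(1/sum w)", {
  # single comparison: the summary is that comparison
  one <- weighted_rr(0.4, 0.02)
  expect_equal(one$rr_weighted, 0.4)
  expect_equal(one$se_weighted, sqrt(0.02))

  # hand example: weights 100 and 25
  w <- weighted_rr(c(0.2, 0.6), c(0.01, 0.04))
  expect_equal(w$rr_weighted, 0.28, tolerance = 1e-12)
  expect_equal(w$se_weighted, 0.08944272, tolerance = 1e-7)

  # equal variances reduce to the arithmetic mean
  eq <- weighted_rr(c(0.1, 0.3, 0.8), rep(0.05, 3))
  expect_equal(eq$rr_weighted, mean(c(0.1, 0.3, 0.8)), tolerance = 1e-12)

  # brute-force accumulation oracle on random inputs
  set.seed(7)
  rr <- rnorm(25); v <- runif(25, 0.001, 0.1)
  acc_num <- 0; acc_den <- 0
  for (i in seq_along(rr)) {
    acc_num <- acc_num + rr[i] / v[i]
    acc_den <- acc_den + 1 / v[i]
  }
  got <- weighted_rr(rr, v)
  expect_equal(got$rr_weighted, acc_num / acc_den, tolerance = 1e-12)
  expect_equal(got$se_weighted, sqrt(1 / acc_den), tolerance = 1e-12)

  expect_error(weighted_rr(numeric(0), numeric(0)),
               class = "empty_input_error")
  expect_error(weighted_rr(0.2, 0), class = "domain_error")
})

test_that("the unpaired t-test behaves at its boundary cases", {
  r <- gene_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  # identical constant groups: p 1 by convention
  expect_equal(gene_t_test(c(2, 2), c(2, 2))$p, 1)

  set.seed(3)
  a <- c(1, 1, 1) + rnorm(3, 0, 1e-4)
  b <- c(2, 2, 2) + rnorm(3, 0, 1e-4)
  r2 <- gene_t_test(a, b)
  expect_lt(r2$p, 0.01)
  # independent oracle: exhaustive label permutation puts the observed mean
  # difference at the extreme of all 20 assignments
  pool <- c(a, b)
  combs <- utils::combn(6, 3)
  diffs <- apply(combs, 2, function(ix) {
    abs(mean(pool[ix]) - mean(pool[-ix]))
  })
  obs <- abs(mean(a) - mean(b))
  expect_equal(mean(diffs >= obs - 1e-12), 2 / 20)

  r3 <- gene_t_test(b, a)
  expect_equal(r3$statistic, -r2$statistic, tolerance = 1e-12)
  expect_equal(r3$p, r2$p, tolerance = 1e-12)
})

test_that("per-family contrasts recover a doubled family and handle
           constant families", {
  m <- matrix(c(1, 1.01, 0.99, 1,   2, 2.02, 1.98, 2), 1, 8)
  m <- rbind(m, 5)  # constant family
  dimnames(m) <- list(c("dbl", "flat"),
                      c(paste0("c", 1:4), paste0("t", 1:4)))
  attr(m, "category") <- c(dbl = "Nitrogen cycling", flat = "Nitrogen cycling")
  design <- contrast_design("T", "C", setNames(rep(c("C", "T"), each = 4),
                                               colnames(m)))
  res <- contrast_all_families(m, design)
  dbl <- res[res$family_id == "dbl", ]
  expect_equal(dbl$rr, log(2), tolerance = 0.02)
  expect_true(dbl$significant)
  flat <- res[res$family_id == "flat", ]
  expect_equal(flat$rr, 0)
  expect_false(flat$significant)

  # permuting sample columns with consistent labels changes nothing
  perm <- sample(ncol(m))
  m_perm <- m[, perm]
  attr(m_perm, "category") <- attr(m, "category")
  res2 <- contrast_all_families(m_perm, design)
  expect_equal(res2[order(res2$family_id), ], res[order(res$family_id), ],
               ignore_attr = TRUE, tolerance = 1e-12)

  # antisymmetry under group swap
  flipped <- contrast_design("C", "T", design$assignment)
  res3 <- contrast_all_families(m, flipped)
  expect_equal(res3$rr[match(res$family_id, res3$family_id)], -res$rr,
               tolerance = 1e-12)
  expect_equal(res3$variance[match(res$family_id, res3$family_id)],
               res$variance, tolerance = 1e-12)

  expect_error(
    contrast_all_families(m[, 1:3],
                          contrast_design("T", "C", setNames(
                            c("C", "C", "T", "T"), c("c1", "c2", "t1", "x")))),
    class = "design_error"
  )
})

test_that("category shift fractions equal an independent recount", {
  sim <- simulate_geochip_experiment(
    nt = 10, nc = 10,
    effect_spec = list("Nitrogen cycling" =
                         list(fraction_affected = 0.95, theta = 0.5)),
    seed = 5
  )
  fam <- preprocess_geochip(sim$spots, sim$annotation)
  res <- contrast_all_families(fam, sim$truth$design)
  shift <- category_shift_summary(res, "Nitrogen cycling")

  sub <- res[res$category == "Nitrogen cycling", ]
  inc <- 0; dec <- 0
  for (i in seq_len(nrow(sub))) {
    if (isTRUE(sub$significant[i]) && sub$rr[i] > 0) inc <- inc + 1
    if (isTRUE(sub$significant[i]) && sub$rr[i] < 0) dec <- dec + 1
  }
  expect_equal(shift$n_sig_increased, inc)
  expect_equal(shift$n_sig_decreased, dec)
  expect_equal(shift$fraction_increased, inc / nrow(sub))
  expect_true(shift$n_sig_increased + shift$n_sig_decreased <=
                shift$n_families)

  expect_error(category_shift_summary(res, "No such category"),
               class = "empty_category_error")

  # no significant families -> fractions (0, 0)
  null_res <- res
  null_res$significant <- FALSE
  s0 <- category_shift_summary(null_res, "Nitrogen cycling")
  expect_equal(s0$fraction_increased, 0)
  expect_equal(s0$fraction_decreased, 0)
})
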