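test_that("absolute_from_relative inverts the purity/ploidy mixture", {
  expect_equal(absolute_from_relative(c(1, 1.5), 1, 2), c(2, 3))
  r <- c(0.3, 0.77, 1.9)
  expect_equal(absolute_from_relative(r, 1, 1), r)
  # forward model with q = 3, alpha = 0.5, tau = 2 gives r = 1.25
  q <- 3; a <- 0.5; tau <- 2
  r_fwd <- (a * q + 2 * (1 - a)) / (a * tau + 2 * (1 - a))
  expect_equal(r_fwd, 1.25)
  expect_equal(absolute_from_relative(1.25, 0.5, 2), 3)
  # round trip: forward of the inverse reproduces r to 1e-12
  set.seed(1)
  for (i in 1:20) {
    a <- runif(1, 0.2, 1); tau <- runif(1, 1.5, 5)
    r <- runif(10, 0.2, 3)
    qh <- absolute_from_relative(r, a, tau)
    expect_equal((a * qh + 2 * (1 - a)) / (a * tau + 2 * (1 - a)), r,
                 tolerance = 1e-12)
  }
  expect_error(absolute_from_relative(1, 0, 2), "purity")
})

test_that("integer_distance measures distance to the nearest integer", {
  expect_equal(integer_distance(c(2.0, 2.4, 2.5)), c(0, 0.4, 0.5))
  expect_equal(integer_distance(-0.3), 0.3)
  set.seed(2)
  q <- runif(1000, 0, 5)
  expect_equal(integer_distance(q), pmin(q - floor(q), ceiling(q) - q),
               tolerance = 1e-14)
  expect_true(all(integer_distance(q) <= 0.5))
})

test_that("weighted_mean_distance is the width-weighted average", {
  expect_equal(weighted_mean_distance(c(0.1, 0.1), c(5, 11)), 0.1)
  expect_equal(weighted_mean_distance(c(0, 0.4), c(3, 1)), 0.1)
  expect_equal(weighted_mean_distance(0.5, 7), 0.5)
  expect_error(weighted_mean_distance(numeric(), numeric()), "empty")
})

test_that("flat and integer profiles fit with zero heterogeneity", {
  p <- segmented_profile("chr1", c(1, 11, 21), c(10, 20, 30), c(1, 1, 1))
  fit <- suppressWarnings(cnh(p))
  expect_equal(fit$cnh, 0)
  expect_true(any(fit$ties$purity == 1 & fit$ties$ploidy == 2))
  # true q = (2, 3, 4, 2) at alpha = 1, on-grid ploidy
  q <- c(2, 3, 4, 2); w <- c(1, 2, 1, 4)  # weighted mean 20/8 = 2.5
  tau <- weighted.mean(q, w)
  expect_equal(tau, 2.5)
  end <- cumsum(w)
  p2 <- segmented_profile("chr1", end - w + 1, end, q / tau)
  expect_equal(cnh(p2)$cnh, 0)
})

test_that("grid minimum matches the exhaustive enumeration oracle", {
  set.seed(31)
  p <- normalize_profile(segmented_profile(
    "chr1", c(1, 2, 3, 4), c(1, 2, 3, 4), c(2, 3, 4, 2.1) / 2.775))
  fit <- cnh(p)
  expect_equal(fit$cnh, oracle_cnh(p$value, p$width), tolerance = 1e-12)
  for (i in 1:8) {
    p <- random_profile(sample(5:200, 1))
    expect_equal(cnh(p)$cnh, oracle_cnh(p$value, p$width),
                 tolerance = 1e-12)
  }
})

test_that("argmin ties are reported smallest-ploidy-first and attain cnh", {
  set.seed(5)
  p <- random_profile(40)
  fit <- cnh(p)
  expect_true(all(fit$ties$score <= fit$cnh + 1e-12))
  expect_equal(fit$ploidy, min(fit$ties$ploidy))
  first <- fit$ties[fit$ties$ploidy == fit$ploidy, ]
  expect_equal(fit$purity, min(first$purity))
  expect_gte(fit$cnh, 0)
  expect_lte(fit$cnh, 0.5)
  # the reported q/d belong to the argmin
  expect_equal(fit$q, absolute_from_relative(p$value, fit$purity,
                                             fit$ploidy))
  expect_equal(weighted_mean_distance(fit$d, p$width), fit$cnh)
  # fitted ploidy identity: weighted mean of q equals tau for any candidate
  expect_lt(abs(fit$ploidy_residual), 1e-9)
})

test_that("restricting the grid never lowers the minimum", {
  set.seed(8)
  for (i in 1:5) {
    p <- random_profile(30)
    full <- cnh(p)
    con <- cnh(p, purity = 1, purity_window = 0.1)
    expect_true(all(con$ties$purity >= 0.9 - 1e-12))
    expect_gte(con$cnh, full$cnh - 1e-12)
    fixed <- cnh(p, ploidy = 2.13)
    expect_equal(unique(fixed$ties$ploidy), 2.15) # nearest grid value
    expect_gte(fixed$cnh, full$cnh - 1e-12)
  }
  p <- segmented_profile("chr1", c(1, 11), c(10, 20), c(1, 1))
  expect_equal(suppressWarnings(cnh(p, ploidy = 2))$cnh, 0)
  expect_error(cnh(p, purity = 0.05), "purity")
})

test_that("few-level profiles warn but single segments still fit", {
  p <- segmented_profile("chr1", c(1, 11), c(10, 20), c(0.8, 1.2))
  expect_warning(cnh(p), "distinct")
  p1 <- segmented_profile("chr1", 1, 10, 1)
  expect_warning(fit <- cnh(p1), "distinct")
  expect_equal(fit$cnh, 0)
})

test_that("shifted solutions follow the translation algebra", {
  s <- shifted_solution(0.8, 2, 1)
  expect_equal(s$ploidy_new, 3)
  expect_equal(s$purity_new, -2 / 3 + 0.8 + 2 / 2)
  expect_false(s$valid)
  s <- shifted_solution(1, 4, -1)
  expect_equal(s$ploidy_new, 3)
  expect_equal(s$purity_new, -2 / 3 + 1 + 2 / 4)
  expect_true(s$valid)
  s0 <- shifted_solution(0.73, 2.4, 0)
  expect_equal(s0$ploidy_new, 2.4)
  expect_equal(s0$purity_new, 0.73)
  expect_true(s0$valid)
  # exact translation purity: q -> q + shift reproduced algebraically
  set.seed(10)
  for (i in 1:10) {
    a <- runif(1, 0.3, 1); tau <- runif(1, 2, 4); shift <- sample(c(-1, 1), 1)
    s <- shifted_solution(a, tau, shift)
    r <- runif(6, 0.4, 2)
    q1 <- absolute_from_relative(r, a, tau)
    if (s$purity_exact > 0 && s$purity_exact <= 1) {
      q2 <- absolute_from_relative(r, s$purity_exact, s$ploidy_new)
      expect_equal(q2, q1 + shift, tolerance = 1e-9)
    }
  }
  expect_error(shifted_solution(0.5, 2, 0.5), "integer")
})

test_that("fit methods expose coefficients, residuals and predictions", {
  set.seed(21)
  p <- random_profile(20)
  fit <- cnh(p)
  expect_named(coef(fit), c("cnh", "purity", "ploidy"))
  expect_equal(unname(coef(fit)[1]), fit$cnh)
  expect_equal(residuals(fit), fit$d)
  expect_equal(fitted(fit), fit$q)
  expect_equal(predict(fit), fit$q)
  expect_equal(predict(fit, newdata = 1, purity = 1, ploidy = 3), 3)
  expect_output(print(fit), "CNH")
  s <- summary(fit)
  expect_s3_class(s, "summary.cnh_fit")
  expect_output(print(s), "ploidy residual")
  surf <- cnh(p, keep_surface = TRUE)$surface
  expect_equal(dim(surf), c(81, 71))
  expect_equal(min(surf), fit$cnh)
})
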