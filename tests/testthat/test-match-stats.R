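test_that("midpoint cutoff splits separable classes at the gap centre", {
  fit <- fit_rms_cutoff(c(0.1, 0.2, 0.4, 0.5), c(TRUE, TRUE, FALSE, FALSE),
                        "midpoint")
  expect_equal(fit$cutoff, 0.3)
  expect_equal(fit$accuracy, 1)
  expect_true(fit$separable)
  expect_error(fit_rms_cutoff(c(1, 2), c(TRUE, TRUE)), "both")
})

test_that("non-separable data gets the exhaustive best threshold", {
  with_seed(31L, {
    rms <- c(rnorm(40, 0.3, 0.1), rnorm(40, 0.45, 0.1))
    is_match <- rep(c(TRUE, FALSE), each = 40)
  })
  fit <- fit_rms_cutoff(rms, is_match, "midpoint")
  expect_false(fit$separable)
  expect_lt(fit$accuracy, 1)
  # brute-force scan over a fine grid of thresholds
  grid <- seq(min(rms) - 0.01, max(rms) + 0.01, length.out = 20001)
  best <- max(vapply(grid, function(t) mean((rms < t) == is_match), numeric(1)))
  expect_equal(fit$accuracy, best)
  # self-consistency with the classifier
  expect_equal(mean((classify_match(rms, fit$cutoff) == "match") == is_match),
               fit$accuracy)
})

test_that("logistic mode detects perfect separation and falls back to midpoint", {
  rms <- c(0.08, 0.1, 0.12, 0.5, 0.6, 0.7)
  is_match <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  lg <- fit_rms_cutoff(rms, is_match, "logistic")
  md <- fit_rms_cutoff(rms, is_match, "midpoint")
  expect_true(lg$separable)
  expect_equal(lg$cutoff, md$cutoff)
  expect_identical(classify_match(rms, lg$cutoff), classify_match(rms, md$cutoff))
  # overlapping classes: finite logistic cutoff at p = 0.5
  with_seed(8L, {
    r2 <- c(rnorm(150, 0.3, 0.08), rnorm(150, 0.42, 0.08))
    m2 <- rep(c(TRUE, FALSE), each = 150)
  })
  lg2 <- fit_rms_cutoff(r2, m2, "logistic")
  expect_false(lg2$separable)
  expect_true(lg2$cutoff > 0.25 && lg2$cutoff < 0.45)
})

test_that("classification against the reported cutoff is conservative at the boundary", {
  expect_equal(classify_match(0.30, 0.3537), "match")
  expect_equal(classify_match(0.40, 0.3537), "non-match")
  expect_equal(classify_match(0.3537, 0.3537), "non-match")
  expect_error(classify_match(-0.1, 0.3537), "non-negative")
  expect_error(classify_match(0.1, 0), "cutoff")
})

test_that("Box-Cox recovers known transformations and matches a grid oracle", {
  x_log <- with_seed(41L, exp(rnorm(500, 0, 0.6)))
  expect_lt(abs(boxcox_lambda(x_log)$lambda), 0.15)
  x_norm <- with_seed(42L, rnorm(500, 20, 2))
  expect_lt(abs(boxcox_lambda(x_norm)$lambda - 1), 0.3)
  # independent coarse-grid oracle
  x <- with_seed(43L, rgamma(200, shape = 2, rate = 3))
  res <- boxcox_lambda(x)
  coarse <- seq(-3, 3, by = 0.1)
  ll <- vapply(coarse, function(lam) {
    z <- if (lam == 0) log(x) else (x^lam - 1) / lam
    n <- length(x)
    -n / 2 * log(mean((z - mean(z))^2)) + (lam - 1) * sum(log(x))
  }, numeric(1))
  expect_lt(abs(res$lambda - coarse[which.max(ll)]), 0.1 + 1e-9)
  expect_error(boxcox_lambda(c(1, -1, 2)), "positive")
})

test_that("Box-Cox lambda is invariant to positive rescaling", {
  x <- with_seed(44L, rgamma(300, 3, 1))
  l1 <- boxcox_lambda(x)$lambda
  l2 <- boxcox_lambda(x * 7.3)$lambda
  expect_lt(abs(l1 - l2), 0.05 + 1e-9)
})

test_that("Box-Cox agrees with the MASS profile-likelihood implementation", {
  skip_if_not_installed("MASS")
  x <- with_seed(45L, rgamma(250, 2.5, 2))
  res <- boxcox_lambda(x)
  bc <- MASS::boxcox(x ~ 1, lambda = seq(-3, 3, by = 0.01), plotit = FALSE)
  expect_lt(abs(res$lambda - bc$x[which.max(bc$y)]), 0.02 + 1e-9)
})

test_that("pairwise Bonferroni contrasts follow Welch arithmetic", {
  tab <- data.frame(
    participant_a = rep(1:4, times = 3), participant_b = rep(c(1, 1, 2, 2), 3),
    arch = "upper",
    method = rep(c("M1_NONE", "M3_MANUAL_GINGIVAL", "M4_PLANAR"), each = 4),
    replicate = 1, session = 1, operator = 1,
    is_match = rep(c(TRUE, TRUE, FALSE, FALSE), 3),
    rms = c(0.30, 0.34, 0.60, 0.62, 0.10, 0.12, 0.55, 0.60, 0.15, 0.18, 0.58, 0.61),
    cell_seed = 1L, error = NA_character_, timestamp = "t")
  out <- pairwise_bonferroni(tab, "rms")
  expect_equal(nrow(out), 6L)  # 3 method pairs x 2 strata
  row <- out[out$is_match & out$method_a == "M1_NONE" &
               out$method_b == "M3_MANUAL_GINGIVAL", ]
  a <- c(0.30, 0.34)
  b <- c(0.10, 0.12)
  # hand-computed Welch statistic
  tstat <- (mean(a) - mean(b)) / sqrt(var(a) / 2 + var(b) / 2)
  expect_equal(row$statistic, tstat, tolerance = 1e-12)
  expect_equal(row$diff, 0.21)
  expect_equal(row$p_adjusted, min(1, row$p_value * 3))
  # identical samples: zero difference, adjusted p of 1
  tab2 <- tab[tab$method != "M4_PLANAR", ]
  tab2$rms[tab2$method == "M3_MANUAL_GINGIVAL"] <-
    tab2$rms[tab2$method == "M1_NONE"]
  out2 <- pairwise_bonferroni(tab2, "rms")
  expect_true(all(out2$diff == 0))
  expect_true(all(out2$p_adjusted == 1))
})
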