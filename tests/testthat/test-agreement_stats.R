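# Brute-force two-way ANOVA oracle: explicit loops over cells.
anova_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  ssr <- 0; ssc <- 0; ssw <- 0; sse <- 0
  rm_ <- numeric(n); cm_ <- numeric(k)
  for (i in 1:n) rm_[i] <- sum(m[i, ]) / k
  for (j in 1:k) cm_[j] <- sum(m[, j]) / n
  for (i in 1:n) ssr <- ssr + (rm_[i] - grand)^2
  ssr <- k * ssr
  for (j in 1:k) ssc <- ssc + (cm_[j] - grand)^2
  ssc <- n * ssc
  for (i in 1:n) for (j in 1:k) {
    ssw <- ssw + (m[i, j] - rm_[i])^2
    sse <- sse + (m[i, j] - rm_[i] - cm_[j] + grand)^2
  }
  list(BMS = ssr / (n - 1), WMS = ssw / (n * (k - 1)),
       JMS = ssc / (k - 1), EMS = sse / ((n - 1) * (k - 1)))
}

test_that("ANOVA decomposition equals the explicit-loop oracle", {
  m <- matrix(c(1, 2, 3, 4, 5, 7), 3, 2, byrow = TRUE)
  got <- anova_decompose(m)
  want <- anova_oracle(m)
  for (f in c("BMS", "WMS", "JMS", "EMS"))
    expect_lt(abs(got[[f]] - want[[f]]), 1e-12)
  withr::with_seed(17, {
    for (rep in 1:25) {
      n <- sample(3:12, 1); k <- sample(2:4, 1)
      m <- matrix(rnorm(n * k, 50, 10), n, k)
      got <- anova_decompose(m)
      want <- anova_oracle(m)
      for (f in c("BMS", "WMS", "JMS", "EMS"))
        expect_lt(abs(got[[f]] - want[[f]]), 1e-12)
    }
  })
})

test_that("identical raters give zero rater/error variance and ICC 1", {
  m <- cbind(c(3, 9, 5, 7), c(3, 9, 5, 7))
  ms <- anova_decompose(m)
  expect_equal(ms$JMS, 0)
  expect_equal(ms$EMS, 0)
  expect_equal(ms$WMS, 0)
  for (f in c("1,1", "1,k", "2,1", "2,k", "3,1", "3,k"))
    expect_equal(icc(m, f)$estimate, 1)
})

test_that("a constant offset breaks absolute agreement but not consistency", {
  withr::with_seed(23, a <- rnorm(30, 10, 4))
  m <- cbind(a, a + 2.5)
  expect_equal(icc(m, "3,k")$estimate, 1, tolerance = 1e-12)
  expect_lt(icc(m, "2,k")$estimate, 1)
  expect_lt(icc(m, "2,1")$estimate, icc(m, "3,1")$estimate)
})

test_that("listwise deletion drops incomplete rows and degenerate input errors", {
  m <- cbind(c(1, 2, NA, 4), c(1.1, 2.2, 3, 4.4))
  ms <- anova_decompose(m)
  expect_equal(ms$n, 3)
  expect_equal(ms$n_dropped, 1)
  expect_error(anova_decompose(cbind(1:3)), "2 columns")
  expect_error(icc(cbind(c(1, 1), c(1, 1))), "undefined")
})

test_that("ICC estimator recovers the theoretical variance ratio", {
  ts <- generate_two_system(200, mu = 10, sigma_subject = 3,
                            sigma_error = 1, seed = 101)
  expect_equal(ts$icc_theoretical, 0.9)
  est <- icc(ts$matrix, "3,1")$estimate
  expect_lt(abs(est - 0.9), 0.03)
  # consistency: at n = 2000 the mean estimate is within 0.01 of theory
  ests <- vapply(1:30, function(s)
    icc(generate_two_system(2000, sigma_subject = 3, sigma_error = 1,
                            seed = 1000 + s)$matrix, "3,1")$estimate,
    numeric(1))
  expect_lt(abs(mean(ests) - 0.9), 0.01)
})

test_that("ICC confidence bounds bracket the estimate and cover the truth", {
  ts <- generate_two_system(50, sigma_subject = 2, sigma_error = 1,
                            seed = 77)
  for (f in c("1,1", "1,k", "2,1", "2,k", "3,1", "3,k")) {
    r <- icc(ts$matrix, f)
    expect_lte(r$ci95[1], r$estimate)
    expect_gte(r$ci95[2], r$estimate)
  }
})

test_that("Cronbach's alpha behaves at its limits and equals ICC(3,k) for k=2", {
  m <- cbind(c(3, 9, 5, 7), c(3, 9, 5, 7))
  expect_equal(cronbach_alpha(m)$alpha, 1)
  withr::with_seed(41, m2 <- cbind(rnorm(1000), rnorm(1000)))
  expect_lt(abs(cronbach_alpha(m2)$alpha), 0.1)
  withr::with_seed(43, {
    for (rep in 1:100) {
      m3 <- matrix(rnorm(2 * sample(5:40, 1), 20, 5), ncol = 2)
      expect_lt(abs(cronbach_alpha(m3)$alpha - icc(m3, "3,k")$estimate),
                1e-10)
    }
  })
  expect_error(cronbach_alpha(cbind(c(1, 1), c(1, 1))), "undefined")
})

test_that("validity regression is exact on noiseless lines", {
  x <- c(1, 2, 3, 4, 5)
  r <- validity_regression(x, x)
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$constant, 0, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  r2 <- validity_regression(x, 2 * x + 1)
  expect_equal(r2$slope, 2, tolerance = 1e-12)
  expect_equal(r2$constant, 1, tolerance = 1e-12)
  expect_equal(r2$r_squared, r2$r^2, tolerance = 1e-12)
  expect_error(validity_regression(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("slope confidence interval covers the true slope at near-nominal rate", {
  hits <- 0
  for (s in 1:100) {
    withr::with_seed(2000 + s, {
      x <- rnorm(20, 700, 50)
      y <- 0.975 * x + rnorm(20, 0, 15)
    })
    r <- validity_regression(x, y)
    if (r$ci95_slope[1] <= 0.975 && 0.975 <= r$ci95_slope[2])
      hits <- hits + 1
  }
  expect_gte(hits, 93)
})

test_that("Bland-Altman is exact in the self-comparison and formula cases", {
  a <- c(5, 7, 9, 11)
  ba <- bland_altman(a, a)
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa, c(0, 0))
  expect_equal(ba$prop_slope, 0)

  withr::with_seed(53, {
    ref <- rnorm(40, 100, 10)
    cand <- ref - rnorm(40, 3, 2)
  })
  ba2 <- bland_altman(ref, cand)
  d <- ref - cand
  expect_lt(abs(ba2$bias - mean(d)), 1e-12)
  expect_lt(abs(ba2$sd_diff - sd(d)), 1e-12)
  expect_lt(max(abs(ba2$loa - (mean(d) + c(-1, 1) * 1.96 * sd(d)))), 1e-12)
  expect_lt(max(abs(ba2$ci95_bias -
                    (mean(d) + c(-1, 1) * qt(0.975, 39) * sd(d) / sqrt(40)))),
            1e-12)
  # internal identities
  expect_lt(abs(mean(ba2$loa) - ba2$bias), 1e-9)
  expect_lt(abs((ba2$loa[2] - ba2$bias) - 1.96 * ba2$sd_diff), 1e-9)
  expect_error(bland_altman(1:2, 1:2), "at least 3")
})

test_that("Bland-Altman shifts with neither input and scales with both", {
  withr::with_seed(59, {
    ref <- rnorm(25, 50, 5); cand <- ref + rnorm(25, 1, 1)
  })
  b0 <- bland_altman(ref, cand)
  b1 <- bland_altman(ref + 100, cand + 100)
  expect_equal(b1$bias, b0$bias, tolerance = 1e-9)
  expect_equal(b1$loa, b0$loa, tolerance = 1e-9)
  expect_equal(b1$prop_slope, b0$prop_slope, tolerance = 1e-9)
  b2 <- bland_altman(ref * 3, cand * 3)
  expect_equal(b2$bias, 3 * b0$bias, tolerance = 1e-9)
  expect_equal(b2$sd_diff, 3 * b0$sd_diff, tolerance = 1e-9)
  expect_equal(b2$loa, 3 * b0$loa, tolerance = 1e-9)
  expect_equal(b2$p_prop, b0$p_prop, tolerance = 1e-9)
})

test_that("published LoA bounds are reconstructed from bias and CI at n = 20", {
  loa <- reconstruct_loa_from_ci(14.215, 6.787, 21.643, 20)
  expect_lt(abs(loa[2] - 45.325), 0.01)
  expect_lt(abs(loa[1] - (-16.895)), 0.01)
  loa2 <- reconstruct_loa_from_ci(1.515, 1.088, 1.942, 20)
  expect_lt(abs(loa2[1] - (-0.273)), 0.005)
  expect_lt(abs(loa2[2] - 3.303), 0.005)
  expect_equal(reconstruct_loa_from_ci(2, 2, 2, 20), c(2, 2))
  expect_error(reconstruct_loa_from_ci(0, 1, -1, 20), "ci_lo")
})

test_that("qualitative bands are left-closed at the published cut points", {
  expect_equal(classify_icc(0.298), "poor")
  expect_equal(classify_icc(0.5), "moderate")
  expect_equal(classify_icc(0.85), "good")
  expect_equal(classify_icc(0.75), "good")
  expect_equal(classify_icc(0.9), "excellent")
  expect_equal(classify_correlation(0.2), "small")
  expect_equal(classify_correlation(0.05), "negligible")
  expect_equal(classify_correlation(-0.6), "large")
  expect_equal(classify_r2(0.888), "large")
  expect_equal(classify_r2(0.09), "medium")
  expect_equal(classify_r2(0.005), "negligible")
})
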