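test_that("log-normal MLE has its closed form and recovers parameters", {
  f <- lognormal_mle(c(1, exp(2), 1, exp(2)))
  expect_equal(f$params$mu, 1)
  expect_equal(f$params$sigma, 1)

  expect_error(lognormal_mle(rep(exp(1), 5)), "degenerate")
  expect_error(lognormal_mle(c(1, 2)), "at least 3")
  expect_error(lognormal_mle(c(1, -1, 2)), "positive")

  set.seed(7)
  x <- stats::rlnorm(5000, 0.5, 0.8)
  f2 <- lognormal_mle(x)
  expect_equal(f2$params$mu, 0.5, tolerance = 0.05)
  expect_equal(f2$params$sigma, 0.8, tolerance = 0.05)
})

test_that("Burr III CDF/quantile closed-form values and limits hold", {
  expect_equal(pburr3(1, 1, 1, 1), 0.5)
  expect_equal(pburr3(1, 1, 1, 2), 0.25)
  expect_equal(pburr3(1e-12, 5, 3, 0.7), 0, tolerance = 1e-20)
  expect_equal(pburr3(1e12, 5, 3, 0.7), 1)
  expect_equal(qburr3(0.5, 1, 1, 1), 1.0)
  expect_equal(qburr3(0.5, 5, 2.3, 1), 5.0)
  expect_error(pburr3(-1, 1, 1, 1), "x > 0")
  expect_error(qburr3(1.2, 1, 1, 1), "inside \\(0, 1\\)")
  expect_error(pburr3(1, -1, 1, 1), "must all be finite")
})

test_that("Burr III CDF and quantile are exact inverses across parameters", {
  set.seed(5)
  for (i in 1:50) {
    b <- stats::runif(1, 0.05, 200)
    cc <- stats::runif(1, 0.2, 6)
    k <- stats::runif(1, 0.2, 6)
    p <- stats::runif(1, 1e-8, 1 - 1e-8)
    expect_equal(pburr3(qburr3(p, b, cc, k), b, cc, k), p,
                 tolerance = 1e-10)
    x <- stats::runif(1, 1e-3, 1e3)
    expect_equal(qburr3(pburr3(x, b, cc, k), b, cc, k), x,
                 tolerance = 1e-8 * x)
  }
})

test_that("Burr III reduces to the log-logistic at k = 1", {
  x <- 10^seq(-3, 3, length.out = 40)
  b <- 2.5; cc <- 1.7
  expect_equal(pburr3(x, b, cc, 1),
               stats::plogis(cc * (log(x) - log(b))), tolerance = 1e-12)
})

test_that("Burr III MLE recovers tail quantiles and dominates bad fits", {
  set.seed(42)
  x <- rburr3(2000, 10, 2, 1.5)
  f <- burr3_mle(x)
  q5_true <- qburr3(0.05, 10, 2, 1.5)
  expect_lt(abs(dist_quantile(f, 0.05) - q5_true) / q5_true, 0.10)

  # log-logistic data: fitted D beats a deliberately wrong fit (k = 5)
  set.seed(8)
  y <- rburr3(200, 3, 2, 1)
  fy <- burr3_mle(y)
  wrong <- new_sed_fit("burr3", list(b = 3, c = 2, k = 5), length(y), NA)
  expect_lt(fy$ks_D, ks_stat(wrong, y))

  expect_error(burr3_mle(c(1, 2, 3)), "at least 4")
  expect_error(burr3_mle(rep(2, 6)), "degenerate")
})

test_that("Burr III MLE log-likelihood beats random parameter draws", {
  set.seed(21)
  x <- rburr3(100, 8, 1.5, 0.8)
  f <- burr3_mle(x)
  for (i in 1:100) {
    b <- stats::runif(1, 0.5, 50)
    cc <- stats::runif(1, 0.3, 5)
    k <- stats::runif(1, 0.3, 5)
    ll <- sum(dburr3(x, b, cc, k, log = TRUE))
    expect_gte(f$loglik, ll - 1e-9)
  }
})

test_that("KS statistic equals the brute-force gap maximum", {
  f <- new_sed_fit("lnorm", list(mu = 0.5, sigma = 1), 3, NA)
  x <- c(1, 2, 3)
  # brute force over all 6 one-sided gaps
  Fx <- stats::plnorm(sort(x), 0.5, 1)
  gaps <- c(abs((1:3) / 3 - Fx), abs(Fx - (0:2) / 3))
  expect_equal(ks_stat(f, x), max(gaps))
  # invariant to sample order
  expect_equal(ks_stat(f, c(3, 1, 2)), ks_stat(f, x))
  # near-minimal D when data sit at the fitted quantiles
  xq <- dist_quantile(f, ((1:20) - 0.5) / 20)
  expect_lt(ks_stat(f, xq), 0.03)
})

test_that("parametric-bootstrap KS p-values are calibrated under the null", {
  expect_error(ks_test(lognormal_mle(c(1, 2, 3)), c(1, 2, 3), n_boot = 50),
               ">= 99")
  rej <- logical(200)
  for (i in seq_len(200)) {
    set.seed(i)
    x <- stats::rlnorm(50, 1, 0.6)
    f <- lognormal_mle(x)
    rej[i] <- ks_test(f, x, n_boot = 99, seed = i + 500)$ks_p < 0.05
  }
  # nominal 5% rejection; binomial band for 200 repetitions
  expect_gte(mean(rej), 0.005)
  expect_lte(mean(rej), 0.105)
})

test_that("fit_pdd returns both families and selects by smaller KS D", {
  x <- element_column(wami_table(), "As")
  pdd <- fit_pdd(x)
  expect_s3_class(pdd$lnorm, "sed_fit")
  expect_s3_class(pdd$burr3, "sed_fit")
  expect_equal(pdd$selected,
               if (pdd$burr3$ks_D < pdd$lnorm$ks_D) "burr3" else "lnorm")
  for (seed in 1:5) {
    set.seed(seed)
    y <- stats::rlnorm(20, 1, 0.5)
    p <- fit_pdd(y)
    expect_equal(p$selected,
                 if (p$burr3$ks_D < p$lnorm$ks_D) "burr3" else "lnorm")
  }
  expect_error(fit_pdd(rep(3, 10)), "degenerate")
})
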