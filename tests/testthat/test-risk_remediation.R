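test_that("convolving a distribution with itself gives one half", {
  # identical families and parameters, constructed independently
  set.seed(2)
  x <- stats::rlnorm(50, 1, 0.5)
  fl <- lognormal_mle(x)
  expect_equal(fraction_affected(fl, fl), 0.5, tolerance = 1e-6)
  b3a <- new_sed_fit("burr3", list(b = 7, c = 1.4, k = 0.9), 30, NA)
  b3b <- new_sed_fit("burr3", list(b = 7, c = 1.4, k = 0.9), 30, NA)
  expect_equal(fraction_affected(b3a, b3b), 0.5, tolerance = 1e-6)
  # mixed families, same distribution only in the identity sense above
  ln <- new_sed_fit("lnorm", list(mu = 2, sigma = 0.7), 30, NA)
  expect_equal(fraction_affected(ln, ln), 0.5, tolerance = 1e-6)
})

test_that("well-separated exposure and effects give near-zero risk", {
  ssd <- new_sed_fit("burr3", list(b = 100, c = 2, k = 1.2), 30, NA)
  q_low <- dist_quantile(ssd, 0.001)
  pdd <- new_sed_fit("lnorm", list(mu = log(q_low) - log(1e5),
                                   sigma = 0.4), 20, NA)
  expect_lt(fraction_affected(pdd, ssd), 0.001)
})

test_that("quadrature convolution matches the Monte-Carlo oracle", {
  set.seed(31)
  for (i in 1:8) {
    pdd <- new_sed_fit("lnorm",
                       list(mu = stats::runif(1, -1, 4),
                            sigma = stats::runif(1, 0.3, 1.2)), 20, NA)
    ssd <- new_sed_fit("burr3",
                       list(b = stats::runif(1, 0.5, 100),
                            c = stats::runif(1, 0.8, 3),
                            k = stats::runif(1, 0.4, 2)), 30, NA)
    quad <- fraction_affected(pdd, ssd)
    draws <- dist_rand(pdd, 1e5)
    mc <- dist_cdf(ssd, draws)
    se <- stats::sd(mc) / sqrt(1e5)
    expect_lt(abs(quad - mean(mc)), 3 * se + 1e-6)
  }
})

test_that("risk is monotone under upward scaling of the exposure", {
  pdd <- new_sed_fit("lnorm", list(mu = 1, sigma = 0.6), 20, NA)
  ssd <- new_sed_fit("burr3", list(b = 30, c = 1.8, k = 1.2), 30, NA)
  fr <- sapply(c(0.2, 0.5, 1, 2, 5), function(s)
    fraction_affected(scale_fit(pdd, s), ssd))
  expect_true(all(diff(fr) > 0))
  expect_true(all(fr >= 0 & fr <= 1))
  # scaling rules preserve shape: quantiles scale linearly
  expect_equal(dist_quantile(scale_fit(pdd, 2), 0.3),
               2 * dist_quantile(pdd, 0.3))
  expect_equal(dist_quantile(scale_fit(ssd, 0.5), 0.3),
               0.5 * dist_quantile(ssd, 0.3))
})

test_that("species_affected matches its structural identities", {
  # exposure drawn from the same distribution as the SSD: about 50%
  spec <- scenario_spec("Cd", ssd_family = "lnorm",
                        ssd_params = list(mu = 2, sigma = 0.8),
                        n_species = 200, seed = 5)
  tox <- gen_toxicity(spec)
  set.seed(6)
  expo <- stats::rlnorm(200, 2, 0.8)
  rr <- species_affected(expo, tox, pdd_family = "lnorm",
                         ssd_family = "lnorm")
  expect_equal(rr$percent_affected, 50, tolerance = 0.15 * 50)

  # exposure far below the SSD: about 0%
  rr0 <- species_affected(expo / 1e6, tox, pdd_family = "lnorm",
                          ssd_family = "lnorm")
  expect_lt(rr0$percent_affected, 0.1)
  expect_error(species_affected(expo, tox, confidence_percent = 49),
               "\\[50, 99.9\\]")
})

test_that("reduction to a target median is the closed-form percentage", {
  expect_equal(round(required_reduction_to_target(360, 0.8), 1), 99.8)
  expect_equal(required_reduction_to_target(1330, 1618.7), 0)
  expect_equal(required_reduction_to_target(5, 5), 0)
  expect_error(required_reduction_to_target(-1, 2), "positive")
  expect_error(required_reduction_to_target(2, 0), "positive")
})

test_that("risk-based remediation obeys its defining inequalities", {
  set.seed(4)
  expo <- stats::rlnorm(20, log(5), 0.5)
  tox <- make_tox(30, "burr3", list(b = 0.5, c = 1.8, k = 1.2), seed = 13)

  # tightening the allowed impact gives nondecreasing reductions
  rems <- lapply(c(25, 10, 5), function(np)
    required_reduction_for_risk(expo, tox, np, confidence_percent = 50,
                                seed = 1))
  reds <- sapply(rems, `[[`, "required_reduction_percent")
  tars <- sapply(rems, `[[`, "median_target")
  expect_true(all(diff(reds) >= 0))
  expect_true(all(diff(tars) <= 0))

  # the returned scale satisfies the criterion when risk is recomputed
  for (i in seq_along(rems)) {
    pdd <- fit_pdd(expo); sel <- pdd[[pdd$selected]]
    ssd <- fit_ssd(tox)
    achieved <- 100 * fraction_affected(scale_fit(sel, rems[[i]]$scale),
                                        ssd)
    expect_lte(achieved, rems[[i]]$protection_n_percent + 1e-6)
  }
  # target = scale x current median, and both modes agree through it
  r5 <- rems[[3]]
  expect_equal(r5$median_target, r5$scale * r5$current_median)
  expect_equal(required_reduction_to_target(r5$current_median,
                                            r5$median_target),
               r5$required_reduction_percent, tolerance = 1e-6)
})

test_that("already-compliant exposures need no reduction", {
  tox <- make_tox(30, "burr3", list(b = 1000, c = 1.8, k = 1.2), seed = 2)
  set.seed(9)
  expo <- stats::rlnorm(20, log(0.001), 0.3)
  rem <- required_reduction_for_risk(expo, tox, 5, confidence_percent = 50,
                                     seed = 1)
  expect_equal(rem$required_reduction_percent, 0)
  expect_equal(rem$median_target, rem$current_median)
})

test_that("bisection agrees with a brute-force scan over the scale", {
  set.seed(14)
  expo <- stats::rlnorm(20, log(10), 0.4)
  tox <- make_tox(25, "burr3", list(b = 0.8, c = 1.6, k = 1.1), seed = 3)
  rem <- required_reduction_for_risk(expo, tox, 10,
                                     confidence_percent = 50, seed = 1,
                                     pdd_family = "lnorm")
  pdd <- lognormal_mle(expo)
  ssd <- fit_ssd(tox)
  s_grid <- seq(1e-4, 1, length.out = 1e4)
  risk_g <- vapply(s_grid, function(s)
    100 * fraction_affected(scale_fit(pdd, s), ssd), numeric(1))
  s_brute <- max(s_grid[risk_g <= 10])
  expect_lt(abs(rem$scale - s_brute), 2e-4)
})
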