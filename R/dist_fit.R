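#' Fitted exposure / species-sensitivity distributions
#'
#' A `sed_fit` object holds one fitted distribution: the family
#' (`"lnorm"` or `"burr3"`), its parameters, the sample size, the maximised
#' log-likelihood, the Kolmogorov-Smirnov statistic D against the data it
#' was fitted to, an optional parametric-bootstrap KS p-value (see
#' [ks_test()]), and the optimizer convergence status. The same object
#' represents both an exposure distribution (fitted to station
#' concentrations) and a species sensitivity distribution (fitted to
#' per-species toxicity endpoints).
#'
#' @param family `"lnorm"` or `"burr3"`.
#' @param params named list of parameters (`mu`, `sigma` for log-normal;
#'   `b`, `c`, `k` for Burr III).
#' @param n sample size the fit is based on.
#' @param loglik maximised log-likelihood.
#' @param ks_D Kolmogorov-Smirnov statistic against the fitting data.
#' @param convergence optimizer status (0 = converged; closed-form fits are 0).
#' @param role free-text tag, e.g. `"exposure"` or `"ssd"`.
#' @return an object of class `sed_fit`.
#' @keywords internal
new_sed_fit <- function(family, params, n, loglik, ks_D = NA_real_,
                        convergence = 0L, role = "exposure") {
  stopifnot(family %in% c("lnorm", "burr3"))
  structure(
    list(family = family, params = params, n = n, loglik = loglik,
         ks_D = ks_D, ks_p = NA_real_, convergence = convergence,
         role = role),
    class = "sed_fit"
  )
}

#' @export
print.sed_fit <- function(x, ...) {
  fam <- c(lnorm = "log-normal", burr3 = "Burr Type III")[[x$family]]
  cat(sprintf("%s fit (%s), n = %d\n", fam, x$role, x$n))
  cat("  parameters:",
      paste(names(x$params), signif(unlist(x$params), 5), sep = " = ",
            collapse = ", "), "\n")
  cat(sprintf("  log-likelihood: %.4f\n", x$loglik))
  if (is.finite(x$ks_D)) cat(sprintf("  KS D: %.4f", x$ks_D))
  if (is.finite(x$ks_p)) cat(sprintf("  (bootstrap p = %.3f)", x$ks_p))
  if (is.finite(x$ks_D)) cat("\n")
  invisible(x)
}

#' Evaluate a fitted distribution
#'
#' CDF, density, quantile function and random generation for a [new_sed_fit]
#' object, dispatching on the fitted family.
#'
#' @param fit a `sed_fit` object.
#' @param x,q positive concentrations.
#' @param p probabilities in (0, 1).
#' @param n number of random draws.
#' @return numeric vector.
#' @export
dist_cdf <- function(fit, q) {
  stopifnot(inherits(fit, "sed_fit"))
  switch(fit$family,
    lnorm = stats::plnorm(q, fit$params$mu, fit$params$sigma),
    burr3 = pburr3(q, fit$params$b, fit$params$c, fit$params$k))
}

#' @rdname dist_cdf
#' @export
dist_quantile <- function(fit, p) {
  stopifnot(inherits(fit, "sed_fit"))
  switch(fit$family,
    lnorm = stats::qlnorm(p, fit$params$mu, fit$params$sigma),
    burr3 = qburr3(p, fit$params$b, fit$params$c, fit$params$k))
}

#' @rdname dist_cdf
#' @export
dist_density <- function(fit, x) {
  stopifnot(inherits(fit, "sed_fit"))
  switch(fit$family,
    lnorm = stats::dlnorm(x, fit$params$mu, fit$params$sigma),
    burr3 = dburr3(x, fit$params$b, fit$params$c, fit$params$k))
}

#' @rdname dist_cdf
#' @export
dist_rand <- function(fit, n) {
  stopifnot(inherits(fit, "sed_fit"))
  switch(fit$family,
    lnorm = stats::rlnorm(n, fit$params$mu, fit$params$sigma),
    burr3 = rburr3(n, fit$params$b, fit$params$c, fit$params$k))
}

#' Fitted median
#' @param fit a `sed_fit` object.
#' @return the distribution median (0.5 quantile).
#' @export
dist_median <- function(fit) dist_quantile(fit, 0.5)

.check_fit_samples <- function(x, min_n, what = "samples") {
  if (!is.numeric(x) || anyNA(x)) stop(what, " must be numeric without NAs",
                                       call. = FALSE)
  if (length(x) < min_n) {
    stop("need at least ", min_n, " ", what, ", got ", length(x),
         call. = FALSE)
  }
  if (any(x <= 0)) stop("all ", what, " must be strictly positive",
                        call. = FALSE)
  if (max(x) == min(x)) {
    stop("degenerate data: all ", what, " are identical (",
         format(x[1]), ")", call. = FALSE)
  }
  invisible(x)
}

#' Maximum-likelihood log-normal fit
#'
#' Closed-form MLE: `mu` is the mean of the log samples and `sigma` the
#' maximum-likelihood (divisor n) standard deviation of the log samples.
#'
#' @param x positive concentrations, n >= 3, not all equal.
#' @param role tag stored on the result (`"exposure"` or `"ssd"`).
#' @return a [new_sed_fit] object of family `"lnorm"` with the KS statistic
#'   against `x` populated.
#' @examples
#' fit <- lognormal_mle(c(1, exp(2)) * rep(1, 2))  # mu = 1, sigma = 1
#' @export
lognormal_mle <- function(x, role = "exposure") {
  .check_fit_samples(x, 3L)
  lx <- log(x)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))
  ll <- sum(stats::dlnorm(x, mu, sigma, log = TRUE))
  fit <- new_sed_fit("lnorm", list(mu = mu, sigma = sigma), length(x), ll)
  fit$ks_D <- ks_stat(fit, x)
  fit$role <- role
  fit
}

.burr3_nll <- function(theta, x) {
  # theta = log(b, c, k)
  p <- exp(theta)
  nll <- -sum(dburr3(x, p[1], p[2], p[3], log = TRUE))
  if (!is.finite(nll)) 1e10 else nll
}

#' Maximum-likelihood Burr Type III fit
#'
#' Fits the three-parameter Burr III distribution by direct likelihood
#' maximisation on log-transformed parameters. The Burr III likelihood
#' surface is notoriously flat in the two shape parameters, so the optimizer
#' is started from a method-of-moments log-logistic fit (the `k = 1`
#' submodel, for which `log X` is logistic with location `log b` and scale
#' `1/c`) and, unless `multi_start = FALSE`, from a 3x3 grid of scalings of
#' `(c, k)` around that point. Log-scale parameters are kept within
#' `[1e-3, 1e3]` via a box penalty. The achieved log-likelihood is never
#' below the log-logistic starting value because that point is itself a
#' candidate.
#'
#' @param x positive concentrations, n >= 4, not all equal.
#' @param init optional named list/vector `(b, c, k)` used as the single
#'   starting point (used for fast bootstrap refits from a parent fit).
#' @param multi_start logical; use the 3x3 (c, k) start grid.
#' @param role tag stored on the result.
#' @return a [new_sed_fit] object of family `"burr3"`.
#' @export
burr3_mle <- function(x, init = NULL, multi_start = is.null(init),
                      role = "exposure") {
  .check_fit_samples(x, 4L)
  lx <- log(x)
  # log-logistic (k = 1) moment start: logistic sd = pi/(sqrt(3) c)
  s_l <- stats::sd(lx)
  start0 <- c(stats::median(lx), log(pi / (sqrt(3) * s_l)), 0)
  starts <- list()
  if (!is.null(init)) {
    init <- unlist(init)[c("b", "c", "k")]
    starts <- c(starts, list(log(init)))
  }
  if (multi_start) {
    for (sc in c(0.5, 1, 2)) for (sk in c(0.5, 1, 2)) {
      starts <- c(starts, list(c(start0[1], start0[2] + log(sc), log(sk))))
    }
  }
  if (!length(starts)) starts <- list(start0)

  lb <- log(1e-3); ub <- log(1e3)
  pen_nll <- function(theta, x) {
    over <- sum(pmax(theta - ub, 0)^2 + pmax(lb - theta, 0)^2)
    .burr3_nll(pmin(pmax(theta, lb), ub), x) + 1e4 * over
  }
  # single-start refits (bootstrap) use a lighter convergence budget
  ctrl <- if (multi_start) list(maxit = 2000, reltol = 1e-10)
          else list(maxit = 500, reltol = 1e-8)
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      stats::optim(s, pen_nll, x = x, method = "Nelder-Mead", control = ctrl),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    stop("Burr III fit failed to converge from any starting point",
         call. = FALSE)
  }
  if (multi_start) {
    # polish with one more restart from the winner
    theta <- pmin(pmax(best$par, lb), ub)
    opt2 <- stats::optim(theta, pen_nll, x = x, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-12))
    if (is.finite(opt2$value) && opt2$value < best$value) best <- opt2
  }
  theta <- pmin(pmax(best$par, lb), ub)
  p <- exp(theta)
  ll <- sum(dburr3(x, p[1], p[2], p[3], log = TRUE))
  ll_start <- -.burr3_nll(start0, x)
  if (ll < ll_start - 1e-6) {
    # never accept worse than the log-logistic initialization
    p <- exp(start0)
    ll <- ll_start
  }
  fit <- new_sed_fit("burr3", list(b = p[1], c = p[2], k = p[3]),
                     length(x), ll, convergence = best$convergence)
  fit$ks_D <- ks_stat(fit, x)
  fit$role <- role
  fit
}

#' Kolmogorov-Smirnov statistic of a fit against data
#'
#' D is the supremum distance between the empirical CDF and the fitted CDF,
#' evaluated at every order statistic using both one-sided gaps
#' (i/n - F(x_(i)) and F(x_(i)) - (i-1)/n), so ties are handled correctly.
#'
#' @param fit a `sed_fit` object.
#' @param x the sample.
#' @return D in [0, 1].
#' @export
ks_stat <- function(fit, x) {
  xs <- sort(x)
  n <- length(xs)
  Fx <- dist_cdf(fit, xs)
  max(seq_len(n) / n - Fx, Fx - (seq_len(n) - 1) / n)
}

#' Kolmogorov-Smirnov goodness of fit with parametric-bootstrap p-value
#'
#' Because the fitted parameters are estimated from the same sample, the
#' classical KS null table is anti-conservative. The p-value here is the
#' parametric-bootstrap tail fraction: `n_boot` synthetic samples of size n
#' are drawn from the fitted distribution, the same family is refitted to
#' each (Burr III refits start from the parent parameters), and p is the
#' fraction of bootstrap D statistics at least as large as the observed D,
#' with the usual +1 continuity correction.
#'
#' @param fit a `sed_fit` produced from `x`.
#' @param x the sample the fit was estimated from.
#' @param n_boot bootstrap replicates, >= 99.
#' @param seed integer seed driving the bootstrap draws.
#' @return the `fit` with `ks_D` and `ks_p` populated (also returned in
#'   `$ks_D` / `$ks_p`).
#' @export
ks_test <- function(fit, x, n_boot = 999, seed = 1) {
  stopifnot(inherits(fit, "sed_fit"))
  if (n_boot < 99) {
    stop("n_boot must be >= 99 for a usable p-value resolution",
         call. = FALSE)
  }
  D <- ks_stat(fit, x)
  n <- length(x)
  Dboot <- rep(NA_real_, n_boot)
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    xb <- dist_rand(fit, n)
    fb <- tryCatch(
      if (fit$family == "lnorm") lognormal_mle(xb)
      else burr3_mle(xb, init = fit$params, multi_start = FALSE),
      error = function(e) NULL)
    if (!is.null(fb)) Dboot[b] <- fb$ks_D
  }
  Dboot <- Dboot[is.finite(Dboot)]
  p <- (1 + sum(Dboot >= D)) / (length(Dboot) + 1)
  fit$ks_D <- D
  fit$ks_p <- p
  fit
}

#' Fit an exposure distribution, both families
#'
#' Fits the log-normal and Burr Type III distributions to a concentration
#' sample (the tier-2 exposure distribution; equally used for species
#' sensitivity data via [fit_ssd()]) and selects the family with the smaller
#' Kolmogorov-Smirnov D; ties go to the log-normal. When `n_boot` is given,
#' bootstrap KS p-values are attached to both fits.
#'
#' @param x positive concentrations (station means).
#' @param n_boot optional KS bootstrap replicates (>= 99); `NULL` skips the
#'   p-value and keeps the deterministic D.
#' @param seed seed for the KS bootstrap.
#' @return a list of class `sed_pdd` with components `lnorm`, `burr3`
#'   (both `sed_fit`), and `selected` (`"lnorm"` or `"burr3"`).
#' @export
fit_pdd <- function(x, n_boot = NULL, seed = 1) {
  fl <- lognormal_mle(x)
  fb <- burr3_mle(x)
  if (!is.null(n_boot)) {
    fl <- ks_test(fl, x, n_boot = n_boot, seed = seed)
    fb <- ks_test(fb, x, n_boot = n_boot, seed = seed + 1L)
  }
  selected <- if (fb$ks_D < fl$ks_D) "burr3" else "lnorm"
  structure(list(lnorm = fl, burr3 = fb, selected = selected),
            class = "sed_pdd")
}

#' @export
print.sed_pdd <- function(x, ...) {
  cat("Exposure distribution fits (n =", x$lnorm$n, ")\n")
  cat(sprintf("  log-normal:    KS D = %.4f\n", x$lnorm$ks_D))
  cat(sprintf("  Burr III:      KS D = %.4f\n", x$burr3$ks_D))
  cat("  selected:", c(lnorm = "log-normal", burr3 = "Burr III")[x$selected],
      "\n")
  invisible(x)
}
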