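#' Fit a species sensitivity distribution
#'
#' Fits the chosen family to per-species toxicity endpoints. The Burr Type
#' III family is the default (three parameters, flexible left tail); the
#' log-normal is available by flag. `family = "auto"` fits both and keeps
#' the smaller Kolmogorov-Smirnov D, ties to log-normal.
#'
#' @param tox a [toxicity_dataset] (>= 4 records for Burr III, >= 3 for
#'   log-normal).
#' @param family `"burr3"`, `"lnorm"`, or `"auto"`.
#' @return a `sed_fit` tagged with role `"ssd"`.
#' @export
fit_ssd <- function(tox, family = c("burr3", "lnorm", "auto")) {
  stopifnot(inherits(tox, "toxicity_dataset"))
  family <- match.arg(family)
  x <- tox$concentration
  if (family == "auto") {
    pdd <- fit_pdd(x)
    fit <- pdd[[pdd$selected]]
  } else if (family == "burr3") {
    fit <- burr3_mle(x)
  } else {
    fit <- lognormal_mle(x)
  }
  fit$role <- "ssd"
  fit$element <- tox$element
  fit
}

#' Hazardous concentration point estimate
#'
#' `HC_n`, the concentration affecting `n_percent` of species: the
#' `n_percent/100` quantile of the fitted species sensitivity distribution.
#'
#' @param ssd a fitted SSD (`sed_fit`).
#' @param n_percent percent of species affected, in (0, 100).
#' @return concentration in the SSD's (canonical) units.
#' @export
hc_point <- function(ssd, n_percent) {
  if (any(n_percent <= 0 | n_percent >= 100)) {
    stop("n_percent must lie strictly between 0 and 100", call. = FALSE)
  }
  dist_quantile(ssd, n_percent / 100)
}

# Shared bootstrap engine: resample species with replacement, refit,
# return a replicate x n-level matrix of HC values. Burr III refits are
# started from the parent fit's parameters. Failed or degenerate refits
# are dropped (NA rows) and counted by the caller.
.hc_bootstrap <- function(tox, n_percent, n_boot, seed, family) {
  x <- tox$concentration
  n <- length(x)
  parent <- fit_ssd(tox, family = family)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  reps <- matrix(NA_real_, n_boot, length(n_percent))
  for (b in seq_len(n_boot)) {
    xb <- x[idx[b, ]]
    fb <- tryCatch({
      if (family == "burr3") {
        burr3_mle(xb, init = parent$params, multi_start = FALSE)
      } else {
        lognormal_mle(xb)
      }
    }, error = function(e) NULL)
    if (!is.null(fb)) reps[b, ] <- dist_quantile(fb, n_percent / 100)
  }
  list(reps = reps, parent = parent,
       n_failed = sum(!stats::complete.cases(reps)))
}

#' Hazardous concentration with bootstrap lower confidence limit
#'
#' Estimates `HC_n;p` — the concentration affecting `n_percent` of species,
#' reported at the `confidence_percent` lower confidence limit — by
#' nonparametric bootstrap over species: records are resampled with
#' replacement, the SSD is refitted to each replicate and its
#' `n_percent/100` quantile recorded. `HC_n;p` is the `(100 - p)`th
#' percentile of the replicate HC distribution, so `HC_n;50` is the
#' replicate median and `HC_n;95` a conservative lower bound. Replicates
#' whose refit fails are dropped and counted; more than 20% failures is an
#' error.
#'
#' @param tox a [toxicity_dataset].
#' @param n_percent percent of species affected, in (0, 100).
#' @param confidence_percent lower confidence level p in \[50, 99.9\].
#' @param n_boot bootstrap replicates (>= 500 when `confidence_percent`
#'   is 95 or more; default 2000).
#' @param seed integer seed; results are reproducible bit-for-bit given
#'   (seed, n_boot).
#' @param family SSD family, default Burr III.
#' @return object of class `hc_estimate`: `value` (HC_n;p), the MLE
#'   `point_estimate`, and the bootstrap summary.
#' @export
hc_confidence <- function(tox, n_percent, confidence_percent,
                          n_boot = 2000, seed = 1,
                          family = c("burr3", "lnorm")) {
  family <- match.arg(family)
  stopifnot(length(n_percent) == 1, length(confidence_percent) == 1)
  if (confidence_percent < 50 || confidence_percent > 99.9) {
    stop("confidence_percent must lie in [50, 99.9]", call. = FALSE)
  }
  if (confidence_percent >= 95 && n_boot < 500) {
    stop("n_boot must be >= 500 for a 95% lower confidence limit",
         call. = FALSE)
  }
  bt <- .hc_bootstrap(tox, n_percent, n_boot, seed, family)
  fail_rate <- bt$n_failed / n_boot
  if (fail_rate > 0.2) {
    stop(sprintf("bootstrap refit failure rate %.1f%% exceeds 20%%",
                 100 * fail_rate), call. = FALSE)
  }
  hc <- bt$reps[is.finite(bt$reps[, 1]), 1]
  value <- unname(stats::quantile(hc, (100 - confidence_percent) / 100))
  point <- hc_point(bt$parent, n_percent)
  structure(
    list(n_percent = n_percent, confidence_percent = confidence_percent,
         value = value, point_estimate = point, family = family,
         n_boot = n_boot, n_failed = bt$n_failed, seed = seed,
         element = tox$element),
    class = "hc_estimate")
}

#' @export
print.hc_estimate <- function(x, ...) {
  cat(sprintf("HC%g;%g = %.4g mg/kg dw (%s SSD; MLE point %.4g)\n",
              x$n_percent, x$confidence_percent, x$value, x$family,
              x$point_estimate))
  cat(sprintf("  bootstrap: %d replicates, %d failed, seed %d\n",
              x$n_boot, x$n_failed, x$seed))
  invisible(x)
}

#' Hazardous concentration table
#'
#' Computes `HC_n;p` for every combination of the requested species-affected
#' levels and confidence levels from a single bootstrap replicate set, so
#' all entries are mutually consistent: for fixed confidence the HC is
#' nondecreasing in `n`, and for fixed `n` the value at higher confidence is
#' no larger. Both orderings are asserted on every output.
#'
#' @param tox a [toxicity_dataset].
#' @param n_percent vector of species-affected levels (default 5, 10, 25).
#' @param confidence_percent vector of lower confidence levels
#'   (default 50, 95).
#' @inheritParams hc_confidence
#' @return data.frame of class `hc_table`: one row per element with one
#'   column `HC<n>_<p>` per combination, in mg/kg dw, plus the failed
#'   replicate count.
#' @export
hc_table <- function(tox, n_percent = c(5, 10, 25),
                     confidence_percent = c(50, 95), n_boot = 2000,
                     seed = 1, family = c("burr3", "lnorm")) {
  family <- match.arg(family)
  if (any(confidence_percent >= 95) && n_boot < 500) {
    stop("n_boot must be >= 500 for a 95% lower confidence limit",
         call. = FALSE)
  }
  n_percent <- sort(n_percent)
  bt <- .hc_bootstrap(tox, n_percent, n_boot, seed, family)
  if (bt$n_failed / n_boot > 0.2) {
    stop(sprintf("bootstrap refit failure rate %.1f%% exceeds 20%%",
                 100 * bt$n_failed / n_boot), call. = FALSE)
  }
  keep <- stats::complete.cases(bt$reps)
  out <- data.frame(element = tox$element)
  vals <- matrix(NA_real_, length(n_percent), length(confidence_percent))
  for (i in seq_along(n_percent)) {
    hc <- bt$reps[keep, i]
    for (j in seq_along(confidence_percent)) {
      vals[i, j] <- unname(
        stats::quantile(hc, (100 - confidence_percent[j]) / 100))
      out[[sprintf("HC%g_%g", n_percent[i], confidence_percent[j])]] <-
        vals[i, j]
    }
  }
  # monotone in n at fixed confidence; antitone in confidence at fixed n
  stopifnot(all(apply(vals, 2, diff) >= 0))
  ord <- order(confidence_percent)
  stopifnot(all(apply(vals[, ord, drop = FALSE], 1, diff) <= 0))
  out$n_boot <- n_boot
  out$n_failed <- bt$n_failed
  attr(out, "seed") <- seed
  attr(out, "family") <- family
  class(out) <- c("hc_table", class(out))
  out
}
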