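#' The Burr Type III distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the three-parameter Burr Type III distribution with cumulative
#' distribution function
#' \deqn{F(x) = \left(1 + (b/x)^c\right)^{-k}, \quad x > 0,}
#' where `b > 0` is a scale parameter (in concentration units) and
#' `c > 0`, `k > 0` are shape parameters. At `k = 1` the distribution
#' reduces to the log-logistic. Burr III is the standard flexible family for
#' species sensitivity distributions; its left tail controls the hazardous
#' concentrations that protect most species.
#'
#' Probabilities are computed in log space so that extreme arguments
#' (`x` far into either tail) do not overflow `(b/x)^c`.
#'
#' @param x,q vector of positive quantiles (concentrations).
#' @param p vector of probabilities in (0, 1).
#' @param n number of draws.
#' @param b scale parameter, > 0.
#' @param c shape parameter, > 0.
#' @param k shape parameter, > 0.
#' @param log,log.p logical; if TRUE, densities/probabilities are on the
#'   log scale.
#' @return `dburr3` the density, `pburr3` the CDF, `qburr3` the quantile
#'   function (exact inverse of `pburr3`), `rburr3` random draws.
#' @examples
#' pburr3(1, b = 1, c = 1, k = 1)   # 0.5
#' qburr3(0.5, b = 5, c = 2.3, k = 1)  # 5: F(b) = 0.5 whenever k = 1
#' @name burr3
NULL

.check_burr3 <- function(b, c, k) {
  if (!all(is.finite(b), is.finite(c), is.finite(k)) ||
      any(b <= 0, c <= 0, k <= 0)) {
    stop("Burr III parameters b, c, k must all be finite and > 0",
         call. = FALSE)
  }
}

# log(1 + exp(t)) without overflow
.log1pexp <- function(t) {
  out <- t
  lo <- t <= 35
  out[lo] <- log1p(exp(t[lo]))
  out
}

#' @rdname burr3
#' @export
pburr3 <- function(q, b, c, k, log.p = FALSE) {
  .check_burr3(b, c, k)
  if (any(!is.finite(q) & !is.infinite(q)) || any(q <= 0)) {
    stop("Burr III CDF is defined for concentrations x > 0", call. = FALSE)
  }
  # log F = -k * log(1 + (b/x)^c), with (b/x)^c = exp(c*(log b - log x))
  t <- c * (log(b) - log(q))
  logF <- -k * .log1pexp(t)
  if (log.p) logF else exp(logF)
}

#' @rdname burr3
#' @export
dburr3 <- function(x, b, c, k, log = FALSE) {
  .check_burr3(b, c, k)
  if (any(x <= 0)) stop("Burr III density is defined for x > 0", call. = FALSE)
  t <- c * (log(b) - log(x))
  logf <- log(k) + log(c) + t - log(x) - (k + 1) * .log1pexp(t)
  if (log) logf else exp(logf)
}

#' @rdname burr3
#' @export
qburr3 <- function(p, b, c, k, log.p = FALSE) {
  .check_burr3(b, c, k)
  lp <- if (log.p) p else log(p)
  if (any(!is.finite(lp) | lp >= 0)) {
    stop("Burr III quantiles require probabilities strictly inside (0, 1)",
         call. = FALSE)
  }
  # x = b / (p^(-1/k) - 1)^(1/c); p^(-1/k) - 1 = expm1(-log(p)/k)
  exp(log(b) - log(expm1(-lp / k)) / c)
}

#' @rdname burr3
#' @export
rburr3 <- function(n, b, c, k) {
  qburr3(stats::runif(n), b, c, k)
}
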