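#' Tier-1 guideline screening
#'
#' Compares every station concentration against the low and high guideline
#' trigger values for its element. An exceedance is a strict inequality
#' (value > trigger), so a concentration exactly at the guideline is not
#' alarming. Alongside the desk comparison, an exposure distribution is
#' fitted per element (both families, see [fit_pdd()]) and two
#' distributional diagnostics are reported: the fitted probability of
#' exceeding the low trigger and the fitted `q`-quantile (default the 99th
#' percentile) of the selected family, whose position relative to the low
#' trigger is the tier-1 pass flag.
#'
#' Guideline units are reconciled to the exposure table's unit before
#' comparison. Elements in the table but absent from the guideline set are
#' reported with `screened = FALSE` rather than erroring.
#'
#' @param table an [exposure_table].
#' @param guidelines a [guideline_set].
#' @param q guard quantile for the fitted-distribution check (default 0.99).
#' @param fit logical; set `FALSE` to skip distribution fitting and report
#'   only measured exceedances.
#' @return a data.frame of class `screening_result` with one row per
#'   element: exceedance counts and sorted station identities for both
#'   triggers, fitted-exceedance probability of the low trigger, the fitted
#'   `q` quantile for both families and the selected family, and the
#'   pass flag `quantile(q) < low trigger`.
#' @examples
#' tab <- read_exposure_table(sedrisk_example("wami_table3.csv"))
#' gl <- suppressWarnings(read_guidelines(sedrisk_example("isqg_table2.csv")))
#' screen_exposure(tab, gl, fit = FALSE)
#' @export
screen_exposure <- function(table, guidelines, q = 0.99, fit = TRUE) {
  stopifnot(inherits(table, "exposure_table"),
            inherits(guidelines, "guideline_set"))
  rows <- lapply(table$elements, function(e) {
    x <- element_column(table, e)
    screened <- e %in% guidelines$elements
    low <- high <- NA_real_
    n_low <- n_high <- NA_integer_
    st_low <- st_high <- ""
    if (screened) {
      low <- convert_units(guidelines$low[[e]], guidelines$unit, table$unit)
      high <- convert_units(guidelines$high[[e]], guidelines$unit, table$unit)
      i_low <- which(x > low)
      i_high <- which(x > high)
      n_low <- length(i_low); n_high <- length(i_high)
      st_low <- paste(sort(table$stations[i_low]), collapse = ";")
      st_high <- paste(sort(table$stations[i_high]), collapse = ";")
    }
    out <- data.frame(
      element = e, screened = screened, low_trigger = low,
      high_trigger = high, n_exceed_low = n_low, n_exceed_high = n_high,
      stations_low = st_low, stations_high = st_high,
      p_exceed_low = NA_real_, family = NA_character_,
      q_lnorm = NA_real_, q_burr3 = NA_real_, q_selected = NA_real_,
      pass = NA)
    if (fit) {
      pdd <- fit_pdd(x)
      sel <- pdd[[pdd$selected]]
      out$family <- pdd$selected
      out$q_lnorm <- dist_quantile(pdd$lnorm, q)
      out$q_burr3 <- dist_quantile(pdd$burr3, q)
      out$q_selected <- dist_quantile(sel, q)
      if (screened) {
        out$p_exceed_low <- exceedance_probability(sel, low)
        out$pass <- out$q_selected < low
      }
    }
    out
  })
  out <- do.call(rbind, rows)
  attr(out, "unit") <- table$unit
  attr(out, "q") <- q
  class(out) <- c("screening_result", class(out))
  out
}

#' Probability that a fitted distribution exceeds a threshold
#'
#' `1 - F(threshold)` under the fitted exposure distribution: the degree to
#' which the contaminant data are likely to exceed a guideline value.
#'
#' @param fit a `sed_fit` object.
#' @param threshold positive concentration in the fit's units.
#' @return probability in \[0, 1\].
#' @export
exceedance_probability <- function(fit, threshold) {
  stopifnot(inherits(fit, "sed_fit"))
  if (!is.numeric(threshold) || any(threshold <= 0)) {
    stop("threshold must be a positive concentration", call. = FALSE)
  }
  1 - dist_cdf(fit, threshold)
}

#' Fitted-quantile guard against a trigger value
#'
#' Passes when the fitted `q` quantile (e.g. the 99th percentile) lies
#' strictly below the trigger concentration — the distributional version of
#' "the element is not of concern".
#'
#' @param fit a `sed_fit` object.
#' @param q probability in (0, 1).
#' @param trigger positive trigger concentration.
#' @return list with `pass` (logical) and `value` (the fitted quantile).
#' @export
percentile_guard <- function(fit, q, trigger) {
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)", call. = FALSE)
  if (trigger <= 0) stop("trigger must be > 0", call. = FALSE)
  value <- dist_quantile(fit, q)
  list(pass = value < trigger, value = value)
}
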