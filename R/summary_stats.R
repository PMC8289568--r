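#' Per-element descriptive statistics
#'
#' Arithmetic mean, sample standard deviation (n - 1 denominator) and
#' empirical median (mean of the two central order statistics for even n)
#' of each element column of an exposure table. With a single station the
#' SD is undefined and reported as `NA` with `sd_defined = FALSE`.
#'
#' @param table an [exposure_table].
#' @return data.frame with columns `element`, `n`, `mean`, `sd`, `median`,
#'   `min`, `max`, `sd_defined`, in the table's unit.
#' @examples
#' tab <- read_exposure_table(sedrisk_example("wami_table3.csv"))
#' element_summary(tab)
#' @export
element_summary <- function(table) {
  stopifnot(inherits(table, "exposure_table"))
  rows <- lapply(table$elements, function(e) {
    x <- element_column(table, e)
    n <- length(x)
    data.frame(element = e, n = n, mean = mean(x),
               sd = if (n > 1) stats::sd(x) else NA_real_,
               median = stats::median(x), min = min(x), max = max(x),
               sd_defined = n > 1)
  })
  out <- do.call(rbind, rows)
  attr(out, "unit") <- table$unit
  out
}

#' Pearson correlation matrix with significance flags
#'
#' Product-moment correlations between element concentration columns
#' (station means), with two-tailed p-values from the exact t transform
#' `t = r sqrt(n-2) / sqrt(1 - r^2)` on n - 2 degrees of freedom, and
#' significance flags at `alpha`. Metals whose concentrations correlate
#' significantly are conventionally read as sharing a source.
#'
#' @param table an [exposure_table] with >= 3 stations.
#' @param alpha two-tailed significance level (default 0.05).
#' @return object of class `correlation_matrix`: list with matrices `r`,
#'   `p`, logical `significant`, and `n`. Diagonal p-values are `NA`.
#' @export
pearson_matrix <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "exposure_table"))
  m <- table$mean_conc
  n <- nrow(m)
  if (n < 3) stop("need >= 3 stations for correlation analysis",
                  call. = FALSE)
  const <- apply(m, 2, function(x) max(x) == min(x))
  if (any(const)) {
    stop("constant concentration column: ",
         paste(colnames(m)[const], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(m)
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA_real_
  sig <- !is.na(p) & p < alpha
  structure(list(r = r, p = p, significant = sig, n = n, alpha = alpha),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("Pearson correlations (n = %d); * marks p < %g (2-tailed)\n",
              x$n, x$alpha))
  els <- colnames(x$r)
  txt <- matrix("", length(els), length(els), dimnames = list(els, els))
  for (i in seq_along(els)) for (j in seq_len(i)) {
    txt[i, j] <- paste0(formatC(x$r[i, j], format = "f", digits = digits),
                        if (isTRUE(x$significant[i, j])) "*" else "")
  }
  print(as.data.frame(txt), right = TRUE)
  invisible(x)
}

#' Write a correlation matrix as a lower-triangle CSV
#'
#' Mirrors the conventional report layout: lower triangle, 2 dp, asterisk
#' on entries significant at the stored alpha.
#'
#' @param cm a [pearson_matrix()] result.
#' @param path output CSV path.
#' @param digits rounding for display (unrounded values stay in `cm`).
#' @return `path`, invisibly.
#' @export
write_correlation <- function(cm, path, digits = 2) {
  stopifnot(inherits(cm, "correlation_matrix"))
  els <- colnames(cm$r)
  txt <- matrix("", length(els), length(els), dimnames = list(els, els))
  for (i in seq_along(els)) for (j in seq_len(i)) {
    txt[i, j] <- paste0(formatC(cm$r[i, j], format = "f", digits = digits),
                        if (isTRUE(cm$significant[i, j])) "*" else "")
  }
  utils::write.csv(data.frame(element = els, txt, check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
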