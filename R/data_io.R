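#' Station-by-element exposure tables
#'
#' An `exposure_table` holds the measured sediment concentration matrix:
#' one row per sampling station, one column per element, on a dry-weight
#' mass-fraction basis with an explicit unit. Per-cell replicate standard
#' deviations may be attached as metadata; all distribution fitting in this
#' package operates on the station means (one pooled composite per station).
#'
#' @param stations character/integer vector of station identifiers.
#' @param mean_conc numeric matrix (stations x elements) of mean
#'   concentrations, all strictly positive; column names are element symbols.
#' @param sd_conc optional matrix of replicate standard deviations, same
#'   shape and unit, all >= 0.
#' @param unit `"mg/kg"` or `"ng/g"` (dry weight).
#' @return an object of class `exposure_table`.
#' @export
exposure_table <- function(stations, mean_conc, sd_conc = NULL,
                           unit = "mg/kg") {
  unit <- normalize_unit(unit)
  mean_conc <- as.matrix(mean_conc)
  if (is.null(colnames(mean_conc))) {
    stop("mean_conc must carry element symbols as column names",
         call. = FALSE)
  }
  if (length(stations) != nrow(mean_conc)) {
    stop("length(stations) must equal nrow(mean_conc)", call. = FALSE)
  }
  if (anyNA(mean_conc)) {
    bad <- which(is.na(mean_conc), arr.ind = TRUE)[1, ]
    stop(sprintf("missing concentration at station %s, element %s",
                 stations[bad[1]], colnames(mean_conc)[bad[2]]),
         call. = FALSE)
  }
  if (any(mean_conc <= 0)) {
    bad <- which(mean_conc <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-positive concentration (%s) at station %s, element %s",
      format(mean_conc[bad[1], bad[2]]), stations[bad[1]],
      colnames(mean_conc)[bad[2]]), call. = FALSE)
  }
  colnames(mean_conc) <- normalize_element(colnames(mean_conc))
  if (!is.null(sd_conc)) {
    sd_conc <- as.matrix(sd_conc)
    stopifnot(all(dim(sd_conc) == dim(mean_conc)))
    colnames(sd_conc) <- colnames(mean_conc)
    if (any(sd_conc < 0, na.rm = TRUE)) {
      stop("replicate standard deviations must be >= 0", call. = FALSE)
    }
  }
  structure(
    list(stations = as.character(stations),
         elements = colnames(mean_conc),
         mean_conc = mean_conc, sd_conc = sd_conc, unit = unit),
    class = "exposure_table")
}

# Known symbols are case-normalized; anything else passes through so the
# tool is not restricted to the six study metals.
normalize_element <- function(el) {
  known <- c("As", "Cd", "Cr", "Cu", "Pb", "Zn")
  idx <- match(tolower(el), tolower(known))
  ifelse(is.na(idx), el, known[idx])
}

#' @export
print.exposure_table <- function(x, ...) {
  cat(sprintf("exposure_table: %d stations x %d elements [%s dw]\n",
              length(x$stations), length(x$elements), x$unit))
  cat("  elements:", paste(x$elements, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.exposure_table <- function(x, ...) {
  df <- data.frame(station = x$stations, x$mean_conc, check.names = FALSE)
  rownames(df) <- NULL
  df
}

#' Extract one element's station means
#' @param table an [exposure_table].
#' @param element element symbol.
#' @return numeric vector of station mean concentrations.
#' @export
element_column <- function(table, element) {
  stopifnot(inherits(table, "exposure_table"))
  element <- normalize_element(element)
  if (!element %in% table$elements) {
    stop("element ", sQuote(element), " not present in the exposure table",
         call. = FALSE)
  }
  as.numeric(table$mean_conc[, element])
}

.read_csv_chr <- function(source) {
  df <- utils::read.csv(source, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  if (nrow(df) == 0 || ncol(df) == 0) {
    stop("empty input: ", source, call. = FALSE)
  }
  df
}

.parse_num <- function(chr, where) {
  v <- suppressWarnings(as.numeric(chr))
  bad <- which(is.na(v) & nzchar(chr))
  if (length(bad)) {
    stop(sprintf("non-numeric value %s at %s", sQuote(chr[bad[1]]),
                 where[bad[1]]), call. = FALSE)
  }
  v[!nzchar(chr)] <- NA_real_
  v
}

#' Read an exposure table from CSV
#'
#' Expected layout: a `station` column, then `<El>_mean` and optional
#' `<El>_sd` columns per element (comma separated, header row, period
#' decimal separator). Row and column order are preserved.
#'
#' @param source path to a CSV file (or connection).
#' @param unit unit of all concentration columns.
#' @return an [exposure_table].
#' @export
read_exposure_table <- function(source, unit = "mg/kg") {
  df <- .read_csv_chr(source)
  if (!"station" %in% names(df)) {
    stop("exposure CSV must have a 'station' column", call. = FALSE)
  }
  mean_cols <- grep("_mean$", names(df), value = TRUE)
  if (!length(mean_cols)) {
    stop("exposure CSV has no '<element>_mean' columns", call. = FALSE)
  }
  els <- sub("_mean$", "", mean_cols)
  stations <- df$station
  m <- sapply(seq_along(els), function(j) {
    where <- sprintf("station %s, element %s", stations, els[j])
    .parse_num(df[[mean_cols[j]]], where)
  })
  m <- matrix(m, nrow = nrow(df), dimnames = list(NULL, els))
  sd_cols <- paste0(els, "_sd")
  s <- NULL
  if (any(sd_cols %in% names(df))) {
    s <- sapply(seq_along(els), function(j) {
      if (!sd_cols[j] %in% names(df)) return(rep(NA_real_, nrow(df)))
      where <- sprintf("station %s, element %s (sd)", stations, els[j])
      .parse_num(df[[sd_cols[j]]], where)
    })
    s <- matrix(s, nrow = nrow(df), dimnames = list(NULL, els))
  }
  exposure_table(stations, m, s, unit = unit)
}

#' Write an exposure table to CSV
#' @param table an [exposure_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_exposure_table <- function(table, path) {
  stopifnot(inherits(table, "exposure_table"))
  out <- data.frame(station = table$stations, check.names = FALSE)
  for (e in table$elements) {
    out[[paste0(e, "_mean")]] <- table$mean_conc[, e]
    if (!is.null(table$sd_conc)) {
      out[[paste0(e, "_sd")]] <- table$sd_conc[, e]
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sediment quality guideline sets
#'
#' A `guideline_set` stores, per element, the low and high trigger
#' concentrations (e.g. the Australian interim sediment quality guidelines
#' ISQG-Low and ISQG-High). A high trigger below or equal to its low trigger
#' is anomalous; such rows load with a warning attached to the result (and
#' emitted) rather than an error, so printed-source anomalies are preserved
#' verbatim.
#'
#' @param elements element symbols.
#' @param low,high trigger concentrations, low > 0, same length.
#' @param unit concentration unit of both triggers.
#' @return object of class `guideline_set`; any trigger-ordering warnings
#'   are kept in `attr(, "anomalies")`.
#' @export
guideline_set <- function(elements, low, high, unit = "mg/kg") {
  unit <- normalize_unit(unit)
  stopifnot(length(elements) == length(low), length(low) == length(high))
  if (anyNA(low) || anyNA(high)) {
    stop("every element needs both a low and a high trigger", call. = FALSE)
  }
  if (any(low <= 0)) stop("low triggers must be > 0", call. = FALSE)
  elements <- normalize_element(elements)
  anomalies <- character()
  for (i in seq_along(elements)) {
    if (high[i] < low[i]) {
      anomalies <- c(anomalies, sprintf(
        "%s: high trigger (%g) below low trigger (%g)",
        elements[i], high[i], low[i]))
    } else if (high[i] == low[i]) {
      anomalies <- c(anomalies, sprintf(
        "%s: high trigger equals low trigger (%g)", elements[i], low[i]))
    }
  }
  for (a in anomalies) warning(a, call. = FALSE)
  structure(
    list(elements = elements,
         low = stats::setNames(as.numeric(low), elements),
         high = stats::setNames(as.numeric(high), elements),
         unit = unit),
    class = "guideline_set", anomalies = anomalies)
}

#' @export
print.guideline_set <- function(x, ...) {
  cat(sprintf("guideline_set [%s dw]\n", x$unit))
  print(data.frame(element = x$elements, low = x$low, high = x$high,
                   row.names = NULL))
  an <- attr(x, "anomalies")
  if (length(an)) cat("anomalies:\n", paste(" -", an, collapse = "\n"), "\n")
  invisible(x)
}

#' Read a guideline set from CSV (`element,low,high,unit`)
#' @param source CSV path.
#' @return a [guideline_set]; trigger anomalies warn and are recorded in
#'   `attr(, "anomalies")`.
#' @export
read_guidelines <- function(source) {
  df <- .read_csv_chr(source)
  need <- c("element", "low", "high")
  if (!all(need %in% names(df))) {
    stop("guideline CSV must have columns element,low,high[,unit]",
         call. = FALSE)
  }
  low <- .parse_num(df$low, paste("element", df$element, "(low)"))
  high <- .parse_num(df$high, paste("element", df$element, "(high)"))
  if (anyNA(low) || anyNA(high)) {
    miss <- df$element[is.na(low) | is.na(high)][1]
    stop("element ", miss, " has only one trigger value", call. = FALSE)
  }
  unit <- if ("unit" %in% names(df)) unique(normalize_unit(df$unit)) else "mg/kg"
  if (length(unit) != 1) {
    stop("guideline CSV mixes units; use one unit per file", call. = FALSE)
  }
  guideline_set(df$element, low, high, unit = unit)
}

#' Write a guideline set to CSV
#' @param guidelines a [guideline_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_guidelines <- function(guidelines, path) {
  stopifnot(inherits(guidelines, "guideline_set"))
  utils::write.csv(
    data.frame(element = guidelines$elements, low = guidelines$low,
               high = guidelines$high, unit = guidelines$unit,
               row.names = NULL),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Species toxicity datasets (SSD input)
#'
#' A `toxicity_dataset` holds per-species sediment toxicity endpoint
#' concentrations for one element — the input to species sensitivity
#' distribution fitting. Concentrations are stored in the canonical unit
#' (mg/kg dw); at least 3 records are required for log-normal fitting and
#' 4 for Burr III.
#'
#' @param element element symbol.
#' @param concentration per-species endpoint concentrations, all > 0.
#' @param species optional species labels.
#' @param endpoint optional endpoint labels (e.g. "LC50").
#' @param unit unit of `concentration`; converted to mg/kg internally.
#' @return object of class `toxicity_dataset`.
#' @export
toxicity_dataset <- function(element, concentration, species = NULL,
                             endpoint = NULL, unit = "mg/kg") {
  if (!length(concentration)) stop("no toxicity records", call. = FALSE)
  if (anyNA(concentration) || any(concentration <= 0)) {
    stop("all endpoint concentrations must be strictly positive",
         call. = FALSE)
  }
  conc <- convert_units(as.numeric(concentration), unit, "mg/kg")
  n <- length(conc)
  structure(
    list(element = normalize_element(element),
         species = species %||% paste0("sp", seq_len(n)),
         endpoint = endpoint %||% rep("endpoint", n),
         concentration = conc, unit = "mg/kg"),
    class = "toxicity_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.toxicity_dataset <- function(x, ...) {
  cat(sprintf("toxicity_dataset: %s, %d species endpoints [mg/kg dw]\n",
              x$element, length(x$concentration)))
  cat(sprintf("  range: %.4g - %.4g\n", min(x$concentration),
              max(x$concentration)))
  invisible(x)
}

#' Read a toxicity dataset from CSV
#'
#' Layout `species,endpoint,concentration[,unit]`: one endpoint
#' concentration per row; a per-row `unit` column (mg/kg or ng/g) is
#' honoured and everything is converted to the canonical mg/kg dw.
#'
#' @param source CSV path.
#' @param element element symbol the endpoints refer to.
#' @param unit default unit when the file has no unit column.
#' @return a [toxicity_dataset].
#' @export
read_toxicity <- function(source, element, unit = "mg/kg") {
  df <- .read_csv_chr(source)
  if (!"concentration" %in% names(df)) {
    stop("toxicity CSV must have a 'concentration' column", call. = FALSE)
  }
  conc <- .parse_num(df$concentration,
                     paste("toxicity row", seq_len(nrow(df))))
  if (anyNA(conc)) stop("missing endpoint concentration", call. = FALSE)
  units <- if ("unit" %in% names(df)) df$unit else rep(unit, nrow(df))
  conc_mg <- vapply(seq_along(conc), function(i) {
    convert_units(conc[i], units[i], "mg/kg")
  }, numeric(1))
  toxicity_dataset(element, conc_mg,
                   species = if ("species" %in% names(df)) df$species,
                   endpoint = if ("endpoint" %in% names(df)) df$endpoint,
                   unit = "mg/kg")
}

#' Write a toxicity dataset to CSV
#' @param tox a [toxicity_dataset].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_toxicity <- function(tox, path) {
  stopifnot(inherits(tox, "toxicity_dataset"))
  utils::write.csv(
    data.frame(species = tox$species, endpoint = tox$endpoint,
               concentration = tox$concentration, unit = tox$unit),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Path to a packaged example dataset
#'
#' `wami_table3.csv` is the 20-station x 6-element sediment concentration
#' table (mg/kg dw, means and replicate SDs) from the Wami Estuary survey;
#' `isqg_table2.csv` is the matching Australian interim sediment quality
#' guideline table, preserving the printed Zn high trigger (equal to its
#' low trigger) verbatim.
#'
#' @param file fixture file name; with no argument, lists available files.
#' @return a file path (or vector of file names).
#' @export
sedrisk_example <- function(file = NULL) {
  dir <- system.file("extdata", package = "sedrisk")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("no packaged file ", sQuote(file), call. = FALSE)
  path
}
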