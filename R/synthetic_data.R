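#' Synthetic scenario specification
#'
#' Bundles every knob of the synthetic generators: the exposure
#' distribution (station means), the replicate structure, and the species
#' sensitivity distribution the per-species toxicity endpoints are drawn
#' from. The generators are pure functions of the spec — the seed is
#' mandatory and identical specs yield identical datasets. Generated
#' toxicity data are an emulation with known structure, standing in for
#' dose-response datasets that are typically unpublished; every scenario is
#' tagged as such.
#'
#' @param element element symbol the scenario emulates.
#' @param exposure_family `"lnorm"` or `"burr3"`.
#' @param exposure_params named list of parameters for the exposure family.
#' @param n_stations number of stations (>= 3 for [gen_exposure()]).
#' @param n_replicates replicates per station (drives the reported SDs).
#' @param replicate_cv coefficient of variation of within-station
#'   replicates (0 gives all-zero SDs).
#' @param ssd_family `"lnorm"` or `"burr3"`.
#' @param ssd_params named list of parameters for the SSD family.
#' @param n_species number of species endpoints (>= 4 for
#'   [gen_toxicity()]).
#' @param seed integer seed (mandatory).
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(element, exposure_family = "lnorm",
                          exposure_params = list(mu = 0, sigma = 0.5),
                          n_stations = 20, n_replicates = 3,
                          replicate_cv = 0.07,
                          ssd_family = "burr3",
                          ssd_params = list(b = 100, c = 1.8, k = 1.2),
                          n_species = 30, seed) {
  if (missing(seed) || !is.finite(seed)) {
    stop("scenario_spec requires an explicit integer seed", call. = FALSE)
  }
  stopifnot(exposure_family %in% c("lnorm", "burr3"),
            ssd_family %in% c("lnorm", "burr3"),
            n_stations >= 1, n_replicates >= 1, n_species >= 1,
            replicate_cv >= 0)
  .check_family_params(exposure_family, exposure_params)
  .check_family_params(ssd_family, ssd_params)
  structure(
    list(element = element, exposure_family = exposure_family,
         exposure_params = exposure_params, n_stations = n_stations,
         n_replicates = n_replicates, replicate_cv = replicate_cv,
         ssd_family = ssd_family, ssd_params = ssd_params,
         n_species = n_species, seed = as.integer(seed)),
    class = "scenario_spec")
}

.check_family_params <- function(family, params) {
  if (family == "lnorm") {
    stopifnot(all(c("mu", "sigma") %in% names(params)),
              params$sigma > 0)
  } else {
    .check_burr3(params$b, params$c, params$k)
  }
}

.family_fit <- function(family, params) {
  new_sed_fit(family, params, n = 0L, loglik = NA_real_)
}

# Deterministic per-unit substream: unit i of a spec gets its own seed, so
# extending the station/species count never changes earlier draws.
.substream_seed <- function(seed, i, offset) {
  (seed + offset + 9973L * i) %% .Machine$integer.max
}

#' Generate a synthetic toxicity dataset
#'
#' Draws `n_species` i.i.d. endpoint concentrations from the scenario's
#' species sensitivity distribution. Each species has its own
#' deterministic substream of the spec seed, so the first k endpoints do
#' not depend on `n_species`.
#'
#' @param spec a [scenario_spec] with `n_species >= 4`.
#' @return a [toxicity_dataset] (endpoint label `"synthetic"`).
#' @export
gen_toxicity <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$n_species < 4) {
    stop("need n_species >= 4 to support downstream SSD fitting",
         call. = FALSE)
  }
  gen <- .family_fit(spec$ssd_family, spec$ssd_params)
  conc <- vapply(seq_len(spec$n_species), function(i) {
    set.seed(.substream_seed(spec$seed, i, 0L))
    dist_rand(gen, 1)
  }, numeric(1))
  toxicity_dataset(spec$element, conc,
                   species = sprintf("synthetic_sp%02d",
                                     seq_len(spec$n_species)),
                   endpoint = rep("synthetic", spec$n_species))
}

#' Generate a synthetic exposure table
#'
#' Station mean concentrations are i.i.d. draws from the scenario's
#' exposure distribution; per-station SDs are the sample SDs of
#' `n_replicates` simulated replicates scattered around each mean with
#' coefficient of variation `replicate_cv` (zero CV gives zero SDs). SDs
#' are metadata only — fitting always uses the means.
#'
#' @param spec a [scenario_spec] with `n_stations >= 3`.
#' @return an [exposure_table] in mg/kg dw with one column for
#'   `spec$element`.
#' @export
gen_exposure <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$n_stations < 3) {
    stop("need n_stations >= 3 to support downstream fitting",
         call. = FALSE)
  }
  gen <- .family_fit(spec$exposure_family, spec$exposure_params)
  means <- numeric(spec$n_stations)
  sds <- numeric(spec$n_stations)
  for (i in seq_len(spec$n_stations)) {
    set.seed(.substream_seed(spec$seed, i, 1000000L))
    means[i] <- dist_rand(gen, 1)
    if (spec$replicate_cv > 0) {
      reps <- means[i] * exp(stats::rnorm(spec$n_replicates, 0,
                                          spec$replicate_cv))
      sds[i] <- stats::sd(reps)
    }
  }
  m <- matrix(means, ncol = 1,
              dimnames = list(NULL, spec$element))
  s <- matrix(sds, ncol = 1, dimnames = list(NULL, spec$element))
  exposure_table(seq_len(spec$n_stations), m, s, unit = "mg/kg")
}

#' Scenario emulating one element of the packaged survey
#'
#' Builds a [scenario_spec] whose exposure side is the log-normal fit of
#' the element's column in the packaged 20-station table, and whose SSD is
#' a Burr III placed so that its HC5 sits two orders of magnitude below the
#' exposure median — a deliberately impacted scenario in which most
#' stations exceed concentrations hazardous to sensitive species. The SSD
#' is an emulation with known parameters, explicitly not a real
#' dose-response dataset, and every dataset generated from it is labelled
#' synthetic.
#'
#' @param element one of As, Cd, Cr, Cu, Pb, Zn.
#' @param seed integer seed.
#' @return a [scenario_spec].
#' @export
wami_like_scenario <- function(element, seed) {
  element <- normalize_element(element)
  tab <- read_exposure_table(sedrisk_example("wami_table3.csv"))
  if (!element %in% tab$elements) {
    stop("unknown element ", sQuote(element), "; scenario covers ",
         paste(tab$elements, collapse = ", "), call. = FALSE)
  }
  x <- element_column(tab, element)
  fit <- lognormal_mle(x)
  # Burr III with moderate shapes; b solved so qburr3(0.05) = median/100
  cc <- 1.8; kk <- 1.2
  hc5_target <- exp(fit$params$mu) / 100
  b <- hc5_target / qburr3(0.05, 1, cc, kk)
  scenario_spec(element,
                exposure_family = "lnorm",
                exposure_params = list(mu = fit$params$mu,
                                       sigma = fit$params$sigma),
                n_stations = 20, n_replicates = 3, replicate_cv = 0.07,
                ssd_family = "burr3",
                ssd_params = list(b = b, c = cc, k = kk),
                n_species = 30, seed = seed)
}
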