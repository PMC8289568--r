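test_that("packaged survey fixture loads with the printed values", {
  tab <- wami_table()
  expect_equal(length(tab$stations), 20)
  expect_equal(tab$elements, c("As", "Cd", "Cr", "Cu", "Pb", "Zn"))
  expect_equal(tab$unit, "mg/kg")
  expect_equal(unname(tab$mean_conc[1, "Cd"]), 0.45)
  expect_equal(unname(tab$sd_conc[1, "Cd"]), 0.03)
  expect_equal(unname(tab$mean_conc[15, "Cu"]), 68.14)
  # checksum against independently hand-entered column totals
  expect_equal(unname(colSums(tab$mean_conc)),
               c(32.80, 7.44, 939.61, 735.56, 381.87, 1645.79),
               tolerance = 1e-12)
})

test_that("exposure parsing rejects bad cells and reports where", {
  df <- data.frame(station = 1:3, Cd_mean = c(0.4, -1.2, 0.5))
  expect_error(read_exposure_table(tmp_csv(df)), "station 2.*Cd")
  df2 <- data.frame(station = 1:3, Cd_mean = c(0.4, "oops", 0.5))
  expect_error(read_exposure_table(tmp_csv(df2)), "non-numeric.*station 2")
  df3 <- data.frame(station = 1:3, Cd_mean = c(0.4, NA, 0.5))
  expect_error(read_exposure_table(tmp_csv(df3)), "station 2")
})

test_that("exposure tables round-trip through write-then-read", {
  for (tab in list(
    exposure_table("s1", matrix(0.45, 1, 1, dimnames = list(NULL, "Cd"))),
    wami_table())) {
    p <- tempfile(fileext = ".csv")
    write_exposure_table(tab, p)
    back <- read_exposure_table(p, unit = tab$unit)
    expect_equal(back$mean_conc, tab$mean_conc)
    expect_equal(back$stations, tab$stations)
    expect_equal(back$sd_conc, tab$sd_conc)
  }
})

test_that("unit conversion has the right factors and is an involution", {
  expect_equal(convert_units(0.36, "mg/kg", "ng/g"), 360)
  expect_equal(convert_units(46.2, "ng/g", "mg/kg"), 0.0462)
  expect_equal(convert_units(65, "mg/kg", "mg/kg"), 65)
  expect_equal(convert_units(65, "mg/kg dw", "mg/kg"), 65)
  expect_error(convert_units(1, "mg/kg", "ppm"), "unknown")
  x <- c(0.001, 0.36, 65, 1e4)
  for (a in c("mg/kg", "ng/g")) for (b in c("mg/kg", "ng/g")) {
    expect_equal(convert_units(convert_units(x, a, b), b, a), x)
  }
})

test_that("guideline fixture carries the printed triggers and Zn anomaly", {
  expect_warning(gl <- read_guidelines(isqg_path()),
                 "Zn.*equals")
  expect_equal(gl$low[["Cu"]], 65)
  expect_equal(gl$high[["Cu"]], 270)
  expect_equal(gl$low[["Zn"]], gl$high[["Zn"]])
  expect_match(attr(gl, "anomalies"), "Zn", all = FALSE)
})

test_that("guideline parsing errors are informative", {
  empty <- tempfile(fileext = ".csv")
  writeLines("element,low,high,unit", empty)
  expect_error(read_guidelines(empty), "empty")
  one_trigger <- tmp_csv(data.frame(element = "Cu", low = 65, high = ""))
  expect_error(read_guidelines(one_trigger), "only one trigger")
  inverted <- tmp_csv(data.frame(element = "Cu", low = 65, high = 30,
                                 unit = "mg/kg"))
  expect_warning(gl <- read_guidelines(inverted), "below low")
})

test_that("toxicity datasets read, count and convert correctly", {
  set.seed(3)
  conc <- round(rlnorm(12, 2, 1), 4)
  p <- tmp_csv(data.frame(species = paste0("sp", 1:12), endpoint = "LC50",
                          concentration = conc, unit = "mg/kg"))
  tox <- read_toxicity(p, "Cu")
  expect_s3_class(tox, "toxicity_dataset")
  expect_length(tox$concentration, 12)
  expect_equal(tox$concentration, conc)

  expect_error(read_toxicity(
    tmp_csv(data.frame(species = "a", endpoint = "e", concentration = 0)),
    "Cu"), "positive")

  # mixed per-row units normalize consistently with convert_units
  mixed <- data.frame(species = c("a", "b"), endpoint = "LC50",
                      concentration = c(1.5, 1500),
                      unit = c("mg/kg", "ng/g"))
  tox2 <- read_toxicity(tmp_csv(mixed), "Cd")
  expect_equal(tox2$concentration,
               c(1.5, convert_units(1500, "ng/g", "mg/kg")))
  expect_equal(tox2$concentration[1], tox2$concentration[2])

  # round trip
  p2 <- tempfile(fileext = ".csv")
  write_toxicity(tox, p2)
  expect_equal(read_toxicity(p2, "Cu")$concentration, tox$concentration)
})

test_that("type constructors enforce positivity invariants", {
  expect_error(exposure_table("s1", matrix(0, 1, 1,
               dimnames = list(NULL, "Cd"))), "non-positive")
  expect_error(guideline_set("Cu", low = 0, high = 10), "low triggers")
  expect_error(toxicity_dataset("Cu", numeric(0)), "no toxicity records")
  expect_error(toxicity_dataset("Cu", c(1, -2)), "positive")
})
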