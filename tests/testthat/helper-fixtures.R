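# Shared fixtures and small builders used across the suite.

wami_path <- function() sedrisk_example("wami_table3.csv")
isqg_path <- function() sedrisk_example("isqg_table2.csv")

wami_table <- function() read_exposure_table(wami_path())
isqg_set <- function() suppressWarnings(read_guidelines(isqg_path()))

# a seeded synthetic toxicity dataset
make_tox <- function(n_species = 30, family = "burr3",
                     params = list(b = 100, c = 1.8, k = 1.2), seed = 7,
                     element = "Cd") {
  gen_toxicity(scenario_spec(element, ssd_family = family,
                             ssd_params = params, n_species = n_species,
                             seed = seed))
}

# write a data.frame to a temp CSV and return the path
tmp_csv <- function(df) {
  p <- tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
  p
}
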