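# Shared fixtures: a reference growth curve and the packaged study files.

ref_params <- function() vbgf_params("R. terraenovae", "male", L_inf = 900, k = 0.5, t0 = -1)

fixture <- function(file) sharktag_example(file)

# The published per-recapture table (printed, rounded values) as a data frame.
published_table1 <- function() {
  utils::read.csv(fixture("table1_published.csv"), stringsAsFactors = FALSE,
                  na.strings = c("NA", ""))
}

# Liberty records built from the packaged raw study files and synthetic
# parameter registry, warnings muffled (angler-length records warn by design).
fixture_records <- function() {
  suppressWarnings(build_liberty_records(
    read_tags(fixture("tags.csv")),
    read_recaptures(fixture("recaptures.csv")),
    read_vbgf_registry(fixture("vbgf_params_synthetic.yaml")),
    read_band_counts(fixture("band_counts.csv"))
  ))
}

# Random valid VBGF parameter sets for property loops.
random_params <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    vbgf_params("sp", "combined",
                L_inf = runif(1, 500, 2000),
                k = runif(1, 0.05, 0.9),
                t0 = runif(1, -3, 0)))
}
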