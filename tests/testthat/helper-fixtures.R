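# Fixtures are built in code at test time.

# Six-row export: 2 fully valid rows, then one row failing exactly one
# filter rule each (no NCAA, missing quantitative, wrong HLA, wrong
# response type).
six_row_export <- function() {
  data.frame(
    `Name` = c("GILGFVFTL + OTH(L9)", "KLVALGINAV + PHOS(L2)",
               "SIINFEKLL", "GILGFVFTL + OTH(L9)",
               "GILGFVFTL + OTH(L9)", "GILGFVFTL + OTH(L9)"),
    `Qualitative Measurement` = c("Positive", "Negative", "Positive",
                                  "Positive", "Positive", "Positive"),
    `Quantitative Measurement` = c("12.5", "6400", "3.2", "", "55", "90"),
    `Response Measured` = c("IC50", "half maximal inhibitory concentration (IC50)",
                            "IC50", "IC50", "IC50", "EC50"),
    `HLA` = c("HLA-A*02:01", "HLA-A*02:01", "HLA-A*02:01", "HLA-A*02:01",
              "HLA-B*07:02", "HLA-A*02:01"),
    check.names = FALSE, stringsAsFactors = FALSE)
}

write_fixture_export <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

# Evaluate code under a seed without clobbering the session RNG state.
with_seed_local <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Small synthetic descriptor-like matrix with known structure.
random_matrix <- function(n, p, seed) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p)
}

# A cached encoding of one default synthetic cohort, shared by tests that
# only need "some realistic X and y".
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- generative_spec(seed = 11L)
      sim <- generate_affinity_data(spec)
      fil <- apply_filters(sim$records)
      enc <- encode_dataset(affinity_dataset(fil), sim$registry)
      cache <<- list(sim = sim, enc = enc)
    }
    cache
  }
})
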