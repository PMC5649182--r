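# Shared lazily-computed simulation runs, reused across test files.
# Heavy strand runs at full acceptance settings (100 pre-pacing beats,
# 4 coupled beats) are cached so each condition is simulated once.

.run_cache <- new.env(parent = emptyenv())

cache_get <- function(key, compute) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, compute(), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# full-accuracy strand biomarkers (matches scripts/acceptance.R settings)
acc_strand <- function(condition, drug_name = NULL, conc = 0,
                       actions = "all") {
  key <- paste("acc", condition, drug_name, conc, actions, sep = "_")
  cache_get(key, function() {
    drug <- if (!is.null(drug_name) && conc > 0)
      drug_spec(drug_name, conc, actions) else NULL
    strand_biomarkers(condition = condition, drug = drug,
                      n_prepace = 100, n_beats = 4)
  })
}

# reduced-cost strand biomarkers with ERP, for property (trend) tests
prop_strand <- function(condition, drug_name = NULL, conc = 0,
                        actions = "all", erp = TRUE) {
  key <- paste("prop", condition, drug_name, conc, actions, erp, sep = "_")
  cache_get(key, function() {
    drug <- if (!is.null(drug_name) && conc > 0)
      drug_spec(drug_name, conc, actions) else NULL
    strand_biomarkers(condition = condition, drug = drug,
                      n_prepace = 60, n_beats = 3, erp = erp,
                      n_s1 = 1, erp_resolution = 2)
  })
}

# steady single-cell beat cache
acc_beat <- function(condition = "SQT1", drug_name = NULL, conc = 0,
                     actions = "all", cl = 1000, n_beats = 50,
                     cell_type = "ENDO") {
  key <- paste("beat", condition, drug_name, conc, actions, cl, n_beats,
               cell_type, sep = "_")
  cache_get(key, function() {
    drug <- if (!is.null(drug_name) && conc > 0)
      drug_spec(drug_name, conc, actions) else NULL
    steady_beat(cell_params(cell_type, condition), drug,
                stimulus_spec(period = cl), n_beats = n_beats)
  })
}
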