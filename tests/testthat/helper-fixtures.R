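# Shared cohort fixtures: simulated at the package's default scale, QC'd and
# assembled into model data once per test run (several tests and the
# acceptance checks reuse them). Fixture seed fixed once for the suite.

FIXTURE_SEED <- 104729

.fixtures <- new.env(parent = emptyenv())

qc_model_data <- function(bundle, cohort) {
  cg <- assign_contemporary_groups(bundle$emissions)
  ef <- apply_emission_filters(cg$records)
  wf <- apply_weight_and_window_filters(ef$records, cohort,
                                        dmi = bundle$dmi,
                                        carcass = bundle$carcass,
                                        ct = bundle$ct)
  prepare_model_data(wf$records, bundle$animals, dmi_links = wf$dmi_links,
                     carcass_links = wf$carcass_links)
}

growing_fixture <- function() {
  if (is.null(.fixtures$growing)) {
    b <- simulate_flocks(sim_config("growing", seed = FIXTURE_SEED))
    md <- qc_model_data(b, "growing")
    rmt_bw <- derive_residual_trait("RMT_BW", md, "growing")
    .fixtures$growing <- list(bundle = b, md = md, rmt_bw = rmt_bw)
  }
  .fixtures$growing
}

ewe_fixture <- function() {
  if (is.null(.fixtures$ewe)) {
    b <- simulate_flocks(sim_config("ewe", seed = FIXTURE_SEED))
    md <- qc_model_data(b, "ewe")
    .fixtures$ewe <- list(bundle = b, md = md)
  }
  .fixtures$ewe
}

# small growing bundle for fast structural tests
small_growing_bundle <- function(seed = 42, n_animals = 250, n_flocks = 5) {
  key <- paste0("small", seed, "_", n_animals)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- simulate_flocks(
      sim_config("growing", seed = seed, n_animals = n_animals,
                 n_flocks = n_flocks))
  }
  .fixtures[[key]]
}
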