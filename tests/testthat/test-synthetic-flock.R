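test_that("record bookkeeping and reproducibility hold", {
  cfg <- sim_config("growing", seed = 5, n_animals = 100,
                    records_per_animal = 2, n_flocks = 3)
  b <- simulate_flocks(cfg)
  expect_equal(nrow(b$emissions), 200L)
  expect_equal(sort(unique(table(b$emissions$animal_id))), 2L)

  b2 <- simulate_flocks(sim_config("growing", seed = 5, n_animals = 100,
                                   records_per_animal = 2, n_flocks = 3))
  expect_identical(b$emissions, b2$emissions)
  expect_identical(b$animals, b2$animals)
  expect_identical(b$weights, b2$weights)

  b3 <- simulate_flocks(sim_config("growing", seed = 6, n_animals = 100,
                                   records_per_animal = 2, n_flocks = 3))
  expect_false(identical(b$emissions$ch4, b3$emissions$ch4))
})

test_that("configuration errors are rejected", {
  expect_error(sim_config("growing", variance_components = list(cg_var = -1)),
               "non-negative")
  expect_error(sim_config("growing", n_animals = 0), "at least one animal")
  expect_error(sim_config("growing", records_per_animal = 0), ">= 1")
  expect_error(sim_config("growing",
                          records_per_animal = c(`1` = 0.4, `2` = 0.4)),
               "sum to 1")
})

test_that("body weights respect the cohort windows by construction", {
  g <- small_growing_bundle()
  expect_true(all(g$emissions$body_weight >= 25 &
                    g$emissions$body_weight <= 80))
  e <- simulate_flocks(sim_config("ewe", seed = 12, n_animals = 200,
                                  n_flocks = 4))
  expect_true(all(e$emissions$body_weight >= 55 &
                    e$emissions$body_weight <= 100))
  expect_true(all(e$emissions$sex == "female"))
  expect_true(all(e$emissions$lactation %in% c("lactating", "dry")))
})

test_that("degenerate variance configurations behave as configured", {
  # no animal variance: repeated records are exchangeable, R near 0
  cfg0 <- sim_config("growing", seed = 8, n_animals = 400,
                     records_per_animal = 2, n_flocks = 4,
                     variance_components = list(animal_var = 0),
                     trait_links = list(mbw = 0, dmi = 0))
  b0 <- simulate_flocks(cfg0)
  md0 <- prepare_model_data(
    assign_contemporary_groups(b0$emissions)$records, b0$animals)
  r0 <- estimate_repeatability(md0, "ch4", factors = "sex", nboot = 0)
  expect_lt(r0$R, 0.08)

  # only animal variance: every record of an animal identical, R = 1
  cfg1 <- sim_config("growing", seed = 9, n_animals = 60,
                     records_per_animal = 2, n_flocks = 2,
                     variance_components = list(cg_var = 0, resid_var = 0,
                                                animal_var = 4),
                     trait_links = list(mbw = 0, dmi = 0),
                     fixed_effects = list(sex_effect = 0, age_slope = 0,
                                          heterosis_slope = 0,
                                          recombination_slope = 0,
                                          birth_litter = c(`1` = 0, `2` = 0,
                                                           `3+` = 0),
                                          rearing_litter = c(`1` = 0, `2` = 0,
                                                             `3+` = 0),
                                          breed_effects = c(Belclare = 0,
                                            `Blackface Mountain` = 0,
                                            Charollais = 0, Cheviot = 0,
                                            Lleyn = 0, Texel = 0, Vendeen = 0,
                                            Other = 0)))
  b1 <- simulate_flocks(cfg1)
  per_animal_sd <- tapply(b1$emissions$ch4, b1$emissions$animal_id, sd)
  expect_lt(max(per_animal_sd), 1e-2)  # identical up to output rounding
  md1 <- prepare_model_data(
    assign_contemporary_groups(b1$emissions)$records, b1$animals)
  r1 <- estimate_repeatability(md1, "ch4", nboot = 0, include_cg = FALSE)
  expect_gt(r1$R, 0.99)
})

test_that("the realized effect draws match the configured variance decomposition", {
  cfg <- sim_config("growing", seed = 314, n_animals = 16000,
                    records_per_animal = 2, n_flocks = 300)
  b <- simulate_flocks(cfg)
  vc <- cfg$variance_components
  expect_lt(abs(var(b$truth$animal$effect) / vc$animal_var - 1), 0.05)
  expect_lt(abs(var(b$truth$cg$effect) / vc$cg_var - 1), 0.05)
  expect_lt(abs(var(b$truth$resid) / vc$resid_var - 1), 0.05)

  # and the realized methane decomposes accordingly: REML on a mid-sized
  # simulation recovers the configured components once the intake and MBW
  # links are included in the model
  cfg2 <- sim_config("growing", seed = 315, n_animals = 4000,
                     records_per_animal = 2, n_flocks = 40)
  b2 <- simulate_flocks(cfg2)
  md <- prepare_model_data(assign_contemporary_groups(b2$emissions)$records,
                           b2$animals)
  md$dmi_latent <- b2$truth$animal$dmi_animal[match(md$animal_id,
                                                    b2$truth$animal$animal_id)]
  sp <- residual_trait_spec("RMT_MBW", "growing")
  fit <- fit_lmm(lmm_spec("ch4", factors = sp$factors,
                          covariates = c(sp$covariates, "dmi_latent"),
                          random = c("contemporary_group", "animal_id"),
                          ref_levels = sp$ref_levels), md)
  expect_lt(abs(fit$varcomp[["animal_id"]] / vc$animal_var - 1), 0.10)
  expect_lt(abs(fit$varcomp[["resid"]] / vc$resid_var - 1), 0.10)
  expect_lt(abs(fit$varcomp[["contemporary_group"]] / vc$cg_var - 1), 0.20)
})

test_that("intake, CT, carcass and maternal tables link to the same animals", {
  g <- growing_fixture()$bundle
  expect_true(all(g$dmi$animal_id %in% g$animals$animal_id))
  expect_true(all(g$ct$animal_id %in% g$animals$animal_id))
  expect_true(all(g$carcass$animal_id %in% g$animals$animal_id))
  expect_true(all(g$weights$animal_id %in% g$animals$animal_id))
  e <- ewe_fixture()$bundle
  expect_equal(sort(e$maternal$animal_id), sort(e$animals$animal_id))
  expect_true(all(e$maternal$lambs_reared <= e$maternal$lambs_born))
})
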