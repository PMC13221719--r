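mk_records <- function(n, flock = "F1", date = as.Date("2023-05-01"),
                       run = 1L, ch4 = 12, co2 = 700, bw = 50,
                       ids = sprintf("a%02d", seq_len(n))) {
  data.frame(record_id = paste0("r", seq_len(n), "_", flock, run),
             animal_id = ids, flock_id = flock, measurement_date = date,
             pac_run = run, ch4 = ch4, co2 = co2, body_weight = bw,
             cohort = "growing", stringsAsFactors = FALSE)
}

test_that("contemporary groups key on flock x date x run", {
  r <- mk_records(12)
  out <- assign_contemporary_groups(r)
  expect_equal(length(unique(out$records$contemporary_group)), 1L)
  expect_equal(unique(out$records$cg_size), 12L)

  r2 <- rbind(mk_records(6, run = 1L), mk_records(6, run = 2L))
  out2 <- assign_contemporary_groups(r2)
  expect_equal(length(unique(out2$records$contemporary_group)), 2L)

  r3 <- mk_records(3)
  r3$pac_run[2] <- NA
  out3 <- assign_contemporary_groups(r3)
  expect_equal(nrow(out3$rejected), 1L)
  expect_match(out3$rejected$reason, "missing")
})

test_that("emission filters implement the floor, SD screen, CO2 ceiling and group-size rules", {
  r <- mk_records(10, ch4 = c(3.9, 5, 6, 7, 8, 9, 5, 6, 7, 8))
  r$co2[3] <- 2600
  out <- apply_emission_filters(assign_contemporary_groups(r)$records)
  # 3.9 g/d is below the hard floor
  expect_false(any(out$records$ch4 < 4))
  expect_true("ch4_below_floor" %in% out$exclusions$rule)
  # CO2 above the ceiling stays for methane traits, invalid for CO2 traits
  expect_true(r$record_id[3] %in% out$records$record_id)
  expect_false(out$records$co2_valid[out$records$record_id == r$record_id[3]])
  # the surviving group still has >= 5 animals, so no group removal
  expect_equal(nrow(out$records), 9L)

  # toy cohort {5,6,7,8,9}: nothing below 4, nothing beyond 3 SD
  toy <- mk_records(5, ch4 = 5:9)
  out2 <- apply_emission_filters(assign_contemporary_groups(toy)$records)
  expect_equal(sort(out2$records$ch4), 5:9)

  # an extreme record beyond 3 SD of the post-floor mean is removed
  r3 <- mk_records(30, ch4 = c(rep(c(11, 12, 13), 9), 12, 12, 40))
  out3 <- apply_emission_filters(assign_contemporary_groups(r3)$records,
                                 min_group = NULL)
  expect_false(40 %in% out3$records$ch4)
  expect_true("ch4_outside_3sd" %in% out3$exclusions$rule)

  # a group of 4 animals is dropped by the >= 5 rule
  r4 <- rbind(mk_records(4, run = 1L), mk_records(8, run = 2L))
  out4 <- apply_emission_filters(assign_contemporary_groups(r4)$records)
  expect_equal(nrow(out4$records), 8L)
  expect_equal(sum(out4$exclusions$rule == "contemporary_group_lt_min"), 4L)
})

test_that("weight windows and production-table edits follow the printed rules", {
  r <- mk_records(6, bw = c(24.5, 30, 50, 80, 80.5, 60))
  out <- apply_weight_and_window_filters(r, "growing")
  expect_equal(sort(out$records$body_weight), c(30, 50, 60, 80))
  ewes <- mk_records(3, bw = c(54.9, 55, 100))
  oute <- apply_weight_and_window_filters(ewes, "ewe")
  expect_equal(sort(oute$records$body_weight), c(55, 100))

  # carcass: weight window, age window, closest-record pairing
  d0 <- as.Date("2023-05-01")
  r2 <- mk_records(2, ids = c("a1", "a1"))
  r2$measurement_date <- c(d0 - 10, d0 - 25)
  carcass <- data.frame(animal_id = c("a1", "a2", "a3"),
                        slaughter_date = d0,
                        carcass_weight = c(20, 26.5, 20),
                        days_to_slaughter = c(200, 210, 460),
                        stringsAsFactors = FALSE)
  out2 <- apply_weight_and_window_filters(r2, "growing", carcass = carcass)
  # only animal a1 links; its 10-d-gap record is the one paired
  expect_equal(nrow(out2$carcass_links), 1L)
  expect_equal(out2$carcass_links$record_id,
               r2$record_id[r2$measurement_date == d0 - 10])
  expect_true("carcass_weight_outside_15_26" %in% out2$exclusions$rule)
  expect_true("slaughter_age_outside_100_450" %in% out2$exclusions$rule)

  # ADG retention band
  adg <- data.frame(record_id = r$record_id[1:4],
                    animal_id = r$animal_id[1:4],
                    adg = c(140, 150, 350, 360), stringsAsFactors = FALSE)
  out3 <- apply_weight_and_window_filters(r, "growing", adg = adg)
  expect_equal(sort(out3$adg$adg), c(150, 350))

  # DMI: +/-30 d inclusive link and 3 SD screen
  r4 <- mk_records(4, ids = c("a1", "a2", "a3", "a4"))
  dmi <- data.frame(animal_id = c("a1", "a2", "a3", "a4"),
                    date = r4$measurement_date[1] + c(30, 31, 0, 0),
                    dmi = c(1.5, 1.5, 1.6, 1.6), stringsAsFactors = FALSE)
  out4 <- apply_weight_and_window_filters(r4, "growing", dmi = dmi)
  expect_setequal(out4$dmi_links$animal_id, c("a1", "a3", "a4"))
  expect_true(any(out4$exclusions$rule == "dmi_unlinked_to_methane_record"))
})

test_that("filters only subset, never mutate, and ignore row order", {
  b <- small_growing_bundle()
  r <- assign_contemporary_groups(b$emissions)$records
  out <- apply_emission_filters(r)
  expect_true(all(out$records$record_id %in% r$record_id))
  keep <- match(out$records$record_id, r$record_id)
  expect_identical(out$records$ch4, r$ch4[keep])
  expect_identical(out$records$body_weight, r$body_weight[keep])
  expect_equal(nrow(out$records) + sum(out$exclusions$rule != "co2_above_ceiling_co2_traits_only"),
               nrow(r))

  set.seed(9)
  perm <- sample(nrow(r))
  out_p <- apply_emission_filters(r[perm, ])
  expect_setequal(out_p$records$record_id, out$records$record_id)

  # determinism: identical input gives an identical exclusion log
  out_again <- apply_emission_filters(r)
  expect_identical(out$exclusions, out_again$exclusions)
})
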