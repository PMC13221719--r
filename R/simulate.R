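bcode <- function(b) gsub(" ", ".", b, fixed = TRUE)

sub_seed <- function(seed, k) {
  as.integer((abs(as.numeric(seed)) * 7 + k * 1000003) %% 2147483647)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

sample_parent_breeds <- function(cfg) {
  type <- sample(names(cfg$breed_mix), 1L, prob = cfg$breed_mix)
  breeds <- names(cfg$breed_freq)
  if (type == "purebred") {
    b <- sample(breeds, 1L, prob = cfg$breed_freq)
    list(sire = breed_vector(stats::setNames(1, b)),
         dam = breed_vector(stats::setNames(1, b)))
  } else if (type == "f1") {
    b <- sample(breeds, 2L, prob = cfg$breed_freq)
    list(sire = breed_vector(stats::setNames(1, b[1])),
         dam = breed_vector(stats::setNames(1, b[2])))
  } else {
    mk <- function() {
      k <- sample(2:3, 1L)
      b <- sample(breeds, k, prob = cfg$breed_freq)
      breed_vector(stats::setNames(rdirichlet1(rep(2, k)), b))
    }
    list(sire = mk(), dam = mk())
  }
}

#' Simulate a PAC methane phenotyping campaign
#'
#' Generates a dataset bundle with the statistical structure the methane
#' metric analysis assumes: per-record daily methane built as overall mean +
#' fixed effects (sex, litter sizes, age class, heterosis, recombination
#' loss, breed proportions, lactation status for ewes) + production-trait
#' links (metabolic body weight, latent intake) + contemporary-group effect
#' + permanent animal effect + residual, with the configured variances; plus
#' linked production tables (intake, longitudinal weights, carcass, CT,
#' maternal) keyed to the same animals. Identical configurations (including
#' the seed) yield identical bundles.
#'
#' @param config A [sim_config()].
#' @return List of class \code{flock_bundle} with data frames
#'   \code{animals}, \code{emissions}, \code{dmi}, \code{weights},
#'   \code{carcass}, \code{ct}, \code{maternal}, the echoed \code{config},
#'   and \code{truth} (the drawn random effects, for verification).
#' @examples
#' b <- simulate_flocks(sim_config("growing", seed = 7, n_animals = 60,
#'                                 n_flocks = 3))
#' nrow(b$emissions)
#' @export
simulate_flocks <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  cfg <- config
  vc <- cfg$variance_components
  fe <- cfg$fixed_effects
  n <- cfg$n_animals

  ## ---- animals -----------------------------------------------------------
  set.seed(sub_seed(cfg$seed, 1L))
  animal_id <- sprintf("A%05d", seq_len(n))
  flock_id <- sprintf("F%03d", sample.int(cfg$n_flocks, n, replace = TRUE))
  sex <- if (cfg$cohort == "ewe") rep("female", n) else {
    ifelse(stats::runif(n) < cfg$female_fraction, "female", "male")
  }
  breeds <- names(cfg$breed_freq)
  sire_m <- matrix(0, n, length(breeds), dimnames = list(NULL, breeds))
  dam_m <- sire_m
  het <- numeric(n)
  rec <- numeric(n)
  for (i in seq_len(n)) {
    pb <- sample_parent_breeds(cfg)
    sire_m[i, names(pb$sire)] <- unclass(pb$sire)
    dam_m[i, names(pb$dam)] <- unclass(pb$dam)
    het[i] <- heterosis_coefficient(pb$sire, pb$dam)
    rec[i] <- recombination_loss(pb$sire, pb$dam)
  }
  prop_m <- (sire_m + dam_m) / 2
  birth_litter <- sample(names(cfg$litter_probs), n, replace = TRUE,
                         prob = cfg$litter_probs)
  rearing_litter <- sample(names(cfg$litter_probs), n, replace = TRUE,
                           prob = cfg$litter_probs)
  bw_dev <- stats::rnorm(n, 0, cfg$body_weight$sd_animal)
  a_eff <- stats::rnorm(n, 0, sqrt(vc$animal_var))
  dmi_animal <- cfg$dmi$mean + cfg$dmi$bw_slope * bw_dev +
    stats::rnorm(n, 0, cfg$dmi$sd_animal)
  dmi_animal <- pmax(dmi_animal, 0.3)
  weaning_weight <- if (cfg$cohort == "growing") {
    round(stats::rnorm(n, 35, 4.5), 1)
  } else rep(NA_real_, n)

  ## ---- measurement schedule ---------------------------------------------
  set.seed(sub_seed(cfg$seed, 2L))
  step <- max(14L, round(cfg$session_span / 10))
  flock_dates <- lapply(seq_len(cfg$n_flocks), function(f) {
    as.Date("2022-03-01") + ((f * 3L) %% 28L) +
      seq(0L, cfg$session_span, by = step)
  })
  names(flock_dates) <- sprintf("F%03d", seq_len(cfg$n_flocks))

  rp <- cfg$records_per_animal
  n_rec <- if (length(rp) == 1L && is.null(names(rp))) {
    rep(as.integer(rp), n)
  } else {
    sample(as.integer(names(rp)), n, replace = TRUE, prob = rp)
  }

  rec_animal <- rep(seq_len(n), n_rec)
  rec_date <- as.Date(rep(NA, length(rec_animal)), origin = "1970-01-01")
  pos <- 1L
  for (i in seq_len(n)) {
    dates <- flock_dates[[flock_id[i]]]
    S <- length(dates)
    k <- min(n_rec[i], S)
    if (cfg$cohort == "growing") {
      # confine a growing animal's records to a contiguous block of
      # sessions so its age stays inside the cohort window
      s0 <- sample.int(max(1L, S - 7L), 1L)
      cand <- s0:min(s0 + 7L, S)
      k <- min(k, length(cand))
      picked <- sort(sample(cand, k))
    } else {
      picked <- sort(sample.int(S, k))
    }
    rec_date[pos:(pos + k - 1L)] <- dates[picked]
    if (k < n_rec[i]) {
      rec_animal <- rec_animal[-((pos + k):(pos + n_rec[i] - 1L))]
    }
    n_rec[i] <- k
    pos <- pos + k
  }
  m <- length(rec_animal)
  rec_date <- rec_date[seq_len(m)]

  # PAC runs: animals measured in a flock on a day are chambered in batches
  # of pac_capacity, in random arrival order; the last run may be partial
  set.seed(sub_seed(cfg$seed, 3L))
  key_fd <- paste(flock_id[rec_animal], rec_date, sep = "|")
  pac_run <- integer(m)
  for (kfd in unique(key_fd)) {
    idx <- which(key_fd == kfd)
    ord <- sample.int(length(idx))
    pac_run[idx[ord]] <- ceiling(seq_along(idx) / cfg$pac_capacity)
  }

  ## ---- ages ---------------------------------------------------------------
  set.seed(sub_seed(cfg$seed, 4L))
  first_date <- as.Date(tapply(as.numeric(rec_date), rec_animal, min),
                        origin = "1970-01-01")
  age_first <- pmin(pmax(round(stats::rnorm(
    n, cfg$age$mean_days, cfg$age$sd_days)), cfg$age$min_days),
    cfg$age$max_days - cfg$session_span)
  birth_date <- first_date - age_first[as.integer(names(first_date))]
  birth_by_animal <- rep(as.Date(NA), n)
  birth_by_animal[as.integer(names(first_date))] <- birth_date
  age_days <- as.integer(rec_date - birth_by_animal[rec_animal])
  age_class <- if (cfg$age$classes == "months") {
    as.character(pmin(pmax(floor(age_days / 30.44), 4L), 19L))
  } else {
    as.character(pmin(pmax(floor(age_days / 365.25), 1L), 7L))
  }

  ## ---- methane and linked gases -----------------------------------------
  set.seed(sub_seed(cfg$seed, 5L))
  bw_rec <- pmin(pmax(cfg$body_weight$mean + bw_dev[rec_animal] +
                        stats::rnorm(m, 0, cfg$body_weight$sd_record),
                      cfg$body_weight$min), cfg$body_weight$max)
  bw_rec <- round(bw_rec, 1)
  mbw_rec <- metabolic_body_weight(bw_rec)
  mbw_ref <- metabolic_body_weight(cfg$body_weight$mean)

  cg_key <- paste(flock_id[rec_animal], rec_date, pac_run, sep = "|")
  cg_levels <- unique(cg_key)
  cg_eff <- stats::setNames(stats::rnorm(length(cg_levels), 0,
                                         sqrt(vc$cg_var)), cg_levels)
  lactation <- if (cfg$cohort == "ewe") {
    ifelse(stats::runif(m) < cfg$lactating_fraction, "lactating", "dry")
  } else rep(NA_character_, m)

  age_num <- if (cfg$age$classes == "months") as.numeric(age_class) else
    as.numeric(age_class)
  fixed_part <- fe$mu +
    ifelse(sex[rec_animal] == "male", fe$sex_effect, 0) +
    fe$birth_litter[birth_litter[rec_animal]] +
    fe$rearing_litter[rearing_litter[rec_animal]] +
    fe$age_slope * (age_num - fe$age_ref) +
    fe$heterosis_slope * het[rec_animal] +
    fe$recombination_slope * rec[rec_animal] +
    as.numeric(prop_m[rec_animal, names(fe$breed_effects), drop = FALSE] %*%
                 fe$breed_effects)
  if (cfg$cohort == "ewe") {
    fixed_part <- fixed_part +
      ifelse(lactation == "lactating", fe$lactation_effect, 0)
  }
  resid_eff <- stats::rnorm(m, 0, sqrt(vc$resid_var))
  # latent intake driving each record's methane; the DMI protocol measures
  # this quantity (indoor weigh-back: the animal's stable intake; pasture
  # n-alkane: the intake around the methane date), so observed DMI below is
  # this same value, not a noisy proxy of it
  dmi_latent <- if (isTRUE(cfg$dmi$per_record)) {
    pmax(dmi_animal[rec_animal] + stats::rnorm(m, 0, cfg$dmi$sd_record), 0.2)
  } else {
    dmi_animal[rec_animal]
  }
  ch4 <- fixed_part +
    cfg$trait_links$mbw * (mbw_rec - mbw_ref) +
    cfg$trait_links$dmi * (dmi_latent - cfg$dmi$mean) +
    cg_eff[cg_key] + a_eff[rec_animal] + resid_eff
  ch4 <- as.numeric(pmax(ch4, 0.5))

  co2 <- cfg$co2$mean + cfg$co2$ch4_slope * (ch4 - fe$mu) +
    stats::rnorm(m, 0, cfg$co2$sd) +
    ifelse(stats::runif(m) < cfg$co2$spike_prob, cfg$co2$spike, 0)
  co2 <- pmax(co2, 20)

  emissions <- data.frame(
    record_id = sprintf("R%06d", seq_len(m)),
    animal_id = animal_id[rec_animal],
    flock_id = flock_id[rec_animal],
    measurement_date = rec_date,
    pac_run = pac_run,
    ch4 = round(ch4, 3), co2 = round(co2, 2),
    body_weight = bw_rec,
    age_days = age_days, age_class = age_class,
    sex = sex[rec_animal],
    lactation = lactation,
    cohort = cfg$cohort,
    stringsAsFactors = FALSE)

  ## ---- production tables --------------------------------------------------
  set.seed(sub_seed(cfg$seed, 6L))
  dmi_idx <- which(stats::runif(n) < cfg$dmi$animal_fraction)
  dmi <- if (length(dmi_idx)) {
    rows <- list()
    for (i in dmi_idx) {
      recs <- which(rec_animal == i)
      if (!length(recs)) next
      if (isTRUE(cfg$dmi$per_record)) {
        take <- recs[stats::runif(length(recs)) < 0.85]
        if (!length(take)) take <- recs[1L]
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = animal_id[i],
          date = rec_date[take] + sample(-20:20, length(take), replace = TRUE),
          dmi = round(dmi_latent[take], 3),
          stringsAsFactors = FALSE)
      } else {
        take <- recs[1L]
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = animal_id[i], date = rec_date[take],
          dmi = round(dmi_latent[take], 3),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  } else {
    data.frame(animal_id = character(), date = as.Date(character()),
               dmi = numeric(), stringsAsFactors = FALSE)
  }

  weights <- data.frame(animal_id = character(), date = as.Date(character()),
                        weight = numeric(), stringsAsFactors = FALSE)
  if (cfg$weights_per_animal > 0L) {
    growth <- pmin(pmax(stats::rnorm(n, 250, 45), 80), 430)   # g/d
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      t0 <- birth_by_animal[i] + age_first[i]
      off <- sort(sample(-110:110, cfg$weights_per_animal))
      base <- cfg$body_weight$mean + bw_dev[i]
      rows[[i]] <- data.frame(
        animal_id = animal_id[i], date = t0 + off,
        weight = round(pmax(base + growth[i] * off / 1000 +
                              stats::rnorm(length(off), 0, 0.4), 5), 2),
        stringsAsFactors = FALSE)
    }
    weights <- do.call(rbind, rows)
  }

  carcass <- data.frame(animal_id = character(),
                        slaughter_date = as.Date(character()),
                        carcass_weight = numeric(),
                        days_to_slaughter = integer(),
                        stringsAsFactors = FALSE)
  if (cfg$slaughter_fraction > 0) {
    sl_idx <- which(stats::runif(n) < cfg$slaughter_fraction & n_rec > 0)
    if (length(sl_idx)) {
      last_date <- as.Date(tapply(as.numeric(rec_date), rec_animal, max),
                           origin = "1970-01-01")
      ld <- last_date[as.character(sl_idx)]
      sdate <- ld + sample(0:40, length(sl_idx), replace = TRUE)
      cw <- round(0.42 * (cfg$body_weight$mean + bw_dev[sl_idx]) +
                    stats::rnorm(length(sl_idx), 0, 1.3), 2)
      carcass <- data.frame(
        animal_id = animal_id[sl_idx], slaughter_date = sdate,
        carcass_weight = cw,
        days_to_slaughter = as.integer(sdate - birth_by_animal[sl_idx]),
        stringsAsFactors = FALSE)
    }
  }

  ct <- data.frame(animal_id = character(), date = as.Date(character()),
                   muscle_mass = numeric(), fat_mass = numeric(),
                   ko_pct = numeric(), mf_ratio = numeric(),
                   rumen_volume = numeric(), stringsAsFactors = FALSE)
  if (cfg$ct_fraction > 0) {
    ct_idx <- which(stats::runif(n) < cfg$ct_fraction & n_rec > 0)
    if (length(ct_idx)) {
      fd <- as.Date(tapply(as.numeric(rec_date), rec_animal, min),
                    origin = "1970-01-01")[as.character(ct_idx)]
      bwi <- cfg$body_weight$mean + bw_dev[ct_idx]
      muscle <- pmax(0.27 * bwi + stats::rnorm(length(ct_idx), 0, 1.5), 3)
      fat <- pmax(0.08 * bwi + stats::rnorm(length(ct_idx), 0, 1.0), 0.4)
      ct <- data.frame(
        animal_id = animal_id[ct_idx],
        date = fd + sample(-6:6, length(ct_idx), replace = TRUE),
        muscle_mass = round(muscle, 2), fat_mass = round(fat, 2),
        ko_pct = round(pmin(pmax(stats::rnorm(length(ct_idx), 0.45, 0.04),
                                 0.32), 0.6), 3),
        mf_ratio = round(muscle / fat, 3),
        rumen_volume = round(pmin(pmax(0.1 * bwi +
                                         stats::rnorm(length(ct_idx), 0, 1.2),
                                       2), 13), 2),
        stringsAsFactors = FALSE)
    }
  }

  maternal <- data.frame(animal_id = character(), lambs_born = integer(),
                         lambs_reared = integer(),
                         litter_weaning_weight = numeric(),
                         bcs = numeric(), stringsAsFactors = FALSE)
  if (cfg$cohort == "ewe") {
    set.seed(sub_seed(cfg$seed, 7L))
    lb <- sample(1:4, n, replace = TRUE, prob = c(0.25, 0.50, 0.20, 0.05))
    lr <- pmax(1L, lb - stats::rbinom(n, 1, 0.2))
    maternal <- data.frame(
      animal_id = animal_id, lambs_born = lb, lambs_reared = lr,
      litter_weaning_weight = round(lr * stats::rnorm(n, 30, 3), 1),
      bcs = sample(1:5, n, replace = TRUE,
                   prob = c(0.05, 0.2, 0.45, 0.25, 0.05)),
      stringsAsFactors = FALSE)
  }

  animals <- data.frame(animal_id = animal_id, flock_id = flock_id,
                        sex = sex, birth_date = birth_by_animal,
                        birth_litter = birth_litter,
                        rearing_litter = rearing_litter,
                        heterosis = het,
                        recombination = rec,
                        weaning_weight = weaning_weight,
                        cohort = cfg$cohort,
                        stringsAsFactors = FALSE)
  colnames(sire_m) <- paste0("sire_", bcode(breeds))
  colnames(dam_m) <- paste0("dam_", bcode(breeds))
  colnames(prop_m) <- paste0("breed_", bcode(breeds))
  animals <- cbind(animals, as.data.frame(sire_m), as.data.frame(dam_m),
                   as.data.frame(prop_m))

  structure(list(
    animals = animals, emissions = emissions, dmi = dmi, weights = weights,
    carcass = carcass, ct = ct, maternal = maternal, config = cfg,
    truth = list(cg = data.frame(contemporary_group = cg_levels,
                                 effect = unname(cg_eff),
                                 stringsAsFactors = FALSE),
                 animal = data.frame(animal_id = animal_id,
                                     effect = a_eff,
                                     dmi_animal = dmi_animal,
                                     stringsAsFactors = FALSE),
                 resid = resid_eff)
  ), class = "flock_bundle")
}

#' @export
print.flock_bundle <- function(x, ...) {
  cat(sprintf("Synthetic %s flock bundle: %d animals, %d emission records\n",
              x$config$cohort, nrow(x$animals), nrow(x$emissions)))
  cat(sprintf("  tables: dmi %d, weights %d, carcass %d, ct %d, maternal %d\n",
              nrow(x$dmi), nrow(x$weights), nrow(x$carcass), nrow(x$ct),
              nrow(x$maternal)))
  invisible(x)
}
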