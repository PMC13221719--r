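sim_defaults <- function(cohort) {
  common <- list(
    n_flocks = 40L,
    pac_capacity = 12L,
    breed_mix = c(purebred = 0.40, f1 = 0.30, composite = 0.30),
    breed_freq = c(Texel = 0.30, Suffolk = 0.22, Belclare = 0.15,
                   Charollais = 0.09, Cheviot = 0.08, Lleyn = 0.06,
                   `Blackface Mountain` = 0.05, Vendeen = 0.03, Other = 0.02),
    litter_probs = c(`1` = 0.30, `2` = 0.55, `3+` = 0.15)
  )
  if (cohort == "growing") {
    c(common, list(
      n_animals = 3400L,
      records_per_animal = c(`1` = 0.71, `2` = 0.05, `3` = 0.06, `4` = 0.06,
                             `5` = 0.06, `6` = 0.04, `7` = 0.02),
      variance_components = list(cg_var = 4, animal_var = 4.2, resid_var = 11.8),
      fixed_effects = list(
        mu = 14, sex_effect = 0.8,
        birth_litter = c(`1` = 0, `2` = 0.2, `3+` = 0.35),
        rearing_litter = c(`1` = 0, `2` = 0.15, `3+` = 0.25),
        age_slope = 0.25, age_ref = 7,
        heterosis_slope = -0.6, recombination_slope = 0.4,
        # Vendeen is not separately modelled in the growing cohort, so it
        # carries no effect distinct from the pooled Other class
        breed_effects = c(Belclare = -0.8, `Blackface Mountain` = 0.6,
                          Charollais = -2.1, Cheviot = -1.0, Lleyn = -0.5,
                          Texel = 0.3, Vendeen = 0, Other = 0)
      ),
      trait_links = list(mbw = 0.35, dmi = 1.8),
      body_weight = list(mean = 48, sd_animal = 9, sd_record = 2.5,
                         min = 25, max = 80),
      dmi = list(mean = 1.53, sd_animal = 0.42, sd_record = 0.38,
                 animal_fraction = 0.053, per_record = FALSE,
                 bw_slope = 0.02),
      co2 = list(mean = 690, sd = 130, ch4_slope = 9,
                 spike_prob = 0.004, spike = 2200),
      age = list(mean_days = 223, sd_days = 55, min_days = 105,
                 max_days = 590, classes = "months"),
      session_span = 140L,
      female_fraction = 0.63,
      lactating_fraction = 0,
      ct_fraction = 0.22,
      slaughter_fraction = 0.26,
      weights_per_animal = 4L
    ))
  } else {
    c(common, list(
      n_animals = 3900L,
      records_per_animal = c(`1` = 0.72, `2` = 0.07, `3` = 0.07, `4` = 0.07,
                             `5` = 0.05, `6` = 0.02),
      variance_components = list(cg_var = 8, animal_var = 10.2, resid_var = 19.8),
      fixed_effects = list(
        mu = 21, sex_effect = 0,
        birth_litter = c(`1` = 0, `2` = 0.2, `3+` = 0.35),
        rearing_litter = c(`1` = 0, `2` = 0.15, `3+` = 0.25),
        age_slope = 0.3, age_ref = 4,
        lactation_effect = 1.5,
        heterosis_slope = -0.6, recombination_slope = 0.4,
        # Blackface Mountain is not separately modelled in ewes
        breed_effects = c(Belclare = -2.2, `Blackface Mountain` = 0,
                          Charollais = -1.0, Cheviot = -4.4, Lleyn = -0.5,
                          Texel = 0.3, Vendeen = 0.2, Other = 0)
      ),
      trait_links = list(mbw = 0.4, dmi = 2.0),
      body_weight = list(mean = 75, sd_animal = 7.5, sd_record = 3,
                         min = 55, max = 100),
      dmi = list(mean = 1.86, sd_animal = 0.5, sd_record = 0.45,
                 animal_fraction = 0.14, per_record = TRUE,
                 bw_slope = 0.02),
      co2 = list(mean = 1030, sd = 180, ch4_slope = 9,
                 spike_prob = 0.004, spike = 2000),
      age = list(mean_days = 1412, sd_days = 560, min_days = 380,
                 max_days = 3850, classes = "years"),
      session_span = 600L,
      female_fraction = 1,
      lactating_fraction = 0.256,
      ct_fraction = 0,
      slaughter_fraction = 0,
      weights_per_animal = 0L
    ))
  }
}

#' Configure a synthetic flock simulation
#'
#' Builds the configuration object consumed by [simulate_flocks()]. Defaults
#' emulate the structure of a multi-breed Irish PAC phenotyping campaign:
#' flock x measurement-date x PAC-run contemporary groups (12 chamber slots,
#' runs may be partially filled), a crossbred population of purebreds, F1s
#' and Dirichlet-mixed composites over the main breed set, repeated records
#' on roughly 28\% of animals, and cohort-specific body-weight windows
#' (growing 25--80 kg, ewes 55--100 kg) enforced by construction.
#'
#' @param cohort \code{"growing"} or \code{"ewe"}.
#' @param seed Integer seed; the generator derives deterministic sub-seeds
#'   per table from it.
#' @param n_animals,n_flocks Population size.
#' @param records_per_animal A single count, or a named numeric vector of
#'   probabilities over counts (names are the counts).
#' @param variance_components List with \code{cg_var}, \code{animal_var},
#'   \code{resid_var} in (g/d)^2 for the methane model.
#' @param fixed_effects,trait_links,... Overrides merged into the cohort
#'   defaults (see the package vignette for the full catalogue and the
#'   rationale behind each default).
#' @return Object of class \code{sim_config}.
#' @examples
#' cfg <- sim_config("growing", seed = 1, n_animals = 100,
#'                   records_per_animal = 2)
#' @export
sim_config <- function(cohort = c("growing", "ewe"), seed = 1L,
                       n_animals = NULL, n_flocks = NULL,
                       records_per_animal = NULL,
                       variance_components = NULL,
                       fixed_effects = NULL, trait_links = NULL, ...) {
  cohort <- match.arg(cohort)
  cfg <- sim_defaults(cohort)
  cfg$cohort <- cohort
  cfg$seed <- as.integer(seed)
  if (!is.null(n_animals)) cfg$n_animals <- as.integer(n_animals)
  if (!is.null(n_flocks)) cfg$n_flocks <- as.integer(n_flocks)
  if (!is.null(records_per_animal)) cfg$records_per_animal <- records_per_animal
  if (!is.null(variance_components)) {
    cfg$variance_components <- utils::modifyList(cfg$variance_components,
                                                 variance_components)
  }
  if (!is.null(fixed_effects)) {
    cfg$fixed_effects <- utils::modifyList(cfg$fixed_effects, fixed_effects)
  }
  if (!is.null(trait_links)) {
    cfg$trait_links <- utils::modifyList(cfg$trait_links, trait_links)
  }
  dots <- list(...)
  for (nm in names(dots)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      utils::modifyList(cfg[[nm]], dots[[nm]])
    } else dots[[nm]]
  }
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  vc <- cfg$variance_components
  if (any(unlist(vc) < 0)) stop("variance components must be non-negative")
  if (cfg$n_animals < 1L) stop("cohort must contain at least one animal")
  rp <- cfg$records_per_animal
  if (length(rp) == 1L && is.null(names(rp))) {
    if (rp < 1) stop("records_per_animal must be >= 1")
  } else {
    counts <- as.integer(names(rp))
    if (anyNA(counts) || any(counts < 1L)) {
      stop("records_per_animal probabilities must be named by counts >= 1")
    }
    if (any(rp < 0) || abs(sum(rp) - 1) > 1e-8) {
      stop("records_per_animal probabilities must be in [0,1] and sum to 1")
    }
  }
  probs <- c(cfg$breed_mix, cfg$breed_freq, cfg$litter_probs,
             cfg$female_fraction, cfg$lactating_fraction,
             cfg$dmi$animal_fraction, cfg$ct_fraction, cfg$slaughter_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities/fractions must lie in [0,1]")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Synthetic flock config: %s cohort, %d animals, %d flocks, seed %d\n",
              x$cohort, x$n_animals, x$n_flocks, x$seed))
  vc <- x$variance_components
  cat(sprintf("  variance components (g/d)^2: cg %.3g, animal %.3g, residual %.3g\n",
              vc$cg_var, vc$animal_var, vc$resid_var))
  invisible(x)
}

#' Configuration for a repeatability calibration study
#'
#' Builds a [sim_config()] in which the true between-animal fraction of the
#' methane variance (net of fixed effects and contemporary group) equals the
#' requested repeatability: the production-trait links are switched off so
#' no unmodelled intake variance leaks into the animal term, and the animal
#' variance is set to \eqn{R/(1-R)} times the cohort's residual variance.
#' The flock count is kept small so PAC runs are full (about 12 animals per
#' contemporary group), which keeps the group variance well identified and
#' the repeatability estimator precise.
#'
#' @param cohort \code{"growing"} or \code{"ewe"}.
#' @param repeatability Target intraclass correlation in (0, 1).
#' @param n_animals Number of animals (default 1000).
#' @param records_per_animal Records per animal (default 2).
#' @param seed Integer seed.
#' @return A \code{sim_config}.
#' @export
repeatability_study_config <- function(cohort, repeatability,
                                       n_animals = 1000L,
                                       records_per_animal = 2L, seed = 1L) {
  stopifnot(repeatability > 0, repeatability < 1)
  base <- sim_defaults(cohort)
  resid <- base$variance_components$resid_var
  sim_config(cohort, seed = seed, n_animals = n_animals,
             n_flocks = 10L,
             records_per_animal = records_per_animal,
             variance_components = list(
               animal_var = repeatability / (1 - repeatability) * resid),
             trait_links = list(mbw = 0, dmi = 0))
}
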