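growing_rmt <- c("RMT_BW", "RMT_MBW", "RMT_DMI", "RMT_MBW+DMI", "RMT_ADG",
                 "RMT_CW", "RMT_MBW+ADG")
ewe_rmt <- c("RMT_BW", "RMT_MBW", "RMT_DMI", "RMT_MBW+DMI")

rmt_production_terms <- list(
  "RMT_BW" = "body_weight", "RMT_MBW" = "mbw", "RMT_DMI" = "dmi",
  "RMT_MBW+DMI" = c("mbw", "dmi"), "RMT_ADG" = "adg_kg",
  "RMT_CW" = "carcass_weight", "RMT_MBW+ADG" = c("mbw", "adg_kg"))

#' Residual methane trait catalogue
#'
#' Names of the residual methane traits defined per cohort: seven for
#' growing animals, four for ewes. Each trait adjusts daily methane for one
#' production trait or a combination (body weight, metabolic body weight,
#' dry matter intake, average daily gain, carcass weight) on top of the
#' cohort's systematic fixed effects and the random contemporary-group and
#' animal terms.
#'
#' @param cohort \code{"growing"} or \code{"ewe"}.
#' @return Character vector of trait names.
#' @export
residual_trait_names <- function(cohort = c("growing", "ewe")) {
  cohort <- match.arg(cohort)
  if (cohort == "growing") growing_rmt else ewe_rmt
}

breed_covariate_columns <- function(cohort) {
  # Suffolk is the reference breed in both cohorts; the remaining listed
  # breeds plus the pooled Other class enter as continuous proportions
  if (cohort == "growing") {
    paste0("breed_", bcode(c("Belclare", "Blackface Mountain", "Charollais",
                             "Cheviot", "Lleyn", "Texel", "Other")))
  } else {
    paste0("breed_", bcode(c("Belclare", "Charollais", "Cheviot", "Lleyn",
                             "Texel", "Vendeen", "Other")))
  }
}

#' Model specification for a residual methane trait
#'
#' Builds the [lmm_spec()] for one residual trait: daily methane as the
#' response; sex (growing) or lactation status (ewes), birth and rearing
#' litter size and age class as categorical fixed effects; heterosis,
#' recombination loss and the non-reference breed proportions as continuous
#' covariates; the trait's production term(s) appended as covariates; and
#' contemporary group and animal as random terms.
#'
#' @param name A trait name from [residual_trait_names()].
#' @param cohort \code{"growing"} or \code{"ewe"}.
#' @return An [lmm_spec()].
#' @export
residual_trait_spec <- function(name, cohort = c("growing", "ewe")) {
  cohort <- match.arg(cohort)
  if (!name %in% residual_trait_names(cohort)) {
    stop(sprintf("'%s' is not a residual trait of the %s cohort", name, cohort))
  }
  factors <- if (cohort == "growing") {
    c("sex", "birth_litter", "rearing_litter", "age_class")
  } else {
    c("age_class", "lactation", "birth_litter", "rearing_litter")
  }
  ref <- c(sex = "female", lactation = "dry", birth_litter = "1",
           rearing_litter = "1",
           age_class = if (cohort == "growing") "7" else "4")
  covars <- c("recombination", "heterosis", breed_covariate_columns(cohort),
              rmt_production_terms[[name]])
  lmm_spec("ch4", factors = factors, covariates = covars,
           random = c("contemporary_group", "animal_id"),
           ref_levels = as.list(ref), cohort = cohort)
}

#' Derive a residual methane trait
#'
#' Fits the trait's mixed model and returns the per-record residual methane
#' values in g/d. In the default mode the derived value retains the animal
#' effect: \code{y - (X beta + CG BLUP)}, i.e. permanent animal deviation
#' plus conditional residual, so the trait captures animal-specific factors
#' (host genetics, rumen microbiome) beyond the modelled production level.
#' \code{mode = "conditional"} instead subtracts the animal BLUP too. Values
#' are reported as deviations from their cohort mean (a residual trait has
#' mean zero by definition; \code{center = FALSE} gives the raw deviations,
#' whose mean is already within shrinkage error of zero).
#'
#' @param name Trait name from [residual_trait_names()].
#' @param data Model data frame (see [prepare_model_data()]): methane
#'   records joined with animal covariates and production terms.
#' @param cohort \code{"growing"} or \code{"ewe"}.
#' @param mode \code{"animal"} (default) or \code{"conditional"}.
#' @param center Centre the derived values on zero (default TRUE).
#' @param ... Passed to [fit_lmm()].
#' @return List with \code{values} (data frame record_id, animal_id, value),
#'   \code{fit} (the \code{methlmm} object) and \code{name}.
#' @export
derive_residual_trait <- function(name, data, cohort = c("growing", "ewe"),
                                  mode = c("animal", "conditional"),
                                  center = TRUE, ...) {
  cohort <- match.arg(cohort)
  mode <- match.arg(mode)
  spec <- residual_trait_spec(name, cohort)
  if (!is.null(data$cohort) && !all(data$cohort == cohort)) {
    stop("data contain records from a different cohort")
  }
  fit <- fit_lmm(spec, data, ...)
  stop_if_not_converged(fit)
  resid <- fit$y - fit$fitted_fixed
  if ("contemporary_group" %in% names(fit$fitted_random)) {
    resid <- resid - fit$fitted_random[["contemporary_group"]]
  }
  if (mode == "conditional" && "animal_id" %in% names(fit$fitted_random)) {
    resid <- resid - fit$fitted_random[["animal_id"]]
  }
  if (center) resid <- resid - mean(resid)
  used <- which(fit$complete)
  list(name = name,
       values = data.frame(record_id = data$record_id[used],
                           animal_id = data$animal_id[used],
                           value = resid, stringsAsFactors = FALSE),
       fit = fit)
}

#' Derive every residual trait of a cohort
#'
#' Convenience wrapper over [derive_residual_trait()]: records missing a
#' production term are excluded from that trait only, so trait columns have
#' differing record counts.
#'
#' @inheritParams derive_residual_trait
#' @param names Traits to derive (default: the cohort catalogue).
#' @return List with \code{values} (wide data frame record_id x trait) and
#'   \code{fits}.
#' @export
derive_all_residual_traits <- function(data, cohort = c("growing", "ewe"),
                                       names = NULL, mode = "animal",
                                       center = TRUE, ...) {
  cohort <- match.arg(cohort)
  if (is.null(names)) names <- residual_trait_names(cohort)
  fits <- list()
  wide <- data.frame(record_id = data$record_id,
                     animal_id = data$animal_id, stringsAsFactors = FALSE)
  for (nm in names) {
    pt <- rmt_production_terms[[nm]]
    if (!all(pt %in% colnames(data)) ||
        !any(stats::complete.cases(data[, pt, drop = FALSE]))) next
    d <- tryCatch(derive_residual_trait(nm, data, cohort, mode = mode,
                                        center = center, ...),
                  error = function(e) {
                    warning(sprintf("skipping %s: %s", nm, conditionMessage(e)),
                            call. = FALSE)
                    NULL
                  })
    if (is.null(d)) next
    fits[[nm]] <- d$fit
    wide[[nm]] <- d$values$value[match(wide$record_id, d$values$record_id)]
  }
  list(values = wide, fits = fits)
}
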