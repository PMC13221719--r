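#' Write / read a dataset bundle as plain CSV tables
#'
#' One CSV per entity (animals, emissions, dmi, weights, carcass, ct,
#' maternal) with ISO-8601 dates, plus the generating configuration echoed
#' as a YAML sidecar when present.
#'
#' @param bundle A [simulate_flocks()] bundle (or a list of equally named
#'   data frames).
#' @param dir Directory to write into (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c("animals", "emissions", "dmi", "weights", "carcass", "ct",
              "maternal")
  written <- character()
  for (tb in tables) {
    if (!is.null(bundle[[tb]])) {
      f <- file.path(dir, paste0(tb, ".csv"))
      utils::write.csv(bundle[[tb]], f, row.names = FALSE)
      written <- c(written, f)
    }
  }
  if (!is.null(bundle$config)) {
    cfg <- unclass(bundle$config)
    f <- file.path(dir, "config.yaml")
    yaml::write_yaml(cfg, f)
    written <- c(written, f)
  }
  invisible(written)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  out <- list()
  for (tb in c("animals", "emissions", "dmi", "weights", "carcass", "ct",
               "maternal")) {
    f <- file.path(dir, paste0(tb, ".csv"))
    if (file.exists(f)) {
      d <- utils::read.csv(f, stringsAsFactors = FALSE)
      for (dc in intersect(c("measurement_date", "date", "birth_date",
                             "slaughter_date"), names(d))) {
        d[[dc]] <- as.Date(d[[dc]])
      }
      if ("age_class" %in% names(d)) d$age_class <- as.character(d$age_class)
      for (lc in intersect(c("birth_litter", "rearing_litter"), names(d))) {
        d[[lc]] <- as.character(d[[lc]])
      }
      out[[tb]] <- d
    }
  }
  f <- file.path(dir, "config.yaml")
  if (file.exists(f)) out$config <- yaml::read_yaml(f)
  out
}

#' Assemble the model data frame for the mixed models
#'
#' Joins filtered emission records with animal covariates (sex, litter
#' sizes, heterosis, recombination, breed proportions), derives metabolic
#' body weight per record, and attaches per-record production terms (DMI,
#' ADG, carcass weight) where linked.
#'
#' @param records Filtered emission records carrying
#'   \code{contemporary_group}.
#' @param animals Animal table.
#' @param covariates Optional output of [build_covariates()]; when absent,
#'   heterosis/recombination are taken from the animal table.
#' @param dmi_links,adg,carcass_links Linked production tables from
#'   [apply_weight_and_window_filters()].
#' @return Data frame with one row per record, ready for
#'   [derive_residual_trait()] and [estimate_repeatability()].
#' @export
prepare_model_data <- function(records, animals, covariates = NULL,
                               dmi_links = NULL, adg = NULL,
                               carcass_links = NULL) {
  acols <- c("animal_id", "birth_litter", "rearing_litter",
             grep("^breed_", names(animals), value = TRUE))
  if (!"sex" %in% names(records)) acols <- c(acols, "sex")
  if (is.null(covariates)) {
    acols <- c(acols, intersect(c("heterosis", "recombination"),
                                names(animals)))
  }
  d <- merge(records, animals[, acols, drop = FALSE], by = "animal_id",
             sort = FALSE)
  if (!is.null(covariates)) {
    d <- merge(d, covariates$animal, by = "animal_id", sort = FALSE)
  }
  d$mbw <- metabolic_body_weight(d$body_weight)
  link <- function(tab, col) {
    if (is.null(tab) || !nrow(tab)) rep(NA_real_, nrow(d)) else
      tab[[col]][match(d$record_id, tab$record_id)]
  }
  d$dmi <- link(dmi_links, "dmi")
  d$adg <- link(adg, "adg")
  d$adg_kg <- d$adg / 1000
  d$carcass_weight <- link(carcass_links, "carcass_weight")
  d[order(d$record_id), , drop = FALSE]
}

#' Configure a full pipeline run
#'
#' @param output_dir Directory for all stage outputs.
#' @param cohort \code{"growing"} or \code{"ewe"}.
#' @param simulate Optional [sim_config()] (takes precedence over
#'   \code{input_dir}).
#' @param input_dir Optional directory of CSV tables (see [read_bundle()]).
#' @param qc List of QC thresholds: \code{ch4_floor}, \code{sd_mult},
#'   \code{co2_ceiling}, \code{min_group}.
#' @param rmt_mode Residual-trait mode (\code{"animal"} or
#'   \code{"conditional"}).
#' @param include_cg Keep contemporary group in the repeatability model.
#' @param nboot Bootstrap replicates for the repeatability SE.
#' @param seed Seed for the bootstrap stage.
#' @param ranking_metrics Metric columns for the selection comparison.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(output_dir, cohort = c("growing", "ewe"),
                            simulate = NULL, input_dir = NULL,
                            qc = list(), rmt_mode = "animal",
                            include_cg = TRUE, nboot = 0L, seed = 1L,
                            ranking_metrics = c("ch4", "mi_mbw", "my",
                                                "RMT_MBW+DMI")) {
  cohort <- match.arg(cohort)
  qc <- utils::modifyList(list(ch4_floor = 4, sd_mult = 3,
                               co2_ceiling = 2500, min_group = 5L), qc)
  if (any(unlist(qc[c("ch4_floor", "sd_mult", "co2_ceiling")]) <= 0)) {
    stop("QC thresholds must be positive")
  }
  if (is.null(simulate) && is.null(input_dir)) {
    stop("either a simulation config or an input directory is required")
  }
  if (!is.null(input_dir) && is.null(simulate) && !dir.exists(input_dir)) {
    stop("input_dir does not exist: ", input_dir)
  }
  structure(list(output_dir = output_dir, cohort = cohort,
                 simulate = simulate, input_dir = input_dir, qc = qc,
                 rmt_mode = rmt_mode, include_cg = include_cg,
                 nboot = nboot, seed = as.integer(seed),
                 ranking_metrics = ranking_metrics),
            class = "pipeline_config")
}

#' Run the full methane-metric analysis pipeline
#'
#' Sequences the stages: simulate (optional) -> contemporary groups + QC
#' editing -> covariates -> ratio traits -> residual traits ->
#' repeatability -> correlations -> top-quartile ranking. Every stage
#' writes its CSV output and appends to a structured JSON-lines log;
#' identical configurations produce identical artifact trees.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the stage results and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$output_dir, "pipeline_log.jsonl")
  if (file.exists(logf)) unlink(logf)
  log_stage <- function(stage, ...) {
    entry <- c(list(stage = stage), list(...))
    cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
        file = logf, append = TRUE, sep = "")
  }
  outp <- function(name) file.path(config$output_dir, name)
  res <- list()

  ## simulate or load
  bundle <- if (!is.null(config$simulate)) {
    b <- simulate_flocks(config$simulate)
    write_bundle(b, outp("input"))
    b
  } else {
    read_bundle(config$input_dir)
  }
  if (is.null(bundle$emissions) || !nrow(bundle$emissions)) {
    stop("pipeline input has no emission records")
  }
  log_stage("input", n_records = nrow(bundle$emissions),
            n_animals = nrow(bundle$animals))

  ## covariates (heterosis/recombination from breed vectors, ADG)
  cov <- build_covariates(bundle$animals, emissions = bundle$emissions,
                          weights = bundle$weights)
  utils::write.csv(cov$animal, outp("covariates.csv"), row.names = FALSE)
  log_stage("covariates", n_animals = nrow(cov$animal),
            n_adg = if (is.null(cov$adg)) 0L else sum(!is.na(cov$adg$adg)))

  ## contemporary groups + emission QC
  cg <- assign_contemporary_groups(bundle$emissions)
  ef <- apply_emission_filters(cg$records, ch4_floor = config$qc$ch4_floor,
                               sd_mult = config$qc$sd_mult,
                               co2_ceiling = config$qc$co2_ceiling,
                               min_group = config$qc$min_group)
  wf <- apply_weight_and_window_filters(
    ef$records, config$cohort, dmi = bundle$dmi, carcass = bundle$carcass,
    ct = bundle$ct, adg = cov$adg, sd_mult = config$qc$sd_mult)
  exclusions <- rbind(
    if (nrow(cg$rejected)) data.frame(record_id = cg$rejected$record_id,
                                      rule = cg$rejected$reason,
                                      value = NA_real_,
                                      stringsAsFactors = FALSE),
    ef$exclusions, wf$exclusions)
  utils::write.csv(wf$records, outp("filtered_emissions.csv"),
                   row.names = FALSE)
  utils::write.csv(exclusions, outp("exclusions.csv"), row.names = FALSE)
  log_stage("qc", n_in = nrow(bundle$emissions), n_out = nrow(wf$records),
            n_excluded = nrow(exclusions))
  if (!nrow(wf$records)) stop("qc removed every record")

  ## ratio traits
  rt <- compute_ratio_traits(wf$records, dmi_links = wf$dmi_links,
                             adg = wf$adg, carcass_links = wf$carcass_links,
                             ct_links = wf$ct_links)
  utils::write.csv(rt$traits, outp("traits.csv"), row.names = FALSE)
  log_stage("ratio_traits", n_rows = nrow(rt$traits))

  ## residual traits
  model_data <- prepare_model_data(wf$records, bundle$animals,
                                   covariates = cov,
                                   dmi_links = wf$dmi_links, adg = wf$adg,
                                   carcass_links = wf$carcass_links)
  rmt <- derive_all_residual_traits(model_data, config$cohort,
                                    mode = config$rmt_mode)
  utils::write.csv(rmt$values, outp("residual_traits.csv"),
                   row.names = FALSE)
  log_stage("residual_traits", traits = names(rmt$fits))

  ## repeatability of methane
  rep_spec <- residual_trait_spec("RMT_BW", config$cohort)
  rep_cov <- setdiff(rep_spec$covariates, "body_weight")
  rpt <- estimate_repeatability(model_data, "ch4",
                                factors = rep_spec$factors,
                                covariates = rep_cov,
                                ref_levels = rep_spec$ref_levels,
                                include_cg = config$include_cg,
                                nboot = config$nboot, seed = config$seed)
  utils::write.csv(data.frame(trait = "ch4", R = rpt$R, SE = rpt$SE),
                   outp("repeatability.csv"), row.names = FALSE)
  log_stage("repeatability", R = rpt$R)

  ## correlations among metrics
  all_traits <- merge(rt$traits, rmt$values[, setdiff(names(rmt$values),
                                                      "animal_id")],
                      by = "record_id", all.x = TRUE)
  corr_cols <- setdiff(names(all_traits)[vapply(all_traits, is.numeric, TRUE)],
                       "pac_run")
  corr <- correlation_matrix(all_traits, corr_cols)
  utils::write.csv(corr, outp("correlations.csv"), row.names = FALSE)
  log_stage("correlations", n_pairs = nrow(corr))

  ## top-quartile ranking
  rank_res <- NULL
  metrics <- intersect(config$ranking_metrics, names(all_traits))
  complete_animals <- unique(all_traits$animal_id[
    rowSums(is.na(all_traits[, metrics, drop = FALSE])) == 0])
  if (length(metrics) == length(config$ranking_metrics) &&
      length(complete_animals) >= 8L) {
    gt <- data.frame(record_id = model_data$record_id,
                     dmi = model_data$dmi, ch4 = model_data$ch4,
                     body_weight = model_data$body_weight,
                     stringsAsFactors = FALSE)
    if (config$cohort == "growing" && "weaning_weight" %in% names(bundle$animals)) {
      gt$weaning_weight <- bundle$animals$weaning_weight[
        match(model_data$animal_id, bundle$animals$animal_id)]
    }
    if (config$cohort == "ewe" && !is.null(bundle$maternal) &&
        nrow(bundle$maternal)) {
      midx <- match(model_data$animal_id, bundle$maternal$animal_id)
      gt$lambs_born <- bundle$maternal$lambs_born[midx]
      gt$lambs_reared <- bundle$maternal$lambs_reared[midx]
    }
    rank_res <- rank_top_quartile(all_traits, metrics, group_traits = gt)
    utils::write.csv(rank_res$group_means, outp("ranking_report.csv"),
                     row.names = FALSE)
    log_stage("ranking", n_complete = rank_res$n_complete,
              n_selected = rank_res$n_selected)
  } else {
    log_stage("ranking", skipped = "fewer than 8 complete-case animals")
  }

  ## trait summary last: absolute + ratio + residual columns together
  summ <- trait_summary(all_traits,
                        setdiff(corr_cols, c("age_days", "body_weight")))
  utils::write.csv(summ, outp("trait_summary.csv"), row.names = FALSE)

  invisible(list(bundle = bundle, records = wf$records, qc = wf,
                 covariates = cov, traits = rt$traits, residual = rmt,
                 repeatability = rpt, correlations = corr,
                 ranking = rank_res, summary = summ,
                 output_dir = config$output_dir))
}
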