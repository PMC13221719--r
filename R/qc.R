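#' Assign contemporary groups
#'
#' Annotates emission records with their contemporary-group key -- flock x
#' measurement date x PAC run -- and the group size counted over distinct
#' animals. Records missing any key field are rejected with a logged reason.
#'
#' @param records Emission-record data frame with \code{flock_id},
#'   \code{measurement_date}, \code{pac_run}, \code{animal_id}.
#' @return List with \code{records} (annotated with
#'   \code{contemporary_group} and \code{cg_size}) and \code{rejected}
#'   (dropped rows with a \code{reason} column).
#' @export
assign_contemporary_groups <- function(records) {
  need <- c("animal_id", "flock_id", "measurement_date", "pac_run")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack key columns: ", paste(miss, collapse = ", "))
  bad <- !stats::complete.cases(records[, need])
  rejected <- records[bad, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- "missing contemporary-group key field"
  records <- records[!bad, , drop = FALSE]
  records$contemporary_group <- paste(records$flock_id,
                                      records$measurement_date,
                                      records$pac_run, sep = "|")
  sizes <- tapply(records$animal_id, records$contemporary_group,
                  function(a) length(unique(a)))
  records$cg_size <- as.integer(sizes[records$contemporary_group])
  list(records = records, rejected = rejected)
}

exclusion_rows <- function(records, rule, value) {
  exclusion_df(if (nrow(records)) records$record_id else character(), rule, value)
}

exclusion_df <- function(ids, rule, value) {
  if (!length(ids)) {
    return(data.frame(record_id = character(), rule = character(),
                      value = numeric(), stringsAsFactors = FALSE))
  }
  data.frame(record_id = ids, rule = rule, value = value,
             stringsAsFactors = FALSE)
}

#' Apply the gaseous-emission editing rules
#'
#' Within a cohort dataset: methane records below the hard floor (default
#' 4 g/d) are removed; records more than \code{sd_mult} (default 3) standard
#' deviations from the cohort mean (mean and SD computed once on the
#' post-floor data, no iteration) are removed; carbon-dioxide values above
#' the CO2 ceiling (default 2,500 g/d) are retained for methane traits but
#' flagged invalid for all CO2-based traits. Optionally, contemporary groups
#' with fewer than \code{min_group} animals (default 5) are then dropped.
#'
#' @param records Emission records (after [assign_contemporary_groups()] if
#'   the group-size rule is wanted).
#' @param ch4_floor Minimum admissible methane, g/d.
#' @param sd_mult Width of the outlier screen in SD units.
#' @param co2_ceiling Maximum CO2 admissible for CO2-based traits, g/d.
#' @param min_group Minimum animals per contemporary group; \code{NULL} (or
#'   records without a \code{cg_size} column) skips the rule.
#' @return List with \code{records} (retained, with logical column
#'   \code{co2_valid}) and \code{exclusions} (record_id, rule, value).
#' @export
apply_emission_filters <- function(records, ch4_floor = 4, sd_mult = 3,
                                   co2_ceiling = 2500, min_group = 5L) {
  if (!nrow(records)) {
    warning("no emission records supplied")
    return(list(records = records, exclusions = exclusion_rows(records, "", 0)))
  }
  excl <- list()

  low <- records$ch4 < ch4_floor
  excl[[1]] <- exclusion_rows(records[low, ], "ch4_below_floor",
                              records$ch4[low])
  records <- records[!low, , drop = FALSE]

  mu <- mean(records$ch4)
  sdv <- stats::sd(records$ch4)
  out <- abs(records$ch4 - mu) > sd_mult * sdv
  out[is.na(out)] <- FALSE
  excl[[2]] <- exclusion_rows(records[out, ], "ch4_outside_3sd",
                              records$ch4[out])
  records <- records[!out, , drop = FALSE]

  records$co2_valid <- records$co2 <= co2_ceiling
  excl[[3]] <- exclusion_rows(records[!records$co2_valid, ],
                              "co2_above_ceiling_co2_traits_only",
                              records$co2[!records$co2_valid])

  if (!is.null(min_group) && "cg_size" %in% names(records)) {
    # recompute group sizes on the surviving records before applying the rule
    sizes <- tapply(records$animal_id, records$contemporary_group,
                    function(a) length(unique(a)))
    records$cg_size <- as.integer(sizes[records$contemporary_group])
    small <- records$cg_size < min_group
    excl[[4]] <- exclusion_rows(records[small, ], "contemporary_group_lt_min",
                                records$cg_size[small])
    records <- records[!small, , drop = FALSE]
  }

  list(records = records, exclusions = do.call(rbind, excl))
}

#' Apply body-weight window and production-table edits
#'
#' Enforces the production-data editing rules on a dataset bundle:
#' \itemize{
#'   \item body weight at measurement inside the cohort window (growing
#'     25--80 kg, ewes 55--100 kg);
#'   \item carcass: cold carcass weight 15--26 kg, slaughter age 100--450 d,
#'     slaughter within 30 d of a methane record; where several methane
#'     records fall in that window the one closest to slaughter is paired;
#'   \item ADG: only slopes of 150--350 g/d retained;
#'   \item CT: only scans within 3 d of a methane record, and trait values
#'     within \code{sd_mult} SD of the trait mean;
#'   \item DMI: only intakes within 30 d of a methane record, and values
#'     within \code{sd_mult} SD of the mean.
#' }
#' All windows are inclusive of both endpoints. Unlinkable production rows
#' are dropped and logged.
#'
#' @param records Filtered emission records.
#' @param cohort \code{"growing"} or \code{"ewe"}.
#' @param dmi,carcass,ct Optional production tables as produced by
#'   [simulate_flocks()].
#' @param adg Optional per-record ADG table from [build_covariates()].
#' @param sd_mult SD-screen width (default 3).
#' @param bw_window Override of the body-weight window \code{c(min, max)}.
#' @return List with \code{records}, linked production tables keyed by
#'   record (\code{dmi_links}, \code{adg}, \code{carcass_links},
#'   \code{ct_links}), and \code{exclusions}.
#' @export
apply_weight_and_window_filters <- function(records, cohort,
                                            dmi = NULL, carcass = NULL,
                                            ct = NULL, adg = NULL,
                                            sd_mult = 3, bw_window = NULL) {
  excl <- list()
  win <- if (!is.null(bw_window)) bw_window else {
    if (cohort == "growing") c(25, 80) else c(55, 100)
  }
  bad <- records$body_weight < win[1] | records$body_weight > win[2]
  excl$bw <- exclusion_rows(records[bad, ], "body_weight_outside_window",
                            records$body_weight[bad])
  records <- records[!bad, , drop = FALSE]

  out <- list(records = records)
  rec_dates <- records$measurement_date
  rec_animal <- records$animal_id

  if (!is.null(dmi) && nrow(dmi)) {
    linked <- merge(dmi, records[, c("record_id", "animal_id",
                                     "measurement_date")],
                    by = "animal_id")
    gap <- abs(as.numeric(linked$date - linked$measurement_date))
    linked <- linked[gap <= 30, , drop = FALSE]
    # closest intake first, so a record pairing picks the nearest one
    linked <- linked[order(linked$record_id,
                           abs(as.numeric(linked$date -
                                            linked$measurement_date))), ,
                     drop = FALSE]
    orphan <- !paste(dmi$animal_id, dmi$date) %in%
      paste(linked$animal_id, linked$date)
    if (any(orphan)) {
      excl$dmi_orphan <- exclusion_df(paste0("dmi:", dmi$animal_id[orphan]),
                                      "dmi_unlinked_to_methane_record",
                                      dmi$dmi[orphan])
    }
    if (nrow(linked)) {
      mu <- mean(linked$dmi)
      sdv <- stats::sd(linked$dmi)
      far <- if (is.na(sdv) || sdv == 0) rep(FALSE, nrow(linked)) else
        abs(linked$dmi - mu) > sd_mult * sdv
      excl$dmi_sd <- exclusion_df(linked$record_id[far], "dmi_outside_3sd",
                                  linked$dmi[far])
      linked <- linked[!far, , drop = FALSE]
    }
    out$dmi_links <- linked
  }

  if (!is.null(adg) && nrow(adg)) {
    adg <- adg[adg$record_id %in% records$record_id, , drop = FALSE]
    keep <- !is.na(adg$adg) & adg$adg >= 150 & adg$adg <= 350
    excl$adg <- exclusion_df(adg$record_id[!keep & !is.na(adg$adg)],
                             "adg_outside_150_350",
                             adg$adg[!keep & !is.na(adg$adg)])
    out$adg <- adg[keep, , drop = FALSE]
  }

  if (!is.null(carcass) && nrow(carcass)) {
    cc <- carcass
    badw <- cc$carcass_weight < 15 | cc$carcass_weight > 26
    excl$cw <- exclusion_df(paste0("carcass:", cc$animal_id[badw]),
                            "carcass_weight_outside_15_26",
                            cc$carcass_weight[badw])
    cc <- cc[!badw, , drop = FALSE]
    bada <- cc$days_to_slaughter < 100 | cc$days_to_slaughter > 450
    excl$sl_age <- exclusion_df(paste0("carcass:", cc$animal_id[bada]),
                                "slaughter_age_outside_100_450",
                                cc$days_to_slaughter[bada])
    cc <- cc[!bada, , drop = FALSE]
    links <- list()
    for (i in seq_len(nrow(cc))) {
      ridx <- which(rec_animal == cc$animal_id[i])
      if (!length(ridx)) next
      gap <- abs(as.numeric(rec_dates[ridx] - cc$slaughter_date[i]))
      ok <- gap <= 30
      if (!any(ok)) next
      # closest methane measurement to slaughter retained
      pick <- ridx[ok][which.min(gap[ok])]
      links[[length(links) + 1L]] <- data.frame(
        record_id = records$record_id[pick], animal_id = cc$animal_id[i],
        carcass_weight = cc$carcass_weight[i],
        days_to_slaughter = cc$days_to_slaughter[i],
        stringsAsFactors = FALSE)
    }
    out$carcass_links <- if (length(links)) do.call(rbind, links) else
      data.frame(record_id = character(), animal_id = character(),
                 carcass_weight = numeric(), days_to_slaughter = integer(),
                 stringsAsFactors = FALSE)
  }

  if (!is.null(ct) && nrow(ct)) {
    linked <- merge(ct, records[, c("record_id", "animal_id",
                                    "measurement_date")],
                    by = "animal_id")
    linked <- linked[abs(as.numeric(linked$date -
                                      linked$measurement_date)) <= 3, ,
                     drop = FALSE]
    if (nrow(linked)) {
      keep <- rep(TRUE, nrow(linked))
      for (tr in c("muscle_mass", "fat_mass", "ko_pct", "mf_ratio",
                   "rumen_volume")) {
        mu <- mean(linked[[tr]])
        sdv <- stats::sd(linked[[tr]])
        if (!is.na(sdv) && sdv > 0) {
          keep <- keep & abs(linked[[tr]] - mu) <= sd_mult * sdv
        }
      }
      excl$ct <- exclusion_df(linked$record_id[!keep],
                              "ct_trait_outside_3sd", NA_real_)
      linked <- linked[keep, , drop = FALSE]
    }
    out$ct_links <- linked
  }

  out$exclusions <- do.call(rbind, c(excl, make.row.names = FALSE))
  out
}
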