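growing_only_ratios <- c("mi_adg", "mi_cw", "mi_mm", "mi_fm", "mi_ko",
                         "mi_mf", "mi_rumen")

#' Compute the absolute and ratio methane traits
#'
#' One row per eligible emission record with daily methane (g/d) and the
#' twelve ratio traits, each the exact quotient of methane (or CO2) by its
#' denominator:
#' \describe{
#'   \item{mi_bw, mi_mbw}{methane per kg body weight / metabolic body weight}
#'   \item{mi_adg}{methane per kg/d of average daily gain (growing only)}
#'   \item{mi_cw}{methane per kg cold carcass weight (growing only)}
#'   \item{mi_mm, mi_fm}{methane per kg CT muscle / fat mass (growing only)}
#'   \item{mi_ko}{methane per unit predicted kill-out proportion (growing only)}
#'   \item{mi_mf}{methane per unit muscle-to-fat ratio (growing only)}
#'   \item{mi_rumen}{methane per litre rumen volume (growing only)}
#'   \item{my}{methane yield, g CH4 per kg dry matter intake}
#'   \item{ch4_fraction}{CH4/(CH4 + CO2), both in g/d}
#'   \item{co2_yield}{g CO2 per kg dry matter intake}
#' }
#' A ratio is absent when its denominator is absent for the record, not
#' positive (logged), or ineligible for the cohort; CO2-based traits are
#' absent when the record's CO2 failed the ceiling screen.
#'
#' @param records Filtered emission records (with \code{co2_valid} if
#'   [apply_emission_filters()] was run).
#' @param dmi_links,adg,carcass_links,ct_links Optional per-record linked
#'   production tables from [apply_weight_and_window_filters()].
#' @return List with \code{traits} (one row per record) and \code{dropped}
#'   (record_id, trait, reason for non-positive denominators).
#' @examples
#' r <- data.frame(record_id = "r1", animal_id = "a1", cohort = "growing",
#'                 ch4 = 10, co2 = 690, body_weight = 50)
#' compute_ratio_traits(r)$traits$mi_bw  # 0.2
#' @export
compute_ratio_traits <- function(records, dmi_links = NULL, adg = NULL,
                                 carcass_links = NULL, ct_links = NULL) {
  n <- nrow(records)
  tr <- data.frame(record_id = records$record_id,
                   animal_id = records$animal_id,
                   cohort = records$cohort,
                   ch4 = records$ch4, stringsAsFactors = FALSE)
  co2_ok <- if ("co2_valid" %in% names(records)) records$co2_valid else
    rep(TRUE, n)
  dropped <- data.frame(record_id = character(), trait = character(),
                        reason = character(), stringsAsFactors = FALSE)
  drop_log <- function(ids, trait, reason) {
    if (length(ids)) {
      dropped <<- rbind(dropped, data.frame(record_id = ids, trait = trait,
                                            reason = reason,
                                            stringsAsFactors = FALSE))
    }
  }
  safe_ratio <- function(num, den, trait) {
    out <- rep(NA_real_, n)
    ok <- !is.na(num) & !is.na(den) & den > 0
    bad <- !is.na(num) & !is.na(den) & den <= 0
    drop_log(records$record_id[bad], trait, "non-positive denominator")
    out[ok] <- num[ok] / den[ok]
    out
  }
  lookup <- function(tab, col) {
    if (is.null(tab) || !nrow(tab)) return(rep(NA_real_, n))
    tab[[col]][match(records$record_id, tab$record_id)]
  }

  tr$mi_bw <- safe_ratio(records$ch4, records$body_weight, "mi_bw")
  tr$mi_mbw <- safe_ratio(records$ch4,
                          metabolic_body_weight(records$body_weight), "mi_mbw")
  dmi_kg <- lookup(dmi_links, "dmi")
  tr$my <- safe_ratio(records$ch4, dmi_kg, "my")
  co2v <- ifelse(co2_ok, records$co2, NA_real_)
  tr$ch4_fraction <- safe_ratio(records$ch4, records$ch4 + co2v,
                                "ch4_fraction")
  tr$co2_yield <- safe_ratio(co2v, dmi_kg, "co2_yield")

  growing <- records$cohort == "growing"
  gmask <- function(x) ifelse(growing, x, NA_real_)
  tr$mi_adg <- gmask(safe_ratio(records$ch4, lookup(adg, "adg") / 1000,
                                "mi_adg"))
  tr$mi_cw <- gmask(safe_ratio(records$ch4,
                               lookup(carcass_links, "carcass_weight"),
                               "mi_cw"))
  tr$mi_mm <- gmask(safe_ratio(records$ch4, lookup(ct_links, "muscle_mass"),
                               "mi_mm"))
  tr$mi_fm <- gmask(safe_ratio(records$ch4, lookup(ct_links, "fat_mass"),
                               "mi_fm"))
  tr$mi_ko <- gmask(safe_ratio(records$ch4, lookup(ct_links, "ko_pct"),
                               "mi_ko"))
  tr$mi_mf <- gmask(safe_ratio(records$ch4, lookup(ct_links, "mf_ratio"),
                               "mi_mf"))
  tr$mi_rumen <- gmask(safe_ratio(records$ch4,
                                  lookup(ct_links, "rumen_volume"),
                                  "mi_rumen"))
  list(traits = tr, dropped = dropped)
}

#' Summary table for trait columns
#'
#' Number of records and distinct animals, mean, SD, range and coefficient
#' of variation (CV = 100 SD / mean) per trait column, computed over
#' non-missing values. The CV is reported absent when the trait mean is zero
#' (as for mean-centred residual traits).
#'
#' @param traits Data frame with \code{animal_id} and trait columns.
#' @param columns Trait columns to summarise (default: all numeric columns
#'   except identifiers).
#' @return Data frame: trait, n_records, n_animals, mean, sd, min, max, cv.
#' @export
trait_summary <- function(traits, columns = NULL) {
  if (!nrow(traits)) stop("no trait rows to summarise")
  if (is.null(columns)) {
    columns <- setdiff(names(traits)[vapply(traits, is.numeric, TRUE)],
                       c("record_id", "animal_id"))
  }
  rows <- lapply(columns, function(cl) {
    v <- traits[[cl]]
    ok <- !is.na(v)
    v <- v[ok]
    if (!length(v)) {
      return(data.frame(trait = cl, n_records = 0L, n_animals = 0L,
                        mean = NA_real_, sd = NA_real_, min = NA_real_,
                        max = NA_real_, cv = NA_real_,
                        stringsAsFactors = FALSE))
    }
    m <- mean(v)
    s <- if (length(v) > 1L) stats::sd(v) else 0
    data.frame(trait = cl, n_records = length(v),
               n_animals = length(unique(traits$animal_id[ok])),
               mean = m, sd = s, min = min(v), max = max(v),
               cv = if (abs(m) < 1e-12) NA_real_ else 100 * s / m,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
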