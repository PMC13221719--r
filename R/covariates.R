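#' Metabolic body weight
#'
#' Body weight raised to the power 0.75, the interspecific metabolic-rate
#' scaling used to express maintenance requirements.
#'
#' @param bw Body weight in kg (vectorised); must be positive.
#' @return \code{bw^0.75} in kg^0.75.
#' @examples
#' metabolic_body_weight(c(16, 81))  # 8, 27
#' @export
metabolic_body_weight <- function(bw) {
  if (any(!is.finite(bw)) || any(bw <= 0)) {
    stop("body weight must be positive and finite")
  }
  bw^0.75
}

#' Average daily gain around a methane measurement
#'
#' Ordinary least-squares slope of body weight on date for one growing
#' animal, using only weights recorded within a window around the methane
#' measurement date (both endpoints inclusive). The slope is returned in
#' grams per day.
#'
#' @param dates Dates (or anything coercible via [as.Date()]) of the weight
#'   records.
#' @param weights Body weights in kg, same length as \code{dates}.
#' @param methane_date The date of the methane measurement.
#' @param window Half-width of the admissible window in days (default 120).
#' @return List with \code{adg} (g/d, \code{NA} if fewer than two in-window
#'   weights), \code{n_points} used, and \code{in_range} (logical: slope
#'   within the 150--350 g/d retention band, \code{NA} when \code{adg} is).
#' @examples
#' average_daily_gain(as.Date("2023-01-01") + c(0, 10), c(40, 42),
#'                    as.Date("2023-01-05"))
#' @export
average_daily_gain <- function(dates, weights, methane_date, window = 120) {
  dates <- as.Date(dates)
  methane_date <- as.Date(methane_date)
  if (length(dates) != length(weights)) stop("dates and weights differ in length")
  if (any(!is.finite(weights)) || any(weights <= 0)) stop("weights must be positive")
  keep <- abs(as.numeric(dates - methane_date)) <= window
  if (sum(keep) < 2L) {
    return(list(adg = NA_real_, n_points = sum(keep), in_range = NA))
  }
  # abscissa: days since the first in-window weight
  d <- as.numeric(dates[keep] - min(dates[keep]))
  w <- weights[keep]
  if (anyDuplicated(d)) {
    dup <- d[duplicated(d)]
    for (dd in unique(dup)) {
      if (length(unique(w[d == dd])) > 1L) {
        stop("conflicting weights recorded on the same date")
      }
    }
    first <- !duplicated(d)
    w <- w[first]
    d <- d[first]
  }
  if (length(d) < 2L) {
    return(list(adg = NA_real_, n_points = length(d), in_range = NA))
  }
  # two points: exact slope; more: OLS fit of kg on days, converted to g/d
  slope_kg <- if (length(d) == 2L) diff(w) / diff(d) else {
    stats::cov(d, w) / stats::var(d)
  }
  adg <- slope_kg * 1000
  list(adg = adg, n_points = length(d), in_range = adg >= 150 && adg <= 350)
}

decode_breed <- function(x) {
  # column names carry dots for syntactic validity; map back to breed names
  hit <- match(gsub(".", " ", x, fixed = TRUE), MAIN_BREEDS)
  ifelse(is.na(hit), x, MAIN_BREEDS[hit])
}

#' Derived covariates for a set of animals
#'
#' Computes heterosis and recombination-loss coefficients from the parental
#' breed vectors stored in an animal table, plus (optionally) per-record
#' average daily gain for growing animals from a longitudinal weight table.
#'
#' @param animals Animal table as produced by [simulate_flocks()]: one row
#'   per animal with columns \code{animal_id} and \code{sire_<breed>} /
#'   \code{dam_<breed>} breed-fraction columns.
#' @param emissions Optional emission-record table (needed for ADG); must
#'   carry \code{record_id}, \code{animal_id}, \code{measurement_date}.
#' @param weights Optional weight series table with \code{animal_id},
#'   \code{date}, \code{weight}.
#' @param window ADG window half-width in days.
#' @return List with \code{animal} (animal_id, heterosis, recombination) and,
#'   when \code{emissions} and \code{weights} are supplied, \code{adg}
#'   (record_id, animal_id, adg, adg_in_range).
#' @export
build_covariates <- function(animals, emissions = NULL, weights = NULL,
                             window = 120) {
  sire_cols <- grep("^sire_", names(animals), value = TRUE)
  dam_cols <- grep("^dam_", names(animals), value = TRUE)
  if (!length(sire_cols) || !length(dam_cols)) {
    stop("animal table lacks sire_/dam_ breed-fraction columns")
  }
  het <- numeric(nrow(animals))
  rec <- numeric(nrow(animals))
  for (i in seq_len(nrow(animals))) {
    s <- as.numeric(animals[i, sire_cols])
    names(s) <- decode_breed(sub("^sire_", "", sire_cols))
    d <- as.numeric(animals[i, dam_cols])
    names(d) <- decode_breed(sub("^dam_", "", dam_cols))
    # tolerate storage rounding of the fractions before the strict check
    if (abs(sum(s) - 1) < 1e-4) s <- s / sum(s)
    if (abs(sum(d) - 1) < 1e-4) d <- d / sum(d)
    sv <- breed_vector(s[s > 0])
    dv <- breed_vector(d[d > 0])
    het[i] <- heterosis_coefficient(sv, dv)
    rec[i] <- recombination_loss(sv, dv)
  }
  out <- list(animal = data.frame(animal_id = animals$animal_id,
                                  heterosis = het, recombination = rec,
                                  stringsAsFactors = FALSE))
  if (!is.null(emissions) && !is.null(weights)) {
    adg <- vapply(seq_len(nrow(emissions)), function(i) {
      ws <- weights[weights$animal_id == emissions$animal_id[i], , drop = FALSE]
      if (nrow(ws) < 2L) return(NA_real_)
      average_daily_gain(ws$date, ws$weight,
                         emissions$measurement_date[i], window = window)$adg
    }, numeric(1))
    out$adg <- data.frame(record_id = emissions$record_id,
                          animal_id = emissions$animal_id,
                          adg = adg,
                          adg_in_range = adg >= 150 & adg <= 350,
                          stringsAsFactors = FALSE)
  }
  out
}
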