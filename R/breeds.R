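#' Recognised breed names
#'
#' The breed set carried through the pipeline: the eight main breeds of the
#' Irish multi-breed sheep population plus a pooled \code{"Other"} class for
#' minor breeds.
#'
#' @format Character vector of length 9.
#' @export
MAIN_BREEDS <- c("Belclare", "Blackface Mountain", "Charollais", "Cheviot",
                 "Lleyn", "Suffolk", "Texel", "Vendeen", "Other")

#' Construct a breed-fraction vector
#'
#' A breed vector maps breed names to the fraction of that breed in a parent;
#' fractions must be non-negative and sum to one. Breeds outside
#' [MAIN_BREEDS] are pooled into \code{"Other"}.
#'
#' @param fractions Named numeric vector of breed proportions.
#' @param tol Tolerance on the sum-to-one check.
#' @return Named numeric vector of class \code{breed_vector}, covering only
#'   breeds with positive fraction.
#' @examples
#' breed_vector(c(Texel = 0.5, Suffolk = 0.5))
#' @export
breed_vector <- function(fractions, tol = 1e-9) {
  if (is.null(names(fractions)) || any(!nzchar(names(fractions)))) {
    stop("breed fractions must be named")
  }
  if (any(!is.finite(fractions)) || any(fractions < -tol)) {
    stop("breed fractions must be finite and non-negative")
  }
  if (abs(sum(fractions) - 1) > tol) {
    stop(sprintf("breed fractions must sum to 1 (got %.12f)", sum(fractions)))
  }
  nm <- names(fractions)
  nm[!nm %in% MAIN_BREEDS] <- "Other"
  out <- tapply(fractions, nm, sum)
  out <- out[out > 0]
  v <- as.numeric(out)
  names(v) <- names(out)
  structure(v, class = "breed_vector")
}

check_breed_vector <- function(x, arg = "breed vector") {
  if (!inherits(x, "breed_vector")) x <- breed_vector(x)
  x
}

#' Heterosis coefficient of a cross
#'
#' Expected fraction of loci carrying alleles from two different breeds in
#' the offspring of the given sire and dam:
#' \deqn{het = 1 - \sum_i sire_i \cdot dam_i}
#' where \eqn{sire_i}, \eqn{dam_i} are the proportions of breed \eqn{i} in
#' each parent. Zero iff both parents are purebreds of the same breed; one
#' for an F1 between two distinct purebreds.
#'
#' @param sire,dam Breed vectors (see [breed_vector()]).
#' @return Numeric scalar in \[0, 1\].
#' @examples
#' heterosis_coefficient(breed_vector(c(Texel = 1)), breed_vector(c(Suffolk = 1)))
#' @export
heterosis_coefficient <- function(sire, dam) {
  sire <- check_breed_vector(sire, "sire")
  dam <- check_breed_vector(dam, "dam")
  shared <- intersect(names(sire), names(dam))
  h <- 1 - sum(unclass(sire)[shared] * unclass(dam)[shared])
  min(max(h, 0), 1)
}

#' Recombination loss coefficient of a cross
#'
#' Expected breakdown of favourable breed-specific epistatic combinations in
#' the offspring of the given sire and dam:
#' \deqn{rec = 1 - \frac{\sum_i sire_i^2 + \sum_i dam_i^2}{2}}
#' Zero iff each parent is purebred (of any breed).
#'
#' @inheritParams heterosis_coefficient
#' @return Numeric scalar in \[0, 1\].
#' @examples
#' recombination_loss(breed_vector(c(A = 0.5, B = 0.5)), breed_vector(c(A = 1)))
#' @export
recombination_loss <- function(sire, dam) {
  sire <- check_breed_vector(sire, "sire")
  dam <- check_breed_vector(dam, "dam")
  r <- 1 - (sum(unclass(sire)^2) + sum(unclass(dam)^2)) / 2
  min(max(r, 0), 1)
}

#' Offspring breed composition
#'
#' The offspring's breed proportions are the average of the parental breed
#' vectors.
#'
#' @inheritParams heterosis_coefficient
#' @return A [breed_vector()].
#' @export
offspring_breeds <- function(sire, dam) {
  sire <- check_breed_vector(sire, "sire")
  dam <- check_breed_vector(dam, "dam")
  all_b <- union(names(sire), names(dam))
  s <- structure(numeric(length(all_b)), names = all_b)
  d <- s
  s[names(sire)] <- unclass(sire)
  d[names(dam)] <- unclass(dam)
  breed_vector((s + d) / 2)
}
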