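#' Repeatability of a repeated trait
#'
#' Intraclass correlation of a trait across repeated records on the same
#' animal, estimated from an EM-REML animal model:
#' \deqn{R = \sigma^2_A / (\sigma^2_A + \sigma^2_e)}
#' where \eqn{\sigma^2_A} is the between-animal variance and
#' \eqn{\sigma^2_e} the residual variance. By default the model also
#' carries a random contemporary-group term, whose variance is excluded from
#' the denominator (management variance is not animal permanence); setting
#' \code{include_cg = FALSE} drops the term from the model entirely.
#'
#' The standard error is obtained by parametric bootstrap: new responses are
#' simulated from the fitted model (fixed effects plus fresh random-effect
#' and residual draws at the estimated components) and the model refitted.
#'
#' @param data Data frame of emission records; must contain \code{response},
#'   an \code{animal_id} column and (if used) \code{contemporary_group}.
#' @param response Name of the trait column (e.g. \code{"ch4"}).
#' @param factors,covariates Fixed-effect terms passed to [lmm_spec()].
#' @param ref_levels Optional reference levels for the factors.
#' @param animal,cg Column names of the animal and contemporary-group terms.
#' @param include_cg Keep contemporary group as a random term (default TRUE).
#' @param nboot Bootstrap replicates for the SE (default 200; 0 skips the
#'   SE and returns \code{NA}).
#' @param seed Optional integer seed for the bootstrap.
#' @param ... Passed on to [fit_lmm()].
#' @return List with \code{R}, \code{SE}, \code{varcomp} and the underlying
#'   \code{fit}.
#' @export
estimate_repeatability <- function(data, response, factors = character(),
                                   covariates = character(), ref_levels = NULL,
                                   animal = "animal_id",
                                   cg = "contemporary_group",
                                   include_cg = TRUE, nboot = 200L,
                                   seed = NULL, ...) {
  counts <- table(data[[animal]][!is.na(data[[response]])])
  if (!any(counts >= 2L)) {
    stop("repeatability is unidentifiable: no animal has repeated records")
  }
  random <- if (include_cg && cg %in% names(data)) c(cg, animal) else animal
  spec <- lmm_spec(response, factors = factors, covariates = covariates,
                   random = random, ref_levels = ref_levels)
  fit <- fit_lmm(spec, data, ...)
  stop_if_not_converged(fit)
  s2a <- fit$varcomp[[animal]]
  s2e <- fit$varcomp[["resid"]]
  R <- s2a / (s2a + s2e)

  SE <- NA_real_
  if (nboot > 0L) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv())) {
        get(".Random.seed", envir = globalenv())
      } else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
    }
    mf <- data[fit$complete, , drop = FALSE]
    fan <- factor(mf[[animal]])
    fcg <- if (length(random) == 2L) factor(mf[[cg]]) else NULL
    Rb <- vapply(seq_len(nboot), function(b) {
      ystar <- fit$fitted_fixed +
        stats::rnorm(fit$n, sd = sqrt(s2e)) +
        sqrt(s2a) * stats::rnorm(nlevels(fan))[as.integer(fan)]
      if (!is.null(fcg)) {
        ystar <- ystar +
          sqrt(fit$varcomp[[cg]]) * stats::rnorm(nlevels(fcg))[as.integer(fcg)]
      }
      mfb <- mf
      mfb[[response]] <- ystar
      fb <- fit_lmm(spec, mfb, ...)
      fb$varcomp[[animal]] / (fb$varcomp[[animal]] + fb$varcomp[["resid"]])
    }, numeric(1))
    SE <- stats::sd(Rb)
  }
  list(R = R, SE = SE, varcomp = fit$varcomp, fit = fit)
}
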