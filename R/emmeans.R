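#' Estimated marginal means for a fixed factor
#'
#' Model-based group means for each level of a categorical fixed effect:
#' continuous covariates are held at their sample means (over the records
#' used in the fit), other categorical factors sit at their reference
#' levels, and random effects enter at their population average of zero.
#' Pairwise level differences are tested with a Wald z statistic.
#'
#' @param fit A converged [fit_lmm()] result.
#' @param factor_name Name of a categorical fixed effect of the fit.
#' @return List with \code{emmeans} (data frame: level, emmean, se) and
#'   \code{contrasts} (data frame: level_a, level_b, estimate, se, z,
#'   p_value).
#' @examples
#' d <- data.frame(y = c(1, 2, 3, 4, 13, 14, 15, 16),
#'                 sex = rep(c("female", "male"), each = 4))
#' fit <- fit_lmm(lmm_spec("y", factors = "sex"), d)
#' marginal_means(fit, "sex")
#' @export
marginal_means <- function(fit, factor_name) {
  stopifnot(inherits(fit, "methlmm"))
  stop_if_not_converged(fit)
  if (!factor_name %in% fit$factors) {
    stop(sprintf("'%s' is not a categorical fixed effect of this model",
                 factor_name))
  }
  levs <- fit$xlevels[[factor_name]]
  grid <- data.frame(row.names = seq_along(levs))
  for (f in fit$factors) {
    grid[[f]] <- factor(if (f == factor_name) levs else
                          rep(fit$xlevels[[f]][1L], length(levs)),
                        levels = fit$xlevels[[f]])
  }
  for (cv in fit$covariates) grid[[cv]] <- fit$covariate_means[[cv]]
  L <- stats::model.matrix(fit$formula, grid, xlev = fit$xlevels)
  L <- L[, names(fit$beta), drop = FALSE]
  est <- as.numeric(L %*% fit$beta)
  se <- sqrt(pmax(rowSums((L %*% fit$vcov_beta) * L), 0))
  emm <- data.frame(level = levs, emmean = est, se = se,
                    stringsAsFactors = FALSE)

  pairs <- utils::combn(seq_along(levs), 2)
  ctr <- data.frame(
    level_a = levs[pairs[1, ]], level_b = levs[pairs[2, ]],
    estimate = NA_real_, se = NA_real_, z = NA_real_, p_value = NA_real_,
    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    cvec <- L[pairs[1, k], ] - L[pairs[2, k], ]
    dse <- sqrt(max(as.numeric(cvec %*% fit$vcov_beta %*% cvec), 0))
    dest <- sum(cvec * fit$beta)
    ctr$estimate[k] <- dest
    ctr$se[k] <- dse
    ctr$z[k] <- if (dse > 0) dest / dse else NA_real_
    ctr$p_value[k] <- if (dse > 0) 2 * stats::pnorm(-abs(dest / dse)) else NA_real_
  }
  list(emmeans = emm, contrasts = ctr)
}
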