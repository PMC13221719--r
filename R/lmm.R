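#' Declare a linear mixed model
#'
#' Declarative description of a methane mixed model: a response, categorical
#' fixed factors (with optional declared reference levels), continuous
#' covariates, and up to two crossed random intercept terms (typically
#' contemporary group and animal).
#'
#' @param response Name of the response column (e.g. \code{"ch4"}).
#' @param factors Character vector of categorical fixed-effect columns.
#' @param covariates Character vector of continuous fixed-effect columns.
#' @param random Character vector (length 0--2) of random-term columns.
#' @param ref_levels Optional named character vector giving the reference
#'   level for factors (defaults to the first sorted observed level).
#' @param cohort Optional cohort tag ("growing" or "ewe") carried through to
#'   outputs.
#' @return An object of class \code{lmm_spec}.
#' @export
lmm_spec <- function(response, factors = character(), covariates = character(),
                     random = character(), ref_levels = NULL, cohort = NULL) {
  stopifnot(is.character(response), length(response) == 1L)
  if (length(random) > 2L) stop("at most two random terms are supported")
  structure(list(response = response, factors = factors,
                 covariates = covariates, random = random,
                 ref_levels = ref_levels, cohort = cohort),
            class = "lmm_spec")
}

#' @export
print.lmm_spec <- function(x, ...) {
  cat("Linear mixed model spec\n")
  cat("  response  :", x$response, "\n")
  cat("  factors   :", if (length(x$factors)) paste(x$factors, collapse = ", ") else "(none)", "\n")
  cat("  covariates:", if (length(x$covariates)) paste(x$covariates, collapse = ", ") else "(none)", "\n")
  cat("  random    :", if (length(x$random)) paste(x$random, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

# Build the fixed-effect design matrix for a spec on a model frame.
# Factors with fewer than two observed levels and zero-variance covariates
# are dropped (recorded in `dropped`): they are unestimable alongside the
# intercept rather than scientifically meaningful aliasing.
build_design <- function(spec, data) {
  keep_f <- character()
  dropped <- character()
  for (f in spec$factors) {
    v <- data[[f]]
    if (is.null(v)) stop(sprintf("model term '%s' not found in data", f))
    if (length(unique(v[!is.na(v)])) >= 2L) keep_f <- c(keep_f, f)
    else dropped <- c(dropped, f)
  }
  keep_c <- character()
  for (cv in spec$covariates) {
    v <- data[[cv]]
    if (is.null(v)) stop(sprintf("model term '%s' not found in data", cv))
    if (stats::sd(v, na.rm = TRUE) > 0 && !all(is.na(v))) keep_c <- c(keep_c, cv)
    else dropped <- c(dropped, cv)
  }
  vars <- c(spec$response, keep_f, keep_c, spec$random)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("model terms not found in data: ", paste(miss, collapse = ", "))
  mf <- data[, vars, drop = FALSE]
  complete <- stats::complete.cases(mf)
  mf <- mf[complete, , drop = FALSE]
  if (!nrow(mf)) stop("no complete records for the model terms")
  for (f in keep_f) {
    v <- factor(mf[[f]])
    ref <- spec$ref_levels[[f]]
    if (!is.null(ref) && ref %in% levels(v)) v <- stats::relevel(v, ref = ref)
    mf[[f]] <- v
  }
  rhs <- c(keep_f, keep_c)
  form <- stats::reformulate(if (length(rhs)) rhs else "1")
  X <- stats::model.matrix(form, mf)
  # rank check on the retained design
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient fixed-effect design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  covariate_means <- if (length(keep_c)) colMeans(mf[, keep_c, drop = FALSE]) else numeric()
  xlevels <- lapply(mf[keep_f], levels)
  names(xlevels) <- keep_f
  list(y = as.numeric(mf[[spec$response]]), X = X, mf = mf,
       formula = form, xlevels = xlevels, covariate_means = covariate_means,
       factors = keep_f, covariates = keep_c, dropped = dropped,
       complete = complete)
}

# EM-REML for y = X beta + Z_A u_A + Z_B u_B + e via Henderson's MME with
# the larger random factor absorbed. fA, fB are factors (fB has >= levels
# than fA); either may be NULL. Returns components, solutions, PEV traces,
# REML log-likelihood.
em_reml <- function(y, X, fA = NULL, fB = NULL, tol = 1e-8, max_iter = 2000L,
                    floor = 1e-10, accelerate = TRUE) {
  n <- length(y)
  p <- ncol(X)
  if (is.null(fB) && !is.null(fA)) { fB <- fA; fA <- NULL }

  if (is.null(fB)) {                                  # pure fixed model: OLS
    XtX <- crossprod(X)
    Xty <- crossprod(X, y)
    beta <- solve(XtX, Xty)
    res <- y - as.numeric(X %*% beta)
    s2e <- sum(res^2) / (n - p)
    m2l <- (n - p) * log(2 * pi) + (n - p) * log(s2e) +
      determinant(XtX, logarithm = TRUE)$modulus - p * log(s2e) +
      sum(res^2) / s2e
    return(list(beta = as.numeric(beta), beta_names = colnames(X),
                vcov_beta = solve(XtX) * s2e,
                varcomp = c(resid = s2e), blup_A = NULL, blup_B = NULL,
                loglik = -0.5 * as.numeric(m2l), n_iter = 0L,
                converged = TRUE, n = n, rank = p,
                fitted_fixed = as.numeric(X %*% beta)))
  }

  fB <- droplevels(as.factor(fB))
  qB <- nlevels(fB)
  if (qB < 2L) stop("random terms need at least two levels")
  ZB <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(fB),
                             dims = c(n, qB))
  has_A <- !is.null(fA)
  if (has_A) {
    fA <- droplevels(as.factor(fA))
    qA <- nlevels(fA)
    if (qA < 2L) stop("random terms need at least two levels")
    ZA <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(fA),
                               dims = c(n, qA))
    W <- cbind(Matrix::Matrix(X, sparse = TRUE), ZA)
  } else {
    qA <- 0L
    W <- Matrix::Matrix(X, sparse = TRUE)
  }
  m <- p + qA
  WtW <- as.matrix(Matrix::crossprod(W))
  Wty <- as.numeric(Matrix::crossprod(W, y))
  WtZ <- Matrix::crossprod(W, ZB)                      # m x qB sparse
  ZtyB <- as.numeric(Matrix::crossprod(ZB, y))
  nB <- as.numeric(Matrix::colSums(ZB))
  yty <- sum(y^2)
  idxA <- if (has_A) p + seq_len(qA) else integer()

  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  s2e <- vy / 2
  s2B <- vy / 4
  s2A <- if (has_A) vy / 4 else NA_real_

  em_step <- function(s2A, s2B, s2e) {
    lamB <- s2e / s2B
    dB <- nB + lamB
    WtZd <- WtZ %*% Matrix::Diagonal(qB, 1 / dB)
    S <- WtW - as.matrix(WtZd %*% Matrix::t(WtZ))
    if (has_A) {
      lamA <- s2e / s2A
      S[idxA, idxA] <- S[idxA, idxA] + diag(lamA, qA)
    }
    rhs <- Wty - as.numeric(WtZd %*% ZtyB)
    ch <- chol(S)
    theta1 <- backsolve(ch, forwardsolve(t(ch), rhs))
    Sinv <- chol2inv(ch)
    uB <- (ZtyB - as.numeric(Matrix::crossprod(WtZ, theta1))) / dB
    # PEV traces from the inverse MME coefficient matrix (lambda form)
    M2 <- as.matrix(WtZd %*% Matrix::t(WtZd))
    trBB <- sum(1 / dB) + sum(Sinv * M2)
    ssq <- yty - sum(theta1 * Wty) - sum(uB * ZtyB)
    s2e_new <- max(ssq / (n - p), floor)
    s2B_new <- max((sum(uB^2) + s2e * trBB) / qB, floor)
    out <- list(s2A = s2A, s2B = s2B_new, s2e = s2e_new,
                theta1 = theta1, uB = uB, Sinv = Sinv, dB = dB, S = S)
    if (has_A) {
      trAA <- sum(diag(Sinv)[idxA])
      out$s2A <- max((sum(theta1[idxA]^2) + s2e * trAA) / qA, floor)
    }
    out
  }

  pack <- function(st) if (has_A) c(st$s2A, st$s2B, st$s2e) else c(st$s2B, st$s2e)
  step_at <- function(v) if (has_A) em_step(v[1], v[2], v[3]) else
    em_step(NA, v[1], v[2])

  # solution and REML log-likelihood at given components (MME determinant form)
  solve_at <- function(s2A, s2B, s2e) {
    st <- em_step(s2A, s2B, s2e)
    yPy <- (yty - sum(st$theta1 * Wty) - sum(st$uB * ZtyB)) / s2e
    logdetS <- 2 * sum(log(diag(chol(st$S))))
    m2l <- (n - p) * log(2 * pi) +
      (n - p - qA - qB) * log(s2e) +
      (if (has_A) qA * log(s2A) else 0) + qB * log(s2B) +
      sum(log(st$dB)) + logdetS + yPy
    st$loglik <- -0.5 * as.numeric(m2l)
    st
  }
  ll_at <- function(v) {
    out <- try(if (has_A) solve_at(v[1], v[2], v[3]) else
      solve_at(NA, v[1], v[2]), silent = TRUE)
    if (inherits(out, "try-error")) -Inf else out$loglik
  }

  # Aitken delta-squared extrapolation of the per-component EM trajectory:
  # EM converges linearly (and sublinearly toward a zero-variance boundary),
  # so jumping to the extrapolated fixed point cuts the iteration count and
  # leaves the final iterate far inside the stopping tolerance. A jump is
  # kept only when the restricted likelihood does not decrease, which makes
  # the scheme safe against noisy step ratios near the optimum.
  aitken_jump <- function(cur, h) {
    d1 <- h[2, ] - h[1, ]
    d2 <- h[3, ] - h[2, ]
    r <- d2 / d1
    ok <- is.finite(r) & r > 0 & r < 1 & abs(d1) > 1e-300
    if (!any(ok)) return(cur)
    ext <- cur
    ext[ok] <- h[3, ok] + d2[ok] * r[ok] / (1 - r[ok])
    ext[!is.finite(ext)] <- cur[!is.finite(ext)]
    ext <- pmax(ext, floor)
    if (all(ext == cur)) return(cur)
    if (ll_at(ext) >= ll_at(cur) - 1e-9) ext else cur
  }

  cur <- c(if (has_A) s2A else NULL, s2B, s2e)
  hist <- matrix(NA_real_, nrow = 3L, ncol = length(cur))
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    nxt <- pack(step_at(cur))
    # relative change, with components at the variance floor measured
    # against a small fraction of the total variance so floating-point
    # wiggle at the floor cannot mask convergence
    rel <- max(abs(nxt - cur) / pmax(abs(cur), 1e-6 * sum(cur), floor))
    hist <- rbind(hist[-1, , drop = FALSE], nxt)
    if (rel < tol) { cur <- nxt; converged <- TRUE; break }
    if (iter >= max_iter) { cur <- nxt; break }
    cur <- nxt
    if (accelerate && iter %% 4L == 0L && !anyNA(hist)) {
      cur <- aitken_jump(cur, hist)
      hist[] <- NA_real_
    }
  }

  # post-convergence polish: the EM stopping rule leaves an error of order
  # tol/(1 - rate); one extra extrapolated cycle pushes the components to
  # the fixed point well beyond the stopping tolerance
  if (converged) {
    h3 <- matrix(NA_real_, 3L, length(cur))
    for (j in 1:3) {
      cur <- pack(step_at(cur))
      h3[j, ] <- cur
    }
    cur <- aitken_jump(cur, h3)
  }

  if (has_A) { s2A <- cur[1]; s2B <- cur[2]; s2e <- cur[3] }
  else { s2B <- cur[1]; s2e <- cur[2] }
  st <- solve_at(s2A, s2B, s2e)
  # Boundary polish: near a zero variance the EM step size collapses below
  # the stopping tolerance while the component is still small-but-positive;
  # adopt the floor whenever the restricted likelihood is no worse there.
  total <- s2B + s2e + (if (has_A) s2A else 0)
  if (s2B > floor && s2B < 1e-3 * total) {
    st2 <- solve_at(s2A, floor, s2e)
    if (st2$loglik >= st$loglik - 1e-8) { s2B <- floor; st <- st2 }
  }
  if (has_A && s2A > floor && s2A < 1e-3 * total) {
    st2 <- solve_at(floor, s2B, s2e)
    if (st2$loglik >= st$loglik - 1e-8) { s2A <- floor; st <- st2 }
  }
  theta1 <- st$theta1
  beta <- theta1[seq_len(p)]
  uA <- if (has_A) theta1[idxA] else NULL
  uB <- st$uB
  m2l <- -2 * st$loglik

  varcomp <- c(if (has_A) stats::setNames(s2A, "A") else NULL,
               stats::setNames(s2B, "B"), resid = s2e)
  fitted_fixed <- as.numeric(X %*% beta)
  fit_A <- if (has_A) uA[as.integer(fA)] else NULL
  fit_B <- uB[as.integer(fB)]
  blup_A <- if (has_A) stats::setNames(uA, levels(fA)) else NULL
  blup_B <- stats::setNames(uB, levels(fB))

  list(beta = beta, beta_names = colnames(X),
       vcov_beta = st$Sinv[seq_len(p), seq_len(p), drop = FALSE] * s2e,
       varcomp = varcomp, blup_A = blup_A, blup_B = blup_B,
       fit_A = fit_A, fit_B = fit_B,
       loglik = -0.5 * as.numeric(m2l), n_iter = iter, converged = converged,
       n = n, rank = p, fitted_fixed = fitted_fixed)
}

#' Fit a linear mixed model by EM-REML
#'
#' Fits the model described by a [lmm_spec()] using restricted maximum
#' likelihood. Variance components are estimated by EM-REML iterations on
#' Henderson's mixed-model equations with the larger random factor absorbed;
#' fixed-effect solutions and BLUPs of the random terms are the MME solution
#' at the converged components. Components are floored at \code{floor};
#' convergence is declared when the largest relative change across
#' components falls below \code{tol}.
#'
#' @param spec A [lmm_spec()].
#' @param data A data frame holding all model terms; rows with missing
#'   values in any term are dropped.
#' @param tol Relative-change convergence tolerance (default 1e-8).
#' @param max_iter Maximum EM iterations (default 2000).
#' @param floor Lower bound for variance components (default 1e-10).
#' @return Object of class \code{methlmm}: fixed-effect estimates and
#'   standard errors, variance components (one per random term plus
#'   \code{resid}), per-level BLUPs, per-record fitted components, REML
#'   log-likelihood, iteration count and convergence flag.
#' @examples
#' d <- data.frame(y = c(10, 12, 11, 13, 20, 22),
#'                 animal = rep(c("a", "b", "c"), each = 2))
#' fit <- fit_lmm(lmm_spec("y", random = "animal"), d)
#' fit$varcomp
#' @export
fit_lmm <- function(spec, data, tol = 1e-8, max_iter = 2000L, floor = 1e-10) {
  stopifnot(inherits(spec, "lmm_spec"))
  des <- build_design(spec, data)
  rnd <- spec$random
  fac <- lapply(rnd, function(r) factor(des$mf[[r]]))
  names(fac) <- rnd
  # absorb the random factor with the most levels
  ord <- if (length(fac) == 2L) order(vapply(fac, nlevels, 1L)) else seq_along(fac)
  fA <- if (length(fac) == 2L) fac[[ord[1]]] else NULL
  fB <- if (length(fac) >= 1L) fac[[ord[length(ord)]]] else NULL
  res <- em_reml(des$y, des$X, fA = fA, fB = fB, tol = tol,
                 max_iter = max_iter, floor = floor)

  vc <- c(resid = unname(res$varcomp[["resid"]]))
  blups <- list()
  fitted_random <- list()
  if (length(fac) >= 1L) {
    nmB <- rnd[ord[length(ord)]]
    vc[nmB] <- unname(res$varcomp[["B"]])
    blups[[nmB]] <- res$blup_B
    fitted_random[[nmB]] <- res$fit_B
    if (length(fac) == 2L) {
      nmA <- rnd[ord[1]]
      vc[nmA] <- unname(res$varcomp[["A"]])
      blups[[nmA]] <- res$blup_A
      fitted_random[[nmA]] <- res$fit_A
    }
  }
  beta <- stats::setNames(res$beta, res$beta_names)
  vcov_beta <- as.matrix(res$vcov_beta)
  dimnames(vcov_beta) <- list(res$beta_names, res$beta_names)
  resid_cond <- des$y - res$fitted_fixed
  for (fr in fitted_random) resid_cond <- resid_cond - fr

  structure(list(
    spec = spec, beta = beta, se_beta = sqrt(pmax(diag(vcov_beta), 0)),
    vcov_beta = vcov_beta,
    varcomp = vc[c(setdiff(names(vc), "resid"), "resid")],
    blups = blups,
    y = des$y, fitted_fixed = res$fitted_fixed,
    fitted_random = fitted_random, residuals = resid_cond,
    reml_loglik = res$loglik, n_iterations = res$n_iter,
    converged = res$converged, n = res$n, rank = res$rank,
    xlevels = des$xlevels, covariate_means = des$covariate_means,
    factors = des$factors, covariates = des$covariates,
    formula = des$formula, dropped_terms = des$dropped,
    complete = des$complete
  ), class = "methlmm")
}

#' @export
print.methlmm <- function(x, ...) {
  cat("EM-REML linear mixed model:", x$spec$response, "\n")
  cat(sprintf("  n = %d records, rank(X) = %d, %d iterations, converged: %s\n",
              x$n, x$rank, x$n_iterations, x$converged))
  cat("  variance components:\n")
  for (nm in names(x$varcomp)) {
    cat(sprintf("    %-20s %.6g\n", nm, x$varcomp[[nm]]))
  }
  invisible(x)
}

stop_if_not_converged <- function(fit) {
  if (!isTRUE(fit$converged)) {
    stop("mixed model did not converge; refusing downstream use")
  }
  invisible(fit)
}
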