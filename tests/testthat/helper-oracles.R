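# Independent REML oracle: direct dense-V restricted log-likelihood and a
# brute-force maximiser, used to validate the EM-REML engine on small
# instances. Deliberately shares no code with the engine.

reml_loglik_direct <- function(y, X, groups, varcomp) {
  n <- length(y)
  V <- diag(varcomp[["resid"]], n)
  for (g in names(groups)) {
    Z <- outer(groups[[g]], unique(groups[[g]]), "==") * 1
    V <- V + varcomp[[g]] * tcrossprod(Z)
  }
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  -0.5 * as.numeric(
    (n - ncol(X)) * log(2 * pi) +
      determinant(V, logarithm = TRUE)$modulus +
      determinant(XtViX, logarithm = TRUE)$modulus +
      t(r) %*% Vi %*% r)
}

# brute force: multi-start Nelder-Mead on log-variances, then a grid refine
reml_brute <- function(y, X, groups) {
  nms <- c(names(groups), "resid")
  obj <- function(lp) {
    vc <- as.list(exp(lp))
    names(vc) <- nms
    -reml_loglik_direct(y, X, groups, vc)
  }
  vy <- stats::var(y)
  starts <- list(log(rep(vy / (length(nms)), length(nms))),
                 log(c(rep(vy / 50, length(groups)), vy)),
                 log(c(rep(vy, length(groups)), vy / 50)))
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 20000))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 20000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  vc <- exp(best$par)
  names(vc) <- nms
  # components driven to the boundary by the optimiser are reported as 0
  vc[vc < 1e-8] <- 0
  list(varcomp = vc, loglik = -best$value)
}

balanced_anova_components <- function(y, f) {
  k <- unique(table(f))
  stopifnot(length(k) == 1L)
  m <- tapply(y, f, mean)
  MSB <- k * stats::var(m)
  MSW <- sum((y - ave(y, f))^2) / (length(y) - length(m))
  c(animal = (MSB - MSW) / k, resid = MSW, MSB = MSB, MSW = MSW)
}

random_breed_vec <- function() {
  k <- sample(1:4, 1)
  b <- sample(MAIN_BREEDS, k)
  w <- rgamma(k, 1.5)
  breed_vector(stats::setNames(w / sum(w), b))
}
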