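test_that("degenerate variance layouts land on the right boundary", {
  # zero within-animal spread: residual variance collapses to the floor and
  # the animal variance absorbs the spread of the animal means
  d <- data.frame(y = rep(c(10, 12, 14, 16), each = 2),
                  animal = rep(letters[1:4], each = 2))
  f <- fit_lmm(lmm_spec("y", random = "animal"), d)
  expect_lt(f$varcomp[["resid"]], 1e-8)
  expect_equal(f$varcomp[["animal"]], var(c(10, 12, 14, 16)),
               tolerance = 1e-6)

  # identical within-animal patterns: no between-animal signal, the REML
  # optimum is the boundary sigma2_a = 0 with sigma2_e = RSS/(n-1) = 1.2
  # (value computed with the direct restricted-likelihood oracle)
  d2 <- data.frame(y = rep(c(10, 12), 3), animal = rep(letters[1:3], each = 2))
  f2 <- fit_lmm(lmm_spec("y", random = "animal"), d2)
  br <- reml_brute(d2$y, matrix(1, 6, 1), list(animal = d2$animal))
  expect_equal(unname(br$varcomp[["animal"]]), 0)
  expect_equal(unname(br$varcomp[["resid"]]), 1.2, tolerance = 1e-6)
  expect_lt(f2$varcomp[["animal"]], 1e-8)
  expect_equal(f2$varcomp[["resid"]], 1.2, tolerance = 1e-6)
})

test_that("balanced one-way REML equals the ANOVA closed form", {
  set.seed(17)
  for (rep in 1:6) {
    k <- sample(2:5, 1)
    a <- sample(5:12, 1)
    y <- rnorm(a * k, rep(rnorm(a, 0, 2), each = k), 1.5)
    d <- data.frame(y = y, animal = rep(seq_len(a), each = k))
    f <- fit_lmm(lmm_spec("y", random = "animal"), d)
    an <- balanced_anova_components(y, d$animal)
    if (an[["MSB"]] >= an[["MSW"]]) {
      expect_equal(f$varcomp[["animal"]], an[["animal"]], tolerance = 1e-8)
      expect_equal(f$varcomp[["resid"]], an[["resid"]], tolerance = 1e-8)
    } else {
      expect_lt(f$varcomp[["animal"]], 1e-8)
    }
  }
})

test_that("EM-REML matches brute-force restricted-likelihood maximisation on small instances", {
  set.seed(23)
  for (rep in 1:6) {
    n <- sample(12:30, 1)
    two_terms <- rep %% 2 == 0
    d <- data.frame(
      y = rnorm(n),
      animal = sample(letters[1:sample(3:6, 1)], n, replace = TRUE),
      cg = sample(LETTERS[1:3], n, replace = TRUE),
      x = rnorm(n))
    d$y <- d$y + 0.8 * d$x + rnorm(6, 0, 1.3)[as.integer(factor(d$animal))] +
      if (two_terms) rnorm(3, 0, 1)[as.integer(factor(d$cg))] else 0
    groups <- if (two_terms) list(cg = d$cg, animal = d$animal) else
      list(animal = d$animal)
    spec <- lmm_spec("y", covariates = "x",
                     random = if (two_terms) c("cg", "animal") else "animal")
    f <- fit_lmm(spec, d)
    X <- cbind(1, d$x)
    br <- reml_brute(d$y, X, groups)
    for (nm in names(groups)) {
      expect_lt(abs(f$varcomp[[nm]] - max(unname(br$varcomp[[nm]]), 1e-10)),
                1e-6)
    }
    expect_lt(abs(f$varcomp[["resid"]] - unname(br$varcomp[["resid"]])),
              1e-6)
    # returned components attain the restricted likelihood the oracle found
    vc <- as.list(f$varcomp)
    ll <- reml_loglik_direct(d$y, X, groups, vc)
    expect_gte(ll, br$loglik - 1e-6)
    expect_equal(f$reml_loglik, ll, tolerance = 1e-6)
  }
})

test_that("estimates are invariant to record order and equivariant to shifts", {
  set.seed(31)
  n <- 120
  d <- data.frame(y = rnorm(n), animal = sample(letters[1:30], n, TRUE),
                  cg = sample(LETTERS[1:8], n, TRUE), x = rnorm(n))
  d$y <- d$y + 0.5 * d$x + rnorm(30, 0, 1)[as.integer(factor(d$animal))] +
    rnorm(8, 0, 0.6)[as.integer(factor(d$cg))]
  spec <- lmm_spec("y", covariates = "x", random = c("cg", "animal"))
  f1 <- fit_lmm(spec, d)
  f2 <- fit_lmm(spec, d[sample(n), ])
  expect_equal(f1$varcomp, f2$varcomp, tolerance = 1e-10)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)

  d3 <- d
  d3$y <- d$y + 7
  f3 <- fit_lmm(spec, d3)
  expect_equal(f3$beta[["(Intercept)"]] - f1$beta[["(Intercept)"]], 7,
               tolerance = 1e-8)
  expect_equal(f3$beta[["x"]], f1$beta[["x"]], tolerance = 1e-8)
  expect_equal(f3$varcomp, f1$varcomp, tolerance = 1e-8)
})

test_that("variance components agree with an independent REML implementation", {
  skip_if_not_installed("lme4")
  set.seed(41)
  n_a <- 80; k <- 3
  d <- data.frame(animal = rep(sprintf("a%02d", 1:n_a), each = k),
                  cg = sample(sprintf("g%02d", 1:15), n_a * k, TRUE),
                  x = rnorm(n_a * k),
                  sex = sample(c("female", "male"), n_a * k, TRUE))
  d$y <- 2 + 0.5 * d$x + 0.8 * (d$sex == "male") +
    rnorm(n_a, 0, 1.1)[as.integer(factor(d$animal))] +
    rnorm(15, 0, 0.7)[as.integer(factor(d$cg))] + rnorm(n_a * k)
  f <- fit_lmm(lmm_spec("y", factors = "sex", covariates = "x",
                        random = c("cg", "animal"),
                        ref_levels = list(sex = "female")), d)
  lf <- lme4::lmer(y ~ sex + x + (1 | cg) + (1 | animal), d, REML = TRUE)
  v <- as.data.frame(lme4::VarCorr(lf))
  vl <- stats::setNames(v$vcov, v$grp)
  # lme4's optimiser stops well short of the EM tolerance; 1e-4 relative
  expect_equal(f$varcomp[["animal"]], vl[["animal"]], tolerance = 1e-4)
  expect_equal(f$varcomp[["cg"]], vl[["cg"]], tolerance = 1e-4)
  expect_equal(f$varcomp[["resid"]], vl[["Residual"]], tolerance = 1e-4)
  expect_equal(unname(f$beta), unname(lme4::fixef(lf)), tolerance = 1e-5)
  expect_equal(f$reml_loglik, -0.5 * lme4::REMLcrit(lf), tolerance = 1e-5)
  # BLUPs too
  re <- lme4::ranef(lf)$animal
  expect_equal(unname(f$blups$animal[rownames(re)]), re[["(Intercept)"]],
               tolerance = 1e-4)
})

test_that("rank-deficient fixed designs fail loudly naming the aliased columns", {
  set.seed(51)
  d <- data.frame(y = rnorm(20), x1 = rnorm(20),
                  animal = rep(letters[1:5], 4))
  d$x2 <- 2 * d$x1
  expect_error(fit_lmm(lmm_spec("y", covariates = c("x1", "x2"),
                                random = "animal"), d),
               "rank-deficient.*x2")
})

test_that("repeatability follows its defining ratio and recovers simulated fractions", {
  # formula cases through the engine: boundary and balanced layouts
  set.seed(61)
  d <- data.frame(y = rnorm(40), animal_id = rep(1:20, each = 2))
  r0 <- estimate_repeatability(d, "y", nboot = 0)
  expect_equal(r0$R,
               r0$varcomp[["animal_id"]] /
                 (r0$varcomp[["animal_id"]] + r0$varcomp[["resid"]]))
  expect_error(
    estimate_repeatability(data.frame(y = rnorm(5), animal_id = 1:5), "y"),
    "unidentifiable")

  # sigma_a = 0 data: R at the floor
  d0 <- data.frame(y = rnorm(200), animal_id = rep(1:100, each = 2))
  expect_lt(estimate_repeatability(d0, "y", nboot = 0)$R, 0.05)

  # pure animal signal: R near 1
  d1 <- data.frame(y = rep(rnorm(60), each = 2) + rnorm(120, 0, 1e-4),
                   animal_id = rep(1:60, each = 2))
  expect_gt(estimate_repeatability(d1, "y", nboot = 0)$R, 0.999)

  # parameter recovery at the spec'd scale: fraction 0.3, 1,000 x 2
  cfg <- repeatability_study_config("growing", 0.3, seed = 77)
  b <- simulate_flocks(cfg)
  md <- prepare_model_data(assign_contemporary_groups(b$emissions)$records,
                           b$animals)
  sp <- residual_trait_spec("RMT_BW", "growing")
  est <- estimate_repeatability(md, "ch4", factors = sp$factors,
                                covariates = setdiff(sp$covariates,
                                                     "body_weight"),
                                ref_levels = sp$ref_levels, nboot = 20,
                                seed = 7)
  expect_lt(abs(est$R - 0.3), 0.05)
  expect_gt(est$SE, 0)
  expect_lt(est$SE, 0.1)
})
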