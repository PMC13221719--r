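test_that("correlation cells match their closed forms", {
  x <- 1:10
  cc <- correlate(x, 2 * x)
  expect_equal(cc$r, 1)
  expect_equal(cc$se, 0)
  expect_equal(cc$n, 10L)

  # orthogonal mean-zero pair built by construction: r = 0, se = 1/sqrt(n-2)
  x0 <- c(1, 1, 1, 1, -1, -1, -1, -1, 0, 0)
  y <- c(1, -1, 1, -1, 1, -1, 1, -1, 0, 0)
  stopifnot(sum(x0 * y) == 0, sum(x0) == 0, sum(y) == 0)
  cc0 <- correlate(x0, y)
  expect_equal(cc0$r, 0)
  expect_equal(cc0$se, 1 / sqrt(8))

  set.seed(99)
  z1 <- rnorm(10000)
  z2 <- 0.5 * z1 + sqrt(1 - 0.25) * rnorm(10000)
  expect_lt(abs(correlate(z1, z2)$r - 0.5), 0.03)

  expect_true(is.na(correlate(rep(1, 5), rnorm(5))$r))
  cm <- correlation_matrix(data.frame(a = x, b = 2 * x, c = rnorm(10)))
  expect_equal(nrow(cm), 3L)
  expect_equal(cm$r[cm$trait_a == "a" & cm$trait_b == "b"], 1)
})

mk_metric_values <- function(vals, metrics = "m1") {
  n <- length(vals)
  d <- data.frame(record_id = sprintf("r%02d", seq_len(n)),
                  animal_id = sprintf("a%02d", seq_len(n)),
                  stringsAsFactors = FALSE)
  for (mcol in metrics) d[[mcol]] <- vals
  d
}

test_that("top-quartile selection counts, ties and degenerate agreement", {
  d <- mk_metric_values(c(5, 3, 8, 1, 9, 7, 2, 6))
  rr <- rank_top_quartile(d, "m1")
  expect_equal(rr$n_selected, 2L)       # round(0.25 * 8)
  expect_setequal(rr$selected$animal_id, c("a04", "a07"))

  # identical metric vectors select identical sets
  d2 <- mk_metric_values(c(5, 3, 8, 1, 9, 7, 2, 6), c("m1", "m2"))
  rr2 <- rank_top_quartile(d2, c("m1", "m2"))
  expect_equal(rr2$selected$animal_id[rr2$selected$metric == "m1"],
               rr2$selected$animal_id[rr2$selected$metric == "m2"])

  # a tie across the quartile boundary resolves by ascending animal id
  d3 <- mk_metric_values(c(1, 2, 2, 2, 5, 6, 7, 8))
  rr3 <- rank_top_quartile(d3, "m1")
  expect_equal(sort(rr3$selected$animal_id), c("a01", "a02"))

  expect_error(rank_top_quartile(mk_metric_values(1:7), "m1"), "at least 8")
})

test_that("selection is invariant under monotone transforms and each animal uses its best record", {
  set.seed(7)
  n_animal <- 24
  d <- data.frame(record_id = sprintf("r%03d", 1:(2 * n_animal)),
                  animal_id = rep(sprintf("a%02d", 1:n_animal), each = 2),
                  m1 = rexp(2 * n_animal) + 1, stringsAsFactors = FALSE)
  rr <- rank_top_quartile(d, "m1")
  d2 <- d
  d2$m1 <- log(d$m1)                     # strictly increasing transform
  rr2 <- rank_top_quartile(d2, "m1")
  expect_setequal(rr$selected$animal_id, rr2$selected$animal_id)
  expect_setequal(rr$selected$record_id, rr2$selected$record_id)

  # the selected animals' per-animal minima are below everyone else's
  mins <- tapply(d$m1, d$animal_id, min)
  sel <- rr$selected$animal_id
  expect_lte(max(mins[sel]), min(mins[setdiff(names(mins), sel)]))
})

test_that("intake-driven methane yield selects higher-intake animals than absolute methane", {
  set.seed(8)
  n <- 240
  dmi <- exp(rnorm(n, log(1.6), 0.35))
  bw <- rnorm(n, 48, 8)
  ch4 <- 8 + 1.2 * dmi + 0.05 * bw + rnorm(n, 0, 2.2)
  ch4 <- pmax(ch4, 4)
  d <- data.frame(record_id = sprintf("r%03d", 1:n),
                  animal_id = sprintf("a%03d", 1:n),
                  ch4 = ch4, mi_mbw = ch4 / bw^0.75, my = ch4 / dmi,
                  stringsAsFactors = FALSE)
  gt <- data.frame(record_id = d$record_id, dmi = dmi, ch4 = ch4,
                   body_weight = bw, stringsAsFactors = FALSE)
  rr <- rank_top_quartile(d, c("ch4", "mi_mbw", "my"), group_traits = gt)
  gm <- rr$group_means
  dmi_means <- gm$mean[gm$trait == "dmi"]
  names(dmi_means) <- gm$metric[gm$trait == "dmi"]
  expect_gt(dmi_means[["my"]], dmi_means[["ch4"]])
  expect_gt(dmi_means[["my"]], dmi_means[["mi_mbw"]])
  # Welch/Holm annotation separates the intake means at these effect sizes
  pw <- rr$pairwise
  expect_lt(pw$p_holm[pw$trait == "dmi" & pw$metric_a == "ch4" &
                        pw$metric_b == "my"], 0.05)
})
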