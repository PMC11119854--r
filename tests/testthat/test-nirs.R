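test_that("fractional oxygen extraction is the normalised arterio-regional gap", {
  expect_equal(foe_from_nirs(0.96, 0.48), 0.5)
  expect_equal(foe_from_nirs(1.0, 0.45), 0.55)
  expect_equal(foe_from_nirs(0.8, 0.8), 0)
  expect_equal(foe_from_gases(0.95, 0.70), 0.25 / 0.95)
  expect_equal(foe_from_gases(0.6, 0.6), 0)
  expect_error(foe_from_nirs(0, 0.5))
  # complementarity: FOE + r/s = 1
  s <- runif(50, 0.5, 1); r <- runif(50, 0, 1)
  expect_equal(foe_from_nirs(s, r) + r / s, rep(1, 50))
})

test_that("NIRS- and gas-derived extraction share slopes under a constant offset", {
  # regional venous saturation differs from the NIRS reading by a constant
  sao2 <- c(0.99, 0.97, 0.93, 0.86)
  svo2 <- c(0.70, 0.65, 0.58, 0.50)
  rso2 <- svo2 + 0.05
  fio2 <- c(0.5, 0.4, 0.3, 0.21)
  s_nirs <- fit_linear_trend(fio2, foe_from_nirs(sao2, rso2) * sao2)
  s_gas <- fit_linear_trend(fio2, foe_from_gases(sao2, svo2) * sao2)
  expect_equal(s_nirs$slope, s_gas$slope, tolerance = 1e-12)
})

test_that("delta_from_baseline computes per-animal relative changes", {
  d <- data.frame(
    animal_id = rep(c("a", "b"), each = 3),
    period = rep(c("baseline", "fio2_30", "fio2_21"), 2),
    value = c(50.4, 46.3, 41.2, 54.6, 38.4, 27.9)
  )
  out <- delta_from_baseline(d)
  expect_equal(out$delta_rel[out$animal_id == "a" & out$period == "fio2_21"],
               (41.2 - 50.4) / 50.4)
  expect_equal(out$delta_rel[out$animal_id == "b" & out$period == "fio2_21"],
               (27.9 - 54.6) / 54.6, tolerance = 1e-12)
  expect_equal(out$delta_rel[out$period == "baseline"], c(0, 0))
  expect_error(delta_from_baseline(d[d$period != "baseline", ]), "baseline")
})

test_that("relative deltas are scale-free and shift as forced by translation", {
  d <- data.frame(animal_id = "a",
                  period = c("baseline", "post1h", "fio2_40"),
                  value = c(50, 45, 40))
  rel0 <- delta_from_baseline(d)$delta_rel
  d_scaled <- d; d_scaled$value <- d$value * 3.7
  expect_equal(delta_from_baseline(d_scaled)$delta_rel, rel0)
  d_shift <- d; d_shift$value <- d$value + 10
  expect_equal(delta_from_baseline(d_shift)$delta_rel,
               (d$value - 50) / (50 + 10))
})

test_that("risk flags use strict thresholds at 45% and a 20% drop", {
  f <- flag_risk(c(44.9, 45.0, 39, 50), c(50, 45, 50, 50))
  expect_equal(f$below_45, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(f$drop_gt20, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(f$relative_drop[3], 0.22)
  # exact 20% drop is not flagged
  expect_false(flag_risk(40, 50)$drop_gt20)
})

test_that("saturation binning partitions observations into the four printed ranges", {
  obs <- data.frame(
    sao2 = c(100, 97.5, 95, 94.9, 90, 89.9, 85, 84.9, 60),
    rcso2 = 40, group = "oa", baseline = 55
  )
  out <- bin_by_sao2(obs)
  oa <- out[out$group == "oa", ]
  expect_equal(sum(oa$n), nrow(obs))
  expect_equal(oa$n[oa$sao2_range == "95-100"], 3) # 100, 97.5, and boundary 95
  expect_equal(oa$n[oa$sao2_range == "90-95"], 2)
  expect_equal(oa$n[oa$sao2_range == "85-90"], 2)
  expect_equal(oa$n[oa$sao2_range == "<85"], 2)
})

test_that("bin summaries report flagged counts and rounded percentages", {
  set.seed(11)
  obs <- data.frame(
    sao2 = c(rep(97, 11), rep(82, 9)),
    rcso2 = c(rep(40, 7), rep(50, 4), rep(30, 8), rep(50, 1)),
    group = "oa",
    baseline = 54.6
  )
  out <- bin_by_sao2(obs)
  top <- out[out$group == "oa" & out$sao2_range == "95-100", ]
  low <- out[out$group == "oa" & out$sao2_range == "<85", ]
  expect_equal(top$n, 11)
  expect_equal(top$n_flagged, 7)
  expect_equal(top$pct_flagged, 64) # 7/11 -> 63.6 -> 64
  expect_equal(low$n_flagged, 8)
  expect_equal(low$pct_flagged, 89) # 8/9 -> 88.9 -> 89
  empty <- out[out$sao2_range == "90-95", ]
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$mean_rcso2))
})

test_that("linear trend matches the closed-form normal equations", {
  x <- 1:5
  expect_equal(fit_linear_trend(x, 2 * x + 1),
               tibble::tibble(slope = 2, intercept = 1, r_squared = 1, n = 5L))
  set.seed(3)
  y <- 3.2 * x - 4 + rnorm(5)
  fit <- fit_linear_trend(x, y)
  hand <- oracle_ols(x, y)
  expect_equal(fit$slope, unname(hand["slope"]))
  expect_equal(fit$intercept, unname(hand["intercept"]))
  expect_error(fit_linear_trend(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(fit_linear_trend(1:2, 1:2), "3 points")
})
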