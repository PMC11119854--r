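test_that("alveolar gas equation reproduces hand-computed tensions", {
  expect_equal(alveolar_po2(1, 0), 713)
  expect_equal(alveolar_po2(0.21, 40), 0.21 * 713 - 50)
  expect_equal(alveolar_po2(0.5, 40), 306.5)
  expect_error(alveolar_po2(0, 40), "fio2")
  expect_error(alveolar_po2(1.2, 40), "fio2")
  expect_warning(out <- alveolar_po2(0.05, 80), "clamped")
  expect_equal(out, 0)
})

test_that("A-a difference and P/F ratio are the stated arithmetic", {
  expect_equal(aa_difference(100, 100), 0)
  expect_equal(aa_difference(99.73, 60), 39.73)
  expect_equal(aa_difference(306.5, 80), 226.5)
  expect_warning(aa_difference(50, 60), "inconsistency")
  expect_equal(pf_ratio(100, 0.5), 200)
  expect_equal(pf_ratio(100, 1), 100)
  expect_equal(pf_ratio(63, 0.21), 300)
  expect_error(pf_ratio(100, 0), "fio2")
})

test_that("dissociation curve matches its closed form and round-trips", {
  expect_equal(hb_saturation(0), 0)
  expect_equal(hb_saturation(26.9), 1 / (1 + 23400 / (26.9^3 + 150 * 26.9)))
  expect_equal(hb_saturation(26.9), 0.5, tolerance = 0.01)
  expect_gte(hb_saturation(150), 0.98)
  p <- exp(seq(log(1), log(600), length.out = 200))
  expect_equal(hb_po2(hb_saturation(p)), p, tolerance = 1e-6)
  s <- seq(0.01, 0.999, length.out = 100)
  expect_equal(hb_saturation(hb_po2(s)), s, tolerance = 1e-6)
  expect_true(all(diff(hb_saturation(seq(0, 500, by = 0.5))) > 0))
  expect_error(hb_po2(0), "strictly inside")
  expect_error(hb_po2(1), "strictly inside")
})

test_that("oxygen content is the capacity-bound plus dissolved term and linear in Hb", {
  expect_equal(o2_content(0, 0, 0), 0)
  expect_equal(o2_content(12, 1, 100), 1.34 * 12 + 0.3)
  expect_equal(o2_content(10, 0.5, 40), 6.7 + 0.12)
  hbs <- c(5, 10, 15)
  expect_equal(o2_content(2 * hbs, 0.7, 60) - o2_content(0, 0.7, 60),
               2 * (o2_content(hbs, 0.7, 60) - o2_content(0, 0.7, 60)))
})

test_that("Berggren shunt equation handles limits and is scale-invariant", {
  expect_equal(shunt_equation(20, 20, 15), 0)
  expect_equal(shunt_equation(20, 15, 15), 1)
  expect_equal(shunt_equation(20, 18, 15), 0.4)
  expect_error(shunt_equation(15, 14, 15), "exceed")
  # invariance under common rescaling of all three contents
  expect_equal(shunt_equation(2 * 20, 2 * 18, 2 * 15), shunt_equation(20, 18, 15))
  expect_warning(q <- shunt_equation(20, 21, 15), "clamped")
  expect_equal(q, 0)
})

test_that("predict_sao2 agrees with the closed-form content-balance oracle", {
  for (fio2 in c(0.21, 0.3, 0.5)) {
    for (q in c(0, 0.15, 0.3, 0.45, 0.6)) {
      for (v in c(0, 25, 60, 120, 200)) {
        expect_equal(predict_sao2(fio2, q, v, 40),
                     oracle_sao2(fio2, q, v, 40), tolerance = 1e-8)
      }
    }
  }
})

test_that("predict_sao2 reduces to the bare dissociation curve with no defect", {
  for (fio2 in c(0.21, 0.4, 1)) {
    expect_equal(predict_sao2(fio2, 0, 0, 40),
                 hb_saturation(alveolar_po2(fio2, 40)), tolerance = 1e-9)
  }
})

test_that("predict_sao2 is monotone in FiO2, shunt and V:Q displacement", {
  fio2s <- seq(0.21, 1, length.out = 9)
  qs <- seq(0, 0.6, length.out = 7)
  vs <- seq(0, 150, length.out = 6)
  for (q in qs) {
    s <- predict_sao2(fio2s, q, 30, 45)
    expect_true(all(diff(s) >= -1e-12))
  }
  for (f in c(0.21, 0.5)) {
    s <- predict_sao2(f, qs, 30, 45)
    expect_true(all(diff(s) <= 1e-12))
    s <- predict_sao2(f, 0.3, vs, 45)
    expect_true(all(diff(s) <= 1e-12))
  }
  expect_lt(predict_sao2(0.21, 0.4, 30, 45), predict_sao2(0.21, 0.2, 30, 45))
})

test_that("fit_shunt_vq inverts the forward model exactly on noiseless steps", {
  fio2 <- c(0.5, 0.4, 0.3, 0.21)
  for (q in c(0.1, 0.2, 0.4)) {
    for (v in c(0, 20, 60)) {
      steps <- data.frame(fio2 = fio2, paco2 = 40,
                          sao2 = predict_sao2(fio2, q, v, 40))
      fit <- fit_shunt_vq(steps)
      expect_lte(abs(fit$qs_qt - q), 0.01)
      expect_lte(abs(fit$vq_shift - v), 2)
      expect_true(fit$converged)
      expect_gte(fit$n_points, 2)
    }
  }
})

test_that("fit_shunt_vq flags the unidentifiable healthy-lung limit", {
  steps <- data.frame(fio2 = c(0.5, 0.4, 0.3, 0.21), paco2 = 40, sao2 = 1)
  expect_warning(fit <- fit_shunt_vq(steps), "unidentifiable")
  expect_equal(fit$qs_qt, 0)
  expect_error(fit_shunt_vq(data.frame(fio2 = 0.5, sao2 = 0.9, paco2 = 40)),
               "2 distinct")
})

test_that("fit_shunt_vq accepts percent-scale saturations", {
  fio2 <- c(0.5, 0.4, 0.3, 0.21)
  sa <- predict_sao2(fio2, 0.25, 10, 40)
  f1 <- fit_shunt_vq(data.frame(fio2 = fio2, paco2 = 40, sao2 = sa))
  f2 <- fit_shunt_vq(data.frame(fio2 = fio2, paco2 = 40, sao2 = 100 * sa))
  expect_equal(f1$qs_qt, f2$qs_qt)
  expect_equal(f1$vq_shift, f2$vq_shift)
})

test_that("shunt_fit tidy and glance expose the estimates", {
  fio2 <- c(0.5, 0.4, 0.3, 0.21)
  fit <- fit_shunt_vq(data.frame(fio2 = fio2, paco2 = 40,
                                 sao2 = predict_sao2(fio2, 0.2, 20, 40)))
  td <- generics::tidy(fit)
  expect_equal(td$term, c("qs_qt", "vq_shift"))
  gl <- generics::glance(fit)
  expect_named(gl, c("qs_qt", "vq_shift", "rss", "n_points", "converged"))
})
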