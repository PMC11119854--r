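test_that("a noiseless control series passes the forward model through exactly", {
  cfg <- animal_config("control", seed = 1,
                       noise = list(sao2 = 0, rso2 = 0, paw = 0))
  a <- generate_animal(cfg, waveforms = FALSE)
  expect_equal(a$data$period, names(step_periods()))
  expect_equal(a$data$fio2, unname(step_periods()))
  for (i in seq_len(5)) {
    expect_equal(a$data$sao2[i],
                 predict_sao2(a$data$fio2[i], cfg$qs_qt[[i]], cfg$vq_shift[[i]],
                              cfg$paco2[[i]]))
  }
  expect_equal(a$data$nirs_brain[1], cfg$baseline_rcso2)
})

test_that("generation is deterministic under a fixed seed", {
  c1 <- generate_cohort(2, 2, master_seed = 99, waveforms = TRUE)
  c2 <- generate_cohort(2, 2, master_seed = 99, waveforms = TRUE)
  expect_identical(c1$data, c2$data)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$waveforms, c2$waveforms)
  c3 <- generate_cohort(2, 2, master_seed = 100, waveforms = FALSE)
  expect_false(identical(c1$data$sao2, c3$data$sao2))
})

test_that("cohort dimensions and group structure match the requested design", {
  coh <- generate_cohort(6, 7, master_seed = 42, waveforms = FALSE)
  expect_equal(nrow(coh$data), 65)
  expect_equal(length(unique(coh$data$animal_id)), 13)
  tab <- table(unique(coh$data[c("animal_id", "group")])$group)
  expect_equal(unname(tab[["control"]]), 6)
  expect_equal(unname(tab[["oa"]]), 7)
  # injury manifests as lower cerebral saturation at room air
  m <- tapply(coh$data$nirs_brain[coh$data$period == "fio2_21"],
              coh$data$group[coh$data$period == "fio2_21"], mean)
  expect_lt(m[["oa"]], m[["control"]])
})

test_that("oa configs must worsen shunt and compliance after injury", {
  expect_error(
    animal_config("oa", qs_qt = 0.05, seed = 1),
    "increased shunt"
  )
  expect_error(
    animal_config("oa", C = 2, seed = 1),
    "decreased compliance"
  )
})

test_that("shunt fits recover the generating shunt fraction from noisy steps", {
  cfg_fun <- function(animal_id, seed) {
    animal_config("oa", animal_id, seed = seed,
                  qs_qt = c(baseline = 0.05, post1h = 0.3, fio2_40 = 0.3,
                            fio2_30 = 0.3, fio2_21 = 0.3),
                  vq_shift = c(baseline = 5, post1h = 20, fio2_40 = 20,
                               fio2_30 = 20, fio2_21 = 20))
  }
  coh <- generate_cohort(1, 8, master_seed = 7, oa_config = cfg_fun,
                         waveforms = FALSE)
  oa <- coh$data[coh$data$group == "oa" & coh$data$period != "baseline", ]
  err <- vapply(split(oa, oa$animal_id), function(d) {
    fit_shunt_vq(d[c("fio2", "sao2", "paco2")])$qs_qt - 0.3
  }, numeric(1))
  expect_lt(abs(mean(err)), 0.05)
})

test_that("mechanics fits recover the generating parameters from noisy waveforms", {
  coh <- generate_cohort(2, 2, master_seed = 11, waveforms = TRUE)
  for (id in names(coh$waveforms)) {
    truth <- coh$truth[coh$truth$animal_id == id, ]
    for (per in names(coh$waveforms[[id]])) {
      fit <- fit_single_compartment(coh$waveforms[[id]][[per]])
      tc <- truth$C[truth$period == per]
      expect_lt(abs(fit$C - tc) / tc, 0.05)
    }
  }
})

test_that("injected impairment causes are recovered by the classifier", {
  # one cause at a time: pure hypotension, pure hypoxemia, pure hypercapnia
  mk <- function(kind) {
    function(animal_id, seed) {
      base <- list(animal_id = animal_id, seed = seed, group = "oa")
      args <- switch(kind,
        bp = list(mbp = c(baseline = 80, post1h = 28, fio2_40 = 28,
                          fio2_30 = 28, fio2_21 = 28),
                  paco2 = 40,
                  rcso2_deficit = c(baseline = 0, post1h = 0.35, fio2_40 = 0.35,
                                    fio2_30 = 0.35, fio2_21 = 0.35)),
        o2 = list(mbp = 70,
                  paco2 = 40,
                  qs_qt = c(baseline = 0.05, post1h = 0.45, fio2_40 = 0.45,
                            fio2_30 = 0.5, fio2_21 = 0.5),
                  vq_shift = c(baseline = 5, post1h = 40, fio2_40 = 40,
                               fio2_30 = 40, fio2_21 = 40),
                  rcso2_deficit = c(baseline = 0, post1h = 0, fio2_40 = 0,
                                    fio2_30 = 0.35, fio2_21 = 0.35)),
        co2 = list(mbp = 70,
                   paco2 = c(baseline = 40, post1h = 60, fio2_40 = 60,
                             fio2_30 = 60, fio2_21 = 60),
                   rcso2_deficit = c(baseline = 0, post1h = 0.35, fio2_40 = 0.35,
                                     fio2_30 = 0.35, fio2_21 = 0.35))
      )
      do.call(animal_config, c(base, args))
    }
  }
  for (kind in c("bp", "o2", "co2")) {
    coh <- generate_cohort(1, 6, master_seed = 20 + match(kind, c("bp", "o2", "co2")),
                           oa_config = mk(kind), waveforms = FALSE)
    base <- coh$data[coh$data$period == "baseline",
                     c("animal_id", "nirs_brain", "mbp")]
    names(base) <- c("animal_id", "baseline_rcso2", "baseline_mbp")
    obs <- merge(coh$data[coh$data$period != "baseline", ], base, by = "animal_id")
    obs$rcso2 <- obs$nirs_brain
    cls <- suppressWarnings(classify_autoreg(obs))
    truth <- coh$truth[coh$truth$period != "baseline", ]
    key <- paste(cls$animal_id, cls$period)
    tkey <- paste(truth$animal_id, truth$period)
    injected <- truth$impair_cause[match(key, tkey)]
    sel <- injected == kind & cls$group == "oa"
    agree <- mean(as.character(cls$autoreg[sel]) == paste0("impaired_", kind))
    expect_gte(agree, 0.9)
  }
})
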