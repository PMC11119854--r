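#' Measurement periods of the FiO2 step-down protocol
#'
#' Five periods: baseline and 1 h post injury/sham at FiO2 50%, then
#' step-down to 40, 30 and 21% inspired oxygen.
#'
#' @return Named numeric vector of FiO2 fractions, names are period labels.
#' @examples
#' step_periods()
#' @export
step_periods <- function() {
  c(baseline = 0.5, post1h = 0.5, fio2_40 = 0.4, fio2_30 = 0.3, fio2_21 = 0.21)
}

per_period <- function(x, default) {
  pers <- names(step_periods())
  if (is.null(x)) x <- default
  if (length(x) == 1L) x <- rep(x, 5)
  if (is.null(names(x))) names(x) <- pers
  stopifnot(setequal(names(x), pers))
  x[pers]
}

#' Configuration of one simulated animal
#'
#' Declares the physiological ground truth from which [generate_animal()]
#' produces observable data: per-period shunt fraction and V:Q displacement
#' (drives arterial gases through the shunt forward model), respiratory
#' mechanics, blood pressure and PaCO2, regional baseline saturations, and a
#' per-period cerebral "autoregulation deficit" — the fractional shortfall of
#' measured rcSO2 below the nomogram-expected value (a deficit beyond the
#' nomogram's cut makes the observation truly impaired).
#'
#' Defaults emulate the study design: controls keep a small constant shunt
#' and stable mechanics with a modest cerebral decline at room air; oleic-acid
#' (`"oa"`) animals gain shunt, lose compliance, gain resistance, run mildly
#' hypercapnic and mildly hypotensive after injury, and carry cerebral
#' deficits that grow as FiO2 falls.
#'
#' @param group `"control"` or `"oa"`.
#' @param animal_id Identifier; defaults are assigned by [generate_cohort()].
#' @param weight Body weight, kg.
#' @param qs_qt,vq_shift Per-period shunt fraction and V:Q displacement
#'   (length 1 or named length 5).
#' @param C,R,P0 Per-period respiratory mechanics (mL/cmH2O, cmH2O.s/L,
#'   cmH2O).
#' @param mbp,paco2 Per-period mean arterial pressure (mmHg) and PaCO2 (mmHg).
#' @param baseline_rcso2,baseline_rgso2,baseline_rrso2 Regional baseline
#'   saturations, percent.
#' @param rcso2_deficit Per-period fractional cerebral deficit in [0, 1).
#' @param regional_deficit Per-period fractional decline applied to the gut
#'   and kidney beds.
#' @param hr Per-period heart rate, bpm.
#' @param noise Named list of Gaussian noise SDs: `sao2` (fraction), `rso2`
#'   (percent points), `paw` (cmH2O).
#' @param seed Integer seed for this animal's noise draws.
#' @param nomogram The [autoreg_nomogram()] used as cerebral forward model.
#' @param constants A [physio_constants()] object.
#' @return An object of class `animal_config`.
#' @examples
#' animal_config("oa", seed = 1)
#' @export
animal_config <- function(group = c("control", "oa"),
                          animal_id = "a1",
                          weight = 2.1,
                          qs_qt = NULL, vq_shift = NULL,
                          C = NULL, R = NULL, P0 = 6,
                          mbp = NULL, paco2 = NULL,
                          baseline_rcso2 = NULL,
                          baseline_rgso2 = NULL,
                          baseline_rrso2 = NULL,
                          rcso2_deficit = NULL,
                          regional_deficit = NULL,
                          hr = NULL,
                          noise = list(sao2 = 0.01, rso2 = 2, paw = 0.2),
                          seed = 1L,
                          nomogram = autoreg_nomogram(),
                          constants = physio_constants()) {
  group <- match.arg(group)
  ctrl <- group == "control"
  cfg <- list(
    group = group, animal_id = animal_id, weight = weight,
    qs_qt = per_period(qs_qt, if (ctrl) 0.05 else
      c(baseline = 0.05, post1h = 0.30, fio2_40 = 0.30, fio2_30 = 0.32, fio2_21 = 0.35)),
    vq_shift = per_period(vq_shift, if (ctrl) 5 else
      c(baseline = 5, post1h = 25, fio2_40 = 25, fio2_30 = 25, fio2_21 = 25)),
    C = per_period(C, if (ctrl) 2.0 else
      c(baseline = 2.2, post1h = 1.2, fio2_40 = 1.2, fio2_30 = 1.1, fio2_21 = 1.1)),
    R = per_period(R, if (ctrl) 50 else
      c(baseline = 50, post1h = 80, fio2_40 = 80, fio2_30 = 85, fio2_21 = 85)),
    P0 = per_period(P0, 6),
    mbp = per_period(mbp, if (ctrl)
      c(baseline = 84, post1h = 82, fio2_40 = 79, fio2_30 = 75, fio2_21 = 74) else
      c(baseline = 77, post1h = 71, fio2_40 = 68, fio2_30 = 72, fio2_21 = 70)),
    paco2 = per_period(paco2, if (ctrl) 41 else 45),
    baseline_rcso2 = baseline_rcso2 %||% (if (ctrl) 50.4 else 54.6),
    baseline_rgso2 = baseline_rgso2 %||% (if (ctrl) 66.5 else 61.9),
    baseline_rrso2 = baseline_rrso2 %||% (if (ctrl) 47.7 else 60.6),
    rcso2_deficit = per_period(rcso2_deficit, if (ctrl)
      c(baseline = 0, post1h = 0.04, fio2_40 = 0.06, fio2_30 = 0.08, fio2_21 = 0.18) else
      c(baseline = 0, post1h = 0.22, fio2_40 = 0.25, fio2_30 = 0.30, fio2_21 = 0.45)),
    regional_deficit = per_period(regional_deficit, if (ctrl)
      c(baseline = 0, post1h = 0.05, fio2_40 = 0.08, fio2_30 = 0.12, fio2_21 = 0.22) else
      c(baseline = 0, post1h = 0.14, fio2_40 = 0.17, fio2_30 = 0.26, fio2_21 = 0.45)),
    hr = per_period(hr, if (ctrl)
      c(baseline = 156, post1h = 156, fio2_40 = 158, fio2_30 = 155, fio2_21 = 171) else
      c(baseline = 158, post1h = 154, fio2_40 = 162, fio2_30 = 161, fio2_21 = 188)),
    noise = utils::modifyList(list(sao2 = 0.01, rso2 = 2, paw = 0.2), noise),
    seed = as.integer(seed),
    nomogram = nomogram,
    constants = constants
  )
  stopifnot(all(cfg$qs_qt >= 0 & cfg$qs_qt < 1), all(cfg$vq_shift >= 0),
            all(cfg$C > 0), all(cfg$R >= 0),
            all(cfg$rcso2_deficit >= 0 & cfg$rcso2_deficit < 1))
  if (!ctrl && (cfg$qs_qt[["post1h"]] <= cfg$qs_qt[["baseline"]] ||
                cfg$C[["post1h"]] >= cfg$C[["baseline"]])) {
    stop("animal_config: oa configs must have increased shunt and decreased compliance post injury",
         call. = FALSE)
  }
  structure(cfg, class = "animal_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# the impairment cause the generator injects: the dominant standardized
# excursion present in the config at that period, given a deficit beyond cut
injected_cause <- function(cfg, period, pao2_true) {
  nom <- cfg$nomogram
  if (cfg$rcso2_deficit[[period]] <= nom$deviation_cut) return("none")
  exc <- c(
    o2 = max(0, nom$hypox_threshold - pao2_true) / nom$hypox_threshold,
    bp = max(max(0, nom$bp_lower - cfg$mbp[[period]]) / nom$bp_lower,
             max(0, cfg$mbp[["baseline"]] - cfg$mbp[[period]]) / cfg$mbp[["baseline"]]),
    co2 = abs(cfg$paco2[[period]] - 40) / 40
  )
  exc <- exc[nom$tie_break]
  if (max(exc) == 0) return("unattributed")
  names(exc)[which.max(exc)]
}

#' Simulate one animal's step-down series
#'
#' Forward-composes the package's physiological models: arterial saturation
#' from [predict_sao2()] under the config's shunt and V:Q displacement;
#' arterial PO2 from the dissociation curve; cerebral NIRS from the
#' autoregulation nomogram with the config's injected deficit; gut and kidney
#' NIRS from their baselines with the config's regional decline; regional
#' venous saturations equal to the noiseless regional values (so NIRS- and
#' gas-derived extraction share slopes); airway waveforms from the
#' single-compartment equation of motion. Independent Gaussian noise is added
#' to SaO2, regional saturations and airway pressure.
#'
#' @param config An [animal_config()].
#' @param waveforms Attach per-period breath waveforms (default TRUE).
#' @return A list with `data` (tibble, one row per period), `truth` (tibble
#'   of generating parameters per period) and `waveforms` (named list of
#'   tibbles, or NULL).
#' @examples
#' a <- generate_animal(animal_config("control", seed = 7))
#' a$data$sao2
#' @export
generate_animal <- function(config, waveforms = TRUE) {
  stopifnot(inherits(config, "animal_config"))
  cfg <- config
  pers <- names(step_periods())
  fio2 <- unname(step_periods())
  const <- cfg$constants
  nom <- cfg$nomogram

  sao2_true <- vapply(seq_along(pers), function(i) {
    predict_sao2(fio2[i], cfg$qs_qt[[i]], cfg$vq_shift[[i]], cfg$paco2[[i]],
                 constants = const)
  }, numeric(1))
  pao2_true <- vapply(sao2_true, function(s) {
    hb_po2(min(max(s, 1e-6), 1 - 1e-9))
  }, numeric(1))

  # cerebral forward model: nomogram expectation minus injected deficit
  rcso2_true <- vapply(seq_along(pers), function(i) {
    if (pers[i] == "baseline") return(cfg$baseline_rcso2)
    e <- expected_rcso2(nom, cfg$mbp[[i]], pao2_true[i], cfg$paco2[[i]],
                        cfg$baseline_rcso2)
    e * (1 - cfg$rcso2_deficit[[i]])
  }, numeric(1))
  rgso2_true <- cfg$baseline_rgso2 * (1 - cfg$regional_deficit)
  rrso2_true <- cfg$baseline_rrso2 * (1 - cfg$regional_deficit)

  cause <- vapply(pers, function(p) {
    if (p == "baseline") "none" else injected_cause(cfg, p, pao2_true[match(p, pers)])
  }, character(1))

  set.seed(cfg$seed)
  n <- length(pers)
  sao2_obs <- pmin(pmax(sao2_true + stats::rnorm(n, 0, cfg$noise$sao2), 0.01), 1)
  rcso2_obs <- pmin(pmax(rcso2_true + stats::rnorm(n, 0, cfg$noise$rso2), 1), 100)
  rgso2_obs <- pmin(pmax(rgso2_true + stats::rnorm(n, 0, cfg$noise$rso2), 1), 100)
  rrso2_obs <- pmin(pmax(rrso2_true + stats::rnorm(n, 0, cfg$noise$rso2), 1), 100)

  svc_so2 <- pmin(pmax(rcso2_true / 100, 1e-3), 1 - 1e-6)
  ivc_so2 <- pmin(pmax((rgso2_true + rrso2_true) / 200, 1e-3), 1 - 1e-6)

  vt <- 6 * cfg$weight
  rr <- 40
  data <- tibble::tibble(
    animal_id = cfg$animal_id,
    group = cfg$group,
    period = pers,
    fio2 = fio2,
    weight = cfg$weight,
    vt_ml = vt,
    rr = rr,
    peep = unname(cfg$P0),
    sao2 = sao2_obs,
    pao2 = pao2_true,
    paco2 = unname(cfg$paco2),
    ph = 7.4,
    hco3 = if (cfg$group == "control") 24 else 21,
    svc_so2 = svc_so2,
    svc_po2 = hb_po2(svc_so2),
    ivc_so2 = ivc_so2,
    ivc_po2 = hb_po2(ivc_so2),
    nirs_brain = rcso2_obs,
    nirs_gut = rgso2_obs,
    nirs_kidney = rrso2_obs,
    mbp = unname(cfg$mbp),
    hr = unname(cfg$hr),
    cvp = 7,
    temp = 37.4
  )
  truth <- tibble::tibble(
    animal_id = cfg$animal_id,
    group = cfg$group,
    period = pers,
    fio2 = fio2,
    qs_qt = unname(cfg$qs_qt),
    vq_shift = unname(cfg$vq_shift),
    C = unname(cfg$C),
    R = unname(cfg$R),
    P0 = unname(cfg$P0),
    mbp = unname(cfg$mbp),
    paco2 = unname(cfg$paco2),
    rcso2_deficit = unname(cfg$rcso2_deficit),
    impair_cause = unname(cause),
    sao2_true = sao2_true,
    pao2_true = pao2_true,
    rcso2_true = rcso2_true
  )
  wf <- NULL
  if (waveforms) {
    wf <- lapply(seq_along(pers), function(i) {
      simulate_breath(cfg$C[[i]], cfg$R[[i]], cfg$P0[[i]], vt = vt,
                      noise_sd = cfg$noise$paw)
    })
    names(wf) <- pers
  }
  list(data = data, truth = truth, waveforms = wf)
}

#' Simulate a study cohort
#'
#' Generates `n_control` control and `n_oa` oleic-acid-injured animals
#' (defaults 6 and 7, the study's group sizes) with per-animal seeds derived
#' deterministically from `master_seed`.
#'
#' @param n_control,n_oa Group sizes (>= 1).
#' @param master_seed Integer master seed.
#' @param control_config,oa_config Functions taking `(animal_id, seed)` and
#'   returning an [animal_config()]; override to inject specific physiology.
#' @param waveforms Attach breath waveforms (default TRUE).
#' @return An object of class `neonoxy_cohort`: a list with `data` (long
#'   tibble over animals x periods), `truth`, `waveforms` and `configs`.
#' @examples
#' coh <- generate_cohort(2, 2, master_seed = 42, waveforms = FALSE)
#' dim(coh$data)
#' @export
generate_cohort <- function(n_control = 6, n_oa = 7, master_seed = 1L,
                            control_config = NULL, oa_config = NULL,
                            waveforms = TRUE) {
  stopifnot(n_control >= 1, n_oa >= 1)
  control_config <- control_config %||%
    function(animal_id, seed) animal_config("control", animal_id, seed = seed)
  oa_config <- oa_config %||%
    function(animal_id, seed) animal_config("oa", animal_id, seed = seed)

  groups <- c(rep("control", n_control), rep("oa", n_oa))
  ids <- c(sprintf("C%02d", seq_len(n_control)), sprintf("OA%02d", seq_len(n_oa)))
  seeds <- derive_seeds(master_seed, length(ids))

  animals <- purrr::pmap(list(groups, ids, seeds), function(g, id, s) {
    cfg <- if (g == "control") control_config(id, s) else oa_config(id, s)
    generate_animal(cfg, waveforms = waveforms)
  })
  wf <- if (waveforms) purrr::map(animals, "waveforms") else NULL
  if (!is.null(wf)) names(wf) <- ids
  structure(
    list(
      data = purrr::list_rbind(purrr::map(animals, "data")),
      truth = purrr::list_rbind(purrr::map(animals, "truth")),
      waveforms = wf,
      master_seed = master_seed
    ),
    class = "neonoxy_cohort"
  )
}

# fixed linear-congruential mix keeping every per-animal seed inside 32-bit
derive_seeds <- function(master_seed, n) {
  vapply(seq_len(n), function(i) {
    as.integer((as.numeric(master_seed) * 48271 + i * 7919) %% 2147483629)
  }, integer(1))
}

#' @export
print.neonoxy_cohort <- function(x, ...) {
  cat("<neonoxy_cohort>\n")
  tab <- table(unique(x$data[c("animal_id", "group")])$group)
  cat(sprintf("  %d animals (%s), %d period-records\n",
              length(unique(x$data$animal_id)),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              nrow(x$data)))
  cat(sprintf("  master seed %s; waveforms: %s\n", x$master_seed,
              !is.null(x$waveforms)))
  invisible(x)
}
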