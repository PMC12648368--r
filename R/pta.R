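#' Monte Carlo probability of target attainment
#'
#' Simulates steady-state trough concentrations for a cohort of virtual
#' individuals under a dosing regimen and reports the proportion exceeding
#' each efficacy target.  Each individual receives one subject-level (BSV)
#' and one visit-level (BVV) clearance effect, allometric fat-free-mass
#' scaling and the regimen's covariate effects, and 14 days of dosing are
#' simulated to steady state.  Because the variability model defines every
#' administered dose as its own occasion, each dose of the simulated
#' history carries independent occasion (BOV) effects on `ka`, `mtt` and
#' `f` by default (`occasion = "per_dose"`); `"single_draw"` instead
#' applies one occasion draw to all doses, which overstates trough
#' variance and is provided for sensitivity analysis.  Troughs are
#' model-predicted concentrations without residual error, the standard
#' convention for target-attainment simulation.
#'
#' @param cohort A tibble from [sample_cohort()] (needs `id`, `weight`,
#'   `ffm`).
#' @param regimen One of [pk_regimens()], or `"all"` for the three distinct
#'   exposure scenarios (QD alone, QD + rifampicin, BID + rifampicin).
#' @param params Typical [structural_params()]; defaults to the final
#'   atazanavir model.
#' @param var [variability_params()]; defaults to the final atazanavir
#'   model.
#' @param thresholds Efficacy targets (mg/L): default the protein-adjusted
#'   IC90 0.014 mg/L and the 0.15 mg/L therapeutic-monitoring target.
#' @param drug `"atazanavir"` or `"ritonavir"`.
#' @param dose mg per administration.
#' @param trough_time Hours post dose at which the trough is read; default
#'   the nominal dosing interval (24 h QD, 12 h BID).  Setting 12 for a QD
#'   regimen reproduces the 12-h sampling alternative.
#' @param occasion `"per_dose"` (default) or `"single_draw"`; see Details.
#' @param days Days of dosing simulated before the trough (default 14,
#'   more than 10 terminal half-lives).
#' @param weight_bands Interior break points (kg) for the per-weight-band
#'   breakdown.
#' @param seed Optional integer seed.
#' @return An object of class `pk_pta`: a tibble with one row per regimen x
#'   threshold (`prop` = attainment proportion in `[0, 1]`, `n`), with the
#'   per-individual troughs in `attr(x, "troughs")` and the per-band
#'   breakdown in `attr(x, "bands")`.
#' @examples
#' pta <- simulate_pta(sample_cohort(100, seed = 1), "ATVr_QD", seed = 2)
#' @export
simulate_pta <- function(cohort, regimen = "all",
                         params = pk_defaults("atazanavir")$structural,
                         var = pk_defaults("atazanavir")$variability,
                         thresholds = c(0.014, 0.15),
                         drug = c("atazanavir", "ritonavir"), dose = NULL,
                         trough_time = NULL,
                         occasion = c("per_dose", "single_draw"),
                         days = 14, weight_bands = c(40, 55, 70),
                         seed = NULL) {
  drug <- match.arg(drug)
  occasion <- match.arg(occasion)
  if (is.null(dose)) dose <- if (drug == "atazanavir") 300 else 100
  stopifnot(nrow(cohort) >= 1)
  regs <- if (identical(regimen, "all"))
    c("ATVr_QD", "ATVr_QD_RIF600", "ATVr_BID_RIF600") else regimen
  if (!all(regs %in% pk_regimens()))
    stop("unsupported regimen", call. = FALSE)
  regtab <- regimen_effects(drug)
  run <- function() {
    n <- nrow(cohort)
    eta_bsv <- stats::rnorm(n, 0, var$bsv_cl)
    eta_bvv <- stats::rnorm(n, 0, var$bvv_cl)
    troughs <- purrr::map_dfr(regs, function(rg) {
      tau <- regtab$tau[regtab$regimen == rg]
      tt <- if (is.null(trough_time)) tau else trough_time
      nd <- ceiling(days * 24 / tau) + 1
      ct <- vapply(seq_len(n), function(i) {
        p <- allometric_scale(params, cohort$ffm[i])
        p <- apply_regimen_effects(p, rg, drug)
        p$cl <- p$cl * exp(eta_bsv[i] + eta_bvv[i])
        if (occasion == "single_draw") {
          p$ka <- p$ka * exp(stats::rnorm(1, 0, var$bov_ka))
          p$mtt <- p$mtt * exp(stats::rnorm(1, 0, var$bov_mtt))
          p$f <- p$f * exp(stats::rnorm(1, 0, var$bov_f))
          return(visit_concentrations(p, tau, dose, tt)$plasma)
        }
        dt <- seq(0, by = tau, length.out = nd)
        f <- p$f * exp(stats::rnorm(nd, 0, var$bov_f))
        ka <- p$ka * exp(stats::rnorm(nd, 0, var$bov_ka))
        mtt <- p$mtt * exp(stats::rnorm(nd, 0, var$bov_mtt))
        cpp_conc_profile(max(dt) + tt, dt, rep(dose, nd), f, ka, mtt,
                         p$cl, p$v, p$q, p$vp, p$nn, log(2) / p$teq,
                         p$ppc)[1, 1]
      }, numeric(1))
      tibble::tibble(regimen = rg, id = cohort$id, weight = cohort$weight,
                     ctrough = ct)
    })
    troughs$band <- cut(troughs$weight,
                        breaks = c(-Inf, weight_bands, Inf),
                        labels = band_labels(weight_bands))
    summ <- purrr::map_dfr(thresholds, function(th) {
      troughs |>
        dplyr::group_by(.data$regimen) |>
        dplyr::summarise(threshold = th,
                         prop = mean(.data$ctrough > th),
                         n = dplyr::n(), .groups = "drop")
    }) |>
      dplyr::arrange(.data$regimen, .data$threshold)
    bands <- purrr::map_dfr(thresholds, function(th) {
      troughs |>
        dplyr::group_by(.data$regimen, .data$band) |>
        dplyr::summarise(threshold = th,
                         prop = mean(.data$ctrough > th),
                         n = dplyr::n(), .groups = "drop")
    })
    structure(summ, troughs = troughs, bands = bands, seed = seed,
              class = c("pk_pta", class(summ)))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

band_labels <- function(breaks) {
  edges <- c(-Inf, breaks, Inf)
  vapply(seq_len(length(edges) - 1), function(i) {
    lo <- edges[i]; hi <- edges[i + 1]
    if (!is.finite(lo)) paste0("<", hi)
    else if (!is.finite(hi)) paste0(">=", lo)
    else paste0(lo, "-", hi)
  }, character(1))
}

#' @export
print.pk_pta <- function(x, ...) {
  cat("<pk_pta> steady-state trough target attainment\n")
  NextMethod()
}

#' Deterministic steady-state profiles of the typical individual
#'
#' No-variability steady-state concentration-time profiles over one or more
#' dosing intervals for a configurable typical body size, for each
#' requested regimen.
#'
#' @param params Typical [structural_params()].
#' @param regimens Character vector of regimen labels.
#' @param duration Hours of steady-state profile to return (default 24).
#' @param weight,height,sex Typical individual (default 61 kg, 1.59 m,
#'   female).
#' @param drug `"atazanavir"` or `"ritonavir"`.
#' @param dose mg per administration.
#' @param dt Grid step (h).
#' @return A tibble with columns `regimen`, `time`, `plasma`, `pbmc`.
#' @examples
#' typical_profiles(regimens = c("ATVr_QD", "ATVr_QD_RIF600"))
#' @export
typical_profiles <- function(params = pk_defaults("atazanavir")$structural,
                             regimens = pk_regimens()[1:3],
                             duration = 24, weight = 61, height = 1.59,
                             sex = "female",
                             drug = c("atazanavir", "ritonavir"),
                             dose = NULL, dt = 0.1) {
  drug <- match.arg(drug)
  if (is.null(dose)) dose <- if (drug == "atazanavir") 300 else 100
  if (!all(regimens %in% pk_regimens()))
    stop("unsupported regimen", call. = FALSE)
  ffm <- compute_ffm(weight, height, sex)
  regtab <- regimen_effects(drug)
  purrr::map_dfr(regimens, function(rg) {
    tau <- regtab$tau[regtab$regimen == rg]
    p <- apply_regimen_effects(allometric_scale(params, ffm), rg, drug)
    grid <- seq(0, duration, by = dt)
    # steady-state periodicity: evaluate within [0, tau) and tile
    conc1 <- visit_concentrations(p, tau, dose, seq(0, tau, by = dt))
    idx <- (grid %% tau) / dt + 1
    tibble::tibble(regimen = rg, time = grid,
                   plasma = conc1$plasma[round(idx)],
                   pbmc = conc1$pbmc[round(idx)])
  })
}
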