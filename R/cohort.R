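#' Demographic configuration for cohort simulation
#'
#' Truncated-normal weight/height/age distributions and a sex ratio
#' matching the study population (median weight 67 kg in 50-75 kg,
#' height 1.59 m, 88\% female).  The SDs are chosen so that roughly 95\% of
#' the untruncated mass falls inside the stated ranges.
#'
#' @param weight,height,age Lists with `mean`, `sd`, `min`, `max`.
#' @param p_female Probability of female sex.
#' @return A list usable as `config` in [sample_cohort()].
#' @export
cohort_config <- function(weight = list(mean = 67, sd = 5, min = 50, max = 75),
                          height = list(mean = 1.59, sd = 0.07,
                                        min = 1.48, max = 1.86),
                          age = list(mean = 44, sd = 10, min = 23, max = 61),
                          p_female = 23 / 26) {
  list(weight = weight, height = height, age = age, p_female = p_female)
}

rtruncnorm <- function(n, spec) {
  if (spec$min > spec$max)
    stop("impossible truncation bounds", call. = FALSE)
  if (spec$min == spec$max) return(rep(spec$min, n))
  plo <- stats::pnorm(spec$min, spec$mean, spec$sd)
  phi <- stats::pnorm(spec$max, spec$mean, spec$sd)
  stats::qnorm(stats::runif(n, plo, phi), spec$mean, spec$sd)
}

#' Sample a synthetic cohort
#'
#' Draws demographics (weight, height, sex, age) from truncated normal
#' distributions and derives fat-free mass with [compute_ffm()].
#'
#' @param n Number of individuals (>= 1).
#' @param config A [cohort_config()] list.
#' @param seed Optional integer seed (same seed, same cohort).
#' @return A tibble with columns `id`, `weight`, `height`, `sex`, `age`,
#'   `bmi`, `ffm`.
#' @examples
#' sample_cohort(5, seed = 1)
#' @export
sample_cohort <- function(n, config = cohort_config(), seed = NULL) {
  stopifnot(n >= 1)
  draw <- function() {
    tibble::tibble(
      id = seq_len(n),
      weight = rtruncnorm(n, config$weight),
      height = rtruncnorm(n, config$height),
      sex = ifelse(stats::runif(n) < config$p_female, "female", "male"),
      age = rtruncnorm(n, config$age)
    ) |>
      dplyr::mutate(bmi = .data$weight / .data$height^2,
                    ffm = compute_ffm(.data$weight, .data$height, .data$sex))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Four-visit rifampicin dose-escalation study design
#'
#' The sampling design of the interaction study the synthetic-data
#' generator emulates: 4 visits under (1) ATV/r 300/100 mg QD alone,
#' (2) + rifampicin 600 mg QD, (3) ATV/r BID + rifampicin 600 mg,
#' (4) ATV/r BID + rifampicin 1200 mg.  Rich plasma sampling at pre-dose,
#' 0.5, 1, 2, 4, 6, 8 and 12 h post-dose at every visit with an extra 24 h
#' sample at visit 1; sparse PBMC trough samples at visits 1, 3 and 4 plus
#' a 12 h sample at visit 2.  Each regimen runs for at least 7 days before
#' its visit, so visits are sampled at steady state; the dose preceding
#' each visit's pre-dose sample is taken unobserved at home.
#'
#' @return An object of class `ddi_design`: a tibble with one row per visit
#'   and columns `visit`, `day`, `regimen`, `tau` (dosing interval, h),
#'   `leadin_days`, plus list-columns `plasma_times` and `pbmc_times`
#'   (hours post observed dose).
#' @examples
#' ddi_study_design()
#' @export
ddi_study_design <- function() {
  d <- tibble::tibble(
    visit = 1:4,
    day = c(7, 21, 28, 35),
    regimen = pk_regimens(),
    tau = c(24, 24, 12, 12),
    leadin_days = c(14, 14, 7, 7),
    plasma_times = list(c(0, 0.5, 1, 2, 4, 6, 8, 12, 24),
                        c(0, 0.5, 1, 2, 4, 6, 8, 12),
                        c(0, 0.5, 1, 2, 4, 6, 8, 12),
                        c(0, 0.5, 1, 2, 4, 6, 8, 12)),
    pbmc_times = list(0, 12, 0, 0)
  )
  class(d) <- c("ddi_design", class(d))
  d
}

#' Simulate a complete pharmacokinetic dataset
#'
#' Composes the structural and stochastic layers over a cohort and a study
#' design: draws each subject's random effects, predicts steady-state
#' plasma and PBMC concentrations at the design's sampling times, applies
#' combined residual error and censors observations below the LLOQ.
#' Dosing before the two explicitly recorded doses per visit (the
#' unobserved pre-visit dose and the observed visit dose) is represented by
#' a steady-state dose train (`ss = 1`, interval `ii`), the standard
#' NONMEM-style shorthand for a long lead-in at the same regimen.
#'
#' @param cohort A tibble from [sample_cohort()] (columns `id`, `weight`,
#'   `height`, `sex`, `ffm`).
#' @param design A [ddi_study_design()] object.
#' @param params Typical [structural_params()] (42 kg fat-free-mass
#'   reference).
#' @param var A [variability_params()] object.
#' @param err An [error_model()] object, or `NULL` for noise-free
#'   deterministic observations.
#' @param drug `"atazanavir"` or `"ritonavir"` (selects regimen effects and
#'   default dose).
#' @param dose mg per administration (default 300 for atazanavir, 100 for
#'   ritonavir).
#' @param seed Optional integer seed.
#' @return A tibble in the [read_pk_dataset()] layout (dosing and
#'   observation rows).  The realised random effects and inputs are
#'   attached as `attr(x, "truth")` for recovery testing.
#' @examples
#' d <- pk_defaults("atazanavir")
#' ds <- simulate_dataset(sample_cohort(2, seed = 1), ddi_study_design(),
#'                        d$structural, d$variability, d$error, seed = 1)
#' @export
simulate_dataset <- function(cohort, design = ddi_study_design(),
                             params, var, err,
                             drug = c("atazanavir", "ritonavir"),
                             dose = NULL, seed = NULL) {
  drug <- match.arg(drug)
  if (is.null(dose)) dose <- if (drug == "atazanavir") 300 else 100
  regtab <- regimen_effects(drug)
  run <- function() {
    draws <- purrr::map(cohort$id, function(i)
      draw_individual(params, var, n_visits = nrow(design),
                      occasions_per_visit = 2))
    names(draws) <- as.character(cohort$id)
    rows <- purrr::map2_dfr(seq_len(nrow(cohort)), cohort$id, function(k, id) {
      subj <- cohort[k, ]
      dr <- draws[[as.character(id)]]
      p_ind <- allometric_scale(params, subj$ffm)
      purrr::map_dfr(seq_len(nrow(design)), function(v) {
        des <- design[v, ]
        p_vis <- apply_regimen_effects(p_ind, des$regimen, drug)
        occ_u <- dr[dr$visit == v & dr$occasion == 1, ]
        occ_o <- dr[dr$visit == v & dr$occasion == 2, ]
        p_real <- p_vis
        p_real$cl <- p_vis$cl * exp(occ_o$eta_cl_bsv + occ_o$eta_cl_bvv)
        eta6 <- c(occ_o$eta_ka, occ_o$eta_mtt, occ_o$eta_f,
                  occ_u$eta_ka, occ_u$eta_mtt, occ_u$eta_f)
        t0 <- des$day * 24
        pl_t <- des$plasma_times[[1]]
        pb_t <- des$pbmc_times[[1]]
        conc <- visit_concentrations(p_real, des$tau, dose,
                                     sort(unique(c(pl_t, pb_t))), eta6)
        pl_pred <- conc$plasma[match(pl_t, conc$time)]
        pb_pred <- conc$pbmc[match(pb_t, conc$time)]
        if (is.null(err)) {
          pl_obs <- pl_pred; pb_obs <- pb_pred
          pl_c <- tibble::tibble(value = pl_obs, blq = FALSE)
          pb_c <- tibble::tibble(value = pb_obs, blq = FALSE)
          lloq_pl <- 0; lloq_pb <- 0
        } else {
          pl_obs <- apply_residual_error(pl_pred, err, "plasma")
          pb_obs <- apply_residual_error(pb_pred, err, "pbmc")
          pl_c <- censor_blq(pl_obs, err$lloq)
          pb_c <- censor_blq(pb_obs, err$lloq_pbmc)
          lloq_pl <- err$lloq; lloq_pb <- err$lloq_pbmc
        }
        occ_base <- 2 * (v - 1)
        dose_rows <- tibble::tibble(
          time = c(t0 - des$tau, t0), evid = 1L, cmt = 1L,
          amt = dose, ss = c(1L, 0L), ii = c(des$tau, 0),
          dv = NA_real_, mdv = 1L, blq = FALSE, lloq = NA_real_,
          occ = occ_base + 1:2, obsdose = c(0L, 1L)
        )
        obs_rows <- dplyr::bind_rows(
          tibble::tibble(time = t0 + pl_t, cmt = 2L, dv = pl_c$value,
                         blq = pl_c$blq, lloq = lloq_pl,
                         occ = ifelse(pl_t == 0, occ_base + 1L,
                                      occ_base + 2L)),
          tibble::tibble(time = t0 + pb_t, cmt = 3L, dv = pb_c$value,
                         blq = pb_c$blq, lloq = lloq_pb,
                         occ = ifelse(pb_t == 0, occ_base + 1L,
                                      occ_base + 2L))
        ) |>
          dplyr::mutate(evid = 0L, amt = NA_real_, ss = 0L, ii = 0,
                        mdv = 0L, obsdose = NA_integer_)
        dplyr::bind_rows(dose_rows, obs_rows) |>
          dplyr::mutate(visit = v, regimen = des$regimen)
      }) |>
        dplyr::mutate(id = id, weight = subj$weight, height = subj$height,
                      sex = subj$sex, age = subj$age, ffm = subj$ffm)
    })
    ds <- rows |>
      dplyr::select("id", "time", "evid", "cmt", "amt", "ss", "ii", "dv",
                    "mdv", "blq", "lloq", "visit", "occ", "obsdose",
                    "regimen", "weight", "height", "sex", "age", "ffm") |>
      dplyr::arrange(.data$id, .data$time, .data$evid)
    attr(ds, "truth") <- list(drug = drug, dose = dose, params = params,
                              variability = var, error = err,
                              cohort = cohort,
                              draws = dplyr::bind_rows(draws, .id = "id"))
    ds
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
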