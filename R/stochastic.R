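#' Draw an individual's random-effect realisation
#'
#' Samples the log-normal random effects of the hierarchical model for one
#' subject: a subject-level eta on clearance (BSV), a visit-level eta on
#' clearance per visit (BVV), and occasion-level etas on `ka`, `mtt` and
#' `f` for each dosing occasion.  Occasions flagged unobserved (doses taken
#' at home before a visit) have their BOV standard deviations inflated by
#' `unobs_dose_scale`.
#'
#' @param typical A [structural_params()] object of typical values (after
#'   any body-size and regimen scaling relevant to the caller).
#' @param var A [variability_params()] object.
#' @param n_visits Number of visits.
#' @param occasions_per_visit Number of dosing occasions per visit carrying
#'   their own absorption etas; by convention occasion 1 is the unobserved
#'   pre-visit dose and the last occasion is the observed visit dose.
#' @param unobserved Logical vector of length `occasions_per_visit` flagging
#'   which occasions are unobserved doses (default: first only).
#' @param seed Optional integer seed; identical seeds reproduce identical
#'   realisations without touching the global RNG stream.
#' @return A tibble with one row per visit x occasion: the etas, the
#'   multiplicative effects `exp(eta)`, and the realised `cl`, `ka`, `mtt`,
#'   `f` for that occasion.
#' @examples
#' d <- pk_defaults("atazanavir")
#' draw_individual(d$structural, d$variability, seed = 1)
#' @export
draw_individual <- function(typical, var, n_visits = 4,
                            occasions_per_visit = 2,
                            unobserved = NULL, seed = NULL) {
  if (is.null(unobserved))
    unobserved <- c(TRUE, rep(FALSE, occasions_per_visit - 1))
  stopifnot(length(unobserved) == occasions_per_visit)
  draw <- function() {
    eta_bsv <- stats::rnorm(1, 0, var$bsv_cl)
    grid <- tidyr::expand_grid(visit = seq_len(n_visits),
                               occasion = seq_len(occasions_per_visit))
    eta_bvv <- stats::rnorm(n_visits, 0, var$bvv_cl)
    scale <- ifelse(unobserved[grid$occasion], var$unobs_dose_scale, 1)
    grid |>
      dplyr::mutate(
        unobserved = unobserved[.data$occasion],
        eta_cl_bsv = eta_bsv,
        eta_cl_bvv = eta_bvv[.data$visit],
        eta_ka = stats::rnorm(dplyr::n(), 0, var$bov_ka * scale),
        eta_mtt = stats::rnorm(dplyr::n(), 0, var$bov_mtt * scale),
        eta_f = stats::rnorm(dplyr::n(), 0, var$bov_f * scale),
        cl = typical$cl * exp(.data$eta_cl_bsv + .data$eta_cl_bvv),
        ka = typical$ka * exp(.data$eta_ka),
        mtt = typical$mtt * exp(.data$eta_mtt),
        f = typical$f * exp(.data$eta_f)
      )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Apply combined residual error to predictions
#'
#' `y = pred * (1 + eps_prop) + eps_add` with independent normal errors;
#' negative draws are floored at zero (simulation output only).
#'
#' @param pred Non-negative predicted concentrations (mg/L), vectorised.
#' @param err An [error_model()] object.
#' @param matrix `"plasma"` or `"pbmc"` (selects the error terms).
#' @param seed Optional integer seed.
#' @return Simulated observed concentrations (mg/L).
#' @export
apply_residual_error <- function(pred, err, matrix = c("plasma", "pbmc"),
                                 seed = NULL) {
  matrix <- match.arg(matrix)
  if (any(pred < 0)) stop("pred must be >= 0", call. = FALSE)
  prop <- if (matrix == "plasma") err$prop else err$prop_pbmc
  add <- if (matrix == "plasma") err$add else err$add_pbmc
  draw <- function() {
    y <- pred * (1 + stats::rnorm(length(pred), 0, prop)) +
      stats::rnorm(length(pred), 0, add)
    pmax(y, 0)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Censor observations below the limit of quantification
#'
#' Values strictly below the LLOQ are replaced by LLOQ/2 and flagged; in the
#' likelihood such observations contribute with their additive error SD
#' inflated by LLOQ/2.
#'
#' @param y Observed concentrations (mg/L).
#' @param lloq Lower limit of quantification (mg/L), > 0.
#' @return A tibble with columns `value` and `blq` (logical).
#' @examples
#' censor_blq(c(0.010, 0.030), lloq = 0.030)
#' @export
censor_blq <- function(y, lloq) {
  if (lloq <= 0) stop("lloq must be > 0", call. = FALSE)
  blq <- y < lloq
  tibble::tibble(value = ifelse(blq, lloq / 2, y), blq = blq)
}
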