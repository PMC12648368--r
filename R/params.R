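#' Structural pharmacokinetic parameters
#'
#' Typical (fixed-effect) parameters of the transit-absorption,
#' two-compartment disposition model with an effect-compartment link to
#' intracellular (PBMC) concentrations.
#'
#' @param cl Clearance (L/h).
#' @param v Central volume of distribution (L).
#' @param q Intercompartmental clearance (L/h); `0` collapses the model to
#'   one disposition compartment.
#' @param vp Peripheral volume of distribution (L).
#' @param f Bioavailability fraction relative to the reference regimen.
#' @param ka First-order absorption rate constant (1/h).
#' @param mtt Mean transit time through the absorption chain (h).
#' @param nn Number of transit compartments; may be non-integer, in which
#'   case the analytic gamma-input form of the transit model is used.
#' @param teq Plasma-to-PBMC equilibration half-life (h); the effect
#'   compartment rate constant is `ke0 = log(2)/teq`.
#' @param ppc Pseudo-partition coefficient: steady-state PBMC-to-plasma
#'   concentration ratio (dimensionless).
#'
#' @return An object of class `structural_params` (a validated named list).
#' @examples
#' p <- structural_params(cl = 7.57, v = 77.5, q = 3.13, vp = 42.1)
#' p$cl
#' @export
structural_params <- function(cl, v, q = 0, vp = 1, f = 1, ka = 1,
                              mtt = 0.5, nn = 1, teq = 1, ppc = 1) {
  p <- list(cl = cl, v = v, q = q, vp = vp, f = f, ka = ka,
            mtt = mtt, nn = nn, teq = teq, ppc = ppc)
  validate_structural_params(p)
  structure(p, class = "structural_params")
}

validate_structural_params <- function(p) {
  num <- vapply(p, is.numeric, logical(1))
  if (!all(num)) stop("structural parameters must be numeric", call. = FALSE)
  pos <- c("cl", "v", "vp", "f", "ka", "mtt", "teq", "ppc")
  for (nm in pos)
    if (p[[nm]] <= 0) stop("'", nm, "' must be strictly positive", call. = FALSE)
  if (p$q < 0) stop("'q' must be non-negative", call. = FALSE)
  if (p$nn < 0) stop("'nn' must be >= 0", call. = FALSE)
  if (p$f > 1.5) stop("'f' must be in (0, 1.5]", call. = FALSE)
  invisible(p)
}

#' @export
print.structural_params <- function(x, ...) {
  cat("<structural_params>\n")
  print(unlist(x))
  invisible(x)
}

#' Random-effect (variability) parameters
#'
#' Standard deviations of the log-normal random effects: between-subject
#' (BSV) and between-visit (BVV) variability on clearance, and
#' between-occasion variability (BOV) on the absorption parameters `ka`,
#' `mtt` and `f`, with every administered dose treated as an occasion.
#' Values are log-scale SDs (omega); the conventional \%CV is
#' `100 * omega` under the reporting identity `%CV = sqrt(omega^2) * 100`.
#'
#' @param bsv_cl,bvv_cl Log-scale SD of the subject- and visit-level effects
#'   on clearance.
#' @param bov_ka,bov_mtt,bov_f Log-scale SDs of the occasion-level effects
#'   on the absorption parameters.
#' @param unobs_dose_scale Multiplier applied to the BOV SDs for doses taken
#'   unobserved at home (the dose preceding each visit's pre-dose sample).
#' @return An object of class `variability_params`.
#' @export
variability_params <- function(bsv_cl = 0, bvv_cl = 0, bov_ka = 0,
                               bov_mtt = 0, bov_f = 0,
                               unobs_dose_scale = 1) {
  p <- list(bsv_cl = bsv_cl, bvv_cl = bvv_cl, bov_ka = bov_ka,
            bov_mtt = bov_mtt, bov_f = bov_f,
            unobs_dose_scale = unobs_dose_scale)
  if (any(unlist(p) < 0)) stop("variability SDs must be >= 0", call. = FALSE)
  structure(p, class = "variability_params")
}

#' Combined residual error model
#'
#' Combined additive and proportional residual error, with separate terms
#' for the plasma and PBMC matrices.  The additive SD is constrained to at
#' least 20\% of the corresponding lower limit of quantification (LLOQ).
#'
#' @param prop,add Proportional SD (fraction) and additive SD (mg/L) for
#'   plasma observations.
#' @param lloq Plasma LLOQ (mg/L).
#' @param prop_pbmc,add_pbmc,lloq_pbmc Same for PBMC observations.
#' @return An object of class `error_model`.
#' @export
error_model <- function(prop, add, lloq, prop_pbmc = prop,
                        add_pbmc = add, lloq_pbmc = lloq) {
  p <- list(prop = prop, add = add, lloq = lloq, prop_pbmc = prop_pbmc,
            add_pbmc = add_pbmc, lloq_pbmc = lloq_pbmc)
  if (p$prop <= 0) stop("'prop' must be > 0", call. = FALSE)
  if (p$add < 0.2 * p$lloq)
    stop("additive SD must be at least 20% of the LLOQ", call. = FALSE)
  if (p$add_pbmc < 0.2 * p$lloq_pbmc)
    stop("PBMC additive SD must be at least 20% of the PBMC LLOQ",
         call. = FALSE)
  structure(p, class = "error_model")
}

#' Final-model parameter defaults
#'
#' Typical values, covariate effects, variabilities and residual-error terms
#' of the final atazanavir and ritonavir population models, referenced to a
#' 42 kg fat-free-mass individual.  These defaults serve both as simulation
#' truth for the synthetic-data generator and as the fixed/fitted parameter
#' set for estimation.
#'
#' @param drug `"atazanavir"` or `"ritonavir"`.
#' @return A list with elements `structural` (`structural_params`),
#'   `variability` (`variability_params`), `error` (`error_model`),
#'   `regimen` (tibble of per-regimen multipliers, see [regimen_effects()]),
#'   `dose` (mg per administration), `ref_ffm` (kg) and `fixed` (names of
#'   parameters fixed during the original model development).
#' @examples
#' pk_defaults("atazanavir")$structural$cl
#' @export
pk_defaults <- function(drug = c("atazanavir", "ritonavir")) {
  drug <- match.arg(drug)
  if (drug == "atazanavir") {
    list(
      drug = drug,
      structural = structural_params(cl = 7.57, v = 77.5, q = 3.13,
                                     vp = 42.1, f = 1, ka = 6, mtt = 0.499,
                                     nn = 10, teq = 0.963, ppc = 0.653),
      variability = variability_params(bsv_cl = 0.276, bvv_cl = 0.175,
                                       bov_ka = 0.979, bov_mtt = 0.594,
                                       bov_f = 0.482,
                                       unobs_dose_scale = 1.63),
      error = error_model(prop = 0.198, add = 0.006, lloq = 0.030,
                          prop_pbmc = 0.749, add_pbmc = 0.003,
                          lloq_pbmc = 0.015),
      regimen = regimen_effects(drug),
      dose = 300, ref_ffm = 42,
      fixed = c("ka", "nn", "add", "add_pbmc")
    )
  } else {
    list(
      drug = drug,
      structural = structural_params(cl = 9.67, v = 55.4, q = 1.56,
                                     vp = 70.1, f = 1, ka = 1.02,
                                     mtt = 0.483, nn = 12.3, teq = 1.40,
                                     ppc = 1.68),
      variability = variability_params(bsv_cl = 0.164, bvv_cl = 0,
                                       bov_ka = 0.823, bov_mtt = 0.436,
                                       bov_f = 0.555, unobs_dose_scale = 1),
      error = error_model(prop = 0.256, add = 0.001, lloq = 0.005,
                          prop_pbmc = 0.514, add_pbmc = 0.003,
                          lloq_pbmc = 0.015),
      regimen = regimen_effects(drug),
      dose = 100, ref_ffm = 42,
      fixed = c("nn", "add", "add_pbmc")
    )
  }
}

#' Per-regimen covariate effects
#'
#' Multiplicative regimen effects on clearance, bioavailability and the
#' absorption rate constant for the four study regimens.  Rifampicin enters
#' the model as a categorical regimen covariate: once-daily dosing with
#' rifampicin induces clearance ~3-fold for atazanavir (~2-fold for
#' ritonavir) and reduces bioavailability and (for atazanavir) the
#' absorption rate; doubling the dosing frequency to twice daily restores
#' atazanavir bioavailability and halves the induction.  Increasing the
#' rifampicin dose from 600 to 1200 mg has no additional effect, so the two
#' twice-daily regimens share one set of multipliers.
#'
#' @param drug `"atazanavir"` or `"ritonavir"`.
#' @return A tibble with columns `regimen`, `tau` (nominal dosing interval,
#'   h), `cl_fold`, `f_mult`, `ka_mult`.
#' @examples
#' regimen_effects("atazanavir")
#' @export
regimen_effects <- function(drug = c("atazanavir", "ritonavir")) {
  drug <- match.arg(drug)
  if (drug == "atazanavir") {
    tibble::tibble(
      regimen = c("ATVr_QD", "ATVr_QD_RIF600", "ATVr_BID_RIF600",
                  "ATVr_BID_RIF1200"),
      tau = c(24, 24, 12, 12),
      cl_fold = c(1, 3.05, 2.03, 2.03),
      f_mult = c(1, 1 - 0.525, 1, 1),
      ka_mult = c(1, 1 - 0.673, 1 - 0.673, 1 - 0.673)
    )
  } else {
    tibble::tibble(
      regimen = c("ATVr_QD", "ATVr_QD_RIF600", "ATVr_BID_RIF600",
                  "ATVr_BID_RIF1200"),
      tau = c(24, 24, 12, 12),
      cl_fold = c(1, 2.12, 2.12, 2.12),
      f_mult = c(1, 1 - 0.688, 1 - 0.333, 1 - 0.333),
      ka_mult = c(1, 1, 1, 1)
    )
  }
}

#' Supported regimen labels
#' @return Character vector of the four regimen labels.
#' @export
pk_regimens <- function() {
  c("ATVr_QD", "ATVr_QD_RIF600", "ATVr_BID_RIF600", "ATVr_BID_RIF1200")
}

#' Fat-free mass (Janmahasatian sex-specific equation)
#'
#' `FFM = 9270 * WT / (6680 + 216 * BMI)` for males and
#' `FFM = 9270 * WT / (8780 + 244 * BMI)` for females, with
#' `BMI = WT / HT^2`.
#'
#' @param weight Body weight (kg).
#' @param height Height (m).
#' @param sex `"male"` or `"female"` (vectorised).
#' @return Fat-free mass (kg), always less than `weight`.
#' @examples
#' compute_ffm(67, 1.59, "female")  # ~40.7 kg
#' @export
compute_ffm <- function(weight, height, sex) {
  if (any(weight <= 0) || any(height <= 0))
    stop("weight and height must be positive", call. = FALSE)
  sex <- match_sex(sex)
  bmi <- weight / height^2
  ifelse(sex == "male",
         9270 * weight / (6680 + 216 * bmi),
         9270 * weight / (8780 + 244 * bmi))
}

match_sex <- function(sex) {
  sex <- tolower(as.character(sex))
  ok <- sex %in% c("male", "female")
  if (!all(ok)) stop("sex must be 'male' or 'female'", call. = FALSE)
  sex
}

#' Allometric body-size scaling
#'
#' Scales the clearance parameters (`cl`, `q`) by `(ffm/ref_ffm)^0.75` and
#' the volumes (`v`, `vp`) by `(ffm/ref_ffm)^1`, the standard allometric
#' exponents, using fat-free mass as the body-size descriptor.
#'
#' @param params A [structural_params()] object.
#' @param ffm Individual fat-free mass (kg).
#' @param ref_ffm Reference fat-free mass (kg); the final-model typical
#'   values refer to 42 kg.
#' @return A scaled `structural_params` object.
#' @examples
#' p <- pk_defaults("atazanavir")$structural
#' allometric_scale(p, ffm = 21, ref_ffm = 42)$cl  # 7.57 * 0.5^0.75
#' @export
allometric_scale <- function(params, ffm, ref_ffm = 42) {
  if (ffm <= 0 || ref_ffm <= 0)
    stop("ffm and ref_ffm must be positive", call. = FALSE)
  r <- ffm / ref_ffm
  params$cl <- params$cl * r^0.75
  params$q <- params$q * r^0.75
  params$v <- params$v * r
  params$vp <- params$vp * r
  params
}

#' Apply regimen covariate effects to structural parameters
#'
#' Multiplies clearance, bioavailability and the absorption rate constant by
#' the regimen's covariate effects.
#'
#' @param params A [structural_params()] object.
#' @param effect Either a one-row tibble with columns `cl_fold`, `f_mult`,
#'   `ka_mult` (e.g. a row of [regimen_effects()]) or a regimen label, in
#'   which case `drug` selects the effect table.
#' @param drug Used only when `effect` is a regimen label.
#' @return A modified `structural_params` object.
#' @examples
#' p <- pk_defaults("atazanavir")$structural
#' apply_regimen_effects(p, "ATVr_QD_RIF600")$cl  # 7.57 * 3.05
#' @export
apply_regimen_effects <- function(params, effect,
                                  drug = c("atazanavir", "ritonavir")) {
  if (is.character(effect)) {
    drug <- match.arg(drug)
    tab <- regimen_effects(drug)
    if (!effect %in% tab$regimen)
      stop("unknown regimen label: ", effect, call. = FALSE)
    effect <- tab[tab$regimen == effect, ]
  }
  if (any(c(effect$cl_fold, effect$f_mult, effect$ka_mult) <= 0))
    stop("regimen effect multipliers must be positive", call. = FALSE)
  params$cl <- params$cl * effect$cl_fold
  params$f <- params$f * effect$f_mult
  params$ka <- params$ka * effect$ka_mult
  params
}

#' Write / read a parameter configuration file
#'
#' Serialises a full parameter set (structural values, regimen effects,
#' variabilities, error terms, dose, fixed flags) to a flat YAML file and
#' back, so parameter sets can be inspected and edited outside R.
#'
#' @param config A list as returned by [pk_defaults()].
#' @param path File path.
#' @return `read_pk_config()` returns a list in the [pk_defaults()] layout.
#' @export
write_pk_config <- function(config, path) {
  flat <- list(
    drug = config$drug,
    dose = config$dose,
    ref_ffm = config$ref_ffm,
    structural = unclass(config$structural),
    variability = unclass(config$variability),
    error = unclass(config$error),
    regimen = as.list(as.data.frame(config$regimen)),
    fixed = as.list(config$fixed)
  )
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_pk_config
#' @export
read_pk_config <- function(path) {
  y <- yaml::read_yaml(path)
  list(
    drug = y$drug,
    structural = do.call(structural_params, y$structural),
    variability = do.call(variability_params, y$variability),
    error = do.call(error_model, y$error),
    regimen = tibble::as_tibble(y$regimen),
    dose = y$dose,
    ref_ffm = y$ref_ffm,
    fixed = unlist(y$fixed)
  )
}
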