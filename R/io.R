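#' Read and write pharmacokinetic datasets
#'
#' Datasets use a NONMEM-convention tabular layout: one row per dosing
#' event (`evid = 1`, `amt` in mg, optional steady-state flag `ss` with
#' dosing interval `ii`) or observation (`evid = 0`, `dv` in mg/L,
#' compartment `cmt` 2 = plasma, 3 = PBMC), with per-row covariates
#' (visit, occasion, regimen label, weight, height, sex, age, fat-free
#' mass), a BLQ flag and the applicable LLOQ.  Uppercase NONMEM aliases
#' (`ID`, `TIME`, `AMT`, `DV`, `EVID`, `MDV`, `CMT`, ...) are accepted on
#' input.  Validation reports offending row numbers.
#'
#' @param path CSV file path.
#' @param ds A dataset tibble (as produced by [simulate_dataset()] or
#'   [read_pk_dataset()]).
#' @return `read_pk_dataset()` returns a validated tibble;
#'   `write_pk_dataset()` writes and returns `path` invisibly.
#' @examples
#' \donttest{
#' d <- pk_defaults("atazanavir")
#' ds <- simulate_dataset(sample_cohort(2, seed = 1), ddi_study_design(),
#'                        d$structural, d$variability, d$error, seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_pk_dataset(ds, f)
#' identical(dim(read_pk_dataset(f)), dim(ds))
#' }
#' @export
read_pk_dataset <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(raw) <- tolower(names(raw))
  alias <- c(reg = "regimen", wt = "weight", ht = "height")
  for (a in names(alias))
    if (a %in% names(raw) && !alias[[a]] %in% names(raw))
      names(raw)[names(raw) == a] <- alias[[a]]
  required <- c("id", "time", "evid", "cmt", "amt", "dv")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  defaults <- list(ss = 0L, ii = 0, mdv = NA_integer_, blq = FALSE,
                   lloq = NA_real_, visit = NA_integer_, occ = NA_integer_,
                   obsdose = NA_integer_, regimen = NA_character_,
                   weight = NA_real_, height = NA_real_,
                   sex = NA_character_, age = NA_real_, ffm = NA_real_)
  for (nm in names(defaults))
    if (!nm %in% names(raw)) raw[[nm]] <- defaults[[nm]]
  raw$mdv <- ifelse(is.na(raw$mdv), as.integer(raw$evid != 0), raw$mdv)
  raw$blq <- as.logical(raw$blq)
  for (nm in c("evid", "cmt", "ss", "mdv", "visit", "occ", "obsdose"))
    raw[[nm]] <- as.integer(raw[[nm]])
  ds <- tibble::as_tibble(raw[, c("id", "time", "evid", "cmt", "amt", "ss",
                                  "ii", "dv", "mdv", "blq", "lloq", "visit",
                                  "occ", "obsdose", "regimen", "weight",
                                  "height", "sex", "age", "ffm")])
  validate_pk_dataset(ds)
  ds
}

#' @rdname read_pk_dataset
#' @export
write_pk_dataset <- function(ds, path) {
  validate_pk_dataset(ds)
  readr::write_csv(ds, path, progress = FALSE)
  invisible(path)
}

#' Validate a pharmacokinetic dataset
#'
#' Checks the structural invariants of the tabular layout: doses carry
#' amounts and no observed value, observations the reverse; times are
#' non-negative and non-decreasing within subject; every observation's
#' occasion references a dose row of the same subject; regimen labels (when
#' present) belong to the supported set; every observation is preceded by
#' at least one dose for that subject.
#'
#' @param ds A dataset tibble.
#' @return `ds`, invisibly; errors name the offending rows.
#' @export
validate_pk_dataset <- function(ds) {
  bad_row <- function(cond, msg) {
    if (any(cond, na.rm = TRUE))
      stop(msg, " (rows ", paste(utils::head(which(cond), 5), collapse = ", "),
           ")", call. = FALSE)
  }
  bad_row(!ds$evid %in% c(0L, 1L), "evid must be 0 (observation) or 1 (dose)")
  is_dose <- ds$evid == 1L
  bad_row(is_dose & (is.na(ds$amt) | ds$amt <= 0),
          "dose rows need a positive amt")
  bad_row(is_dose & !is.na(ds$dv), "dose rows must not carry a dv")
  bad_row(!is_dose & is.na(ds$dv), "observation rows need a dv")
  bad_row(!is_dose & !is.na(ds$amt), "observation rows must not carry amt")
  bad_row(ds$time < 0, "times must be non-negative")
  reg <- ds$regimen[!is.na(ds$regimen)]
  if (length(reg) && !all(reg %in% pk_regimens()))
    stop("unknown regimen labels: ",
         paste(unique(setdiff(reg, pk_regimens())), collapse = ", "),
         call. = FALSE)
  for (sid in unique(ds$id)) {
    sub <- ds[ds$id == sid, ]
    rows <- which(ds$id == sid)
    if (is.unsorted(sub$time))
      stop("times not non-decreasing within subject ", sid, " (rows ",
           paste(utils::head(rows[which(diff(sub$time) < 0) + 1], 5),
                 collapse = ", "), ")", call. = FALSE)
    first_dose <- suppressWarnings(min(sub$time[sub$evid == 1L]))
    early <- sub$evid == 0L & sub$time < first_dose
    if (any(early))
      stop("observation before any dose for subject ", sid, " (rows ",
           paste(utils::head(rows[early], 5), collapse = ", "), ")",
           call. = FALSE)
    occ_obs <- sub$occ[sub$evid == 0L]
    occ_dose <- sub$occ[sub$evid == 1L]
    if (!all(is.na(occ_obs)) && !all(stats::na.omit(occ_obs) %in% occ_dose))
      stop("observation occasion without matching dose for subject ", sid,
           call. = FALSE)
  }
  invisible(ds)
}
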