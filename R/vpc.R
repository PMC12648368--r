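#' Visual predictive check
#'
#' Simulates `n_rep` replicate datasets under the full stochastic model at
#' the original design (same subjects, covariates, visits and sampling
#' times), computes the 5th/50th/95th percentiles of each replicate per
#' time bin, and summarises them into 95\% confidence bands against which
#' the observed percentiles are overlaid.  Binning uses the nominal
#' sampling times (the design is rich and fixed); results are stratified
#' by regimen and observation matrix.  BLQ observations enter as their
#' imputed LLOQ/2 values, in the simulations exactly as in the data.
#'
#' @param dataset A dataset tibble (see [read_pk_dataset()]).
#' @param params Typical [structural_params()] used for simulation.
#' @param var A [variability_params()] object.
#' @param err An [error_model()] object (or `NULL` for no residual error).
#' @param drug `"atazanavir"` or `"ritonavir"`.
#' @param n_rep Number of replicate datasets (>= 100).
#' @param min_bin_n Bins with fewer observations are merged into the
#'   nearest neighbour (with a warning).
#' @param seed Optional integer seed.
#' @return An object of class `pk_vpc`: a tibble with one row per stratum x
#'   time bin holding observed percentiles (`obs_p5`, `obs_p50`,
#'   `obs_p95`) and the simulated 2.5/97.5 bands for each
#'   (`p5_lo`/`p5_hi`, ...).  Plot with [autoplot.pk_vpc()].
#' @export
vpc <- function(dataset, params, var, err,
                drug = c("atazanavir", "ritonavir"),
                n_rep = 200, min_bin_n = 3, seed = NULL) {
  drug <- match.arg(drug)
  if (n_rep < 100) stop("n_rep must be >= 100", call. = FALSE)
  packs <- build_packs(dataset)
  # flat observation table with stratum/bin labels
  obs_tab <- purrr::map_dfr(packs, function(p) {
    tibble::tibble(id = p$id, visit = p$obs[, "visit"],
                   regimen = p$regimens[p$obs[, "visit"]],
                   trel = p$obs[, "trel"],
                   matrix = ifelse(p$obs[, "mtype"] > 0.5, "pbmc", "plasma"),
                   dv = p$obs[, "dv"])
  })
  sim_one <- function() {
    purrr::map(packs, function(p) {
      dr <- draw_individual(params, var, n_visits = p$n_visits,
                            occasions_per_visit = 2)
      pred <- numeric(nrow(p$obs))
      p_ind <- allometric_scale(params, p$ffm)
      for (v in seq_len(p$n_visits)) {
        rows <- which(p$obs[, "visit"] == v)
        if (!length(rows)) next
        p_vis <- apply_regimen_effects(p_ind, p$regimens[v], drug)
        occ_u <- dr[dr$visit == v & dr$occasion == 1, ]
        occ_o <- dr[dr$visit == v & dr$occasion == 2, ]
        p_vis$cl <- p_vis$cl * exp(occ_o$eta_cl_bsv + occ_o$eta_cl_bvv)
        eta6 <- c(occ_o$eta_ka, occ_o$eta_mtt, occ_o$eta_f,
                  occ_u$eta_ka, occ_u$eta_mtt, occ_u$eta_f)
        cc <- visit_concentrations(p_vis, p$vis[v, 1], p$vis[v, 2],
                                   p$obs[rows, "trel"], eta6)
        pred[rows] <- ifelse(p$obs[rows, "mtype"] > 0.5, cc$pbmc, cc$plasma)
      }
      if (!is.null(err)) {
        pl <- p$obs[, "mtype"] < 0.5
        pred[pl] <- apply_residual_error(pred[pl], err, "plasma")
        pred[!pl] <- apply_residual_error(pred[!pl], err, "pbmc")
        pred[pl] <- censor_blq(pred[pl], err$lloq)$value
        pred[!pl] <- censor_blq(pred[!pl], err$lloq_pbmc)$value
      }
      pred
    }) |> unlist()
  }
  run <- function() {
    sims <- vapply(seq_len(n_rep), function(i) sim_one(),
                   numeric(nrow(obs_tab)))
    obs_tab$bin <- paste(obs_tab$regimen, obs_tab$matrix, obs_tab$trel,
                         sep = "|")
    # merge sparse bins into the nearest time within the same stratum
    counts <- table(obs_tab$bin)
    small <- names(counts)[counts < min_bin_n]
    if (length(small)) {
      warning("merging ", length(small), " sparse VPC bin(s) into neighbours")
      for (b in small) {
        parts <- strsplit(b, "|", fixed = TRUE)[[1]]
        stratum <- obs_tab$regimen == parts[1] & obs_tab$matrix == parts[2]
        cand <- unique(obs_tab$trel[stratum & obs_tab$bin != b])
        if (!length(cand)) next
        tnew <- cand[which.min(abs(cand - as.numeric(parts[3])))]
        obs_tab$bin[obs_tab$bin == b] <-
          paste(parts[1], parts[2], tnew, sep = "|")
      }
    }
    pct <- function(x) stats::quantile(x, c(0.05, 0.5, 0.95), names = FALSE)
    out <- obs_tab |>
      dplyr::mutate(row = dplyr::row_number()) |>
      dplyr::group_by(.data$regimen, .data$matrix, .data$bin) |>
      dplyr::summarise(time = stats::median(.data$trel),
                       n = dplyr::n(),
                       obs_p5 = pct(.data$dv)[1],
                       obs_p50 = pct(.data$dv)[2],
                       obs_p95 = pct(.data$dv)[3],
                       rows = list(.data$row), .groups = "drop")
    band <- function(rows, k) {
      per_rep <- apply(sims[rows, , drop = FALSE], 2,
                       function(x) pct(x)[k])
      stats::quantile(per_rep, c(0.025, 0.975), names = FALSE)
    }
    for (k in 1:3) {
      nm <- c("p5", "p50", "p95")[k]
      bnd <- t(vapply(out$rows, band, numeric(2), k = k))
      out[[paste0(nm, "_lo")]] <- bnd[, 1]
      out[[paste0(nm, "_hi")]] <- bnd[, 2]
    }
    out <- dplyr::select(out, -"rows", -"bin") |>
      dplyr::arrange(.data$regimen, .data$matrix, .data$time)
    structure(out, n_rep = n_rep, class = c("pk_vpc", class(out)))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Plot a visual predictive check
#'
#' Observed 5th/50th/95th percentiles (lines) over the simulated 95\%
#' confidence bands (ribbons), faceted by regimen and matrix.
#'
#' @param object A `pk_vpc` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pk_vpc <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p5_lo, ymax = .data$p5_hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p50_lo,
                                      ymax = .data$p50_hi),
                         fill = "firebrick", alpha = 0.25) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p95_lo,
                                      ymax = .data$p95_hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p50), colour = "firebrick") +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p5), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p95), linetype = 2) +
    ggplot2::facet_grid(.data$matrix ~ .data$regimen, scales = "free_y") +
    ggplot2::labs(x = "time after dose (h)", y = "concentration (mg/L)") +
    ggplot2::theme_bw()
}

#' Plot target-attainment troughs
#'
#' Box plots of simulated steady-state troughs by regimen and weight band
#' with the efficacy targets as horizontal lines.
#'
#' @param object A `pk_pta` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pk_pta <- function(object, ...) {
  tr <- attr(object, "troughs")
  th <- unique(object$threshold)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$band, y = .data$ctrough)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, fill = "grey85") +
    ggplot2::geom_hline(yintercept = th, linetype = 2,
                        colour = c("red", "blue")[seq_along(th)]) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~.data$regimen) +
    ggplot2::labs(x = "weight band (kg)",
                  y = "steady-state trough (mg/L)") +
    ggplot2::theme_bw()
}

#' Plot typical steady-state profiles
#'
#' @param profiles A tibble from [typical_profiles()].
#' @param targets Optional horizontal reference concentrations (mg/L).
#' @return A ggplot object.
#' @export
plot_typical_profiles <- function(profiles, targets = c(0.014, 0.15)) {
  gg <- ggplot2::ggplot(profiles,
                        ggplot2::aes(x = .data$time, y = .data$plasma,
                                     colour = .data$regimen,
                                     linetype = .data$regimen)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time after dose (h)",
                  y = "plasma concentration (mg/L)") +
    ggplot2::theme_bw()
  if (length(targets))
    gg <- gg + ggplot2::geom_hline(yintercept = targets, linetype = 3,
                                   colour = "grey40")
  gg
}
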