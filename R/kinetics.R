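#' Coupled-assay design constants
#'
#' Fixed quantities of the GLDH-coupled plate assay needed to convert
#' absorbance rates to molar turnover and to derive catalytic constants:
#' enzyme concentration and well volume (together, the enzyme amount per
#' well), the enzyme molecular weight (moles of enzyme), and the
#' instrument-calibrated conversion factor from mAU/min to pmol/s. The
#' conversion factor is an empirical constant determined from an NADH
#' standard curve, not derived from extinction coefficients; 1.111 is the
#' published value for this plate format.
#'
#' @param enzyme_conc_ug_ml Enzyme concentration in the well, ug/ml
#'   (default 5).
#' @param well_volume_ul Reaction volume, ul (default 200).
#' @param enzyme_mw Enzyme molecular weight, Da. Defaults to 26,400 (the
#'   active-form mass of the *Kutzneria albida* transglutaminase); supply
#'   the correct mass for any other enzyme.
#' @param conversion_factor (pmol/s) per (mAU/min); default 1.111.
#' @return An object of class `assay_design`.
#' @export
assay_design <- function(enzyme_conc_ug_ml = 5,
                         well_volume_ul = 200,
                         enzyme_mw = 26400,
                         conversion_factor = 1.111) {
  stopifnot(enzyme_conc_ug_ml > 0, well_volume_ul > 0,
            is.null(enzyme_mw) || enzyme_mw > 0, conversion_factor > 0)
  structure(
    list(enzyme_conc_ug_ml = enzyme_conc_ug_ml,
         well_volume_ul = well_volume_ul,
         enzyme_mw = enzyme_mw,
         conversion_factor = conversion_factor),
    class = "assay_design"
  )
}

#' Convert an absorbance rate to molar NADH turnover
#'
#' `turnover = |rate| * conversion_factor`, mapping an A340 slope in mAU/min
#' to pmol/s of NADH consumed. The sign of the input is discarded: NADH
#' depletion gives negative slopes but turnover is reported nonnegative.
#'
#' @param rate_mau_per_min Absorbance rate(s), mAU/min (signed).
#' @param design An [assay_design()].
#' @return Turnover rate(s), pmol/s.
#' @export
#' @examples
#' absorbance_to_turnover(-2, assay_design()) # 2.222
absorbance_to_turnover <- function(rate_mau_per_min, design = assay_design()) {
  stopifnot(inherits(design, "assay_design"),
            all(is.finite(rate_mau_per_min)))
  abs(rate_mau_per_min) * design$conversion_factor
}

#' Extract the post-lag linear rate from an absorbance trace
#'
#' Coupled-assay traces begin with a lag while the intermediate (ammonia)
#' accumulates to steady state, then decline quasi-linearly until substrate
#' depletion bends the curve. The extractor scans window start points in
#' time order; the lag ends at the earliest start from which at least one
#' window of `min_points` or more samples achieves a linear fit with
#' `r.squared >= r2_min`. Among the windows anchored at that start, the
#' longest qualifying one is returned (slope, intercept, bounds, r-squared).
#' A constant (flat) window is treated as perfectly linear with slope 0.
#'
#' @param trace A kinetic trace: tibble/data frame with `time_s` and `a340`.
#' @param r2_min Linearity criterion (default 0.995).
#' @param min_points Minimum samples per window (default 10).
#' @return A one-row tibble: `slope_mau_per_min` (signed),
#'   `intercept_au` (fitted A340 at time 0), `lag_end_time_s`,
#'   `window_start_s`, `window_end_s`, `n_points`, `r_squared`.
#' @export
extract_linear_rate <- function(trace, r2_min = 0.995, min_points = 10L) {
  stopifnot(is.data.frame(trace),
            all(c("time_s", "a340") %in% names(trace)))
  t <- trace$time_s
  y <- trace$a340
  n <- length(t)
  min_points <- as.integer(min_points)
  if (n < min_points) {
    stop(sprintf("trace has %d samples; need at least %d", n, min_points),
         call. = FALSE)
  }
  if (is.unsorted(t, strictly = TRUE)) {
    stop("`time_s` must be strictly increasing", call. = FALSE)
  }
  best_r2_seen <- -Inf
  for (i in seq_len(n - min_points + 1L)) {
    tw <- t[i:n]
    yw <- y[i:n]
    m <- seq_along(tw)
    # running least-squares stats for windows [i, i + m - 1]
    sx <- cumsum(tw); sy <- cumsum(yw)
    sxx <- cumsum(tw^2); sxy <- cumsum(tw * yw); syy <- cumsum(yw^2)
    ssxx <- sxx - sx^2 / m
    ssyy <- syy - sy^2 / m
    ssxy <- sxy - sx * sy / m
    r2 <- ifelse(ssyy <= .Machine$double.eps * m,
                 1, ssxy^2 / pmax(ssxx * ssyy, .Machine$double.eps))
    ok <- which(m >= min_points & r2 >= r2_min)
    best_r2_seen <- max(best_r2_seen, max(r2[m >= min_points]))
    if (length(ok) > 0) {
      j <- max(ok)  # longest qualifying window at the earliest viable start
      slope <- if (ssyy[j] <= .Machine$double.eps * j) 0 else ssxy[j] / ssxx[j]
      intercept <- (sy[j] - slope * sx[j]) / j
      return(tibble::tibble(
        slope_mau_per_min = slope * 1000 * 60,  # AU/s -> mAU/min
        intercept_au = intercept,
        lag_end_time_s = t[i],
        window_start_s = t[i],
        window_end_s = t[i + j - 1L],
        n_points = j,
        r_squared = r2[j]
      ))
    }
  }
  stop(sprintf(
    "no window of >= %d samples reached r^2 >= %.4g (best seen %.4g); the trace may be too noisy or nonlinear",
    min_points, r2_min, best_r2_seen
  ), call. = FALSE)
}

#' Fit Michaelis-Menten kinetics to rate observations
#'
#' Nonlinear least squares of `v = Vmax * S / (Km + S)` (Levenberg-
#' Marquardt via [minpack.lm::nlsLM()]), initialized at
#' `Vmax0 = max(rate)` and `Km0 =` the substrate concentration at half of
#' `Vmax0`, interpolated from the sorted observations. Unweighted residuals;
#' standard errors are asymptotic. Observations that are all zero produce a
#' "not detectable" result (no parameters), mirroring how an unreactive
#' enzyme-substrate pair is reported.
#'
#' @param observations A data frame with columns `substrate_conc` (uM) and
#'   `rate` (pmol/s).
#' @return An object of class `mm_fit` with fields `status`
#'   (`"converged"` or `"not_detectable"`), `Vmax`, `Km`, their standard
#'   errors, the underlying `nls` object, and the data. Use [tidy()] /
#'   [glance()] or [derive_catalytic_constants()] on it.
#' @export
#' @examples
#' obs <- data.frame(substrate_conc = c(100, 200, 400, 800),
#'                   rate = 10 * c(100, 200, 400, 800) / (300 + c(100, 200, 400, 800)))
#' fit_michaelis_menten(obs)
fit_michaelis_menten <- function(observations) {
  stopifnot(is.data.frame(observations),
            all(c("substrate_conc", "rate") %in% names(observations)))
  obs <- tibble::as_tibble(observations) |>
    dplyr::filter(is.finite(.data$substrate_conc), is.finite(.data$rate))
  if (any(obs$substrate_conc < 0)) {
    stop("substrate concentrations must be nonnegative", call. = FALSE)
  }
  obs$rate <- abs(obs$rate)
  n_distinct_s <- dplyr::n_distinct(obs$substrate_conc[obs$substrate_conc > 0])
  if (n_distinct_s < 4L) {
    stop("need rate observations at >= 4 distinct nonzero substrate concentrations",
         call. = FALSE)
  }
  if (all(obs$rate <= .Machine$double.eps^0.5)) {
    return(structure(
      list(status = "not_detectable", Vmax = NA_real_, Km = NA_real_,
           Vmax_se = NA_real_, Km_se = NA_real_, kcat = NA_real_,
           efficiency = NA_real_, fit = NULL, data = obs),
      class = "mm_fit"
    ))
  }
  vmax0 <- max(obs$rate)
  # interpolate S at half-maximal rate from the concentration-sorted means
  prof <- obs |>
    dplyr::summarise(rate = mean(.data$rate), .by = "substrate_conc") |>
    dplyr::arrange(.data$substrate_conc)
  km0 <- tryCatch(
    stats::approx(prof$rate, prof$substrate_conc, xout = vmax0 / 2,
                  ties = mean)$y,
    error = function(e) NA_real_
  )
  if (!is.finite(km0) || km0 <= 0) {
    km0 <- stats::median(prof$substrate_conc[prof$substrate_conc > 0])
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rate ~ Vmax * substrate_conc / (Km + substrate_conc),
      data = obs,
      start = list(Vmax = vmax0, Km = km0),
      lower = c(Vmax = 0, Km = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      stop(sprintf("Michaelis-Menten fit failed: %s (starts Vmax=%.3g, Km=%.3g)",
                   conditionMessage(e), vmax0, km0), call. = FALSE)
    }
  )
  est <- stats::coef(fit)
  if (any(est <= 0)) {
    stop(sprintf("fit returned non-positive parameters (Vmax=%.3g, Km=%.3g)",
                 est["Vmax"], est["Km"]), call. = FALSE)
  }
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Vmax = NA_real_, Km = NA_real_))
  structure(
    list(status = "converged",
         Vmax = unname(est["Vmax"]), Km = unname(est["Km"]),
         Vmax_se = unname(se["Vmax"]), Km_se = unname(se["Km"]),
         kcat = NA_real_, efficiency = NA_real_,
         fit = fit, data = obs),
    class = "mm_fit"
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("<mm_fit>\n")
  if (x$status == "not_detectable") {
    cat("  activity not detectable (all rates zero)\n")
    return(invisible(x))
  }
  cat(sprintf("  Vmax = %.4g pmol/s (se %.3g)\n", x$Vmax, x$Vmax_se))
  cat(sprintf("  Km   = %.4g uM (se %.3g)\n", x$Km, x$Km_se))
  if (is.finite(x$kcat)) {
    cat(sprintf("  kcat = %.4g 1/s;  kcat/Km = %.4g 1/(M s)\n",
                x$kcat, x$efficiency))
  }
  invisible(x)
}

#' @method tidy mm_fit
#' @export
tidy.mm_fit <- function(x, ...) {
  if (x$status == "not_detectable") {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          std.error = numeric()))
  }
  tibble::tibble(
    term = c("Vmax", "Km"),
    estimate = c(x$Vmax, x$Km),
    std.error = c(x$Vmax_se, x$Km_se)
  )
}

#' @method glance mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  tibble::tibble(
    status = x$status,
    Vmax = x$Vmax, Km = x$Km,
    kcat = x$kcat, efficiency = x$efficiency,
    n_obs = nrow(x$data),
    sigma = if (!is.null(x$fit)) summary(x$fit)$sigma else NA_real_
  )
}

#' Predicted Michaelis-Menten rate at given substrate concentrations
#'
#' @param object An `mm_fit`.
#' @param newdata Optional data frame with `substrate_conc`; defaults to the
#'   fitted data.
#' @param ... Unused.
#' @return Numeric vector of predicted rates.
#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  if (object$status != "converged") {
    stop("cannot predict from a not-detectable fit", call. = FALSE)
  }
  s <- if (is.null(newdata)) object$data$substrate_conc else newdata$substrate_conc
  object$Vmax * s / (object$Km + s)
}

#' Catalytic efficiency kcat/Km
#'
#' @param kcat Turnover number, 1/s.
#' @param km_um Michaelis constant, uM.
#' @param sig_figs Significant figures for reporting (default 3).
#' @return kcat/Km in 1/(M s), rounded to `sig_figs` significant figures.
#' @export
#' @examples
#' catalytic_efficiency(1.39, 847) # 1640
catalytic_efficiency <- function(kcat, km_um, sig_figs = 3L) {
  stopifnot(all(kcat >= 0), all(km_um > 0))
  signif(kcat / (km_um * 1e-6), sig_figs)
}

#' Derive kcat and catalytic efficiency from a Michaelis-Menten fit
#'
#' `kcat = Vmax / n_enzyme`, where the moles of enzyme in the well follow
#' from the assay design (`enzyme_conc_ug_ml * well_volume_ul / enzyme_mw`);
#' the catalytic efficiency is `kcat / Km` in 1/(M s), reported at
#' `sig_figs` significant figures.
#'
#' @param fit A converged `mm_fit`.
#' @param design An [assay_design()] with a molecular weight.
#' @param sig_figs Significant figures for the efficiency (default 3).
#' @return The `mm_fit` with `kcat` (1/s) and `efficiency` (1/(M s)) filled
#'   in, plus `enzyme_pmol`.
#' @export
derive_catalytic_constants <- function(fit, design = assay_design(),
                                       sig_figs = 3L) {
  stopifnot(inherits(fit, "mm_fit"), inherits(design, "assay_design"))
  if (fit$status != "converged") {
    stop("catalytic constants require a converged fit", call. = FALSE)
  }
  if (is.null(design$enzyme_mw)) {
    stop("`design$enzyme_mw` is required to convert Vmax to kcat",
         call. = FALSE)
  }
  # ug/ml * ul = ng per well; ng / (g/mol) * 1e3 = pmol
  mass_ng <- design$enzyme_conc_ug_ml * design$well_volume_ul
  enzyme_pmol <- mass_ng / design$enzyme_mw * 1e3
  fit$enzyme_pmol <- enzyme_pmol
  fit$kcat <- fit$Vmax / enzyme_pmol
  fit$efficiency <- catalytic_efficiency(fit$kcat, fit$Km, sig_figs)
  fit
}

#' Run the trace-to-parameters kinetic analysis
#'
#' Convenience wrapper over the full kinetic path: extract the post-lag
#' linear rate from each trace, convert to pmol/s via the assay design, fit
#' Michaelis-Menten, and derive catalytic constants.
#'
#' With `depletion_correction = TRUE` (the default) each rate is paired with
#' the mean substrate concentration over its fit window rather than the
#' nominal starting concentration: the trace itself measures consumption,
#' since every mAU of A340 decline corresponds to
#' `conversion_factor * 60` pmol of NADH (and hence of substrate, 1:1
#' through ammonia). At low substrate a one-hour trace consumes an
#' appreciable fraction of the well, and the chord slope of the fit window
#' estimates the rate at the mid-window concentration, not the starting one;
#' the correction removes that bias from the Michaelis-Menten fit.
#'
#' @param traces A list of kinetic traces, each carrying a `substrate_conc`
#'   attribute (as produced by [simulate_kinetic_trace()]), or a tibble with
#'   list-column `trace` and column `substrate_conc`.
#' @param design An [assay_design()].
#' @param r2_min,min_points Passed to [extract_linear_rate()].
#' @param depletion_correction Fit against the mid-window (consumption-
#'   corrected) substrate concentration? Default `TRUE`.
#' @return An `mm_fit` with catalytic constants, carrying the per-trace rate
#'   table (nominal and effective concentrations, slopes, lag, r-squared) as
#'   the `rates` attribute.
#' @export
analyze_kinetics <- function(traces, design = assay_design(),
                             r2_min = 0.995, min_points = 10L,
                             depletion_correction = TRUE) {
  if (is.data.frame(traces)) {
    stopifnot(all(c("trace", "substrate_conc") %in% names(traces)))
    lst <- traces$trace
    concs <- traces$substrate_conc
  } else {
    lst <- traces
    concs <- vapply(traces, function(tr) {
      sc <- attr(tr, "substrate_conc")
      if (is.null(sc)) NA_real_ else sc
    }, numeric(1))
  }
  if (anyNA(concs)) {
    stop("every trace must carry a `substrate_conc` attribute", call. = FALSE)
  }
  # pmol of NADH per AU of absorbance change, from the instrument constant
  pmol_per_au <- design$conversion_factor * 60 * 1000
  rates <- purrr::map2_dfr(lst, concs, function(tr, sc) {
    win <- extract_linear_rate(tr, r2_min = r2_min, min_points = min_points)
    t_mid <- (win$window_start_s + win$window_end_s) / 2
    a_mid <- win$intercept_au + win$slope_mau_per_min / 60000 * t_mid
    consumed_um <- max(tr$a340[1] - a_mid, 0) * pmol_per_au /
      design$well_volume_ul
    tibble::tibble(
      substrate_conc = sc,
      substrate_conc_eff = max(sc - consumed_um, 0),
      slope_mau_per_min = win$slope_mau_per_min,
      rate = absorbance_to_turnover(win$slope_mau_per_min, design),
      lag_end_time_s = win$lag_end_time_s,
      window_end_s = win$window_end_s,
      r_squared = win$r_squared
    )
  })
  obs <- rates
  if (depletion_correction) obs$substrate_conc <- obs$substrate_conc_eff
  fit <- fit_michaelis_menten(obs[, c("substrate_conc", "rate")])
  if (fit$status == "converged" && !is.null(design$enzyme_mw)) {
    fit <- derive_catalytic_constants(fit, design)
  }
  attr(fit, "rates") <- rates
  fit
}
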