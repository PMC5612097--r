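#' Ground-truth peptide activity model for simulations
#'
#' Defines the latent enzyme specificity used by the array simulator.
#' Two modes are supported:
#'
#' * `"consensus-distance"`: each planted motif contributes
#'   `relative_activity * decay^h`, where `h` is the Hamming distance from
#'   the peptide to the motif; a peptide's activity is the baseline plus the
#'   maximum contribution over motifs. This emulates a recognition motif
#'   with graded tolerance to substitutions.
#' * `"position-weight"`: activity is the baseline plus the sum of
#'   per-position residue weights (`weights` is a position x residue matrix),
#'   floored at zero.
#'
#' Exact planted sequences always score their stated `relative_activity`
#' (plus baseline), so motif recovery is well-posed: with the default decay
#' the planted motifs sit far above the bulk of the library.
#'
#' @param mode `"consensus-distance"` (default) or `"position-weight"`.
#' @param planted_motifs A data frame with columns `sequence` and
#'   `relative_activity`, or a named numeric vector.
#' @param baseline_activity Nonnegative scalar added to every peptide.
#' @param decay Multiplicative activity retained per mismatch
#'   (consensus-distance mode), in (0, 1).
#' @param weights Position x residue numeric matrix (position-weight mode);
#'   column names are residue letters.
#' @return An object of class `activity_model`.
#' @export
#' @examples
#' m <- activity_model(planted_motifs = c(YRYRQ = 30000, RYRQR = 28000))
#' peptide_activity(m, c("YRYRQ", "YRYRA", "AGAGA"))
activity_model <- function(mode = c("consensus-distance", "position-weight"),
                           planted_motifs = NULL,
                           baseline_activity = 0,
                           decay = 0.25,
                           weights = NULL) {
  mode <- match.arg(mode)
  if (is.numeric(planted_motifs) && !is.null(names(planted_motifs))) {
    planted_motifs <- tibble::tibble(
      sequence = names(planted_motifs),
      relative_activity = unname(planted_motifs)
    )
  }
  if (!is.null(planted_motifs)) {
    stopifnot(is.data.frame(planted_motifs),
              all(c("sequence", "relative_activity") %in% names(planted_motifs)),
              all(planted_motifs$relative_activity >= 0))
    planted_motifs <- tibble::as_tibble(planted_motifs)
  }
  if (baseline_activity < 0) {
    stop("`baseline_activity` must be nonnegative", call. = FALSE)
  }
  if (mode == "consensus-distance") {
    if (is.null(planted_motifs) || nrow(planted_motifs) == 0) {
      stop("consensus-distance mode needs at least one planted motif",
           call. = FALSE)
    }
    if (!(decay > 0 && decay < 1)) {
      stop("`decay` must lie in (0, 1)", call. = FALSE)
    }
  } else {
    if (is.null(weights) || !is.matrix(weights) || is.null(colnames(weights))) {
      stop("position-weight mode needs a position x residue `weights` matrix",
           call. = FALSE)
    }
  }
  structure(
    list(mode = mode, planted_motifs = planted_motifs,
         baseline_activity = baseline_activity, decay = decay,
         weights = weights),
    class = "activity_model"
  )
}

#' Evaluate a ground-truth activity model on peptides
#'
#' @param model An [activity_model()].
#' @param peptides Character vector of peptide sequences (equal length in
#'   consensus-distance mode when compared with a motif of that length;
#'   peptides of a different length than a motif get no contribution from it).
#' @return Nonnegative numeric vector of activities, one per peptide.
#' @export
peptide_activity <- function(model, peptides) {
  stopifnot(inherits(model, "activity_model"), is.character(peptides))
  n <- length(peptides)
  act <- rep(model$baseline_activity, n)
  if (model$mode == "consensus-distance") {
    best <- rep(0, n)
    split_cache <- strsplit(peptides, "")
    for (i in seq_len(nrow(model$planted_motifs))) {
      motif <- model$planted_motifs$sequence[i]
      amp <- model$planted_motifs$relative_activity[i]
      mlen <- nchar(motif)
      mchars <- strsplit(motif, "")[[1]]
      same_len <- nchar(peptides) == mlen
      if (!any(same_len)) next
      h <- vapply(split_cache[same_len],
                  function(ch) sum(ch != mchars), numeric(1))
      contrib <- amp * model$decay^h
      best[same_len] <- pmax(best[same_len], contrib)
    }
    act <- act + best
  } else {
    w <- model$weights
    L <- nrow(w)
    ok <- nchar(peptides) == L
    score <- numeric(n)
    if (any(ok)) {
      mat <- do.call(rbind, strsplit(peptides[ok], ""))
      s <- numeric(sum(ok))
      for (pos in seq_len(L)) {
        idx <- match(mat[, pos], colnames(w))
        s <- s + ifelse(is.na(idx), 0, w[pos, idx])
      }
      score[ok] <- s
    }
    act <- pmax(act + score, 0)
  }
  # planted sequences score exactly their stated activity
  if (!is.null(model$planted_motifs) && nrow(model$planted_motifs) > 0) {
    hit <- match(peptides, model$planted_motifs$sequence)
    planted <- !is.na(hit)
    act[planted] <- model$baseline_activity +
      model$planted_motifs$relative_activity[hit[planted]]
  }
  act
}

#' Array simulation configuration
#'
#' Parameters of the fluorescence signal model for a duplicate-synthesized
#' peptide array. Per feature and replicate the simulated intensity is
#' `background + gain * activity * f(enzyme_conc) * noise`, where background
#' is a lognormal draw (positive, right-skewed, mean `background_mean`),
#' `f` is a linear enzyme-dose response saturating at `conc_ref`
#' (`f(c) = min(c / conc_ref, 1)`), and `noise` is multiplicative lognormal
#' with coefficient of variation `noise_cv`. A random subset of features
#' (fraction `imperfection_fraction`, chosen independently per replicate)
#' receives a surface-imperfection spike: the intensity is multiplied by a
#' uniform draw from `imperfection_scale`. Defaults mirror the published
#' array statistics: background around 180 fluorescence units and spikes on
#' about 1-3% of features.
#'
#' @param n_replicates On-array copies per peptide (default 2, duplicate
#'   synthesis).
#' @param background_mean,background_sd Background fluorescence mean and sd.
#' @param gain Fluorescence units per activity unit.
#' @param enzyme_conc Enzyme concentration in ng/ul.
#' @param conc_ref Concentration at which the dose response saturates
#'   (ng/ul).
#' @param noise_cv Coefficient of variation of the multiplicative signal
#'   noise.
#' @param imperfection_fraction Fraction of features spiked per replicate,
#'   in \[0, 1\].
#' @param imperfection_scale Length-2 numeric range of spike multipliers
#'   (uniform draw), or a single multiplier.
#' @param seed Integer seed.
#' @return An object of class `array_sim_config`.
#' @export
array_sim_config <- function(n_replicates = 2L,
                             background_mean = 180,
                             background_sd = 40,
                             gain = 1,
                             enzyme_conc = 0.1,
                             conc_ref = 0.1,
                             noise_cv = 0.15,
                             imperfection_fraction = 0.02,
                             imperfection_scale = c(5, 50),
                             seed = 1L) {
  if (imperfection_fraction < 0 || imperfection_fraction > 1) {
    stop("`imperfection_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (length(imperfection_scale) == 1L) {
    imperfection_scale <- rep(imperfection_scale, 2L)
  }
  stopifnot(
    n_replicates >= 1, background_mean > 0, background_sd >= 0, gain >= 0,
    enzyme_conc > 0, conc_ref > 0, noise_cv >= 0,
    length(imperfection_scale) == 2L, all(imperfection_scale > 0),
    imperfection_scale[1] <= imperfection_scale[2]
  )
  structure(
    list(n_replicates = as.integer(n_replicates),
         background_mean = background_mean, background_sd = background_sd,
         gain = gain, enzyme_conc = enzyme_conc, conc_ref = conc_ref,
         noise_cv = noise_cv,
         imperfection_fraction = imperfection_fraction,
         imperfection_scale = imperfection_scale,
         seed = as.integer(seed)),
    class = "array_sim_config"
  )
}

# lognormal parameterized by arithmetic mean and sd
rlnorm_mean_sd <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  sigma2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

# enzyme-dose response: linear in concentration, saturating at conc_ref
dose_response <- function(conc, conc_ref) {
  pmin(conc / conc_ref, 1)
}

#' Simulate fluorescence signals for a peptide array
#'
#' Produces one intensity per peptide and replicate under the signal model
#' described in [array_sim_config()], with ground-truth columns retained so
#' downstream filtering and ranking can be scored against the truth. Fully
#' reproducible from the config seed.
#'
#' @param peptides Peptide tibble (from the library designers) or character
#'   vector.
#' @param model An [activity_model()].
#' @param config An [array_sim_config()].
#' @return A signal table: tibble with columns `feature_id`, `peptide`,
#'   `replicate`, `intensity`, `true_activity`, `is_imperfection`.
#' @export
simulate_array <- function(peptides, model, config = array_sim_config()) {
  tbl <- as_peptide_tbl(peptides)
  stopifnot(inherits(model, "activity_model"),
            inherits(config, "array_sim_config"))
  if (nrow(tbl) == 0) stop("`peptides` is empty", call. = FALSE)
  n <- nrow(tbl)
  activity <- peptide_activity(model, tbl$peptide)
  f <- dose_response(config$enzyme_conc, config$conc_ref)
  set.seed(config$seed)
  reps <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    bg <- rlnorm_mean_sd(n, config$background_mean, config$background_sd)
    noise <- if (config$noise_cv > 0) {
      rlnorm_mean_sd(n, 1, config$noise_cv)
    } else rep(1, n)
    intensity <- bg + config$gain * activity * f * noise
    spiked <- stats::runif(n) < config$imperfection_fraction
    if (any(spiked)) {
      mult <- stats::runif(sum(spiked),
                           config$imperfection_scale[1],
                           config$imperfection_scale[2])
      intensity[spiked] <- intensity[spiked] * mult
    }
    reps[[r]] <- tibble::tibble(
      feature_id = sprintf("F%07d_R%d", tbl$peptide_id, r),
      peptide = tbl$peptide,
      replicate = r,
      intensity = intensity,
      true_activity = activity,
      is_imperfection = spiked
    )
  }
  out <- dplyr::bind_rows(reps)
  attr(out, "enzyme_conc") <- config$enzyme_conc
  out
}

#' Simulate the two-concentration array pair of a Lys-substrate screen
#'
#' Runs two array simulations that differ only in enzyme concentration (and
#' seed), emulating the screen where the same library is probed on two
#' independent arrays at a 10-fold enzyme dilution and per-array signals are
#' averaged after per-array filtering.
#'
#' @inheritParams simulate_array
#' @param concs Two enzyme concentrations in ng/ul (default `c(0.1, 0.01)`).
#' @param seeds Two integer seeds; default `config$seed` and
#'   `config$seed + 1`.
#' @return A named list of two signal tables (`high`, `low`) ordered as
#'   `concs`.
#' @export
simulate_concentration_pair <- function(peptides, model,
                                        config = array_sim_config(),
                                        concs = c(0.1, 0.01),
                                        seeds = NULL) {
  stopifnot(length(concs) == 2L, all(concs > 0))
  if (is.null(seeds)) seeds <- c(config$seed, config$seed + 1L)
  stopifnot(length(seeds) == 2L)
  make <- function(conc, seed) {
    cfg <- config
    cfg$enzyme_conc <- conc
    cfg$seed <- as.integer(seed)
    simulate_array(peptides, model, cfg)
  }
  list(high = make(concs[1], seeds[1]), low = make(concs[2], seeds[2]))
}

#' Parameters of a simulated GLDH-coupled transglutaminase assay
#'
#' The coupled assay reads transglutaminase turnover through ammonia:
#' deamidation of the Gln substrate releases ammonia, which glutamate
#' dehydrogenase (GLDH) consumes together with NADH in the reductive
#' amination of alpha-ketoglutarate; NADH depletion is recorded as the
#' absorbance at 340 nm. Until ammonia reaches its steady-state
#' concentration the absorbance trace shows a lag; afterwards it declines
#' linearly with slope proportional to the transglutaminase rate.
#'
#' @param Vmax_true True maximal rate, pmol/s (per well).
#' @param Km_true True Michaelis constant, uM.
#' @param substrate_concs Substrate concentrations for a titration, uM
#'   (default eight points spanning 0-1 mM).
#' @param gldh_rate_constant First-order rate constant of the coupling
#'   (reporter) reaction in ammonia, 1/s. Larger values shorten the lag.
#' @param nadh0 Initial NADH, uM (default 500).
#' @param trace_duration Trace length, s (default 3600 = 60 min).
#' @param sample_interval Sampling interval, s.
#' @param absorbance_per_nadh A340 units per uM NADH (path-length-dependent
#'   instrument constant; default 0.003).
#' @param noise_sd Additive absorbance measurement noise, AU.
#' @param well_volume_ul Reaction volume, ul (default 200); converts pmol/s
#'   to uM/s.
#' @param seed Integer seed for the measurement noise.
#' @return An object of class `coupled_assay_params`.
#' @export
coupled_assay_params <- function(Vmax_true = 37,
                                 Km_true = 847,
                                 substrate_concs = c(62.5, 125, 250, 375,
                                                     500, 625, 750, 1000),
                                 gldh_rate_constant = 0.05,
                                 nadh0 = 500,
                                 trace_duration = 3600,
                                 sample_interval = 15,
                                 absorbance_per_nadh = 0.003,
                                 noise_sd = 5e-4,
                                 well_volume_ul = 200,
                                 seed = 1L) {
  stopifnot(Vmax_true > 0, Km_true > 0, all(substrate_concs >= 0),
            gldh_rate_constant > 0, nadh0 > 0, trace_duration > 0,
            sample_interval > 0, absorbance_per_nadh > 0, noise_sd >= 0,
            well_volume_ul > 0)
  structure(
    list(Vmax_true = Vmax_true, Km_true = Km_true,
         substrate_concs = substrate_concs,
         gldh_rate_constant = gldh_rate_constant, nadh0 = nadh0,
         trace_duration = trace_duration, sample_interval = sample_interval,
         absorbance_per_nadh = absorbance_per_nadh, noise_sd = noise_sd,
         well_volume_ul = well_volume_ul, seed = as.integer(seed)),
    class = "coupled_assay_params"
  )
}

#' Simulate a GLDH-coupled absorbance trace
#'
#' Integrates the two-step coupled system with [deSolve::ode()]:
#' transglutaminase releases ammonia at the Michaelis-Menten rate
#' `Vmax * S / (Km + S)` (substrate depletion tracked), and GLDH consumes
#' ammonia and NADH first-order in ammonia with rate constant
#' `gldh_rate_constant` (NADH and alpha-ketoglutarate in excess; the
#' reporter reaction stops when NADH is exhausted). A340 is proportional to
#' the remaining NADH, plus additive Gaussian measurement noise. The trace
#' shows the characteristic lag (ammonia accumulating to steady state)
#' followed by a quasi-linear decline whose slope magnitude equals the
#' ammonia-release rate times `absorbance_per_nadh`.
#'
#' Mass balance holds exactly: NADH consumed equals cumulative ammonia
#' processed by GLDH at every time step.
#'
#' @param params A [coupled_assay_params()].
#' @param substrate_conc Substrate concentration for this trace, uM.
#' @return A tibble with columns `time_s` and `a340` and attributes
#'   `substrate_conc`, `truth` (noise-free state trajectory as a tibble with
#'   substrate, ammonia, NADH columns).
#' @export
simulate_kinetic_trace <- function(params, substrate_conc) {
  stopifnot(inherits(params, "coupled_assay_params"), substrate_conc >= 0)
  vmax_um_s <- params$Vmax_true / params$well_volume_ul  # pmol/s / ul = uM/s
  k <- params$gldh_rate_constant
  km <- params$Km_true
  deriv <- function(t, state, parms) {
    S <- max(state[["S"]], 0)
    N <- max(state[["N"]], 0)
    nadh <- max(state[["NADH"]], 0)
    v_tg <- vmax_um_s * S / (km + S)
    v_gldh <- if (nadh > 0) k * N else 0
    list(c(S = -v_tg, N = v_tg - v_gldh, NADH = -v_gldh, P = v_gldh))
  }
  times <- seq(0, params$trace_duration, by = params$sample_interval)
  sol <- deSolve::ode(
    y = c(S = substrate_conc, N = 0, NADH = params$nadh0, P = 0),
    times = times, func = deriv, parms = NULL,
    method = "lsoda", rtol = 1e-9, atol = 1e-9
  )
  sol <- as.data.frame(sol)
  if (any(sol$S < -1e-6) || any(sol$NADH < -1e-6)) {
    stop("integration produced negative concentrations; reduce the step size",
         call. = FALSE)
  }
  a340_clean <- params$absorbance_per_nadh * pmax(sol$NADH, 0)
  set.seed(params$seed + round(substrate_conc))
  noise <- if (params$noise_sd > 0) {
    stats::rnorm(length(a340_clean), 0, params$noise_sd)
  } else 0
  out <- tibble::tibble(time_s = sol$time, a340 = a340_clean + noise)
  attr(out, "substrate_conc") <- substrate_conc
  attr(out, "truth") <- tibble::tibble(
    time_s = sol$time, substrate = sol$S, ammonia = sol$N,
    nadh = sol$NADH, ammonia_processed = sol$P
  )
  out
}
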