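test_that("activity model scores planted motifs above the library bulk", {
  m <- activity_model(planted_motifs = c(YRYRQ = 30000, RYRQR = 27000))
  act <- peptide_activity(m, c("YRYRQ", "RYRQR", "YRYRA", "AGAGA"))
  expect_equal(act[1], 30000)
  expect_equal(act[2], 27000)
  expect_equal(act[3], 30000 * 0.25)       # one mismatch from YRYRQ
  expect_equal(act[4], 30000 * 0.25^5)     # five mismatches: negligible

  # planted motifs sit above the 99.9th percentile of non-planted activities
  lib <- enumerate_library(tiny_library_spec())
  sub <- sample_sublibrary(lib, 20000, seed = 3,
                           include = c("YRYRQ", "RYRQR"))
  a <- peptide_activity(m, sub$peptide)
  non_planted <- a[!sub$peptide %in% c("YRYRQ", "RYRQR")]
  expect_gt(min(30000, 27000), stats::quantile(non_planted, 0.999))
})

test_that("position-weight mode sums per-position weights and floors at zero", {
  w <- matrix(0, nrow = 3, ncol = 3, dimnames = list(NULL, c("A", "G", "Q")))
  w[1, "A"] <- 5; w[2, "G"] <- 3; w[3, "Q"] <- -10
  m <- activity_model(mode = "position-weight", weights = w,
                      baseline_activity = 1)
  expect_equal(peptide_activity(m, "AGA"), 1 + 5 + 3)
  expect_equal(peptide_activity(m, "AGQ"), 0)  # floored
})

test_that("array simulation reproduces the background level and is seed-exact", {
  peps <- paste0(sample(tiny_alphabet, 500, replace = TRUE),
                 "GQRA")  # any sequences; activity irrelevant at gain 0
  cfg <- array_sim_config(gain = 0, noise_cv = 0, imperfection_fraction = 0,
                          background_sd = 40, seed = 9)
  tbl <- simulate_array(unique(peps), activity_model(
    planted_motifs = c(YRYRQ = 1)), cfg)
  expect_equal(mean(tbl$intensity), 180, tolerance = 0.05)
  expect_true(all(tbl$intensity > 0))

  # determinism
  tbl2 <- simulate_array(unique(peps), activity_model(
    planted_motifs = c(YRYRQ = 1)), cfg)
  expect_identical(tbl, tbl2)

  # each peptide appears exactly once per replicate
  counts <- dplyr::count(tbl, peptide, replicate)
  expect_true(all(counts$n == 1))
})

test_that("imperfection flags follow the configured per-replicate fraction", {
  lib <- enumerate_library(tiny_library_spec())
  sub <- sample_sublibrary(lib, 20000, seed = 5)
  cfg <- array_sim_config(imperfection_fraction = 0.02, seed = 21)
  tbl <- simulate_array(sub, activity_model(planted_motifs = c(YRYRQ = 100)),
                        cfg)
  per_rep <- tapply(tbl$is_imperfection, tbl$replicate, sum)
  expected <- 0.02 * 20000
  sigma <- sqrt(20000 * 0.02 * 0.98)
  expect_true(all(abs(per_rep - expected) < 3 * sigma))
})

test_that("expected intensity is monotone in activity and enzyme concentration", {
  m <- activity_model(planted_motifs = c(YRYRQ = 10000), decay = 0.25)
  peps <- c("YRYRQ", "YRYRA", "AGSEA")  # descending activity
  base <- array_sim_config(noise_cv = 0, background_sd = 0,
                           imperfection_fraction = 0, seed = 1)
  tbl <- simulate_array(peps, m, base)
  means <- tapply(tbl$intensity, tbl$peptide, mean)
  expect_gt(means[["YRYRQ"]], means[["YRYRA"]])
  expect_gt(means[["YRYRA"]], means[["AGSEA"]])

  low <- base; low$enzyme_conc <- 0.01
  tbl_low <- simulate_array(peps, m, low)
  expect_true(all(tbl$intensity >= tbl_low$intensity))
})

test_that("concentration pairs differ only as configured", {
  peps <- sample_sublibrary(enumerate_library(tiny_library_spec()), 2000,
                            seed = 4, include = "RYESK")
  m <- activity_model(planted_motifs = c(RYESK = 20000))
  cfg <- array_sim_config(seed = 4)
  same <- simulate_concentration_pair(peps, m, cfg, concs = c(0.1, 0.1),
                                      seeds = c(4, 4))
  expect_identical(same$high, same$low)

  # monotonicity of the signal model itself, with spike noise off so a
  # surface imperfection cannot mask the dose response
  cfg_clean <- array_sim_config(imperfection_fraction = 0, seed = 4)
  pair <- simulate_concentration_pair(peps, m, cfg_clean, concs = c(0.1, 0.01))
  motif_mean <- function(tbl) mean(tbl$intensity[tbl$peptide == "RYESK"])
  expect_gt(motif_mean(pair$high), motif_mean(pair$low))
})

test_that("kinetic traces conserve mass and show lag then linear decline", {
  params <- coupled_assay_params(noise_sd = 0, seed = 1)
  tr <- simulate_kinetic_trace(params, 500)
  truth <- attr(tr, "truth")
  # NADH consumed equals cumulative ammonia processed at every step
  expect_equal(params$nadh0 - truth$nadh, truth$ammonia_processed,
               tolerance = 1e-8)
  expect_true(all(diff(tr$time_s) > 0))
  expect_true(all(tr$a340 >= 0))

  # zero substrate: flat trace
  flat <- simulate_kinetic_trace(params, 0)
  expect_lt(max(abs(diff(flat$a340))), 1e-9)

  # post-lag slope magnitude equals the ammonia-release rate x conversion
  fast <- coupled_assay_params(noise_sd = 0, gldh_rate_constant = 1,
                               trace_duration = 300, sample_interval = 1,
                               seed = 1)
  trf <- simulate_kinetic_trace(fast, 50000)  # S >> Km
  w <- extract_linear_rate(trf)
  expected_slope <- -fast$Vmax_true / fast$well_volume_ul *
    50000 / (fast$Km_true + 50000) * fast$absorbance_per_nadh * 60000
  expect_equal(w$slope_mau_per_min, expected_slope, tolerance = 0.01)
})
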