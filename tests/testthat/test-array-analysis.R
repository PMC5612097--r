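test_that("concordance statistic matches the printed formula and its symmetries", {
  expect_equal(concordance_statistic(100, 200), 1 / 3)
  expect_equal(concordance_statistic(120, 80), 0.2)
  expect_equal(concordance_statistic(100, 100), 0)
  expect_true(is.na(concordance_statistic(0, 0)))
  # symmetric and scale invariant
  s1 <- c(10, 250, 31); s2 <- c(55, 12, 31)
  expect_equal(concordance_statistic(s1, s2), concordance_statistic(s2, s1))
  expect_equal(concordance_statistic(7 * s1, 7 * s2),
               concordance_statistic(s1, s2))
})

test_that("the filter excludes discordant pairs, keeps the boundary, drops zeros", {
  tbl <- signal_table_from_pairs(
    peptide = c("AAAAA", "CCCCC", "DDDDD", "EEEEE"),
    s1 = c(100, 100, 120, 0),
    s2 = c(100, 200, 80, 0)
  )
  out <- concordance_filter(tbl)
  kept <- unique(out$peptide)
  expect_setequal(kept, c("AAAAA", "DDDDD"))  # 1/3 excluded; 0.2 retained
  excl <- attr(out, "exclusions")
  expect_setequal(excl$peptide, c("CCCCC", "EEEEE"))
  expect_equal(excl$reason[excl$peptide == "EEEEE"], "zero_signal")
  expect_equal(excl$statistic[excl$peptide == "CCCCC"], 1 / 3)

  # equal positive replicates are never removed
  eq <- signal_table_from_pairs(paste0("P", 1:50), 1:50 * 10, 1:50 * 10)
  expect_equal(nrow(concordance_filter(eq)), nrow(eq))

  # missing replicate is a validation error naming the peptide
  broken <- tbl[-1, ]
  expect_error(concordance_filter(broken), "AAAAA")
})

test_that("the filter removes >= 95% of spike-affected peptides on a simulated array", {
  lib <- enumerate_library(tiny_library_spec())
  sub <- sample_sublibrary(lib, 20000, seed = 8)
  cfg <- array_sim_config(imperfection_fraction = 0.02, seed = 8)
  tbl <- simulate_array(sub, activity_model(planted_motifs = c(YRYRQ = 30000)),
                        cfg)
  spiked <- unique(tbl$peptide[tbl$is_imperfection])
  out <- concordance_filter(tbl)
  removed <- setdiff(spiked, unique(out$peptide))
  expect_gte(length(removed) / length(spiked), 0.95)
})

test_that("ranking averages replicates, breaks ties deterministically, flags top-k", {
  one <- signal_table_from_pairs("AAAAA", 10, 20)
  prof <- rank_peptides(one, k = 1)
  expect_equal(prof$mean_intensity, 15)
  expect_equal(prof$rank, 1)

  # ties broken lexicographically; permuting rows changes nothing
  tied <- signal_table_from_pairs(c("BBBBB", "AAAAA", "CCCCC"),
                                  c(50, 50, 80), c(50, 50, 80))
  p1 <- rank_peptides(tied, k = 2)
  p2 <- rank_peptides(tied[sample(nrow(tied)), ], k = 2)
  expect_equal(p1$peptide, c("CCCCC", "AAAAA", "BBBBB"))
  expect_equal(p1, p2, ignore_attr = TRUE)

  expect_error(rank_peptides(tied, k = 10), "exceeds")
})

test_that("planted motifs are recovered in the top-22 of a filtered simulated array", {
  lib <- enumerate_library(tiny_library_spec())
  sub <- sample_sublibrary(lib, 20000, seed = 1,
                           include = c("YRYRQ", "RYRQR"))
  tbl <- simulate_array(sub,
                        activity_model(planted_motifs = c(YRYRQ = 30000,
                                                          RYRQR = 27000)),
                        array_sim_config(seed = 1))
  prof <- rank_peptides(concordance_filter(tbl), k = 22)
  expect_true(all(c("YRYRQ", "RYRQR") %in% prof$peptide[prof$top_k]))
})

test_that("self cross-reactivity puts top peptides at the top of the distribution", {
  lib <- enumerate_library(tiny_library_spec())
  sub <- sample_sublibrary(lib, 5000, seed = 2, include = "YRYRQ")
  tbl <- concordance_filter(simulate_array(
    sub, activity_model(planted_motifs = c(YRYRQ = 20000)),
    array_sim_config(seed = 2)
  ))
  prof <- rank_peptides(tbl, k = 22)
  rep_self <- cross_reactivity(prof, tbl)
  n <- glance(rep_self)$n_b
  expect_true(all(tidy(rep_self)$percentile >= 100 * (1 - 22 / n)))
})

test_that("independent random intensities put top peptides near the median", {
  lib <- enumerate_library(tiny_library_spec())
  sub <- sample_sublibrary(lib, 5000, seed = 3, include = "YRYRQ")
  prof <- rank_peptides(concordance_filter(simulate_array(
    sub, activity_model(planted_motifs = c(YRYRQ = 20000)),
    array_sim_config(seed = 3)
  )), k = 22)
  meds <- vapply(1:8, function(s) {
    # enzyme B sees no signal at all: pure background, independent of A
    tbl_b <- concordance_filter(simulate_array(
      sub, activity_model(planted_motifs = c(YRYRQ = 20000)),
      array_sim_config(gain = 0, seed = 100 + s)
    ))
    glance(cross_reactivity(prof, tbl_b))$median_percentile
  }, numeric(1))
  # each median of ~22 uniform percentiles has sd ~ 10; the 8-seed mean has
  # sd ~ 3.6, so 12 is a ~3.3 sigma Monte-Carlo band around the null 50
  expect_lt(abs(mean(meds) - 50), 12)
})

test_that("orthogonal enzymes leave each other's top substrates out of the extreme tail", {
  lib <- enumerate_library(tiny_library_spec())
  sub <- sample_sublibrary(lib, 5000, seed = 4,
                           include = c("YRYRQ", "GESKA"))
  prof_a <- rank_peptides(concordance_filter(simulate_array(
    sub, activity_model(planted_motifs = c(YRYRQ = 20000)),
    array_sim_config(seed = 4)
  )), k = 22)
  tbl_b <- concordance_filter(simulate_array(
    sub, activity_model(planted_motifs = c(GESKA = 20000)),
    array_sim_config(seed = 5)
  ))
  rep <- cross_reactivity(prof_a, tbl_b)
  expect_lt(glance(rep)$median_percentile, 90)
  # a peptide absent from B is reported missing, not dropped; compare
  # against the unfiltered table so only the alien sequence is absent
  tbl_b_raw <- simulate_array(
    sub, activity_model(planted_motifs = c(GESKA = 20000)),
    array_sim_config(seed = 5)
  )
  prof_x <- prof_a
  prof_x$peptide[1] <- "ZZZZZ"
  rep_x <- cross_reactivity(prof_x, tbl_b_raw)
  expect_equal(glance(rep_x)$n_missing, 1)
  expect_true(tidy(rep_x)$missing[tidy(rep_x)$peptide == "ZZZZZ"])
})

test_that("positional enrichment recovers the planted consensus and degenerate cases", {
  lib <- enumerate_library(tiny_library_spec())
  # top-k identical to background: enrichment ~ 0 everywhere
  bg <- sample_sublibrary(lib, 400, seed = 6)
  prof0 <- tibble::tibble(peptide = bg$peptide,
                          top_k = TRUE)
  enr0 <- positional_enrichment(prof0, bg)
  expect_lt(max(abs(enr0$enrichment_log2)), 1e-12)

  # single-sequence top-k: position-5 Q is the column maximum
  prof1 <- tibble::tibble(peptide = c("YRYRQ", bg$peptide),
                          top_k = c(TRUE, rep(FALSE, nrow(bg))))
  enr1 <- positional_enrichment(prof1, bg)
  col5 <- enr1[enr1$position == 5, ]
  expect_equal(col5$residue[which.max(col5$enrichment_log2)], "Q")

  # planted-motif simulation: consensus of per-position maxima is the motif
  sub <- sample_sublibrary(lib, 10000, seed = 6, include = "YRYRQ")
  prof <- rank_peptides(concordance_filter(simulate_array(
    sub, activity_model(planted_motifs = c(YRYRQ = 30000), decay = 0.35),
    array_sim_config(seed = 6)
  )), k = 22)
  enr <- positional_enrichment(prof, sub)
  expect_equal(attr(enr, "consensus"), "YRYRQ")
})

test_that("pair averaging filters per array and keeps the common survivors", {
  pair <- list(
    signal_table_from_pairs(c("AAAAA", "CCCCC", "DDDDD"),
                            c(100, 100, 500), c(100, 300, 500)),
    signal_table_from_pairs(c("AAAAA", "CCCCC", "DDDDD"),
                            c(90, 100, 900), c(90, 100, 200))
  )
  avg <- average_concentration_pair(pair)
  # CCCCC discordant on array 1, DDDDD discordant on array 2
  expect_setequal(unique(avg$peptide), "AAAAA")
  expect_equal(sort(avg$intensity), c(90, 100))
})
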