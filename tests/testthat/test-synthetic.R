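test_that("simulators are deterministic given their seed", {
  model <- migration_model()
  lad <- builtin_ladder("quickload-1kb-extend")
  n <- noise_spec(baseline = 200, sd = 8, seed = 42)
  l1 <- simulate_ladder_lane(lad, model, n, seed_jitter = 5)
  l2 <- simulate_ladder_lane(lad, model, n, seed_jitter = 5)
  expect_identical(l1$profile$intensity, l2$profile$intensity)
  expect_identical(l1$seeds, l2$seeds)

  s1 <- simulate_smear_lane(smear_spec(), model, n)
  s2 <- simulate_smear_lane(smear_spec(), model, n)
  expect_identical(s1$profile$intensity, s2$profile$intensity)

  c1 <- simulate_cohort(cohort_design(seed = 7))
  c2 <- simulate_cohort(cohort_design(seed = 7))
  expect_identical(c1$cohort, c2$cohort)
  expect_identical(c1$truth$r2_map, c2$truth$r2_map)
})

test_that("migration model inverts exactly and rejects bad geometry", {
  for (kappa in c(0, 3, 8)) {
    m <- migration_model(kappa = kappa)
    L <- c(48.5, 20, 9, 5, 2, 0.7)
    expect_equal(model_size_of(m, model_row_of(m, L)), L,
                 tolerance = 1e-12)
    expect_true(all(diff(model_row_of(m, sort(L, decreasing = TRUE))) > 0))
  }
  expect_error(migration_model(s = 10, kappa = -2), "not strictly")
})

test_that("noiseless ladder closure: calibration recovers every band", {
  model <- migration_model()   # kappa = 0: exactly one log2-linear segment
  lad <- builtin_ladder("quickload-1kb-extend")
  sim <- simulate_ladder_lane(lad, model, noise_spec())
  pk <- refine_peaks(sim$profile, sim$seeds)
  sc <- build_scale(pk, lad)
  # refined integer rows differ from the exact band rows by < 1 px, so
  # recovery is pixel-limited here (exact-line recovery to 1e-9 is checked
  # on the analytic two-line fixture); each band within half a pixel's size
  px_rel <- abs(sc$b_lo) * log(2)
  rec <- size_at(sc, model_row_of(model, lad$sizes_kb))
  expect_lt(max(abs(rec - lad$sizes_kb) / lad$sizes_kb), px_rel)
  expect_gte(sc$switch_size_kb, 8)
  expect_lte(sc$switch_size_kb, 10)
})

test_that("curvature makes one segment insufficient: two-segment RSS wins", {
  model <- migration_model(kappa = 8)
  lad <- builtin_ladder("quickload-1kb-extend")
  sim <- simulate_ladder_lane(lad, model, noise_spec())
  pk <- refine_peaks(sim$profile, sim$seeds)$peaks
  fit_rss <- function(sizes) {
    sub <- pk[pk$size_kb %in% sizes, ]
    sum(residuals(lm(log2(size_kb) ~ refined_row, sub))^2)
  }
  single <- fit_rss(c(lad$hi_fit_kb, lad$lo_fit_kb))
  two_seg <- fit_rss(lad$hi_fit_kb) + fit_rss(lad$lo_fit_kb)
  expect_gt(single, two_seg)
})

test_that("full-pipeline closure reproduces analytic truth to 0.5%", {
  # noiseless, kappa = 0, high-resolution scan so that pixel quantization
  # of the step quantiles sits below the tolerance being verified
  model <- migration_model(s = 320)
  lad <- builtin_ladder("quickload-1kb-extend")
  lanes <- list(
    list(type = "ladder", id = "L1", ladder = lad, role = "ladder-left"),
    list(type = "smear", id = "S1", smear = smear_spec(meanlog = log(5)),
         probe = "host"),
    list(type = "smear", id = "S2", smear = smear_spec(meanlog = log(7),
                                                      sdlog = 0.25),
         probe = "symbiont"),
    list(type = "ladder", id = "L2", ladder = lad, role = "ladder-right"))
  mem <- render_membrane(lanes, model, noise_spec())
  profs <- lapply(mem$rois, function(r) extract_profile(mem$image, r))
  names(profs) <- vapply(profs, `[[`, character(1), "lane_id")
  pk <- refine_peaks(profs$L1, mem$seeds[mem$seeds$lane_id == "L1", ])
  sc <- build_scale(pk, lad)
  for (id in c("S1", "S2")) {
    s <- quantify_lane(profs[[id]], sc)
    tr <- mem$truth[[id]]
    for (f in c("mean_kb", "med_kb", "q1_kb", "q3_kb", "iq_kb"))
      expect_lt(abs(s[[f]] - tr[[f]]) / tr[[f]], 0.005)
  }
})

test_that("rendered lanes match their 1-D profiles and stay in range", {
  model <- migration_model()
  lad <- builtin_ladder("quickload-1kb-extend")
  noise <- noise_spec(baseline = 200, sd = 8, seed = 5)
  lanes <- list(
    list(type = "ladder", id = "L1", ladder = lad, role = "ladder-left"),
    list(type = "smear", id = "S1", smear = smear_spec(), probe = "host"))
  mem <- render_membrane(lanes, model, noise)
  expect_lte(max(mem$image$data), 65535)
  for (i in 1:2) {
    roi <- mem$rois[[i]]
    extracted <- extract_profile(mem$image, roi)
    # regenerate the 1-D truth with the same derived per-lane seed
    lane_noise <- noise_spec(200, 8, noise$seed + 97L * i)
    truth <- if (i == 1)
      simulate_ladder_lane(lad, model, lane_noise, lane_id = "L1")$profile
    else
      simulate_smear_lane(smear_spec(), model, lane_noise,
                          lane_id = "S1")$profile
    expect_lt(abs(sum(extracted$intensity) - sum(truth$intensity)) /
                sum(truth$intensity), 0.01)
  }
})

test_that("probe bias and size normalization are mutually consistent", {
  model <- migration_model(s = 320)
  sc <- exact_scale(model)
  overest <- logical(0)
  for (seed in 1:8) {
    noise <- noise_spec(baseline = 200, sd = 4, seed = seed)
    lane <- simulate_smear_lane(smear_spec(probe_bias = TRUE), model, noise)
    # bias on + normalization on: recovers the unbiased truth
    s_on <- quantify_lane(lane$profile, sc)
    expect_lt(abs(s_on$mean_kb - lane$truth$mean_kb) / lane$truth$mean_kb,
              0.05)
    # bias on + normalization off: overestimates mean TL on every replicate
    bg <- subtract_background(lane$profile)
    d <- truncate_low(profile_to_distribution(bg, sc))
    raw_mean <- sum(d$table$raw * d$table$size_kb) / sum(d$table$raw)
    overest <- c(overest, raw_mean > lane$truth$mean_kb)

    # bias off but normalization still applied: biased low (amplitude
    # raised so the unbiased lane has gain comparable to the biased one)
    lane_nb <- simulate_smear_lane(smear_spec(probe_bias = FALSE,
                                              amplitude = 2e5), model,
                                   noise)
    s_nb <- quantify_lane(lane_nb$profile, sc)
    expect_lt(s_nb$mean_kb, lane_nb$truth$mean_kb)
  }
  expect_true(all(overest))
})

test_that("simulated cohorts carry realized variance truth", {
  # island-only signal, no noise: island explains everything
  d0 <- cohort_design(n_islands = 6, colonies_per_island = 20,
                      island_sd = 0.4, community_sd = 0,
                      diameter_slope = 0, residual_sd = 0, seed = 3)
  sim0 <- simulate_cohort(d0)
  agg <- tapply(log(sim0$cohort$htl_mean_kb), sim0$cohort$island,
                function(v) diff(range(v)))
  expect_true(all(agg < 1e-12))       # constant within island
  expect_equal(sim0$truth$r2_full, 1, tolerance = 1e-10)

  r2 <- suppressWarnings(       # noise-free fits are "essentially perfect"
    all_subsets_r2(log(sim0$cohort$htl_mean_kb),
                   list(island = sim0$cohort$island,
                        community = sim0$cohort$symbiodiniaceae_profile,
                        diameter = sim0$cohort$diameter_cm)))
  cm <- commonality(r2)
  expect_lt(abs(cm$table$coefficient[cm$table$subset == "community"]),
            0.02)

  # designed fractions reappear in the realized truth, up to the sampling
  # variability of 30 realized island effects (sd of the variance-
  # fraction estimate ~ 0.065, so 3 sd ~ 0.2)
  d1 <- cohort_design(seed = 11)      # island 50%, community 10%, resid 40%
  sim1 <- simulate_cohort(d1)
  expect_lt(abs(sim1$truth$unique_fraction[["island"]] - 0.5), 0.2)
  expect_lt(abs(sim1$truth$residual_fraction - 0.4), 0.2)
})
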