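with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Electrophoretic migration model
#'
#' Forward model mapping fragment size to migration row:
#' `row(L) = r0 + s*u + kappa*u^2` with `u = log2(Lmax) - log2(L)`. With
#' `kappa = 0` migration is exactly log2-linear (one straight calibration
#' line); `kappa > 0` compresses the high-molecular-weight region, the
#' situation the two-segment calibration approximates.
#'
#' @param r0 row of the largest size `Lmax` (pixels).
#' @param s stretch, rows per log2-kb.
#' @param kappa curvature, rows per (log2-kb)^2.
#' @param Lmax,Lmin valid size range (kb), `Lmax > Lmin > 0`.
#' @return A `migration_model` with helpers accessible via
#'   [model_row_of()] and [model_size_of()].
#' @export
migration_model <- function(r0 = 40, s = 160, kappa = 0, Lmax = 60,
                            Lmin = 0.5) {
  stopifnot(Lmax > Lmin, Lmin > 0, s > 0)
  u_max <- log2(Lmax / Lmin)
  if (s + 2 * kappa * u_max <= 0 || s + 2 * kappa * 0 <= 0)
    stop("migration model is not strictly increasing over the size range")
  structure(list(r0 = r0, s = s, kappa = kappa, Lmax = Lmax, Lmin = Lmin,
                 u_max = u_max),
            class = "migration_model")
}

#' @rdname migration_model
#' @param model a `migration_model`.
#' @param size_kb fragment size(s) in kb.
#' @export
model_row_of <- function(model, size_kb) {
  u <- log2(model$Lmax) - log2(size_kb)
  model$r0 + model$s * u + model$kappa * u^2
}

#' @rdname migration_model
#' @param row pixel row(s).
#' @export
model_size_of <- function(model, row) {
  # invert r = r0 + s*u + kappa*u^2 for u >= 0
  if (model$kappa == 0) {
    u <- (row - model$r0) / model$s
  } else {
    u <- (-model$s + sqrt(model$s^2 + 4 * model$kappa * (row - model$r0))) /
      (2 * model$kappa)
  }
  2^(log2(model$Lmax) - u)
}

model_n_rows <- function(model) as.integer(ceiling(model_row_of(model, model$Lmin)) + 20L)

#' Noise specification for simulated lanes
#'
#' @param baseline constant intensity offset added to every pixel.
#' @param sd standard deviation of additive Gaussian noise (counts).
#' @param seed RNG seed, or `NULL` to use the current RNG state.
#' @return A `noise_spec`.
#' @export
noise_spec <- function(baseline = 0, sd = 0, seed = NULL) {
  stopifnot(sd >= 0, baseline >= 0)
  structure(list(baseline = baseline, sd = sd, seed = seed),
            class = "noise_spec")
}

apply_noise <- function(signal, noise) {
  out <- with_seed(noise$seed,
                   signal + noise$baseline + stats::rnorm(length(signal),
                                                          0, noise$sd))
  pmax(out, 0)  # physical counts cannot go negative
}

#' Simulate a ladder lane
#'
#' Renders each ladder band as a Gaussian bump of width `band_sd` centered
#' at the model's row for that size, plus baseline and noise, and returns
#' the exact peak rows for seeding. `seed_jitter` offsets the returned
#' seed rows by up to that many pixels (uniform integer), emulating
#' imprecise manual peak reporting; keep it at or below the refinement
#' window so peaks remain identifiable.
#'
#' @param ladder a [ladder_spec()].
#' @param model a [migration_model()].
#' @param noise a [noise_spec()].
#' @param band_sd Gaussian band width in pixels.
#' @param amplitude peak intensity of each band.
#' @param seed_jitter max absolute seed offset in pixels (default 0).
#' @param lane_id,role,membrane_id lane annotations.
#' @return List with `profile` ([lane_profile()]), `seeds` (data frame
#'   `size_kb, seed_row`) and `true_rows` (exact rounded peak rows).
#' @export
simulate_ladder_lane <- function(ladder, model, noise = noise_spec(),
                                 band_sd = 4, amplitude = 20000,
                                 seed_jitter = 0, lane_id = "ladder",
                                 role = "ladder-left",
                                 membrane_id = "membrane") {
  stopifnot(inherits(ladder, "ladder_spec"), inherits(model, "migration_model"))
  sizes <- ladder$sizes_kb
  if (any(sizes > model$Lmax | sizes < model$Lmin))
    stop("ladder bands outside the migration model's size range")
  rows <- 0:(model_n_rows(model) - 1L)
  centers <- model_row_of(model, sizes)
  if (any(diff(sort(centers)) < 2 * band_sd))
    warning("adjacent ladder bands closer than twice the band width; ",
            "peaks may not be resolvable")
  sig <- rowSums(vapply(centers, function(c0)
    amplitude * exp(-(rows - c0)^2 / (2 * band_sd^2)), numeric(length(rows))))
  profile <- lane_profile(lane_id, rows, apply_noise(sig, noise),
                          role = role, probe = "none",
                          membrane_id = membrane_id)
  true_rows <- as.integer(round(centers))
  jit <- if (seed_jitter > 0)
    with_seed(if (is.null(noise$seed)) NULL else noise$seed + 1L,
              sample(-seed_jitter:seed_jitter, length(sizes),
                     replace = TRUE))
  else rep(0L, length(sizes))
  list(profile = profile,
       seeds = data.frame(size_kb = sizes,
                          seed_row = pmax(0L, pmin(max(rows),
                                                   true_rows + jit))),
       true_rows = true_rows)
}

#' Telomere smear specification
#'
#' The fragment-length distribution of a telomere smear, by default
#' lognormal on the kb scale (right-skewed, positive, closed-form
#' moments). With `probe_bias = TRUE` the rendered signal density is
#' proportional to `L * g(L)` — longer fragments hybridize proportionally
#' more probe — which is exactly the bias [normalize_by_size()] removes.
#'
#' @param meanlog,sdlog lognormal parameters on ln-kb (default median
#'   5 kb, sdlog 0.3).
#' @param amplitude overall signal amplitude (counts).
#' @param probe_bias logical, default `TRUE`.
#' @param density optional custom density over size kb replacing the
#'   lognormal.
#' @return A `smear_spec`.
#' @export
smear_spec <- function(meanlog = log(5), sdlog = 0.3, amplitude = 4e4,
                       probe_bias = TRUE, density = NULL) {
  stopifnot(sdlog > 0, amplitude > 0)
  g <- if (is.null(density))
    function(L) stats::dlnorm(L, meanlog, sdlog) else density
  structure(list(meanlog = meanlog, sdlog = sdlog, amplitude = amplitude,
                 probe_bias = probe_bias, g = g),
            class = "smear_spec")
}

#' Ground-truth summary of a smear distribution
#'
#' Numeric-integration oracle: mean and step-free quantiles of the
#' fragment-length density truncated to `[min_kb, Lmax]`, the same
#' truncation the quantification pipeline applies, so recovery tests
#' compare like with like.
#'
#' @param smear a [smear_spec()].
#' @param model a [migration_model()] (provides the size range).
#' @param min_kb lower truncation (default 2 kb).
#' @return List `mean_kb, med_kb, q1_kb, q3_kb, iq_kb`.
#' @export
smear_truth <- function(smear, model, min_kb = 2.0) {
  lo <- min_kb; hi <- model$Lmax
  # anchor the adaptive quadrature at the distribution's bulk so that very
  # narrow smears are never stepped over
  anchors <- stats::qlnorm(c(0.001, 0.25, 0.5, 0.75, 0.999),
                           smear$meanlog, smear$sdlog)
  cuts <- function(a, b) sort(unique(c(a, b, anchors[anchors > a &
                                                       anchors < b])))
  piecewise <- function(f, a, b) {
    if (b <= a) return(0)
    cc <- cuts(a, b)
    sum(vapply(seq_len(length(cc) - 1L), function(i)
      stats::integrate(f, cc[i], cc[i + 1L], rel.tol = 1e-10,
                       abs.tol = 0)$value, numeric(1)))
  }
  Z <- piecewise(smear$g, lo, hi)
  mean_kb <- piecewise(function(L) L * smear$g(L), lo, hi) / Z
  cdf <- function(x) piecewise(smear$g, lo, x) / Z
  qf <- function(p) stats::uniroot(function(x) cdf(x) - p, c(lo, hi),
                                   tol = 1e-9)$root
  q <- vapply(c(0.25, 0.5, 0.75), qf, numeric(1))
  list(mean_kb = mean_kb, med_kb = q[2], q1_kb = q[1], q3_kb = q[3],
       iq_kb = q[3] - q[1])
}

#' Simulate a telomere smear lane
#'
#' Signal at pixel row r is `amplitude * B(L) * g(L) * |dL/drow|` with
#' `L = size(r)` and `B(L) = L` when probe bias is on (1 otherwise): the
#' per-pixel intensity is the signal density integrated over the pixel's
#' size increment, which is how a scanned smear arises physically.
#'
#' @inheritParams simulate_ladder_lane
#' @param smear a [smear_spec()].
#' @param probe probe annotation for the lane.
#' @return List with `profile` and `truth` (from [smear_truth()]).
#' @export
simulate_smear_lane <- function(smear, model, noise = noise_spec(),
                                lane_id = "sample", probe = "host",
                                membrane_id = "membrane") {
  stopifnot(inherits(smear, "smear_spec"), inherits(model, "migration_model"))
  rows <- 0:(model_n_rows(model) - 1L)
  L <- model_size_of(model, pmax(rows, model$r0))
  L <- pmin(pmax(L, model$Lmin), model$Lmax)
  u <- log2(model$Lmax) - log2(L)
  dL_drow <- L * log(2) / (model$s + 2 * model$kappa * u)
  bias <- if (smear$probe_bias) L else 1
  sig <- smear$amplitude * bias * smear$g(L) * dL_drow
  sig[rows < model$r0] <- 0
  profile <- lane_profile(lane_id, rows, apply_noise(sig, noise),
                          role = "sample", probe = probe,
                          membrane_id = membrane_id)
  list(profile = profile, truth = smear_truth(smear, model))
}

#' Render a full synthetic membrane
#'
#' Lays out ladder and smear lanes left to right on a 16-bit image
#' (default layout mirrors TRF practice: ladders at the left and right
#' ends, optionally the middle). Each lane's 1-D simulated profile is
#' spread uniformly over its `lane_width` columns and quantized to
#' integer counts, so [extract_profile()] recovers the simulated profile
#' up to rendering quantization.
#'
#' @param lanes list of lane descriptors: each a list with `type`
#'   (`"ladder"` or `"smear"`), `id`, a `ladder` or `smear` object,
#'   and for ladders `role`, for smears `probe`; per-lane `noise`
#'   optional.
#' @param model a [migration_model()].
#' @param noise default [noise_spec()]; per-lane seeds are derived from
#'   its seed so lanes are independent but reproducible.
#' @param lane_width,gap lane width and inter-lane gap in columns.
#' @param membrane_id membrane identifier.
#' @return List with `image` ([gel_image()]), `rois`, `seeds` (ladder
#'   seed data frame) and `truth` (per-smear-lane oracle summaries).
#' @export
render_membrane <- function(lanes, model, noise = noise_spec(),
                            lane_width = 12L, gap = 6L,
                            membrane_id = "membrane") {
  n_rows <- model_n_rows(model)
  n_cols <- length(lanes) * (lane_width + gap) + gap
  img <- matrix(0, n_rows, n_cols)
  rois <- list(); seeds <- NULL; truth <- list()
  for (i in seq_along(lanes)) {
    ln <- lanes[[i]]
    lane_noise <- if (!is.null(ln$noise)) ln$noise else
      noise_spec(noise$baseline, noise$sd,
                 if (is.null(noise$seed)) NULL else noise$seed + 97L * i)
    c0 <- gap + (i - 1L) * (lane_width + gap)
    if (ln$type == "ladder") {
      sim <- simulate_ladder_lane(ln$ladder, model, lane_noise,
                                  seed_jitter = ln$seed_jitter %||% 0,
                                  lane_id = ln$id,
                                  role = ln$role %||% "ladder-left",
                                  membrane_id = membrane_id)
      seeds <- rbind(seeds, data.frame(membrane_id = membrane_id,
                                       lane_id = ln$id, sim$seeds))
      roi <- lane_roi(ln$id, c0, c0 + lane_width,
                      role = ln$role %||% "ladder-left",
                      probe = "none", membrane_id = membrane_id)
    } else if (ln$type == "smear") {
      sim <- simulate_smear_lane(ln$smear, model, lane_noise,
                                 lane_id = ln$id,
                                 probe = ln$probe %||% "host",
                                 membrane_id = membrane_id)
      truth[[ln$id]] <- sim$truth
      roi <- lane_roi(ln$id, c0, c0 + lane_width, role = "sample",
                      probe = ln$probe %||% "host",
                      membrane_id = membrane_id)
    } else stop("unknown lane type: ", ln$type)
    per_col <- round(sim$profile$intensity / lane_width)
    if (any(per_col > 65535))
      stop("lane ", ln$id, " overflows the 16-bit pixel range; ",
           "reduce amplitude or widen the lane")
    img[, (c0 + 1L):(c0 + lane_width)] <- per_col
    rois[[i]] <- roi
  }
  list(image = gel_image(img, bit_depth = 16L, image_id = membrane_id),
       rois = rois, seeds = seeds, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cohort simulation design
#'
#' Generative model for a Pacific-style coral cohort:
#' `ln(TL) = intercept + island effect + community effect +
#' slope * diameter + noise`, island and community effects drawn once per
#' level from centered normals with the stated SDs, community labels
#' assigned independently of island. Defaults emulate the sampling
#' structure of a basin-wide survey: about 30 islands, right-skewed TL
#' around 6 kb, colony diameters 10-80 cm.
#'
#' @param n_islands,colonies_per_island cohort dimensions.
#' @param island_sd,community_sd,residual_sd effect SDs on the ln-kb
#'   scale.
#' @param n_communities number of symbiont community profiles.
#' @param diameter_slope effect of colony diameter (per cm) on ln(TL).
#' @param diameter_range uniform sampling range for diameters (cm).
#' @param intercept baseline ln(TL) (default `log(6)`).
#' @param seed RNG seed.
#' @return A `cohort_design`.
#' @export
cohort_design <- function(n_islands = 30L, colonies_per_island = 27L,
                          island_sd = sqrt(0.5), community_sd = sqrt(0.1),
                          n_communities = 8L, diameter_slope = 0,
                          diameter_range = c(10, 80),
                          residual_sd = sqrt(0.4), intercept = log(6),
                          seed = NULL) {
  stopifnot(n_islands >= 1L, colonies_per_island >= 1L, island_sd >= 0,
            community_sd >= 0, residual_sd >= 0, n_communities >= 1L)
  structure(as.list(environment()), class = "cohort_design")
}

#' Simulate a coral TL cohort
#'
#' Draws a cohort from a [cohort_design()] and reports the realized truth
#' needed by recovery tests: the variance-component shares implied by the
#' realized (not merely designed) effects and design matrix. True
#' subset-R-squared values come from projecting the noiseless linear
#' predictor onto each predictor subset, with the designed residual
#' variance added to the denominator — deterministic linear algebra on
#' the realization, independent of any noisy refit.
#'
#' @param design a [cohort_design()].
#' @return List with `cohort` (data frame in the cohort CSV layout) and
#'   `truth` (realized variance fractions, true subset R-squared map and
#'   true unique coefficients per predictor).
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  with_seed(design$seed, {
    n <- design$n_islands * design$colonies_per_island
    island <- rep(sprintf("I%02d", seq_len(design$n_islands)),
                  each = design$colonies_per_island)
    community <- sample(sprintf("C%02d", seq_len(design$n_communities)),
                        n, replace = TRUE)
    isl_eff <- stats::rnorm(design$n_islands, 0, design$island_sd)
    com_eff <- stats::rnorm(design$n_communities, 0, design$community_sd)
    diam <- stats::runif(n, design$diameter_range[1], design$diameter_range[2])
    eta <- design$intercept +
      isl_eff[as.integer(factor(island))] +
      com_eff[as.integer(factor(community))] +
      design$diameter_slope * diam
    y <- eta + stats::rnorm(n, 0, design$residual_sd)
    tl <- exp(y)
    cohort <- data.frame(
      colony_id = sprintf("colony%04d", seq_len(n)),
      island = island, genus = "Pocillopora", species = "",
      symbiodiniaceae_profile = community, bacteria_profile = community,
      diameter_cm = diam,
      htl_mean_kb = tl, htl_med_kb = tl, htl_q1_kb = tl * 0.8,
      htl_q3_kb = tl * 1.25, htl_iq_kb = tl * 0.45,
      stl_mean_kb = tl, stl_med_kb = tl, stl_q1_kb = tl * 0.8,
      stl_q3_kb = tl * 1.25, stl_iq_kb = tl * 0.45)
    truth <- realized_variance_truth(eta, island, community, diam,
                                     design$residual_sd)
    list(cohort = cohort, truth = truth)
  })
}

realized_variance_truth <- function(eta, island, community, diam,
                                    residual_sd) {
  n <- length(eta)
  ss_eta <- sum((eta - mean(eta))^2)
  ss_tot <- ss_eta + (n - 1) * residual_sd^2
  blocks <- list(island = island, community = community, diameter = diam)
  keep <- vapply(blocks, function(b) length(unique(b)) > 1L, logical(1))
  blocks <- blocks[keep]
  r2_true <- numeric(0)
  nm <- names(blocks)
  p <- length(nm)
  for (mask in seq_len(2^p - 1L)) {
    sel <- nm[bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0]
    fit <- stats::lm(eta ~ ., data = data.frame(eta = eta, blocks[sel]))
    r2_true[subset_key(sel)] <- (ss_eta - sum(stats::residuals(fit)^2)) /
      ss_tot
  }
  cm <- commonality(r2_true)
  uniq <- cm$table[cm$table$n_blocks == 1L, ]
  list(r2_map = r2_true,
       r2_full = unname(r2_true[subset_key(nm)]),
       unique_fraction = stats::setNames(uniq$coefficient, uniq$subset),
       residual_fraction = (n - 1) * residual_sd^2 / ss_tot)
}

#' Write cohort simulation outputs
#'
#' Emits the cohort CSV and a `truth.json` holding the realized variance
#' fractions.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir` invisibly.
#' @export
write_cohort_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$cohort, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(r2_full = sim$truth$r2_full,
         unique_fraction = as.list(sim$truth$unique_fraction),
         residual_fraction = sim$truth$residual_fraction),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
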