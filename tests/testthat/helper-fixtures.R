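# Shared fixtures built in code.

# A piecewise scale whose two segments are the same exact line, matching a
# kappa = 0 migration model: log2(L) = a + b*row with a = log2(Lmax) + r0/s,
# b = -1/s.
exact_scale <- function(model, switch_size_kb = 9) {
  a <- log2(model$Lmax) + model$r0 / model$s
  b <- -1 / model$s
  switch_row <- as.integer(round((log2(switch_size_kb) - a) / b))
  structure(list(a_hi = a, b_hi = b, a_lo = a, b_lo = b,
                 switch_row = switch_row,
                 switch_size_kb = 2^(a + b * switch_row),
                 continuity_gap = 0, valid_min_kb = 2, valid_max_kb = 48.5,
                 ladder_lane_id = "exact", membrane_id = "fixture"),
            class = "piecewise_scale")
}

# Two log2-linear migration lines intersecting exactly at `cross_row`
# where both predict `cross_kb`.
two_line_fixture <- function(cross_row = 258, cross_kb = 9,
                             b_hi = -1 / 100, b_lo = -1 / 160) {
  list(a_hi = log2(cross_kb) - b_hi * cross_row, b_hi = b_hi,
       a_lo = log2(cross_kb) - b_lo * cross_row, b_lo = b_lo)
}

# A synthetic ladder living exactly on the two lines above: integer band
# rows, band sizes derived from the lines (so peak refinement and both
# segment fits are exact). Returns the ladder spec, the profile with
# Gaussian bumps at the band rows, seeds, and the exact row->size pairs.
# lo_rows start below (gel-wise) the 258-row crossing so every low-MW band
# is evaluated by the low segment once the switch lands at the crossing
two_line_ladder <- function(lines = two_line_fixture(),
                            hi_rows = c(60, 100, 140),
                            lo_rows = seq(262, 622, by = 60),
                            n_rows = 760, band_sd = 4, amplitude = 1e4,
                            seed_jitter = 0, seed = 1) {
  hi_sizes <- 2^(lines$a_hi + lines$b_hi * hi_rows)
  lo_sizes <- 2^(lines$a_lo + lines$b_lo * lo_rows)
  sizes <- c(hi_sizes, lo_sizes)
  rows_at <- c(hi_rows, lo_rows)
  ladder <- ladder_spec("two-line-synthetic", sizes,
                        hi_fit_kb = hi_sizes, lo_fit_kb = lo_sizes)
  grid <- 0:(n_rows - 1)
  intensity <- rowSums(vapply(rows_at, function(c0)
    amplitude * exp(-(grid - c0)^2 / (2 * band_sd^2)),
    numeric(length(grid))))
  profile <- lane_profile("two-line", grid, intensity, role = "ladder-left")
  jit <- if (seed_jitter > 0) {
    set.seed(seed)
    sample(-seed_jitter:seed_jitter, length(sizes), replace = TRUE)
  } else 0L
  list(ladder = ladder, profile = profile,
       seeds = data.frame(size_kb = sizes, seed_row = rows_at + jit),
       true_rows = rows_at, true_sizes = sizes, lines = lines)
}

# Random discrete TL distribution on [2, 30] kb.
random_distribution <- function(n = 50) {
  tl_distribution(size_kb = sort(stats::runif(n, 2, 30)),
                  raw = stats::runif(n, 0, 100))
}

# Independent weighted-quantile oracle (step convention, brute force).
oracle_step_quantile <- function(size, w, p) {
  ord <- order(size)
  size <- size[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  size[Position(function(z) z >= p - 1e-12, cw)]
}
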