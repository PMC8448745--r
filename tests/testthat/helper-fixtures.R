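# Shared fixtures: tiny deterministic inputs built in code.

# exact end-of-hold points on sigma = A(exp(B eps) - 1)
exact_curve_points <- function(A, B, strains = seq(0.1, 0.6, by = 0.1)) {
  data.frame(strain = strains, stress_kPa = A * expm1(B * strains))
}

# idealized raw trace whose end-of-hold forces sit exactly on the
# equilibrium curve (no relaxation residual, no noise, no quantization)
ideal_trace <- function(A, B, csa_mm2, sl0_um = 2.0,
                        protocol = stretch_protocol()) {
  n <- protocol$n_increments
  period <- protocol$increment_strain / protocol$strain_rate +
    protocol$hold_duration
  strains <- protocol$increment_strain * seq_len(n)
  f_eq <- A * expm1(B * strains) * 1000 * csa_mm2
  time <- numeric(0); force <- numeric(0)
  for (k in seq_len(n)) {
    tk <- seq((k - 1) * period + 1, k * period, by = 60)
    time <- c(time, tk)
    force <- c(force, rep(f_eq[k], length(tk)))
  }
  raw_trace(time = time, force = force,
            sarcomere_length = sl0_um * (1 + c(0, strains)),
            slack_sarcomere_length = sl0_um, specimen_id = "ideal")
}

# one-pool bundle cohort config with all corruption switched off
noise_free_config <- function(n = 15, seed = 11) {
  cohort_config(n_per_pool = n, groups = "G1", muscles = "multifidus",
                specimen_types = "bundle",
                force_noise_fiber_uN = 0, force_noise_bundle_uN = 0,
                diameter_noise_mm = 0, biological_cv = 0, seed = seed)
}

# tiny section image: nr x nc raster with explicit fiber disks
toy_section <- function(nr, nc, fibers = list(), collagen_idx = integer(0)) {
  labs <- matrix(0L, nrow = nr, ncol = nc)
  px <- rep(seq_len(nc), each = nr)
  py <- rep(seq_len(nr), times = nc)
  for (k in seq_along(fibers)) {
    f <- fibers[[k]]  # c(x, y, r)
    labs[(px - f[1])^2 + (py - f[2])^2 <= f[3]^2] <- k
  }
  mask <- matrix(FALSE, nrow = nr, ncol = nc)
  mask[collagen_idx] <- TRUE
  section_image(mask, labs)
}

# rectangle polygon covering pixel centers [x1..x2] x [y1..y2]
rect_poly <- function(x1, y1, x2, y2) {
  cbind(c(x1 - 0.5, x2 + 0.5, x2 + 0.5, x1 - 0.5),
        c(y1 - 0.5, y1 - 0.5, y2 + 0.5, y2 + 0.5))
}

# brute-force two-sided exact p for the one-sample signed-rank test:
# enumerate all 2^n sign assignments of the absolute-difference ranks
enumerate_signed_rank_p <- function(values, null_median = 1) {
  d <- values - null_median
  d <- d[d != 0]
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_lo <- mean(v_all <= v_obs + 1e-9)
  p_hi <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

# pixel mask of a polygon via the package-internal rule
.polygon_pixel_mask_test <- function(image, polygon) {
  fibermech:::.polygon_pixel_mask(dim(image$collagen_mask), polygon)
}
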