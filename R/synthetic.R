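#' Configuration of a synthetic cohort
#'
#' Defines the virtual study: pools (group x muscle x specimen type),
#' specimen counts, size distributions, shape (axis-ratio) distributions,
#' measurement noise and biological scatter. Defaults emulate the lumbar
#' paraspinal cohorts: fiber minor-axis diameters log-normal around
#' 0.09 mm (spanning roughly 0.06--0.14 mm), bundles of ~7/14/21 fibers,
#' axis-ratio medians of 1.2 for fibers and 1.35 for bundles, transducer
#' noise of 1 uN (fibers) / 10 uN (bundles) and 2 um diameter-reading
#' noise. Biological scatter enters as log-normal multiplicative noise
#' (default CV 25%) on the core modulus and the ECM fraction, which is
#' what keeps cohort-level regressions weak (R^2 well below 0.5) as seen
#' in real pools.
#'
#' @param n_per_pool Specimens per pool (default 60).
#' @param groups,muscles,specimen_types Character vectors defining pools.
#' @param bundle_size_classes Typical fiber counts of small/medium/large
#'   bundles (default c(7, 14, 21)).
#' @param fiber_diameter_median_mm,fiber_diameter_sdlog Log-normal fiber
#'   minor-axis diameter (mm).
#' @param axis_ratio_median_fiber,axis_ratio_median_bundle Median axis
#'   ratios; the excess over 1 is log-normal with `axis_ratio_sdlog`.
#' @param axis_ratio_sdlog Spread of the axis-ratio excess.
#' @param force_noise_fiber_uN,force_noise_bundle_uN Gaussian force noise.
#' @param diameter_noise_mm Gaussian noise per diameter reading.
#' @param biological_cv CV of the log-normal scatter on E_core and f_ECM.
#' @param sl0_mean_um,sl0_sd_um Slack sarcomere length distribution
#'   (size-independent by construction).
#' @param curve_B_median,curve_B_sdlog Log-normal exponent of the passive
#'   stress curve sigma = A(exp(B eps) - 1).
#' @param seed Integer seed; fixing it makes the cohort reproducible.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_pool = 60L,
                          groups = c("G1", "G2", "G3"),
                          muscles = c("multifidus", "longissimus"),
                          specimen_types = c("fiber", "bundle"),
                          bundle_size_classes = c(7L, 14L, 21L),
                          fiber_diameter_median_mm = 0.090,
                          fiber_diameter_sdlog = 0.20,
                          axis_ratio_median_fiber = 1.20,
                          axis_ratio_median_bundle = 1.35,
                          axis_ratio_sdlog = 0.60,
                          force_noise_fiber_uN = 1,
                          force_noise_bundle_uN = 10,
                          diameter_noise_mm = 0.002,
                          biological_cv = 0.25,
                          sl0_mean_um = 2.2,
                          sl0_sd_um = 0.1,
                          curve_B_median = 3,
                          curve_B_sdlog = 0.2,
                          seed = 1L) {
  stopifnot(n_per_pool >= 1, all(bundle_size_classes >= 1),
            fiber_diameter_median_mm > 0, fiber_diameter_sdlog > 0,
            axis_ratio_median_fiber >= 1, axis_ratio_median_bundle >= 1,
            axis_ratio_sdlog > 0, force_noise_fiber_uN >= 0,
            force_noise_bundle_uN >= 0, diameter_noise_mm >= 0,
            biological_cv >= 0, sl0_mean_um > 0, curve_B_median > 0)
  structure(as.list(environment()), class = "cohort_config")
}

# deterministic 32-bit sub-seed for specimen i of a cohort
.sub_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + i * 7919) %% 2147483647
}

#' Generate a synthetic cohort of specimens with ground truth
#'
#' For each specimen the generator draws its size (fiber diameter, or
#' bundle fiber count and packed diameter), computes the true tangent
#' modulus from the composite model (basement-membrane shell fibers;
#' size-dependent ECM fraction for bundles), draws an axis ratio and
#' splits the cross-section into top/side diameters preserving area, and
#' emits three noisy readings per axis. Biological scatter multiplies the
#' core modulus and ECM fraction. The result is deterministic under the
#' config seed.
#'
#' @param config A [cohort_config()].
#' @param comp A [composite_params()].
#' @param scaling An [ecm_scaling_params()].
#' @return List with `specimens` (one row per specimen: pool labels,
#'   diameter readings, derived measured geometry) and `truth` (true
#'   modulus, CSA, ECM fraction, fiber count, generating curve A/B, SL0).
#' @export
generate_cohort <- function(config,
                            comp = composite_params(),
                            scaling = ecm_scaling_params()) {
  pools <- expand.grid(group = config$groups, muscle = config$muscles,
                       specimen_type = config$specimen_types,
                       stringsAsFactors = FALSE)
  rows <- vector("list", nrow(pools) * config$n_per_pool)
  idx <- 0L
  for (p in seq_len(nrow(pools))) {
    for (s in seq_len(config$n_per_pool)) {
      idx <- idx + 1L
      set.seed(.sub_seed(config$seed, idx))
      rows[[idx]] <- .generate_specimen(
        id = sprintf("S%04d", idx),
        group = pools$group[p], muscle = pools$muscle[p],
        specimen_type = pools$specimen_type[p],
        config = config, comp = comp, scaling = scaling
      )
    }
  }
  all <- do.call(rbind, rows)
  spec_cols <- c("specimen_id", "group", "muscle", "specimen_type",
                 paste0("top", 1:3), paste0("side", 1:3))
  truth_cols <- c("specimen_id", "group", "muscle", "specimen_type",
                  "true_modulus_kPa", "true_csa_mm2", "true_f_ECM",
                  "true_n_fibers", "curve_A", "curve_B", "sl0_um")
  list(specimens = all[, spec_cols], truth = all[, truth_cols])
}

.generate_specimen <- function(id, group, muscle, specimen_type,
                               config, comp, scaling) {
  cv <- config$biological_cv
  sdlog_bio <- sqrt(log(1 + cv^2))
  bio <- function() stats::rlnorm(1, -sdlog_bio^2 / 2, sdlog_bio)
  fiber_d_mm <- stats::rlnorm(1, log(config$fiber_diameter_median_mm),
                              config$fiber_diameter_sdlog)
  E_core <- comp$E_core_kPa * bio()
  if (specimen_type == "fiber") {
    n_fibers <- 1L
    f_ECM <- 0
    true_modulus <- shell_fiber_modulus(fiber_d_mm * 1000, comp$t_bm_um,
                                        comp$E_bm_kPa, E_core)
    true_csa <- pi / 4 * fiber_d_mm^2
    ratio_med <- config$axis_ratio_median_fiber
  } else {
    cls <- sample(config$bundle_size_classes, 1L)
    n_fibers <- max(2L, cls + sample(-2:2, 1L))
    f_ECM <- min(0.95, ecm_fraction(n_fibers, scaling) * bio())
    E_fib <- shell_fiber_modulus(fiber_d_mm * 1000, comp$t_bm_um,
                                 comp$E_bm_kPa, E_core)
    true_modulus <- rule_of_mixtures(f_ECM, comp$E_ECM_kPa, E_fib)
    # total fiber area grossed up by the ECM fraction
    true_csa <- n_fibers * pi / 4 * fiber_d_mm^2 / (1 - f_ECM)
    ratio_med <- config$axis_ratio_median_bundle
  }
  ratio <- 1 + (ratio_med - 1) *
    stats::rlnorm(1, 0, config$axis_ratio_sdlog)
  d_equiv <- sqrt(4 * true_csa / pi)
  d_minor <- d_equiv / sqrt(ratio)
  d_major <- d_equiv * sqrt(ratio)
  if (stats::runif(1) < 0.5) {
    d_top <- d_major; d_side <- d_minor
  } else {
    d_top <- d_minor; d_side <- d_major
  }
  noisy <- function(d) pmax(1e-4, d + stats::rnorm(3, 0, config$diameter_noise_mm))
  top <- noisy(d_top); side <- noisy(d_side)
  B <- stats::rlnorm(1, log(config$curve_B_median), config$curve_B_sdlog)
  A <- true_modulus / (B * exp(0.3 * B))
  sl0 <- max(1.5, stats::rnorm(1, config$sl0_mean_um, config$sl0_sd_um))
  data.frame(
    specimen_id = id, group = group, muscle = muscle,
    specimen_type = specimen_type,
    top1 = top[1], top2 = top[2], top3 = top[3],
    side1 = side[1], side2 = side[2], side3 = side[3],
    true_modulus_kPa = true_modulus, true_csa_mm2 = true_csa,
    true_f_ECM = f_ECM, true_n_fibers = n_fibers,
    curve_A = A, curve_B = B, sl0_um = sl0
  )
}

#' Simulate one stretch-relaxation test
#'
#' Builds the raw recording of the incremental protocol for a specimen
#' whose equilibrium stress curve is sigma(eps) = A(exp(B eps) - 1). Each
#' increment ramps at the protocol strain rate to 1.5x the equilibrium
#' force, then relaxes as a double exponential
#' F(t) = F_eq + (F_peak - F_eq)(w1 exp(-t/tau1) + w2 exp(-t/tau2)) with
#' tau1 = 2 s, tau2 = 40 s, w1 = w2 = 0.5, so end-of-hold force at 240 s
#' is within ~0.1% of equilibrium. Gaussian force noise is added
#' throughout; sarcomere readings (pre-stretch and at each hold end) are
#' quantized to the ~10 nm resolution of laser diffraction. A short
#' pre-slack segment at time <= 0 carries only noise below the detection
#' threshold.
#'
#' @param truth One row of the `truth` table from [generate_cohort()]
#'   (needs `curve_A`, `curve_B`, `true_csa_mm2`, `sl0_um`,
#'   `specimen_id`).
#' @param protocol A [stretch_protocol()].
#' @param seed Integer seed.
#' @param force_noise_uN Gaussian force noise SD (uN).
#' @param sample_dt_s Sampling interval of the force channel (s).
#' @param tau1_s,tau2_s,w1,peak_factor Relaxation parameters.
#' @param sl_resolution_um Quantization step of the sarcomere-length
#'   readout (default 0.01 um, the ~10 nm diffraction resolution); 0
#'   disables quantization for noise-free round-trip checks.
#' @return A [raw_trace()].
#' @export
simulate_test <- function(truth, protocol, seed = 1L,
                          force_noise_uN = 0, sample_dt_s = 1,
                          tau1_s = 2, tau2_s = 40, w1 = 0.5,
                          peak_factor = 1.5, sl_resolution_um = 0.01) {
  set.seed(seed)
  A <- truth$curve_A; B <- truth$curve_B
  csa <- truth$true_csa_mm2; sl0 <- truth$sl0_um
  n_inc <- protocol$n_increments
  ramp <- protocol$increment_strain / protocol$strain_rate
  period <- ramp + protocol$hold_duration
  w2 <- 1 - w1
  # true strains: nominal cumulative increments with slight motor jitter
  strains <- cumsum(stats::rnorm(n_inc, protocol$increment_strain,
                                 protocol$increment_strain * 0.005))
  f_eq <- A * expm1(B * strains) * 1000 * csa  # kPa -> uN via mm^2
  # pre-slack: quiet baseline
  t_pre <- seq(-5, 0, by = sample_dt_s)
  f_pre <- abs(stats::rnorm(length(t_pre), 0, max(force_noise_uN, 1e-3) / 4))
  time <- t_pre; force <- f_pre
  f_prev_end <- 0
  for (k in seq_len(n_inc)) {
    t0 <- (k - 1) * period
    t_ramp <- if (ramp >= sample_dt_s) {
      seq(t0 + sample_dt_s, t0 + ramp, by = sample_dt_s)
    } else {
      numeric(0)
    }
    f_peak <- peak_factor * f_eq[k]
    if (length(t_ramp)) {
      frac <- (t_ramp - t0) / ramp
      force <- c(force, f_prev_end + frac * (f_peak - f_prev_end))
      time <- c(time, t_ramp)
    }
    t_hold <- seq(t0 + ramp + sample_dt_s, t0 + period, by = sample_dt_s)
    th <- t_hold - (t0 + ramp)
    f_hold <- f_eq[k] + (f_peak - f_eq[k]) *
      (w1 * exp(-th / tau1_s) + w2 * exp(-th / tau2_s))
    force <- c(force, f_hold)
    time <- c(time, t_hold)
    f_prev_end <- f_hold[length(f_hold)]
  }
  if (force_noise_uN > 0) {
    post <- time > 0
    force[post] <- pmax(0, force[post] +
                          stats::rnorm(sum(post), 0, force_noise_uN))
  }
  sl_true <- sl0 * (1 + c(0, strains))
  if (sl_resolution_um > 0) {
    sl_out <- round(sl_true / sl_resolution_um) * sl_resolution_um
    sl0_out <- round(sl0 / sl_resolution_um) * sl_resolution_um
  } else {
    sl_out <- sl_true
    sl0_out <- sl0
  }
  raw_trace(time = time, force = force, sarcomere_length = sl_out,
            slack_sarcomere_length = sl0_out,
            specimen_id = truth$specimen_id)
}

#' Generate a labeled section image of one bundle
#'
#' Rasterizes `n_fibers` equal circular fibers packed on a jittered
#' hexagonal lattice, builds the paired internal (type A, through the
#' boundary fibers) and external (type B, outside their edges) polygons,
#' and marks collagen-I-positive pixels among the inter-fiber ECM pixels
#' so that the collagen area fraction inside each polygon matches `f_ECM`
#' to within the pixel-count granularity (well inside +/-0.005 at the
#' default resolution). Collagen-I occurs only between fibers, never
#' inside them.
#'
#' @param n_fibers Number of fibers, >= 1.
#' @param f_ECM Target collagen area fraction, in (0, 1).
#' @param seed Integer seed.
#' @param fiber_radius_px Fiber radius in pixels (default 20).
#' @param gap_frac Inter-fiber gap as a fraction of the diameter.
#' @param pixel_size_um Pixel size (um/pixel).
#' @return List with `image` (a [section_image()]) and `segmentation`
#'   (a [bundle_segmentation()]).
#' @export
generate_section_image <- function(n_fibers, f_ECM, seed = 1L,
                                   fiber_radius_px = 20,
                                   gap_frac = 0.15,
                                   pixel_size_um = 1) {
  if (n_fibers < 1) stop("n_fibers must be >= 1")
  if (f_ECM <= 0 || f_ECM >= 1) stop("f_ECM must lie in (0, 1)")
  set.seed(seed)
  r <- fiber_radius_px
  spacing <- 2 * r * (1 + gap_frac)
  centers <- .hex_centers(n_fibers, spacing)
  centers <- centers + matrix(stats::rnorm(2 * n_fibers, 0, r * 0.03),
                              ncol = 2)
  margin <- 3 * r
  xr <- range(centers[, 1]); yr <- range(centers[, 2])
  off <- c(margin - xr[1], margin - yr[1])
  centers <- sweep(centers, 2, off, "+")
  nc <- ceiling(xr[2] - xr[1] + 2 * margin)
  nr <- ceiling(yr[2] - yr[1] + 2 * margin)
  labs <- matrix(0L, nrow = nr, ncol = nc)
  px <- rep(seq_len(nc), each = nr)
  py <- rep(seq_len(nr), times = nc)
  for (k in seq_len(n_fibers)) {
    inside <- (px - centers[k, 1])^2 + (py - centers[k, 2])^2 <= r^2
    labs[inside] <- k
  }
  polyA <- .offset_hull(centers, 0.5 * r)
  polyB <- .offset_hull(centers, 1.4 * r)
  # collagen: calibrated subset of ECM pixels, per region, so that the
  # fraction inside A and inside B both hit the target
  maskA <- .polygon_pixel_mask(c(nr, nc), polyA)
  maskB <- .polygon_pixel_mask(c(nr, nc), polyB)
  collagen <- matrix(FALSE, nrow = nr, ncol = nc)
  for (region in list(maskA, maskB & !maskA)) {
    n_reg <- sum(region)
    if (n_reg == 0L) next
    ecm_idx <- which(region & labs == 0L)
    want <- round(f_ECM * n_reg)
    if (want > length(ecm_idx)) {
      stop("packing error: not enough ECM pixels to reach the target fraction")
    }
    collagen[sample(ecm_idx, want)] <- TRUE
  }
  list(
    image = section_image(collagen, labs, pixel_size_um),
    segmentation = bundle_segmentation(polyA, polyB)
  )
}

# first n sites of a hexagonal lattice, nearest-to-origin first
.hex_centers <- function(n, spacing) {
  m <- ceiling(sqrt(n)) + 2
  g <- expand.grid(i = -m:m, j = -m:m)
  x <- spacing * (g$i + 0.5 * (g$j %% 2))
  y <- spacing * sqrt(3) / 2 * g$j
  o <- order(x^2 + y^2)
  cbind(x[o], y[o])[seq_len(n), , drop = FALSE]
}

# convex hull of the centers, offset radially outward from the centroid;
# degenerate hulls (1-2 points) become regular polygons around the centroid
.offset_hull <- function(centers, offset) {
  ctr <- colMeans(centers)
  if (nrow(centers) < 3L ||
      nrow(unique(round(centers, 6))) < 3L) {
    ang <- seq(0, 2 * pi, length.out = 17L)[-17L]
    rad <- max(sqrt(rowSums(sweep(centers, 2, ctr)^2))) + offset
    return(cbind(ctr[1] + rad * cos(ang), ctr[2] + rad * sin(ang)))
  }
  h <- grDevices::chull(centers)
  v <- centers[h, , drop = FALSE]
  # collinear centers give a zero-area hull; fall back to a circle
  area2 <- abs(sum(v[, 1] * c(v[-1, 2], v[1, 2]) -
                     c(v[-1, 1], v[1, 1]) * v[, 2]))
  if (nrow(v) < 3L || area2 < 1e-6) {
    ang <- seq(0, 2 * pi, length.out = 17L)[-17L]
    rad <- max(sqrt(rowSums(sweep(centers, 2, ctr)^2))) + offset
    return(cbind(ctr[1] + rad * cos(ang), ctr[2] + rad * sin(ang)))
  }
  d <- sweep(v, 2, ctr)
  len <- sqrt(rowSums(d^2))
  v + d / len * offset
}
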