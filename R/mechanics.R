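#' Incremental stretch-relaxation protocol
#'
#' The standard protocol applies cumulative stretches of 10% strain at 10%
#' strain per second, each followed by a 4-minute hold, for four to eight
#' increments. Slack length is taken where passive force first exceeds the
#' transducer noise floor: about 5 uN for single fibers and 50 uN for
#' fiber bundles.
#'
#' @param increment_strain Nominal strain per increment (default 0.10).
#' @param strain_rate Strain rate during the ramp, per second (default 0.10).
#' @param hold_duration Relaxation hold after each ramp, seconds (default 240).
#' @param n_increments Number of cumulative increments, 4..8 (default 6).
#' @param slack_threshold_fiber,slack_threshold_bundle Force thresholds (uN)
#'   marking the first detectable passive-force rise.
#' @return An object of class `stretch_protocol`.
#' @export
stretch_protocol <- function(increment_strain = 0.10,
                             strain_rate = 0.10,
                             hold_duration = 240,
                             n_increments = 6L,
                             slack_threshold_fiber = 5,
                             slack_threshold_bundle = 50) {
  stopifnot(increment_strain > 0, strain_rate > 0, hold_duration > 0,
            slack_threshold_fiber > 0, slack_threshold_bundle > 0)
  n_increments <- as.integer(n_increments)
  if (n_increments < 4L) stop("protocol requires at least 4 increments")
  structure(
    list(increment_strain = increment_strain, strain_rate = strain_rate,
         hold_duration = hold_duration, n_increments = n_increments,
         slack_threshold_fiber = slack_threshold_fiber,
         slack_threshold_bundle = slack_threshold_bundle),
    class = "stretch_protocol"
  )
}

#' Slack threshold for a specimen type
#' @param protocol A [stretch_protocol()].
#' @param specimen_type `"fiber"` or `"bundle"`.
#' @return Threshold in uN.
#' @export
slack_threshold <- function(protocol, specimen_type = c("fiber", "bundle")) {
  specimen_type <- match.arg(specimen_type)
  if (specimen_type == "fiber") protocol$slack_threshold_fiber
  else protocol$slack_threshold_bundle
}

#' Detect the slack point in a passive force recording
#'
#' Returns the index of the first sample whose force strictly exceeds the
#' transducer noise threshold -- the first detectable rise in passive force.
#'
#' @param force Numeric force sequence (uN).
#' @param threshold Noise-floor threshold (uN), > 0.
#' @return 1-based index of the first crossing.
#' @export
detect_slack <- function(force, threshold) {
  if (!length(force)) stop("empty force sequence")
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("threshold must be a positive number")
  }
  idx <- which(force > threshold)
  if (!length(idx)) {
    stop("slack not reached: no force sample exceeds the threshold")
  }
  idx[1L]
}

#' Engineering stress from force and slack-state CSA
#'
#' Force in uN divided by CSA in mm^2 gives stress in Pa (uN/mm^2 == Pa);
#' the result is reported in kPa.
#'
#' @param force_uN Force (uN), >= 0.
#' @param csa_mm2 Cross-sectional area (mm^2), > 0.
#' @return Stress in kPa.
#' @export
engineering_stress <- function(force_uN, csa_mm2) {
  if (anyNA(csa_mm2) || any(csa_mm2 <= 0)) stop("csa must be positive")
  if (anyNA(force_uN) || any(force_uN < 0)) stop("force must be >= 0")
  force_uN / csa_mm2 / 1000
}

#' Sarcomere-based engineering strain
#'
#' Strain relative to the slack sarcomere length: (sl - sl0) / sl0.
#' Readings below slack give negative strain; these are flagged with a
#' warning but returned, so the caller can decide how to treat them.
#'
#' @param sl Sarcomere length (um).
#' @param sl0 Slack sarcomere length (um), > 0.
#' @return Dimensionless strain.
#' @export
strain_from_sarcomere <- function(sl, sl0) {
  if (anyNA(sl0) || any(sl0 <= 0)) stop("slack sarcomere length must be positive")
  strain <- (sl - sl0) / sl0
  if (any(strain < 0)) {
    warning("sarcomere length below slack: negative strain")
  }
  strain
}

#' Raw stretch-relaxation trace
#'
#' Container for one specimen's recording. Time is measured from the onset
#' of the first stretch; an optional pre-slack segment carries `time <= 0`.
#' Sarcomere length is sampled pre-stretch and at the end of each hold
#' (`n_increments + 1` readings).
#'
#' @param time,force Equal-length numeric vectors (s, uN), time strictly
#'   increasing.
#' @param sarcomere_length Numeric vector of end-of-hold sarcomere readings
#'   (um), the first taken pre-stretch.
#' @param slack_sarcomere_length Slack sarcomere length SL0 (um).
#' @param specimen_id Identifier.
#' @return An object of class `raw_trace`.
#' @export
raw_trace <- function(time, force, sarcomere_length,
                      slack_sarcomere_length, specimen_id = NA_character_) {
  if (length(time) != length(force)) stop("time and force lengths differ")
  if (is.unsorted(time, strictly = TRUE)) stop("time must be strictly increasing")
  if (any(sarcomere_length <= 0)) stop("sarcomere lengths must be positive")
  if (slack_sarcomere_length <= 0) stop("SL0 must be positive")
  structure(
    list(time = time, force = force, sarcomere_length = sarcomere_length,
         slack_sarcomere_length = slack_sarcomere_length,
         specimen_id = specimen_id),
    class = "raw_trace"
  )
}

#' @export
print.raw_trace <- function(x, ...) {
  cat("Stretch-relaxation trace", if (!is.na(x$specimen_id)) x$specimen_id, "\n")
  cat(sprintf("  %d force samples over %.0f s; %d sarcomere readings; SL0 = %.3f um\n",
              length(x$force), max(x$time) - min(x$time),
              length(x$sarcomere_length), x$slack_sarcomere_length))
  invisible(x)
}

#' Extract end-of-hold (strain, stress) points from a raw trace
#'
#' Each increment k ends at time k * (ramp + hold); the force reading at
#' the end of each increment is the last sample inside that window. Strain
#' comes from the matching end-of-hold sarcomere reading relative to SL0.
#'
#' @param trace A [raw_trace()].
#' @param protocol A [stretch_protocol()].
#' @param csa_mm2 Slack-state cross-sectional area (mm^2).
#' @return A data.frame with columns `increment`, `strain`, `stress_kPa`,
#'   ordered by strain.
#' @export
end_of_hold_points <- function(trace, protocol, csa_mm2) {
  n_inc <- protocol$n_increments
  if (length(trace$sarcomere_length) != n_inc + 1L) {
    stop("expected ", n_inc + 1L, " sarcomere readings (pre-stretch + one per increment), got ",
         length(trace$sarcomere_length))
  }
  period <- protocol$increment_strain / protocol$strain_rate +
    protocol$hold_duration
  ends <- seq_len(n_inc) * period
  # tolerate a sample landing a hair short of the nominal boundary
  idx <- vapply(ends, function(e) {
    i <- which(trace$time <= e + 1e-9)
    if (!length(i)) NA_integer_ else max(i)
  }, integer(1))
  if (anyNA(idx) || any(trace$time[idx] <= 0)) {
    stop("trace does not cover all ", n_inc, " hold windows")
  }
  force_eoh <- trace$force[idx]
  sl_eoh <- trace$sarcomere_length[-1L]
  strain <- strain_from_sarcomere(sl_eoh, trace$slack_sarcomere_length)
  out <- data.frame(
    increment = seq_len(n_inc),
    strain = strain,
    stress_kPa = engineering_stress(pmax(force_eoh, 0), csa_mm2)
  )
  out[order(out$strain), , drop = FALSE]
}

#' Tangent elastic modulus at a fixed strain
#'
#' Fits the exponential passive stress curve sigma(eps) = A (exp(B eps) - 1)
#' to the end-of-hold points by nonlinear least squares and returns its
#' analytic tangent A * B * exp(B * eval_strain) at the evaluation strain
#' (30% by default). The exponential form is the standard toe-region model
#' for passive muscle and gives a well-defined tangent even when no
#' increment lands exactly on the evaluation strain. If the fit fails to
#' converge, a central finite difference on the piecewise-linear
#' interpolant of the points is used instead and flagged.
#'
#' Only points with strain > 0 enter the fit; negative-strain points
#' (below slack) are dropped.
#'
#' @param points Data.frame with columns `strain`, `stress_kPa` (as from
#'   [end_of_hold_points()]), at least 3 positive-strain points.
#' @param eval_strain Strain at which the tangent is evaluated (default 0.30).
#' @return List with `tangent_modulus_kPa`, `A`, `B`, `fallback_used`.
#' @export
tangent_modulus <- function(points, eval_strain = 0.30) {
  pts <- points[points$strain > 0, , drop = FALSE]
  if (nrow(pts) < 3L) {
    stop("insufficient data: at least 3 positive-strain points are required")
  }
  if (all(pts$stress_kPa <= 0)) {
    stop("degenerate curve: all stresses are zero")
  }
  strain <- pts$strain
  stress <- pts$stress_kPa
  fit <- tryCatch({
    start <- list(A = max(stress) / (exp(2) - 1), B = 2)
    m <- minpack.lm::nlsLM(stress ~ A * (expm1(B * strain)),
                           start = start,
                           lower = c(A = 1e-12, B = 1e-9),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
    stats::coef(m)
  }, error = function(e) NULL)
  if (!is.null(fit)) {
    A <- unname(fit["A"]); B <- unname(fit["B"])
    list(tangent_modulus_kPa = A * B * exp(B * eval_strain),
         A = A, B = B, fallback_used = FALSE)
  } else {
    list(tangent_modulus_kPa = .finite_diff_tangent(strain, stress, eval_strain),
         A = NA_real_, B = NA_real_, fallback_used = TRUE)
  }
}

# slope of the piecewise-linear interpolant at eval_strain (central where
# possible; end segments use the one-sided slope)
.finite_diff_tangent <- function(strain, stress, eval_strain) {
  o <- order(strain)
  x <- strain[o]; y <- stress[o]
  if (eval_strain <= x[1L]) {
    return((y[2L] - y[1L]) / (x[2L] - x[1L]))
  }
  n <- length(x)
  if (eval_strain >= x[n]) {
    return((y[n] - y[n - 1L]) / (x[n] - x[n - 1L]))
  }
  h <- min(diff(x)) / 2
  lo <- max(x[1L], eval_strain - h)
  hi <- min(x[n], eval_strain + h)
  (stats::approx(x, y, xout = hi)$y - stats::approx(x, y, xout = lo)$y) /
    (hi - lo)
}

#' Full per-specimen mechanical analysis
#'
#' Runs [end_of_hold_points()] and [tangent_modulus()] for one trace.
#'
#' @inheritParams end_of_hold_points
#' @inheritParams tangent_modulus
#' @return A one-row data.frame: `specimen_id`, `csa_mm2`, `sl0_um`,
#'   `tangent_modulus_kPa`, `fit_A`, `fit_B`, `fallback_used`.
#' @export
analyze_trace <- function(trace, protocol, csa_mm2, eval_strain = 0.30) {
  pts <- end_of_hold_points(trace, protocol, csa_mm2)
  tm <- tangent_modulus(pts, eval_strain)
  data.frame(
    specimen_id = trace$specimen_id,
    csa_mm2 = csa_mm2,
    sl0_um = trace$slack_sarcomere_length,
    tangent_modulus_kPa = tm$tangent_modulus_kPa,
    fit_A = tm$A, fit_B = tm$B,
    fallback_used = tm$fallback_used
  )
}

#' Read per-increment end-of-hold tables from CSV
#'
#' Expects columns `specimen_id, increment, force_uN, sarcomere_um`. This is
#' the real-data entry point when full traces are not available.
#'
#' @param path CSV file path.
#' @return A data.frame.
#' @export
read_end_of_hold_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "increment", "force_uN", "sarcomere_um")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("end-of-hold CSV missing columns: ", paste(missing, collapse = ", "))
  }
  df
}
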