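#' Run the full analysis pipeline on a synthetic or imported cohort
#'
#' Orchestrates geometry -> mechanics -> cohort statistics per pool
#' (group x muscle x specimen type): derives each specimen's elliptical
#' CSA from noisy diameter readings, simulates (or consumes) its
#' stretch-relaxation test and extracts the tangent modulus at 30% strain,
#' applies the upper-IQR outlier filter within each pool, then fits the
#' modulus-vs-CSA regression, the axis-ratio shape summary, and the
#' slack-sarcomere-length-vs-CSA control regression (which should show no
#' correlation when slack length is size-independent).
#'
#' @param config A [cohort_config()] describing the synthetic cohort.
#' @param protocol A [stretch_protocol()].
#' @param comp A [composite_params()].
#' @param scaling An [ecm_scaling_params()].
#' @param eval_strain Strain at which the tangent modulus is evaluated.
#' @param min_pool_n Pools with fewer specimens after filtering are
#'   reported as skipped (default 5).
#' @param sample_dt_s Force-channel sampling interval for simulated tests.
#' @param outlier_scope `"pool"` (default) filters outliers within each
#'   group x muscle x type pool; `"group"` filters within each study group.
#' @return List of class `pipeline_result`: `specimens` (per-specimen
#'   table), `pools` (per-pool results), `manifest` (seed, counts,
#'   settings).
#' @export
run_pipeline <- function(config = cohort_config(),
                         protocol = stretch_protocol(),
                         comp = composite_params(),
                         scaling = ecm_scaling_params(),
                         eval_strain = 0.30,
                         min_pool_n = 5L,
                         sample_dt_s = 2,
                         outlier_scope = c("pool", "group")) {
  outlier_scope <- match.arg(outlier_scope)
  cohort <- generate_cohort(config, comp, scaling)
  specimens <- cohort$specimens
  truth <- cohort$truth
  # geometry stage
  specimens <- derive_geometry(specimens)
  # mechanics stage: simulate the test and recover the tangent modulus
  n <- nrow(specimens)
  mech <- vector("list", n)
  for (i in seq_len(n)) {
    noise <- if (specimens$specimen_type[i] == "fiber") {
      config$force_noise_fiber_uN
    } else {
      config$force_noise_bundle_uN
    }
    trace <- simulate_test(truth[i, ], protocol,
                           seed = .sub_seed(config$seed, n + i),
                           force_noise_uN = noise,
                           sample_dt_s = sample_dt_s)
    mech[[i]] <- analyze_trace(trace, protocol, specimens$csa_mm2[i],
                               eval_strain)
  }
  mech <- do.call(rbind, mech)
  specimens$tangent_modulus_kPa <- mech$tangent_modulus_kPa
  specimens$sl0_um <- mech$sl0_um
  specimens$fallback_used <- mech$fallback_used
  pools <- summarize_pools(specimens, min_pool_n = min_pool_n,
                           outlier_scope = outlier_scope)
  structure(
    list(specimens = specimens, pools = pools,
         manifest = list(seed = config$seed, n_specimens = n,
                         eval_strain = eval_strain,
                         outlier_scope = outlier_scope,
                         generated = TRUE)),
    class = "pipeline_result"
  )
}

#' Per-pool statistics of a per-specimen results table
#'
#' The statistics stage alone: for each pool, upper-IQR outlier removal
#' on the moduli, OLS regression of modulus on CSA, the axis-ratio shape
#' summary with its Wilcoxon test against a median of 1, and the
#' slack-length-vs-CSA control regression.
#'
#' @param specimens Data.frame with columns `group`, `muscle`,
#'   `specimen_type`, `csa_mm2`, `axis_ratio`, `tangent_modulus_kPa` and
#'   optionally `sl0_um`.
#' @param min_pool_n Minimum specimens for a pool to be analysed.
#' @param outlier_scope `"pool"` or `"group"`; see [run_pipeline()].
#' @return Data.frame, one row per pool.
#' @export
summarize_pools <- function(specimens, min_pool_n = 5L,
                            outlier_scope = c("pool", "group")) {
  outlier_scope <- match.arg(outlier_scope)
  key <- interaction(specimens$group, specimens$muscle,
                     specimens$specimen_type, drop = TRUE)
  if (outlier_scope == "group") {
    fences <- tapply(specimens$tangent_modulus_kPa, specimens$group,
                     function(v) upper_iqr_filter(v)$fence)
  }
  out <- lapply(split(specimens, key), function(d) {
    pool <- sprintf("%s %s %s", d$group[1L], d$muscle[1L],
                    d$specimen_type[1L])
    n_raw <- nrow(d)
    if (n_raw < max(min_pool_n, 4L)) {
      return(data.frame(pool = pool, group = d$group[1L],
                        muscle = d$muscle[1L],
                        specimen_type = d$specimen_type[1L],
                        n_raw = n_raw, n_outliers_removed = NA_integer_,
                        slope = NA_real_, intercept = NA_real_,
                        r2 = NA_real_, p = NA_real_,
                        median_ratio = NA_real_, iqr_ratio = NA_real_,
                        wilcoxon_p = NA_real_,
                        slack_slope = NA_real_, slack_p = NA_real_,
                        skipped = TRUE,
                        skip_reason = sprintf("n = %d below minimum %d",
                                              n_raw, min_pool_n)))
    }
    if (outlier_scope == "pool") {
      filt <- upper_iqr_filter(d$tangent_modulus_kPa)
      keep <- d$tangent_modulus_kPa <= filt$fence
    } else {
      keep <- d$tangent_modulus_kPa <= fences[[as.character(d$group[1L])]]
    }
    kept <- d[keep, , drop = FALSE]
    reg <- ols_regression(kept$csa_mm2, kept$tangent_modulus_kPa)
    shp <- ratio_summary(kept$axis_ratio)
    ctl <- if (!is.null(kept$sl0_um)) {
      ols_regression(kept$csa_mm2, kept$sl0_um)
    } else {
      list(slope = NA_real_, p_value = NA_real_)
    }
    data.frame(pool = pool, group = d$group[1L], muscle = d$muscle[1L],
               specimen_type = d$specimen_type[1L],
               n_raw = n_raw, n_outliers_removed = sum(!keep),
               slope = reg$slope, intercept = reg$intercept,
               r2 = reg$r_squared, p = reg$p_value,
               median_ratio = shp$median_ratio,
               iqr_ratio = shp$iqr_ratio, wilcoxon_p = shp$wilcoxon_p,
               slack_slope = ctl$slope, slack_p = ctl$p_value,
               skipped = FALSE, skip_reason = "")
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d specimens in %d pools (seed %d)\n",
              nrow(x$specimens), nrow(x$pools), x$manifest$seed))
  print(x$pools[, c("pool", "n_raw", "n_outliers_removed", "slope", "r2",
                    "p", "median_ratio", "wilcoxon_p")], digits = 3)
  invisible(x)
}

#' Write pipeline outputs to disk
#'
#' Emits the per-pool CSV, the per-specimen CSV, one CSA-vs-modulus
#' scatter plot with fitted line per pool, and a box plot of axis ratios
#' across pools.
#'
#' @param result A `pipeline_result` from [run_pipeline()], or a list
#'   with `specimens` and `pools`.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(result, outdir) {
  if (is.null(result$pools) || !nrow(result$pools)) {
    stop("empty results: nothing to report")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  pool_csv <- file.path(outdir, "pool_results.csv")
  utils::write.csv(result$pools, pool_csv, row.names = FALSE)
  files <- c(files, pool_csv)
  spec_csv <- file.path(outdir, "specimen_results.csv")
  utils::write.csv(result$specimens, spec_csv, row.names = FALSE)
  files <- c(files, spec_csv)
  for (i in seq_len(nrow(result$pools))) {
    if (isTRUE(result$pools$skipped[i])) next
    p <- result$pools[i, ]
    d <- result$specimens[
      result$specimens$group == p$group &
        result$specimens$muscle == p$muscle &
        result$specimens$specimen_type == p$specimen_type, ]
    g <- ggplot2::ggplot(d, ggplot2::aes(x = .data$csa_mm2,
                                         y = .data$tangent_modulus_kPa)) +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::geom_abline(slope = p$slope, intercept = p$intercept,
                           color = "red") +
      ggplot2::labs(title = p$pool,
                    subtitle = sprintf("slope %.3g, R² %.2f, p %.3g",
                                       p$slope, p$r2, p$p),
                    x = "CSA (mm²)",
                    y = "tangent modulus at 30% strain (kPa)") +
      ggplot2::theme_minimal()
    f <- file.path(outdir, sprintf("scatter_%s.png",
                                   gsub("[^A-Za-z0-9]+", "_", p$pool)))
    ggplot2::ggsave(f, g, width = 5, height = 4, dpi = 120)
    files <- c(files, f)
  }
  g <- ggplot2::ggplot(result$specimens,
                       ggplot2::aes(x = interaction(.data$group, .data$muscle),
                                    y = .data$axis_ratio)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(~specimen_type) +
    ggplot2::labs(x = NULL, y = "major/minor axis ratio") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  f <- file.path(outdir, "axis_ratio_boxplot.png")
  ggplot2::ggsave(f, g, width = 6, height = 4, dpi = 120)
  files <- c(files, f)
  invisible(files)
}

#' Read a pipeline configuration from YAML
#'
#' Recognised blocks: `cohort:` (fields of [cohort_config()]),
#' `protocol:` ([stretch_protocol()]), `composite:`
#' ([composite_params()] plus `f_inf`/`c` for the ECM scaling), and
#' `stats:` (`eval_strain`, `min_pool_n`, `outlier_scope`).
#'
#' @param path YAML file path.
#' @return List with `config`, `protocol`, `comp`, `scaling`, `stats`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  config <- do.call(cohort_config, y$cohort %||% list())
  protocol <- do.call(stretch_protocol, y$protocol %||% list())
  comp_args <- y$composite %||% list()
  scal <- ecm_scaling_params(f_inf = comp_args$f_inf, c = comp_args$c)
  comp_args$f_inf <- NULL; comp_args$c <- NULL
  comp <- do.call(composite_params, comp_args)
  list(config = config, protocol = protocol, comp = comp, scaling = scal,
       stats = y$stats %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
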