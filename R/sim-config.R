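#' Simulation configuration for Infinium-450K-style data
#'
#' Bundles every parameter of the synthetic array generator: cohort sizes,
#' probe design mix, planted differential-methylation effects, the
#' beta-distribution shapes of the three baseline methylation states, and the
#' intensity/background model. Defaults reproduce the study conditions the
#' pipeline is calibrated against: 3 normal-colon (NC) and 8 ulcerative-colitis
#' (UC) samples plus one fully-methylated positive-control cell-line analog,
#' 20,000 probes, 250 planted hypermethylated CpGs at a target beta shift of
#' 0.3 and per-sample biological noise of sd 0.05.
#'
#' @param n_probes number of CpG probes on the synthetic array.
#' @param n_nc,n_uc number of normal-control and UC samples.
#' @param include_positive_control add one fully-methylated positive-control
#'   sample (colon-cancer cell-line analog, group `"POS"`).
#' @param frac_type2 fraction of probes with design type II (the 450K array is
#'   roughly 72\% type II).
#' @param n_planted_hyper,n_planted_hypo number of probes carrying a planted
#'   hyper-/hypomethylation effect in the UC group.
#' @param delta_planted target beta shift of planted probes, in (0,1).
#' @param baseline_beta_params named list of length-2 shape vectors for the
#'   low/intermediate/high baseline methylation states.
#' @param beta_sample_sd per-sample biological variation around the probe
#'   baseline beta (standard deviation, beta scale).
#' @param type2_compression scale `s` of the type-II distortion
#'   `beta' = 0.5 + s*(beta - 0.5)`; values below 1 compress type-II betas
#'   toward 0.5, the distortion BMIQ-style normalization must undo.
#' @param dye_log_sd sd of the per-sample lognormal dye/scanner scale factor
#'   applied multiplicatively to all intensities of a sample.
#' @param total_intensity_log_mean,total_intensity_log_sd lognormal parameters
#'   of the per-probe total intensity T (arbitrary fluorescence units).
#' @param background_mean,background_sd normal parameters of the additive
#'   optical background entering each channel (floored at 0).
#' @param n_negative_controls number of negative-control probes per sample.
#' @param seed integer seed; every draw of the generator flows from it.
#' @return an object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_probes = 20000,
                       n_nc = 3,
                       n_uc = 8,
                       include_positive_control = TRUE,
                       frac_type2 = 0.72,
                       n_planted_hyper = 250,
                       n_planted_hypo = 20,
                       delta_planted = 0.3,
                       baseline_beta_params = list(low = c(2, 18),
                                                   mid = c(5, 5),
                                                   high = c(18, 2)),
                       beta_sample_sd = 0.05,
                       type2_compression = 0.8,
                       dye_log_sd = 0.1,
                       total_intensity_log_mean = log(4000),
                       total_intensity_log_sd = 0.3,
                       background_mean = 200,
                       background_sd = 30,
                       n_negative_controls = 600,
                       seed) {
  if (missing(seed)) stop("sim_config: 'seed' is required", call. = FALSE)
  cfg <- list(n_probes = as.integer(n_probes), n_nc = as.integer(n_nc),
              n_uc = as.integer(n_uc),
              include_positive_control = isTRUE(include_positive_control),
              frac_type2 = frac_type2,
              n_planted_hyper = as.integer(n_planted_hyper),
              n_planted_hypo = as.integer(n_planted_hypo),
              delta_planted = delta_planted,
              baseline_beta_params = baseline_beta_params,
              beta_sample_sd = beta_sample_sd,
              type2_compression = type2_compression,
              dye_log_sd = dye_log_sd,
              total_intensity_log_mean = total_intensity_log_mean,
              total_intensity_log_sd = total_intensity_log_sd,
              background_mean = background_mean,
              background_sd = background_sd,
              n_negative_controls = as.integer(n_negative_controls),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_probes", "n_nc", "n_uc", "n_planted_hyper", "n_planted_hypo",
              "n_negative_controls")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0)
      stop(sprintf("sim_config: '%s' must be a nonnegative count", f),
           call. = FALSE)
  }
  if (cfg$delta_planted <= 0 || cfg$delta_planted >= 1)
    stop("sim_config: 'delta_planted' must lie in (0, 1)", call. = FALSE)
  if (cfg$frac_type2 < 0 || cfg$frac_type2 > 1)
    stop("sim_config: 'frac_type2' must lie in [0, 1]", call. = FALSE)
  if (cfg$n_planted_hyper + cfg$n_planted_hypo > cfg$n_probes)
    stop("sim_config: planted probes exceed n_probes", call. = FALSE)
  if (!is.list(cfg$baseline_beta_params) ||
      length(cfg$baseline_beta_params) != 3L ||
      !all(vapply(cfg$baseline_beta_params,
                  function(p) length(p) == 2L && all(p > 0), logical(1))))
    stop("sim_config: 'baseline_beta_params' must be 3 pairs of positive shapes",
         call. = FALSE)
  if (cfg$total_intensity_log_sd <= 0 || cfg$background_sd <= 0 ||
      !is.finite(cfg$total_intensity_log_mean))
    stop("sim_config: intensity parameters must be positive/finite",
         call. = FALSE)
  if (cfg$type2_compression <= 0 || cfg$type2_compression > 1)
    stop("sim_config: 'type2_compression' must lie in (0, 1]", call. = FALSE)
  invisible(cfg)
}

# Beta draw reparameterised by mean and sd. Variance is capped below the
# feasibility bound m(1-m); means are expected pre-clamped away from 0/1.
rbeta_meansd <- function(n, mean, sd) {
  v <- pmin(sd^2, 0.8 * mean * (1 - mean))
  k <- mean * (1 - mean) / v - 1
  stats::rbeta(n, mean * k, (1 - mean) * k)
}
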