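#' Background correction from negative controls
#'
#' Subtracts each sample's mean negative-control intensity from both channels
#' and floors at zero. Negative-control intensities themselves are retained
#' unchanged so detection p-values can still be computed downstream.
#'
#' @param signals a `signal_set` (matrices `M`, `U` probes x samples and
#'   `negatives` controls x samples).
#' @return a background-corrected `signal_set`.
#' @export
background_correct <- function(signals) {
  stopifnot(inherits(signals, "signal_set"))
  if (nrow(signals$negatives) == 0)
    stop("background_correct: no negative controls", call. = FALSE)
  b <- colMeans(signals$negatives)
  signals$M <- pmax(sweep(signals$M, 2, b), 0)
  signals$U <- pmax(sweep(signals$U, 2, b), 0)
  signals
}

#' Detection p-values against negative-control background
#'
#' A probe's total signal `M + U` is compared with a Gaussian fit to the
#' doubled negative-control intensities (background enters both channels):
#' `p = 1 - Phi((M + U - mu) / sigma)` with `mu`, `sigma` the mean and sd of
#' `2 * negatives` per sample. Small p means the probe is clearly above
#' background; p is monotone decreasing in total signal.
#'
#' @param signals a `signal_set` (use raw, not background-corrected,
#'   intensities).
#' @return probes x samples matrix of detection p-values in `[0,1]`.
#' @export
detection_pvalues <- function(signals) {
  stopifnot(inherits(signals, "signal_set"))
  if (nrow(signals$negatives) < 2)
    stop("detection_pvalues: need >= 2 negative controls", call. = FALSE)
  mu <- colMeans(2 * signals$negatives)
  sigma <- apply(2 * signals$negatives, 2, stats::sd)
  if (any(sigma == 0))
    stop("degenerate controls", call. = FALSE)
  total <- signals$M + signals$U
  p <- 1 - stats::pnorm(sweep(sweep(total, 2, mu), 2, sigma, "/"))
  pmin(pmax(p, 0), 1)
}

#' Call-rate QC over samples and probes
#'
#' Samples whose call rate (fraction of probes with detection p below
#' `p_cut`) falls under `call_rate_min` are dropped; probes failing the
#' detection threshold in any retained sample are excluded.
#'
#' @param detection probes x samples detection p-value matrix.
#' @param p_cut detection p-value threshold.
#' @param call_rate_min minimum per-sample call rate.
#' @return list with `kept_samples`, `kept_probes` (character vectors) and
#'   `report` (per-sample call rates, survivor counts).
#' @export
qc_samples_and_probes <- function(detection, p_cut = 0.05,
                                  call_rate_min = 0.99) {
  call_rate <- colMeans(detection < p_cut)
  kept_samples <- colnames(detection)[call_rate >= call_rate_min]
  if (length(kept_samples) == 0)
    stop("qc: all samples dropped", call. = FALSE)
  sub <- detection[, kept_samples, drop = FALSE]
  probe_ok <- rowSums(sub >= p_cut) == 0
  kept_probes <- rownames(detection)[probe_ok]
  report <- list(
    sample_call_rates = stats::setNames(call_rate, colnames(detection)),
    n_samples_in = ncol(detection),
    n_samples_kept = length(kept_samples),
    n_probes_in = nrow(detection),
    n_probes_kept = length(kept_probes),
    p_cut = p_cut, call_rate_min = call_rate_min)
  list(kept_samples = kept_samples, kept_probes = kept_probes,
       report = report)
}

#' Median dye/intensity scaling across samples
#'
#' Each sample's intensities (both channels and negatives) are multiplied by
#' `grand median total intensity / sample median total intensity`, equalizing
#' per-sample brightness. A deliberately simple stand-in for two-channel dye
#' bias modeling: the generator's dye distortion is a per-sample scale
#' factor, which this corrector removes exactly in expectation.
#'
#' @param signals a `signal_set`.
#' @return list with `signals` (rescaled) and `scale_factors` (per sample).
#' @export
dye_equalize <- function(signals) {
  stopifnot(inherits(signals, "signal_set"))
  med <- apply(signals$M + signals$U, 2, stats::median)
  if (any(med == 0))
    stop("dye_equalize: zero median total intensity", call. = FALSE)
  f <- stats::median(med) / med
  signals$M <- sweep(signals$M, 2, f, "*")
  signals$U <- sweep(signals$U, 2, f, "*")
  signals$negatives <- sweep(signals$negatives, 2, f, "*")
  list(signals = signals, scale_factors = stats::setNames(f, colnames(signals$M)))
}

#' Beta values from channel intensities
#'
#' `beta = M / (M + U + offset)`; the offset (default 100) is the standard
#' Infinium stabilizer guarding low-intensity probes.
#'
#' @param M,U intensity matrices or vectors (nonnegative).
#' @param offset stabilizing constant.
#' @return beta values in `[0,1]`, same shape as `M`.
#' @export
compute_beta <- function(M, U, offset = 100) {
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE))
    stop("compute_beta: negative intensities", call. = FALSE)
  M / (M + U + offset)
}

#' Run the full preprocessing chain
#'
#' background correction -> detection p-values (on raw signals) -> dye
#' scaling -> call-rate QC -> beta computation -> (optionally) BMIQ-style
#' normalization of type-II probes onto the type-I scale.
#'
#' @param signals raw `signal_set`.
#' @param manifest manifest data.frame (needed for BMIQ design types).
#' @param p_cut,call_rate_min QC thresholds.
#' @param offset beta offset.
#' @param bmiq run BMIQ-style normalization.
#' @param bmiq_seed seed for the EM fit subsampling.
#' @param ... passed to [bmiq_normalize()].
#' @return list with `betas` (QC'd, normalized beta matrix), `detection`,
#'   `qc` (QC report), `scale_factors`.
#' @export
preprocess_signals <- function(signals, manifest, p_cut = 0.05,
                               call_rate_min = 0.99, offset = 100,
                               bmiq = TRUE, bmiq_seed = 1L, ...) {
  detection <- detection_pvalues(signals)
  de <- dye_equalize(signals)
  bc <- background_correct(de$signals)
  qc <- qc_samples_and_probes(detection, p_cut, call_rate_min)
  M <- bc$M[qc$kept_probes, qc$kept_samples, drop = FALSE]
  U <- bc$U[qc$kept_probes, qc$kept_samples, drop = FALSE]
  betas <- compute_beta(M, U, offset)
  if (bmiq) {
    mf <- manifest[match(qc$kept_probes, manifest$probe_id), , drop = FALSE]
    betas <- bmiq_normalize(betas, mf, seed = bmiq_seed, ...)$betas
  }
  list(betas = betas, detection = detection, qc = qc$report,
       scale_factors = de$scale_factors)
}
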