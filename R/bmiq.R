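#' Fit a three-state beta mixture to beta values by EM
#'
#' Models a beta-value distribution as a mixture of three beta components —
#' unmethylated (U), hemimethylated (H) and methylated (M) states.
#' Responsibilities come from weighted beta densities; each M-step maximizes
#' the weighted beta log-likelihood per component (BFGS on log-shape
#' parameters, initialized by moment matching), so the observed-data
#' log-likelihood is non-decreasing. Components are relabeled so means
#' ascend. Initialization is moment matching on tertiles of the data.
#'
#' @param betas numeric vector of beta values; values are clamped to
#'   `[1e-6, 1 - 1e-6]` before fitting. At least 50 usable values required.
#' @param n_states number of components (the normalization assumes 3).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param seed integer seed used when `subsample` is smaller than the data.
#' @param subsample maximum number of values used for the EM fit (the fit is
#'   a density estimate; a 5000-value subsample is ample and keeps per-sample
#'   normalization fast). `Inf` fits on everything.
#' @return object of class `bmiq_fit`: `weights`, `shape1`, `shape2`,
#'   `means`, `boundaries` (beta cutpoints between adjacent states),
#'   `loglik` (trace), `converged`, `degenerate`.
#' @export
fit_beta_mixture <- function(betas, n_states = 3, max_iter = 500, tol = 1e-6,
                             seed = 1L, subsample = 5000) {
  x <- betas[is.finite(betas)]
  x <- pmin(pmax(x, 1e-6), 1 - 1e-6)
  if (length(x) < 50)
    stop("fit_beta_mixture: need >= 50 usable values", call. = FALSE)
  if (stats::sd(x) < 1e-8)
    stop("fit_beta_mixture: degenerate input (all values identical)",
         call. = FALSE)
  if (length(x) > subsample) {
    set.seed(as.integer(seed))
    x_fit <- sample(x, subsample)
  } else x_fit <- x
  K <- n_states
  lx <- log(x_fit); l1x <- log1p(-x_fit)
  n <- length(x_fit)

  mom_shapes <- function(m, v) {
    v <- max(min(v, 0.95 * m * (1 - m)), 1e-8)
    k <- m * (1 - m) / v - 1
    c(m * k, (1 - m) * k)
  }
  qs <- unique(stats::quantile(x_fit, probs = seq(0, 1, length.out = K + 1)))
  if (length(qs) < K + 1) {
    # heavy ties: fall back to fixed beta-scale breakpoints
    qs <- unique(c(0, 0.25, 0.75, 1))
  }
  lab <- cut(x_fit, breaks = qs, include.lowest = TRUE, labels = FALSE)
  sh <- t(vapply(split(x_fit, lab),
                 function(xx) mom_shapes(mean(xx), max(stats::var(xx), 1e-8)),
                 numeric(2)))
  if (nrow(sh) < K) sh <- sh[rep(seq_len(nrow(sh)), length.out = K), , drop = FALSE]
  w <- rep(1 / K, K)

  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(K),
                   function(k) w[k] * stats::dbeta(x_fit, sh[k, 1], sh[k, 2]),
                   numeric(n))
    rs <- pmax(rowSums(dens), .Machine$double.xmin)
    ll <- sum(log(rs))
    ll_trace <- c(ll_trace, ll)
    r <- dens / rs
    w <- colMeans(r)
    for (k in seq_len(K)) {
      rk <- r[, k]
      S <- sum(rk)
      if (S < 1e-8) next
      Slx <- sum(rk * lx); Sl1x <- sum(rk * l1x)
      m <- sum(rk * x_fit) / S
      v <- sum(rk * (x_fit - m)^2) / S
      nll <- function(p) {
        a <- exp(p[1]); b <- exp(p[2])
        -(S * (lgamma(a + b) - lgamma(a) - lgamma(b)) +
            (a - 1) * Slx + (b - 1) * Sl1x)
      }
      grad <- function(p) {
        a <- exp(p[1]); b <- exp(p[2])
        c(-(S * (digamma(a + b) - digamma(a)) + Slx) * a,
          -(S * (digamma(a + b) - digamma(b)) + Sl1x) * b)
      }
      o <- stats::optim(log(mom_shapes(m, v)), nll, grad, method = "BFGS")
      sh[k, ] <- exp(o$par)
    }
    if (is.finite(ll_old) && abs((ll - ll_old) / abs(ll_old)) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged)
    warning("fit_beta_mixture: EM reached max_iter without converging; ",
            "returning best-so-far fit")
  means <- sh[, 1] / rowSums(sh)
  ord <- order(means)
  w <- w[ord]; sh <- sh[ord, , drop = FALSE]; means <- means[ord]

  # state boundaries: posterior argmax crossings on a fine beta grid
  grid <- seq(1e-4, 1 - 1e-4, length.out = 2001)
  gd <- vapply(seq_len(K),
               function(k) w[k] * stats::dbeta(grid, sh[k, 1], sh[k, 2]),
               numeric(length(grid)))
  amax <- max.col(gd, ties.method = "first")
  boundaries <- vapply(seq_len(K - 1), function(k) {
    i <- which(amax[-length(amax)] <= k & amax[-1] > k)
    if (length(i) == 0) stats::qbeta((k) / K, 1, 1) else grid[i[1]]
  }, numeric(1))
  boundaries <- sort(boundaries)

  structure(list(weights = w, shape1 = sh[, 1], shape2 = sh[, 2],
                 means = means, boundaries = boundaries, loglik = ll_trace,
                 converged = converged, n_fit = n),
            class = "bmiq_fit")
}

#' BMIQ-style normalization of type-II probes onto the type-I scale
#'
#' Per sample: fit three-state beta mixtures to the type-I and type-II
#' beta distributions separately; assign each type-II probe to the U, H or M
#' state by its fitted state interval (posterior-argmax cutpoints, so
#' assignment is monotone in beta); map U-state and M-state type-II values
#' through the parametric quantile transform
#' `qbeta(pbeta(beta, shape_II), shape_I)` of the matching component, and
#' rescale the intermediate H state linearly onto the gap between the
#' transformed U and M boundaries so the overall map is continuous and
#' monotone. Type-I values pass through untouched; within-sample type-II
#' rank order is preserved; output stays in `[0,1]`.
#'
#' @param betas probes x samples beta matrix (rownames = probe ids).
#' @param manifest manifest aligned to `betas` (needs `probe_id`,
#'   `design_type`; both design types must be present).
#' @param seed,max_iter,tol,subsample EM options, see [fit_beta_mixture()].
#' @param min_state_n states with fewer assigned type-II probes than this are
#'   left untransformed (with a warning).
#' @return list with `betas` (normalized matrix) and `fits` (per-sample list
#'   of type-I/type-II `bmiq_fit` objects).
#' @export
bmiq_normalize <- function(betas, manifest, seed = 1L, max_iter = 500,
                           tol = 1e-6, subsample = 5000, min_state_n = 10) {
  mf <- manifest[match(rownames(betas), manifest$probe_id), , drop = FALSE]
  if (any(is.na(mf$probe_id)))
    stop("bmiq_normalize: manifest does not cover all probes", call. = FALSE)
  t1 <- mf$design_type == "I"
  t2 <- mf$design_type == "II"
  if (!any(t1) || !any(t2))
    stop("bmiq_normalize: both design types must be present", call. = FALSE)
  out <- betas
  fits <- vector("list", ncol(betas))
  names(fits) <- colnames(betas)
  for (j in seq_len(ncol(betas))) {
    b1 <- betas[t1, j]; b2 <- betas[t2, j]
    f1 <- fit_beta_mixture(b1, seed = seed + j, max_iter = max_iter,
                           tol = tol, subsample = subsample)
    f2 <- fit_beta_mixture(b2, seed = seed + j, max_iter = max_iter,
                           tol = tol, subsample = subsample)
    out[t2, j] <- bmiq_transform(b2, f2, f1, min_state_n = min_state_n)
    fits[[j]] <- list(type1 = f1, type2 = f2)
  }
  out <- pmin(pmax(out, 0), 1)
  list(betas = out, fits = fits)
}

# Map type-II betas onto the type-I scale given the two fitted mixtures.
bmiq_transform <- function(b2, f2, f1, min_state_n = 10) {
  x <- pmin(pmax(b2, 1e-6), 1 - 1e-6)
  cut2 <- f2$boundaries  # (U|H, H|M) cutpoints on the type-II scale
  state <- 1L + (x > cut2[1]) + (x > cut2[2])
  res <- x

  map_state <- function(v, k) {
    p <- stats::pbeta(v, f2$shape1[k], f2$shape2[k])
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    stats::qbeta(p, f1$shape1[k], f1$shape2[k])
  }
  nU <- sum(state == 1L); nH <- sum(state == 2L); nM <- sum(state == 3L)
  doU <- nU >= min_state_n; doM <- nM >= min_state_n
  if (!doU || !doM || nH > 0 && nH < min_state_n)
    warning("bmiq_transform: state with too few probes; transform skipped ",
            "for that state")
  if (doU) res[state == 1L] <- map_state(x[state == 1L], 1L)
  if (doM) res[state == 3L] <- map_state(x[state == 3L], 3L)
  if (nH > 0 && nH >= min_state_n) {
    # H state: linear map of the type-II H interval onto the gap between
    # the transformed state boundaries (continuity => monotonicity)
    lo2 <- cut2[1]; hi2 <- cut2[2]
    lo1 <- if (doU) map_state(lo2, 1L) else lo2
    hi1 <- if (doM) map_state(hi2, 3L) else hi2
    if (hi1 <= lo1) { lo1 <- lo2; hi1 <- hi2 }  # degenerate gap: identity
    h <- x[state == 2L]
    res[state == 2L] <- lo1 + (h - lo2) / (hi2 - lo2) * (hi1 - lo1)
  }
  res
}
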