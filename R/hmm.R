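#' Step lengths and chain segments from a fix series
#'
#' Computes consecutive step lengths for one fish and splits the series into
#' independent chain segments wherever the time gap between fixes exceeds
#' `max_gap` (default twice the burst interval); no imputation across gaps.
#'
#' @param fixes `data.frame` with `timestamp_s`, `x_m`, `y_m`, time-ordered.
#' @param burst_interval nominal burst interval in seconds.
#' @param max_gap gap (seconds) that breaks the chain (default
#'   `2 * burst_interval`).
#' @return list with `steps` (metres, one per retained consecutive pair),
#'   `seg_start` (1-based indices into `steps` where segments begin) and
#'   `fix_index` (row index of the first fix of each pair, for mapping
#'   posteriors back onto fixes).
#' @export
track_steps <- function(fixes, burst_interval = 30,
                        max_gap = 2 * burst_interval) {
  n <- nrow(fixes)
  if (n < 2) return(list(steps = numeric(0), seg_start = integer(0),
                         fix_index = integer(0)))
  dt <- diff(fixes$timestamp_s)
  d <- sqrt(diff(fixes$x_m)^2 + diff(fixes$y_m)^2)
  ok <- dt <= max_gap
  steps <- d[ok]
  fix_index <- which(ok)
  # a segment breaks where the previous retained pair is not contiguous
  brk <- c(TRUE, diff(fix_index) > 1)
  list(steps = pmax(steps, 1e-9),
       seg_start = which(brk),
       fix_index = fix_index)
}

#' Specification of the two-state activity HMM
#'
#' Inactive steps are pure positional noise: the distance between two
#' isotropic Gaussian position errors is Rayleigh with scale
#' `sigma_noise * sqrt(2)`. Active steps follow a gamma distribution. The
#' active state is identified as the one with the larger mean step.
#'
#' @param sigma_noise per-axis positional error SD, metres.
#' @param gamma_shape,gamma_scale active-state step-length gamma parameters.
#' @param trans 2 x 2 row-stochastic transition matrix
#'   (state 1 = inactive, 2 = active).
#' @param delta initial state distribution.
#' @return an object of class `hmm_spec`.
#' @export
hmm_spec <- function(sigma_noise = 0.2, gamma_shape = 2, gamma_scale = 3,
                     trans = matrix(c(0.95, 0.05, 0.10, 0.90), 2, 2,
                                    byrow = TRUE),
                     delta = c(0.5, 0.5)) {
  if (any(c(sigma_noise, gamma_shape, gamma_scale) <= 0)) {
    stop("emission parameters must be > 0", call. = FALSE)
  }
  if (any(abs(rowSums(trans) - 1) > 1e-8) || any(trans < 0)) {
    stop("trans must be row-stochastic", call. = FALSE)
  }
  if (abs(sum(delta) - 1) > 1e-8 || any(delta < 0)) {
    stop("delta must be a probability vector", call. = FALSE)
  }
  structure(list(sigma_noise = sigma_noise, gamma_shape = gamma_shape,
                 gamma_scale = gamma_scale, trans = trans, delta = delta),
            class = "hmm_spec")
}

# Rayleigh density with scale sigma.
drayleigh <- function(x, sigma) {
  ifelse(x >= 0, x / sigma^2 * exp(-x^2 / (2 * sigma^2)), 0)
}

# T x 2 emission density matrix for a spec.
emission_densities <- function(steps, spec) {
  cbind(drayleigh(steps, spec$sigma_noise * sqrt(2)),
        dgamma(steps, shape = spec$gamma_shape, scale = spec$gamma_scale))
}

#' Forward-backward posterior state probabilities
#'
#' Scaled forward-backward recursions (numerically stable) for the
#' two-state model; independent chain segments are re-initialized from the
#' initial distribution.
#'
#' @param steps step lengths, metres.
#' @param spec an [hmm_spec()].
#' @param seg_start 1-based segment start indices (default: one segment).
#' @return list with `loglik`, `posterior` (T x 2 matrix; column 2 is
#'   `p_active`), `xi` (summed expected transition counts) and `first`
#'   (summed posterior at segment starts).
#' @export
forward_backward <- function(steps, spec, seg_start = 1L) {
  stopifnot(inherits(spec, "hmm_spec"))
  dens <- emission_densities(steps, spec)
  forward_backward_cpp(dens, spec$trans, spec$delta, as.integer(seg_start))
}

#' Fit the two-state activity HMM by EM
#'
#' Baum-Welch estimation of the Rayleigh/gamma step-length mixture with
#' Markov switching. Runs several seeded random restarts and keeps the
#' best-likelihood solution; states are canonicalized afterwards so that
#' state 2 is the larger-mean-step ("active") state. The gamma shape update
#' solves the weighted maximum-likelihood equation by Newton iteration on
#' the log scale.
#'
#' @param steps step lengths in metres (see [track_steps()]).
#' @param seg_start segment start indices (default: one segment).
#' @param init optional [hmm_spec()] used as the first start.
#' @param n_restarts number of EM starts (default 5).
#' @param seed RNG seed for the restart draws.
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter maximum EM iterations per start (default 500).
#' @param sigma_noise_fixed if non-`NULL`, the positional-noise SD is held
#'   at this value instead of being estimated.
#' @return list of class `hmm_fit`: `spec` (estimated), `loglik`,
#'   `p_active` (posterior per step), `posterior` (T x 2), `n_iter`,
#'   `converged`, `loglik_trace`.
#' @export
fit_activity_hmm <- function(steps, seg_start = 1L, init = NULL,
                             n_restarts = 5, seed = 1L, tol = 1e-8,
                             max_iter = 500, sigma_noise_fixed = NULL) {
  steps <- as.numeric(steps)
  if (length(steps) < 2) stop("need at least 2 steps", call. = FALSE)
  if (length(steps) < 50) {
    warning("fewer than 50 steps: HMM estimates will be unstable")
  }
  if (stats::sd(steps) < .Machine$double.eps) {
    stop("all steps identical: degenerate fit", call. = FALSE)
  }
  seg_start <- as.integer(seg_start)

  starts <- list()
  if (!is.null(init)) starts[[1]] <- init
  med <- median(steps)
  qs <- quantile(steps, c(0.25, 0.9), names = FALSE)
  with_seed(sub_seed(seed, 17L), {
    while (length(starts) < n_restarts) {
      sn <- if (is.null(sigma_noise_fixed)) {
        qs[1] / sqrt(2) / sqrt(pi / 2) * runif(1, 0.5, 1.5)
      } else sigma_noise_fixed
      sh <- runif(1, 0.8, 3)
      sc <- max(qs[2], 2 * med) / sh * runif(1, 0.5, 1.5)
      p12 <- runif(1, 0.02, 0.3)
      p21 <- runif(1, 0.02, 0.3)
      starts[[length(starts) + 1L]] <- hmm_spec(
        sigma_noise = max(sn, 1e-4), gamma_shape = sh, gamma_scale = sc,
        trans = matrix(c(1 - p12, p12, p21, 1 - p21), 2, 2, byrow = TRUE),
        delta = c(0.5, 0.5)
      )
    }
  })

  best <- NULL
  for (st in starts) {
    fit <- em_run(steps, seg_start, st, tol, max_iter, sigma_noise_fixed)
    if (is.null(best) || (is.finite(fit$loglik) && fit$loglik > best$loglik)) {
      best <- fit
    }
  }
  if (!is.finite(best$loglik)) stop("non-finite likelihood", call. = FALSE)

  # canonical labels: state 2 ("active") has the larger mean step
  mean_inactive <- best$spec$sigma_noise * sqrt(2) * sqrt(pi / 2)
  mean_active <- best$spec$gamma_shape * best$spec$gamma_scale
  if (mean_active < mean_inactive) {
    warning("active state mean step below noise mean step; labels may be unreliable")
  }
  structure(
    list(spec = best$spec, loglik = best$loglik,
         p_active = best$posterior[, 2], posterior = best$posterior,
         n_iter = best$n_iter, converged = best$converged,
         loglik_trace = best$loglik_trace),
    class = "hmm_fit"
  )
}

em_run <- function(steps, seg_start, spec, tol, max_iter, sigma_noise_fixed) {
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  fb <- NULL
  it <- 0L
  for (it in seq_len(max_iter)) {
    fb <- tryCatch(
      forward_backward_cpp(emission_densities(steps, spec), spec$trans,
                           spec$delta, seg_start),
      error = function(e) NULL
    )
    if (is.null(fb) || !is.finite(fb$loglik)) {
      return(list(spec = spec, loglik = -Inf, posterior = NULL,
                  n_iter = it, converged = FALSE, loglik_trace = trace))
    }
    trace <- c(trace, fb$loglik)
    if (is.finite(ll_old) &&
        abs(fb$loglik - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- fb$loglik

    w <- fb$posterior
    # M-step: Rayleigh scale (closed form)
    if (is.null(sigma_noise_fixed)) {
      s2 <- sum(w[, 1] * steps^2) / (2 * sum(w[, 1]))
      sigma_noise <- sqrt(max(s2, 1e-12)) / sqrt(2)
    } else sigma_noise <- sigma_noise_fixed
    # gamma by weighted MLE (Newton on log-shape)
    ws <- sum(w[, 2])
    mbar <- sum(w[, 2] * steps) / ws
    lbar <- sum(w[, 2] * log(steps)) / ws
    sh <- gamma_shape_mle(log(mbar) - lbar, spec$gamma_shape)
    sc <- mbar / sh
    tr <- fb$xi / pmax(rowSums(fb$xi), 1e-300)
    delta <- fb$first / sum(fb$first)
    spec <- hmm_spec(sigma_noise = max(sigma_noise, 1e-6),
                     gamma_shape = max(sh, 1e-3),
                     gamma_scale = max(sc, 1e-9),
                     trans = tr, delta = delta)
  }
  list(spec = spec, loglik = ll_old, posterior = fb$posterior,
       n_iter = it, converged = converged, loglik_trace = trace)
}

# Solve log(k) - digamma(k) = s for k > 0 (weighted gamma MLE).
gamma_shape_mle <- function(s, k0 = 1) {
  if (!is.finite(s) || s <= 0) return(max(k0, 1e-3))
  k <- max((3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s), 1e-3)
  for (i in 1:50) {
    f <- log(k) - digamma(k) - s
    fp <- 1 / k - trigamma(k)
    k_new <- k - f / fp
    if (!is.finite(k_new) || k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < 1e-10 * (k + 1)) { k <- k_new; break }
    k <- k_new
  }
  k
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf(paste0("<hmm_fit> loglik %.3f after %d EM iterations (%s)\n",
                     "  noise sd %.3f m; active steps gamma(shape %.2f, scale %.2f), mean %.2f m\n",
                     "  P(inactive->active) %.3f, P(active->inactive) %.3f\n"),
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "not converged",
              x$spec$sigma_noise, x$spec$gamma_shape, x$spec$gamma_scale,
              x$spec$gamma_shape * x$spec$gamma_scale,
              x$spec$trans[1, 2], x$spec$trans[2, 1]))
  invisible(x)
}

#' Classify fixes as active
#'
#' @param p_active posterior activity probabilities (or an `hmm_fit`).
#' @param threshold classification threshold; a fix is active when
#'   `p_active >= threshold` (closed bound; default 0.75).
#' @param warn_unconverged warn when given an unconverged fit.
#' @return logical vector.
#' @export
classify_active <- function(p_active, threshold = 0.75,
                            warn_unconverged = TRUE) {
  if (inherits(p_active, "hmm_fit")) {
    if (warn_unconverged && !p_active$converged) {
      warning("classifying from an unconverged HMM fit")
    }
    p_active <- p_active$p_active
  }
  p_active >= threshold
}

#' Map per-step activity probabilities onto fixes
#'
#' The probability attached to a fix is that of the step starting at it
#' (the pair convention used by the speed filter); fixes without a
#' following retained step get `NA`.
#'
#' @param n_fixes number of fixes in the original series.
#' @param fit an `hmm_fit`.
#' @param step_info the [track_steps()] result used for the fit.
#' @return numeric vector of length `n_fixes`.
#' @export
p_active_per_fix <- function(n_fixes, fit, step_info) {
  out <- rep(NA_real_, n_fixes)
  out[step_info$fix_index] <- fit$p_active
  out
}
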