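#' Transform an activity response for modelling
#'
#' Instantaneous swimming speed is `log(y + 0.1)`-transformed to meet the
#' normality assumption of the mixed model; the other activity measures are
#' modelled on their natural scale.
#'
#' @param y response values.
#' @param measure one of `"a_day"`, `"u_max"`, `"u_inst"`, `"ar_day"`.
#' @return transformed response.
#' @export
transform_response <- function(y, measure = c("a_day", "u_max", "u_inst",
                                              "ar_day")) {
  measure <- match.arg(measure)
  if (measure != "u_inst") return(y)
  if (any(y <= -0.1, na.rm = TRUE)) {
    stop("u_inst values must exceed -0.1 for the log(y + 0.1) transform",
         call. = FALSE)
  }
  log(y + 0.1)
}

# -2 * (restricted) log-likelihood of the random-intercept model with
# fish-specific residual variances, with fixed effects profiled out by GLS.
# theta = c(log sigma_a, log sigma_j ...) (one sigma_j per fish, or a single
# one when homoscedastic). Returns the objective, or the full fit pieces.
hetlmm_obj <- function(theta, y, X, fishi, J, nj, homoscedastic, reml,
                       details = FALSE) {
  sigma_a2 <- exp(2 * theta[1])
  sigma_j <- if (homoscedastic) rep(exp(theta[2]), J) else exp(theta[-1])
  sigma_j2 <- sigma_j^2
  cj <- sigma_a2 / (sigma_j2 + nj * sigma_a2)          # per fish
  w_obs <- 1 / sigma_j2[fishi]                          # per observation

  S <- rowsum(X, fishi)                                 # J x p column sums
  A <- crossprod(X, X * w_obs) - crossprod(S, S * (cj / sigma_j2))
  sy <- as.vector(rowsum(y, fishi))
  b <- crossprod(X, y * w_obs) - crossprod(S, sy * (cj / sigma_j2))
  Ai <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ai)) return(if (details) NULL else 1e10)
  beta <- as.vector(Ai %*% b)
  e <- y - as.vector(X %*% beta)
  S1 <- as.vector(rowsum(e, fishi))
  S2 <- as.vector(rowsum(e^2, fishi))
  quad <- sum((S2 - cj * S1^2) / sigma_j2)
  logdet <- sum(nj * log(sigma_j2) + log1p(nj * sigma_a2 / sigma_j2))
  m2ll <- logdet + quad + length(y) * log(2 * pi)
  if (reml) m2ll <- m2ll + determinant(A, logarithm = TRUE)$modulus[1]
  if (!is.finite(m2ll)) return(if (details) NULL else 1e10)
  if (!details) return(m2ll)
  list(m2ll = m2ll, beta = beta, vcov_beta = Ai,
       sigma_a = sqrt(sigma_a2), sigma_j = sigma_j)
}

#' Random-intercept mixed model with fish-specific residual variances
#'
#' Fits `y = X beta + a_j + e_ij` with `a_j ~ N(0, sigma_a^2)` and
#' `e_ij ~ N(0, sigma_j^2)` varying by fish, by numerical maximization of
#' the (restricted) Gaussian log-likelihood over the log-scale variance
#' parameters, with the fixed effects profiled out by generalized least
#' squares at every evaluation. Several seeded starts guard against flat
#' likelihoods at small numbers of fish; a `sigma_a` boundary fit (near 0)
#' is reported, not an error.
#'
#' @param y numeric response.
#' @param fish factor (or coercible) identifying the fish of each
#'   observation.
#' @param X fixed-effects model matrix including the intercept column
#'   (default: intercept only).
#' @param method `"ML"` or `"REML"`.
#' @param homoscedastic force a single residual variance (the standard
#'   random-intercept model); used for closed-form cross-checks.
#' @param n_starts number of optimizer starts (default 3).
#' @param seed seed for the start jitter.
#' @return object of class `lmm_fit`: `beta` (with `se`), `vcov_beta`,
#'   `sigma_a`, `sigma_j` (named per fish), `icc` (per fish), `loglik`,
#'   `aic`, `n_par`, `method`, `converged`, plus bookkeeping (`fish_levels`,
#'   `nj`, `n_obs`).
#' @export
fit_hetlmm <- function(y, fish, X = NULL, method = c("ML", "REML"),
                       homoscedastic = FALSE, n_starts = 3, seed = 1L) {
  method <- match.arg(method)
  fish <- factor(fish)
  ok <- is.finite(y)
  if (!is.null(X)) ok <- ok & apply(as.matrix(X), 1, function(r) all(is.finite(r)))
  y <- y[ok]; fish <- droplevels(fish[ok])
  X <- if (is.null(X)) matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  else as.matrix(X)[ok, , drop = FALSE]
  fishi <- as.integer(fish)
  J <- nlevels(fish)
  nj <- as.vector(table(fishi))
  if (J < 2 || sum(nj >= 2) < 2) {
    stop("need at least 2 fish with at least 2 observations each", call. = FALSE)
  }
  if (any(nj == 1)) {
    warning(sprintf("%d fish have a single observation; their residual SD is weakly identified",
                    sum(nj == 1)))
  }
  reml <- method == "REML"

  scale_y <- sd(y)
  if (!is.finite(scale_y) || scale_y < 1e-12) {
    # degenerate: constant response
    p <- ncol(X)
    beta <- c(mean(y), rep(0, p - 1))
    fit <- list(beta = setNames(beta, colnames(X)),
                se = setNames(rep(0, p), colnames(X)),
                vcov_beta = matrix(0, p, p), sigma_a = 0,
                sigma_j = setNames(rep(0, J), levels(fish)),
                icc = setNames(rep(NA_real_, J), levels(fish)),
                loglik = Inf, aic = -Inf,
                n_par = p + if (homoscedastic) 2 else J + 1,
                method = method, converged = TRUE, degenerate = TRUE,
                fish_levels = levels(fish), nj = nj, n_obs = length(y))
    class(fit) <- "lmm_fit"
    return(fit)
  }

  # moment-based starting values from an OLS fit
  ols <- stats::lm.fit(X, y)
  r <- ols$residuals
  rbar <- as.vector(rowsum(r, fishi)) / nj
  s_within <- sqrt(pmax((as.vector(rowsum(r^2, fishi)) - nj * rbar^2) /
                          pmax(nj - 1, 1), (0.05 * scale_y)^2))
  s_a0 <- max(sd(rbar), 0.05 * scale_y)
  theta0 <- if (homoscedastic) c(log(s_a0), log(mean(s_within)))
  else c(log(s_a0), log(s_within))
  npar_var <- length(theta0)

  lower <- rep(log(1e-6 * scale_y), npar_var)
  upper <- rep(log(1e3 * scale_y), npar_var)
  lower[1] <- log(1e-8 * scale_y)   # allow sigma_a ~ 0 boundary fits

  best <- NULL
  jit <- with_seed(sub_seed(seed, 29L), {
    lapply(seq_len(max(n_starts, 1L)), function(k) {
      if (k == 1) rep(0, npar_var) else stats::rnorm(npar_var, 0, 0.5)
    })
  })
  for (k in seq_along(jit)) {
    par0 <- pmin(pmax(theta0 + jit[[k]], lower), upper)
    opt <- tryCatch(
      optim(par0, hetlmm_obj, y = y, X = X, fishi = fishi, J = J, nj = nj,
            homoscedastic = homoscedastic, reml = reml,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500, factr = 10, pgtol = 1e-10)),
      error = function(e) NULL
    )
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("mixed-model optimizer failed for every start", call. = FALSE)

  det <- hetlmm_obj(best$par, y, X, fishi, J, nj, homoscedastic, reml,
                    details = TRUE)
  if (is.null(det)) stop("mixed-model fit is singular at the optimum", call. = FALSE)
  p <- ncol(X)
  n_par <- p + npar_var
  loglik <- -det$m2ll / 2
  fit <- list(
    beta = setNames(det$beta, colnames(X)),
    se = setNames(sqrt(pmax(diag(det$vcov_beta), 0)), colnames(X)),
    vcov_beta = det$vcov_beta,
    sigma_a = det$sigma_a,
    sigma_j = setNames(det$sigma_j, levels(fish)),
    icc = setNames(det$sigma_a^2 / (det$sigma_a^2 + det$sigma_j^2),
                   levels(fish)),
    loglik = loglik,
    aic = -2 * loglik + 2 * n_par,
    n_par = n_par,
    method = method,
    converged = best$convergence == 0,
    degenerate = FALSE,
    fish_levels = levels(fish), nj = nj, n_obs = length(y)
  )
  class(fit) <- "lmm_fit"
  fit
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> %s, %d obs / %d fish; loglik %.3f, AIC %.2f (%d parameters)\n",
              x$method, x$n_obs, length(x$fish_levels), x$loglik, x$aic, x$n_par))
  est <- cbind(Estimate = x$beta, SE = x$se)
  print(round(est, 5))
  cat(sprintf("sigma_a = %.4g; sigma_j median %.4g (range %.4g-%.4g)\n",
              x$sigma_a, median(x$sigma_j), min(x$sigma_j), max(x$sigma_j)))
  cat(sprintf("ICC median %.3f (range %.3f-%.3f)\n",
              median(x$icc), min(x$icc), max(x$icc)))
  invisible(x)
}

#' Per-fish intraclass correlation of an lmm fit
#'
#' With fish-specific residual variances the repeatability differs between
#' fish: `ICC_j = sigma_a^2 / (sigma_a^2 + sigma_j^2)`.
#'
#' @param fit an [fit_hetlmm()] result.
#' @return list with `icc` (named per fish), `median`, `min`, `max`.
#' @export
lmm_icc <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  icc <- fit$sigma_a^2 / (fit$sigma_a^2 + fit$sigma_j^2)
  list(icc = icc, median = median(icc), min = min(icc), max = max(icc))
}

#' Likelihood-ratio test between nested lmm fits
#'
#' Both fits must use ML and share the variance structure; the statistic is
#' twice the log-likelihood difference, referred to a chi-squared
#' distribution with df equal to the difference in fixed-effect count.
#'
#' @param full,reduced `lmm_fit` objects.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
lmm_lrt <- function(full, reduced) {
  stopifnot(inherits(full, "lmm_fit"), inherits(reduced, "lmm_fit"))
  if (full$method != "ML" || reduced$method != "ML") {
    warning("likelihood-ratio tests should compare ML fits")
  }
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  df <- full$n_par - reduced$n_par
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Model selection over candidate explanatory variables
#'
#' For one activity measure, fits the intercept-only model (M0), the fork
#' length model (M1, `+FL`) and one model per candidate fish-level
#' explanatory variable (M1a..., `+FL+X`), each with the fish-specific
#' residual-variance structure, using maximum likelihood. Reports per-term
#' likelihood-ratio p-values (FL tested as M1 vs M0; each X as M1x vs M1)
#' and the AIC difference to the best model, then refits the selected model
#' with REML for reported estimates and per-fish ICCs.
#'
#' @param data per-observation `data.frame` with columns `y` (already
#'   transformed as appropriate), `fish`, `FL`, and one column per
#'   candidate (fish-level covariates).
#' @param candidates covariate column names to try (default
#'   `c("FR","SMR","MMR","AMS","MET1","MET2","MET3")`).
#' @param n_starts,seed passed to [fit_hetlmm()].
#' @return list of class `lmm_selection`: `table` (per model: label, focal
#'   term, LRT p-value, AIC, delta AIC), `best` (model label),
#'   `best_fit` (REML refit), `icc` (per-fish ICC summary of the best
#'   model), `fits` (the ML fits).
#' @export
model_select <- function(data,
                         candidates = c("FR", "SMR", "MMR", "AMS",
                                        "MET1", "MET2", "MET3"),
                         n_starts = 3, seed = 1L) {
  stopifnot(all(c("y", "fish", "FL") %in% names(data)))
  candidates <- intersect(candidates, names(data))
  mkX <- function(vars) {
    X <- cbind(`(Intercept)` = rep(1, nrow(data)))
    for (v in vars) X <- cbind(X, setNames(data.frame(data[[v]]), v))
    as.matrix(X)
  }
  safe_fit <- function(vars, method) {
    tryCatch(fit_hetlmm(data$y, data$fish, mkX(vars), method = method,
                        n_starts = n_starts, seed = seed),
             error = function(e) NULL)
  }
  fits <- list(M0 = safe_fit(character(0), "ML"),
               M1 = safe_fit("FL", "ML"))
  labels <- c()
  for (i in seq_along(candidates)) {
    lab <- paste0("M1", letters[i])
    fits[[lab]] <- safe_fit(c("FL", candidates[i]), "ML")
    labels <- c(labels, lab)
  }
  rows <- list()
  aics <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$aic, 0)
  for (nm in names(fits)) {
    f <- fits[[nm]]
    term <- if (nm == "M0") NA_character_
    else if (nm == "M1") "FL"
    else candidates[match(nm, labels)]
    p <- NA_real_
    if (!is.null(f)) {
      ref <- if (nm == "M1") fits$M0 else if (nm %in% labels) fits$M1 else NULL
      if (!is.null(ref)) p <- lmm_lrt(f, ref)$p_value
    }
    rows[[nm]] <- data.frame(model = nm, term = term, p_value = p,
                             aic = aics[[nm]], stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$delta_aic <- tab$aic - min(tab$aic, na.rm = TRUE)
  rownames(tab) <- NULL
  best <- tab$model[which.min(tab$aic)]
  best_vars <- if (best == "M0") character(0)
  else if (best == "M1") "FL"
  else c("FL", candidates[match(best, labels)])
  best_fit <- safe_fit(best_vars, "REML")
  out <- list(table = tab, best = best, best_fit = best_fit,
              icc = if (!is.null(best_fit)) lmm_icc(best_fit) else NULL,
              fits = fits)
  class(out) <- "lmm_selection"
  out
}

#' @export
print.lmm_selection <- function(x, ...) {
  cat("<lmm_selection>\n")
  print(transform(x$table,
                  p_value = signif(p_value, 3),
                  aic = round(aic, 2),
                  delta_aic = round(delta_aic, 2)))
  cat(sprintf("selected: %s\n", x$best))
  invisible(x)
}
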