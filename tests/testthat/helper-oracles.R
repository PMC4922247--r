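# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Exhaustive-path HMM posteriors: enumerate all 2^T state sequences and
# marginalize. dens is a T x 2 matrix of emission densities.
enum_posteriors <- function(dens, trans, delta) {
  T_ <- nrow(dens)
  paths <- as.matrix(expand.grid(rep(list(1:2), T_)))
  probs <- apply(paths, 1, function(s) {
    p <- delta[s[1]] * dens[1, s[1]]
    if (T_ > 1) {
      for (t in 2:T_) p <- p * trans[s[t - 1], s[t]] * dens[t, s[t]]
    }
    p
  })
  z <- sum(probs)
  post <- sapply(1:T_, function(t) sum(probs[paths[, t] == 2]) / z)
  list(loglik = log(z), p_active = post)
}

# Rayleigh / gamma densities matching the model's emission families.
oracle_densities <- function(steps, sigma_noise, shape, scale) {
  cbind(steps / (2 * sigma_noise^2) * exp(-steps^2 / (4 * sigma_noise^2)),
        dgamma(steps, shape = shape, scale = scale))
}

# Monte-Carlo estimate of the buffered-polyline area: sample points over the
# bounding box and test distance to the nearest segment. Returns the
# estimate and its standard error.
mc_buffer_area <- function(x, y, r, n_pts = 1e6, seed = 42) {
  set.seed(seed)
  xmin <- min(x) - r; xmax <- max(x) + r
  ymin <- min(y) - r; ymax <- max(y) + r
  px <- runif(n_pts, xmin, xmax)
  py <- runif(n_pts, ymin, ymax)
  d2 <- rep(Inf, n_pts)
  nseg <- max(1, length(x) - 1)
  for (i in seq_len(nseg)) {
    x1 <- x[i]; y1 <- y[i]
    x2 <- x[min(i + 1, length(x))]; y2 <- y[min(i + 1, length(y))]
    dx <- x2 - x1; dy <- y2 - y1
    l2 <- dx^2 + dy^2
    t <- if (l2 > 0) pmin(pmax(((px - x1) * dx + (py - y1) * dy) / l2, 0), 1) else 0
    d2 <- pmin(d2, (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
  }
  p <- mean(d2 <= r^2)
  box <- (xmax - xmin) * (ymax - ymin)
  list(area = p * box, se = box * sqrt(p * (1 - p) / n_pts))
}

# A small, fast simulation configuration shared by several tests.
quick_config <- function(seed = 1, ...) {
  sim_config(n_fish = 4, seed = seed, n_days_track = 1, sample_period = 10,
             ...)
}

# Simulate directly from the heteroscedastic random-intercept model.
sim_lmm_data <- function(J = 16, n = 12, alpha = -954.1, beta_fl = 8.7,
                         sigma_a = 132, sigma_j = NULL, seed = 1) {
  set.seed(seed)
  fl <- rnorm(J, 16.4, 1.4)
  if (is.null(sigma_j)) sigma_j <- exp(rnorm(J, log(185), 0.5))
  a <- rnorm(J, 0, sigma_a)
  fish <- rep(seq_len(J), each = n)
  y <- alpha + beta_fl * fl[fish] + a[fish] + rnorm(J * n, 0, sigma_j[fish])
  list(data = data.frame(y = y, fish = factor(fish), FL = fl[fish]),
       fl = fl, sigma_j = sigma_j, sigma_a = sigma_a, beta_fl = beta_fl,
       alpha = alpha)
}
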