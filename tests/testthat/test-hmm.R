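test_that("forward-backward equals exhaustive path enumeration", {
  set.seed(11)
  spec <- hmm_spec(sigma_noise = 0.2, gamma_shape = 2, gamma_scale = 3,
                   trans = matrix(c(0.9, 0.1, 0.25, 0.75), 2, 2, byrow = TRUE),
                   delta = c(0.6, 0.4))
  for (T_ in c(1, 2, 5, 12)) {
    steps <- c(abs(rnorm(ceiling(T_ / 2), 0, 0.3)),
               rgamma(floor(T_ / 2), 2, scale = 3))[1:T_]
    fb <- forward_backward(steps, spec)
    oracle <- enum_posteriors(
      oracle_densities(steps, 0.2, 2, 3), spec$trans, spec$delta
    )
    expect_equal(fb$loglik, oracle$loglik, tolerance = 1e-10)
    expect_equal(unname(fb$posterior[, 2]), oracle$p_active, tolerance = 1e-10)
    expect_equal(rowSums(fb$posterior), rep(1, T_), tolerance = 1e-12)
  }
})

test_that("segmented chains factorize over independent segments", {
  set.seed(12)
  spec <- hmm_spec()
  s1 <- rgamma(6, 2, scale = 3)
  s2 <- abs(rnorm(5, 0, 0.3))
  joint <- forward_backward(c(s1, s2), spec, seg_start = c(1L, 7L))
  f1 <- forward_backward(s1, spec)
  f2 <- forward_backward(s2, spec)
  expect_equal(joint$loglik, f1$loglik + f2$loglik, tolerance = 1e-10)
  expect_equal(joint$posterior, rbind(f1$posterior, f2$posterior),
               tolerance = 1e-12)
})

test_that("an absorbing inactive chain yields zero activity posteriors", {
  spec <- hmm_spec(trans = diag(2), delta = c(1, 0))
  fb <- forward_backward(abs(rnorm(20, 0, 0.3)), spec)
  expect_equal(unname(fb$posterior[, 2]), rep(0, 20))
})

test_that("EM log-likelihood is monotone and states are recovered", {
  # well-separated synthetic regime: noise steps ~0.25 m, active ~6 m
  cfg <- sim_config(n_fish = 1, seed = 14, n_days_track = 2,
                    dropout_prob = 0.03)
  ph <- generate_cohort(cfg)[1, ]
  ph$mean_active_speed <- 0.2            # 6 m mean step at 30 s
  ph$activity_propensity <- 0.05
  tk <- simulate_track(ph, cfg)
  st <- track_steps(tk, cfg$burst_interval)
  fit <- fit_activity_hmm(st$steps, st$seg_start, n_restarts = 3, seed = 2)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  expect_true(all(fit$p_active >= 0 & fit$p_active <= 1))
  # state recovery against the simulator's hidden truth (state of the
  # fix at the end of each step, which generated the displacement)
  truth_active <- tk$true_state[st$fix_index + 1L] == 2L
  acc <- mean((fit$p_active >= 0.5) == truth_active)
  expect_gte(acc, 0.95)
  # active state canonicalized as the larger mean step
  expect_gt(fit$spec$gamma_shape * fit$spec$gamma_scale,
            fit$spec$sigma_noise * sqrt(2) * sqrt(pi / 2))
})

test_that("classification threshold is closed at 0.75", {
  expect_identical(classify_active(c(0.75, 0.5, 0.749999, 0.76)),
                   c(TRUE, FALSE, FALSE, TRUE))
})

test_that("classified activity fraction approaches the chain's stationary rate", {
  cfg <- sim_config(n_fish = 1, seed = 15, n_days_track = 4,
                    dropout_prob = 0)
  ph <- generate_cohort(cfg)[1, ]
  ph$mean_active_speed <- 0.2
  ph$activity_propensity <- 0.04
  tk <- simulate_track(ph, cfg)
  st <- track_steps(tk, cfg$burst_interval)
  fit <- fit_activity_hmm(st$steps, st$seg_start, n_restarts = 3, seed = 3)
  p_stat <- 0.04 / (0.04 + cfg$prob_become_inactive)
  frac <- mean(fit$p_active >= 0.5)
  expect_lt(abs(frac - p_stat), 0.05)
})

test_that("transition probabilities are recovered across simulated tracks", {
  cfg <- sim_config(n_fish = 20, seed = 16, n_days_track = 1,
                    dropout_prob = 0.03)
  co <- generate_cohort(cfg)
  co$mean_active_speed <- pmax(co$mean_active_speed, 0.15)
  err_active <- err_inactive <- numeric(nrow(co))
  for (i in seq_len(nrow(co))) {
    tk <- simulate_track(co[i, ], cfg)
    st <- track_steps(tk, cfg$burst_interval)
    fit <- fit_activity_hmm(st$steps, st$seg_start, n_restarts = 2,
                            seed = 100 + i)
    err_active[i] <- fit$spec$trans[1, 2] - co$activity_propensity[i]
    err_inactive[i] <- fit$spec$trans[2, 1] - cfg$prob_become_inactive
  }
  expect_lt(abs(median(err_active)), 0.05)
  expect_lt(abs(median(err_inactive)), 0.05)
})

test_that("degenerate inputs raise errors and short series warn", {
  expect_error(fit_activity_hmm(rep(1, 100)), "identical")
  expect_warning(
    try(fit_activity_hmm(c(rgamma(20, 2, 1), abs(rnorm(20, 0, 0.1))),
                         n_restarts = 1), silent = TRUE),
    "fewer than 50"
  )
})

test_that("step segmentation splits at gaps and maps back to fixes", {
  fx <- data.frame(timestamp_s = c(0, 30, 60, 180, 210, 240),
                   x_m = c(0, 1, 2, 3, 4, 5), y_m = 0)
  st <- track_steps(fx, 30)
  # the 120 s gap (fix 3 -> 4) breaks the chain
  expect_equal(st$fix_index, c(1L, 2L, 4L, 5L))
  expect_equal(st$seg_start, c(1L, 3L))
  pa <- p_active_per_fix(6, list(p_active = c(0.1, 0.2, 0.3, 0.4)), st)
  expect_equal(pa, c(0.1, 0.2, NA, 0.3, 0.4, NA))
})
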