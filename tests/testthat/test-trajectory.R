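test_that("window filter applies the closed/open day bounds", {
  fx <- data.frame(timestamp_s = c(6.9, 7.0, 18.999, 19.0) * 86400)
  out <- filter_window(fx, release_time = 0)
  expect_equal(out$timestamp_s / 86400, c(7.0, 18.999))
  # 19 days of continuous fixes reduce to exactly 12 calendar-day groups
  fx2 <- data.frame(timestamp_s = seq(0, 19 * 86400 - 30, by = 30))
  kept <- filter_window(fx2, release_time = 0)
  expect_equal(length(unique(assign_days(kept$timestamp_s))), 12)
  expect_warning(filter_window(data.frame(timestamp_s = 1), 0), "no fixes")
})

test_that("daily distance sums consecutive Euclidean steps", {
  expect_equal(daily_distance(c(0, 3, 3), c(0, 4, 4)), 5)
  expect_true(is.na(daily_distance(1, 1)))
  # straight line at constant speed for a day
  v <- 0.2; dt <- 30
  t <- seq(0, 86400 - dt, by = dt)
  expect_equal(daily_distance(v * t, rep(0, length(t))),
               v * (86400 - dt), tolerance = 1e-9)
})

test_that("instantaneous speeds apply resolution and activity filters", {
  fx <- data.frame(timestamp_s = c(0, 30, 90, 120, 150),
                   x_m = c(0, 15, 15, 21, 24), y_m = 0)
  pa <- c(0.9, 0.74, 0.75, 0.9, 0.2)
  sp <- instantaneous_speeds(fx, pa)
  # pair 1: 30 s, 15 m, p 0.9 -> 0.5; pair 2: 60 s gap -> dropped;
  # pair 3: p 0.75 boundary -> kept; pair 4: p 0.9 -> kept
  expect_equal(sp$u_inst, c(0.5, 0.2, 0.1))
  expect_equal(sp$timestamp_s, c(0, 90, 120))
  # u_inst invariant to swapping axes
  fx2 <- fx; fx2$x_m <- fx$y_m; fx2$y_m <- fx$x_m
  expect_equal(instantaneous_speeds(fx2, pa)$u_inst, sp$u_inst)
})

test_that("daily max speed matches a brute-force oracle", {
  expect_equal(daily_max_speed(c(0.2, 0.5, 0.3)), 0.5)
  expect_true(is.na(daily_max_speed(numeric(0))))
  set.seed(7)
  n <- 200
  ts <- cumsum(sample(c(30, 30, 30, 60), n, replace = TRUE))
  fx <- data.frame(timestamp_s = ts, x_m = cumsum(rnorm(n)),
                   y_m = cumsum(rnorm(n)))
  pa <- runif(n)
  sp <- instantaneous_speeds(fx, pa)
  # oracle: direct loop over pairs
  umax <- -Inf
  for (i in 1:(n - 1)) {
    dt <- ts[i + 1] - ts[i]
    if (abs(dt - 30) <= 1 && pa[i] >= 0.75) {
      d <- sqrt((fx$x_m[i + 1] - fx$x_m[i])^2 + (fx$y_m[i + 1] - fx$y_m[i])^2)
      umax <- max(umax, d / dt)
    }
  }
  expect_equal(daily_max_speed(sp$u_inst), umax)
})

test_that("daily area matches closed forms for disc and stadium", {
  expect_equal(daily_area(5, 5, radius = 0.5), pi * 0.25, tolerance = 1e-3)
  a <- daily_area(c(0, 10), c(0, 0), radius = 0.5)
  expect_equal(a, 10 + pi * 0.25, tolerance = 1e-3 * (10 + pi * 0.25))
  # accuracy well under 0.1 percent on the stadium
  expect_lt(abs(a - (10 + pi * 0.25)) / (10 + pi * 0.25), 1e-3)
})

test_that("daily area matches a Monte-Carlo oracle on irregular polylines", {
  set.seed(8)
  x <- cumsum(rnorm(15, 0, 2)); y <- cumsum(rnorm(15, 0, 2))
  a <- daily_area(x, y, radius = 0.5)
  mc <- mc_buffer_area(x, y, 0.5, n_pts = 2e5)
  expect_lt(abs(a - mc$area), 3 * mc$se)
})

test_that("daily area is rigid-motion invariant, monotone in radius, subadditive", {
  set.seed(9)
  x <- cumsum(rnorm(8)); y <- cumsum(rnorm(8))
  a0 <- daily_area(x, y, 0.5)
  th <- 0.7
  xr <- cos(th) * x - sin(th) * y + 12
  yr <- sin(th) * x + cos(th) * y - 5
  expect_equal(daily_area(xr, yr, 0.5), a0, tolerance = 2e-3 * a0)
  expect_gt(daily_area(x, y, 0.8), a0)
  seg_sum <- sum(vapply(seq_len(length(x) - 1), function(i) {
    L <- sqrt(diff(x[i:(i + 1)])^2 + diff(y[i:(i + 1)])^2)
    L + pi * 0.25
  }, 0))
  expect_lte(a0, seg_sum * (1 + 1e-6))
})

test_that("per-fish-day metrics assemble with midnight day anchoring", {
  # two days of a fix every 30 s along a line, all active
  dt <- 30
  ts <- seq(7 * 86400, 9 * 86400 - dt, by = dt)
  fx <- data.frame(fish_id = "F01", timestamp_s = ts,
                   x_m = 0.3 * seq_along(ts), y_m = 0)
  pa <- rep(1, nrow(fx))
  am <- activity_metrics(fx, pa, release_time = 0)
  expect_equal(nrow(am$daily), 2)
  expect_equal(am$daily$day, c(7, 8))
  expect_equal(am$daily$a_day, rep(0.3 * (86400 / dt - 1), 2),
               tolerance = 1e-9)
  expect_equal(am$daily$u_max, rep(0.01, 2), tolerance = 1e-12)
  # u_inst pairs straddling midnight belong to the first fix's day
  expect_equal(sum(am$u_inst$day == 7), 86400 / dt)
  # noisy-step positive bias: with positional noise the summed daily
  # distance exceeds the true path length
  set.seed(10)
  fxn <- fx
  fxn$x_m <- fx$x_m + rnorm(nrow(fx), 0, 0.2)
  fxn$y_m <- fx$y_m + rnorm(nrow(fx), 0, 0.2)
  amn <- activity_metrics(fxn, pa, release_time = 0)
  expect_true(all(amn$daily$a_day > am$daily$a_day))
})

test_that("a_day is time-translation invariant", {
  ts <- seq(7 * 86400, 8 * 86400 - 30, by = 30)
  fx <- data.frame(fish_id = "F", timestamp_s = ts,
                   x_m = cumsum(rep(0.5, length(ts))), y_m = 0)
  pa <- rep(1, nrow(fx))
  a1 <- activity_metrics(fx, pa, release_time = 0)$daily$a_day
  fx2 <- fx; fx2$timestamp_s <- fx$timestamp_s + 86400 * 3
  a2 <- activity_metrics(fx2, pa, release_time = 3 * 86400)$daily$a_day
  expect_equal(a1, a2)
})
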