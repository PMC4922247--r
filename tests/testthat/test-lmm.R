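test_that("response transform applies only to instantaneous speed", {
  expect_equal(transform_response(0.9, "u_inst"), 0)
  expect_equal(transform_response(c(1, 2, 3), "a_day"), c(1, 2, 3))
  u <- c(0.01, 0.4, 1.2)
  expect_equal(exp(transform_response(u, "u_inst")) - 0.1, u,
               tolerance = 1e-12)
  expect_error(transform_response(-0.2, "u_inst"), "-0.1")
})

test_that("balanced equal-variance fits match closed-form ANOVA solutions", {
  set.seed(21)
  J <- 10; n <- 8
  fish <- factor(rep(seq_len(J), each = n))
  y <- rep(rnorm(J, 50, 3), each = n) + rnorm(J * n, 0, 2)
  ybar_j <- tapply(y, fish, mean)
  ssw <- sum((y - ybar_j[fish])^2)
  ssb <- n * sum((ybar_j - mean(y))^2)
  # ML closed form
  se2_ml <- ssw / (J * (n - 1))
  sa2_ml <- max(0, ssb / J - se2_ml) / n
  fml <- fit_hetlmm(y, fish, method = "ML", homoscedastic = TRUE)
  expect_equal(fml$sigma_a^2, sa2_ml, tolerance = 1e-6)
  expect_equal(unname(fml$sigma_j[1]^2), se2_ml, tolerance = 1e-6)
  expect_equal(unname(fml$beta[1]), mean(y), tolerance = 1e-8)
  # REML closed form
  sa2_reml <- max(0, ssb / (J - 1) - se2_ml) / n
  freml <- fit_hetlmm(y, fish, method = "REML", homoscedastic = TRUE)
  expect_equal(freml$sigma_a^2, sa2_reml, tolerance = 1e-6)
})

test_that("heteroscedastic ML fit agrees with an independent implementation", {
  skip_if_not_installed("nlme")
  sim <- sim_lmm_data(J = 8, n = 10, seed = 22)
  d <- sim$data
  ours <- fit_hetlmm(d$y, d$fish, cbind(1, FL = d$FL), method = "ML")
  m <- nlme::lme(y ~ FL, random = ~1 | fish,
                 weights = nlme::varIdent(form = ~1 | fish), data = d,
                 method = "ML",
                 control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                            msMaxIter = 200))
  expect_equal(ours$loglik, as.numeric(logLik(m)), tolerance = 1e-4)
  expect_equal(unname(ours$beta), unname(nlme::fixef(m)), tolerance = 1e-3)
})

test_that("constant responses collapse to the degenerate fit", {
  fish <- factor(rep(1:4, each = 5))
  f <- fit_hetlmm(rep(7, 20), fish, cbind(1, FL = rep(c(14, 15, 16, 17),
                                                      each = 5)))
  expect_equal(unname(f$beta), c(7, 0))
  expect_equal(f$sigma_a, 0)
})

test_that("per-fish ICC follows its defining formula and bounds", {
  sim <- sim_lmm_data(J = 6, n = 8, seed = 23)
  f <- fit_hetlmm(sim$data$y, sim$data$fish, method = "ML")
  icc <- lmm_icc(f)
  expect_equal(unname(icc$icc),
               unname(f$sigma_a^2 / (f$sigma_a^2 + f$sigma_j^2)))
  expect_true(all(icc$icc >= 0 & icc$icc <= 1))
  # symmetric case sigma_a = sigma_j -> 0.5; sigma_a = 0 -> 0
  expect_equal(100^2 / (100^2 + 100^2), 0.5)
  # monotone decreasing in sigma_j at fixed sigma_a
  expect_true(all(diff(130^2 / (130^2 + c(50, 100, 200, 400)^2)) < 0))
})

test_that("ICCs are recovered at known variance components", {
  # sigma_a = 100; half the fish at sigma_j = 50 (ICC 0.8), half at 200 (0.2)
  set.seed(24)
  reps <- 12
  icc_lo <- icc_hi <- matrix(NA_real_, reps, 8)
  for (r in seq_len(reps)) {
    sim <- sim_lmm_data(J = 16, n = 12, sigma_a = 100,
                        sigma_j = rep(c(50, 200), each = 8), seed = 300 + r)
    f <- fit_hetlmm(sim$data$y, sim$data$fish, cbind(1, FL = sim$data$FL),
                    method = "REML", n_starts = 2)
    icc_lo[r, ] <- f$icc[1:8]    # sigma_j = 50 fish
    icc_hi[r, ] <- f$icc[9:16]   # sigma_j = 200 fish
  }
  expect_lt(abs(median(icc_lo) - 100^2 / (100^2 + 50^2)), 0.1)
  expect_lt(abs(median(icc_hi) - 100^2 / (100^2 + 200^2)), 0.1)
})

test_that("model selection respects likelihood nesting and selects a true effect", {
  set.seed(25)
  J <- 16; n <- 10
  fl <- rnorm(J, 16.4, 1.4)
  fr <- rnorm(J, 5.9, 0.3)
  x_null <- rnorm(J)
  sj <- exp(rnorm(J, log(120), 0.4))
  a <- rnorm(J, 0, 100)
  fish <- rep(seq_len(J), each = n)
  y <- -900 + 9 * fl[fish] + 250 * fr[fish] + a[fish] +
    rnorm(J * n, 0, sj[fish])
  d <- data.frame(y = y, fish = factor(fish), FL = fl[fish],
                  FR = fr[fish], XN = x_null[fish])
  sel <- model_select(d, candidates = c("FR", "XN"), n_starts = 2)
  lls <- vapply(sel$fits, function(f) f$loglik, 0)
  # nesting: each larger model's ML loglik weakly dominates
  expect_gte(lls[["M1"]] + 1e-6, lls[["M0"]])
  expect_gte(lls[["M1a"]] + 1e-6, lls[["M1"]])
  expect_gte(lls[["M1b"]] + 1e-6, lls[["M1"]])
  # the true FR effect wins the AIC comparison
  expect_equal(sel$best, "M1a")
  expect_lt(sel$table$p_value[sel$table$model == "M1a"], 0.05)
  expect_equal(sel$table$delta_aic[sel$table$model == "M1a"], 0)
  expect_s3_class(sel$best_fit, "lmm_fit")
  expect_identical(sel$best_fit$method, "REML")
  # LRT statistic definition
  lrt <- lmm_lrt(sel$fits$M1a, sel$fits$M1)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$statistic, 2 * (lls[["M1a"]] - lls[["M1"]]),
               tolerance = 1e-10)
  expect_equal(lrt$df, 1)
})

test_that("single-observation fish are allowed but flagged", {
  sim <- sim_lmm_data(J = 6, n = 4, seed = 26)
  d <- sim$data[-(1:3), ]  # fish 1 keeps a single observation
  expect_warning(f <- fit_hetlmm(d$y, d$fish, method = "ML"),
                 "single observation")
  expect_s3_class(f, "lmm_fit")
})
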