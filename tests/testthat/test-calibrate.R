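test_that("wssres matches its definition on small constructed cases", {
  net <- fx_net()
  truth <- fx_parental_truth()$truth

  # simulation equals data exactly -> 0
  obs0 <- fx_parental_truth()$observations
  expect_equal(wssres(obs0, truth), 0)

  # one variable, one time, residual 2, variance 4 -> 1
  rec <- data.frame(time_h = c(48, 48), variable = "GLC", replicate = 1:2,
                    value = chometab:::.traj_value(truth, "GLC", 48) - 2)
  obs1 <- cho_observations(rec, variance = c(GLC = 4))
  expect_equal(wssres(obs1, truth), 1)

  # three variables against a brute-force double loop
  ex <- generate_experiment(clone_spec("parental"),
                            cho_schedule(induced = FALSE), noise_model(),
                            seed = 3, observed = c("GLC", "GLN", "LAC"),
                            base = fx_params(), net = net)
  expect_equal(wssres(ex$observations, truth),
               wssres_bruteforce(ex$observations, truth),
               tolerance = 1e-12)
})

test_that("wssres is record-order invariant and additive over variables", {
  truth <- fx_parental_truth()$truth
  ex <- generate_experiment(clone_spec("parental"),
                            cho_schedule(induced = FALSE), noise_model(),
                            seed = 4, observed = c("Xv", "GLC", "GLN"),
                            base = fx_params(), net = fx_net())
  obs <- ex$observations
  w_all <- wssres(obs, truth)
  perm <- obs
  set.seed(1)
  idx <- sample(nrow(perm$records))
  perm <- cho_observations(perm$records[idx, ], variance = obs$variance)
  expect_equal(wssres(perm, truth), w_all, tolerance = 1e-12)

  parts <- vapply(c("Xv", "GLC", "GLN"), function(v) {
    sub <- cho_observations(obs$records[obs$records$variable == v, ],
                            variance = obs$variance[v])
    wssres(sub, truth)
  }, 0)
  expect_equal(sum(parts), w_all, tolerance = 1e-12)

  expect_error(wssres(cho_observations(
    data.frame(time_h = 48, variable = "nosuchvar", replicate = 1,
               value = 1)), truth), "unknown trajectory variable")
})

test_that("noiseless data at the true parameters gives WSSRES 0 without iteration", {
  # data taken from the identically configured simulation the fitter runs
  sch <- cho_schedule(induced = FALSE)
  tt <- sch$sample_times
  tr <- chometab:::.sim_with(setNames(numeric(0), character(0)), fx_params(),
                             tt, sch, fx_net(), "I+II",
                             rtol = 1e-6, atol = 1e-8)
  rec <- do.call(rbind, lapply(c("Xv", "GLC", "GLN", "LAC"), function(v)
    data.frame(time_h = rep(tt, 2), variable = v,
               replicate = rep(1:2, each = length(tt)),
               value = rep(chometab:::.traj_value(tr, v, tt), 2))))
  obs <- cho_observations(rec, variance = c(Xv = 1, GLC = 1, GLN = 1,
                                            LAC = 1))
  fit <- fit_culture(obs, start = fx_params(), free = character(0),
                     schedule = sch, net = fx_net())
  expect_equal(fit$wssres, 0)
  expect_length(fit$trace, 1)
})

test_that("a singly perturbed parameter is recovered from noiseless data", {
  ex0 <- fx_parental_truth()
  truth_hk <- fx_params()$vmax[["vmaxHK"]]
  start <- param_update(fx_params(), c(vmaxHK = truth_hk * 2))
  fit <- fit_culture(ex0$observations, start = start, free = "vmaxHK",
                     schedule = ex0$truth$schedule, net = fx_net())
  expect_lt(abs(coef(fit)[["vmaxHK"]] / truth_hk - 1), 1e-3)
  expect_lte(fit$wssres, fit$wssres_start)
  # 1-D grid search confirms this is the WSSRES minimum
  grid <- truth_hk * c(0.85, 0.95, 1, 1.05, 1.2)
  wg <- vapply(grid, function(v) {
    tr <- chometab:::.sim_with(c(vmaxHK = v), fx_params(),
                               unique(ex0$observations$means$time_h),
                               ex0$truth$schedule, fx_net(), "I+II")
    wssres(ex0$observations, tr)
  }, 0)
  expect_equal(which.min(wg), 3L)
  expect_lt(fit$wssres, min(wg[-3]))
})

test_that("asymptotic intervals match the closed-form linear-regression oracle", {
  set.seed(7)
  x <- seq(1, 10, length.out = 25)
  y <- 2.5 * x + stats::rnorm(25, 0, 0.8)
  lmfit <- lm(y ~ x - 1)
  bhat <- coef(lmfit)[[1]]
  r <- y - bhat * x
  # residual vector r(theta) = (y - theta x); dr/dtheta = -x
  w <- chometab:::.wald_se(matrix(-x, ncol = 1), sum(r^2),
                           df = length(x) - 1)
  expect_equal(w$se, summary(lmfit)$coefficients[1, 2], tolerance = 1e-10)
  tq <- qt(0.975, length(x) - 1)
  ci_pkg <- c(bhat - tq * w$se, bhat + tq * w$se)
  ci_lm <- unname(confint(lmfit, level = 0.95)[1, ])
  expect_equal(ci_pkg, ci_lm, tolerance = 1e-10)
})

test_that("near-zero residuals give near-zero interval width", {
  ex0 <- fx_parental_truth()
  start <- param_update(fx_params(),
                        c(vmaxHK = fx_params()$vmax[["vmaxHK"]] * 1.5))
  fit <- fit_culture(ex0$observations, start = start, free = "vmaxHK",
                     schedule = ex0$truth$schedule, net = fx_net())
  ci <- confint(fit)
  expect_lt(ci[1, "high"] / ci[1, "low"] - 1, 1e-3)
})

test_that("interval width is invariant to a common rescaling of the variances", {
  # with the error variance re-estimated from the weighted residuals (the
  # nlparci convention), a uniform rescaling of var_m cancels exactly
  ex <- generate_experiment(clone_spec("parental"),
                            cho_schedule(induced = FALSE), noise_model(),
                            seed = 12, base = fx_params(), net = fx_net())
  obs <- ex$observations
  obs2 <- cho_observations(obs$records, variance = obs$variance * 2)
  f1 <- fit_culture(obs, free = "vmaxHK", schedule = ex$truth$schedule,
                    net = fx_net(), start = fx_params())
  f2 <- fit_culture(obs2, free = "vmaxHK", schedule = ex$truth$schedule,
                    net = fx_net(), start = fx_params())
  expect_equal(f2$wssres, f1$wssres / 2, tolerance = 1e-6)
  expect_equal(confint(f2)[, "se_log10"], confint(f1)[, "se_log10"],
               tolerance = 1e-5)
})

test_that("prediction intervals cover the noise-free truth near the estimate", {
  ex <- generate_experiment(clone_spec("parental"),
                            cho_schedule(induced = FALSE), noise_model(),
                            seed = 21, base = fx_params(), net = fx_net())
  fit <- fit_culture(ex$observations, free = c("vmaxHK", "vmaxgrowth"),
                     schedule = ex$truth$schedule, net = fx_net(),
                     start = fx_params())
  pr <- predict(fit, variables = "GLC", interval = "confidence")
  expect_true(all(pr$low <= pr$fit & pr$fit <= pr$high))
  truth_glc <- chometab:::.traj_value(ex$truth, "GLC", pr$time_h)
  # the envelope tracks the truth to within a few noise SDs
  sdg <- sqrt(ex$observations$variance[["GLC"]])
  expect_true(all(abs(pr$fit - truth_glc) < 4 * sdg))
})

test_that("Wald comparison of fits flags the constructed differences", {
  # identical estimates -> p = 1; |zA - zB| = 1.96 sd -> p ~= 0.05
  fake <- function(theta, se) {
    J <- diag(1 / se, length(se))
    structure(list(theta = theta, free = names(theta), jacobian = J,
                   wssres = length(se), df = 1e9), class = "cho_fit")
  }
  # wssres/df -> s2 = 1e-9 ~ 0? use df = length(se) so s2 = 1
  fake <- function(theta, se) {
    n <- length(se)
    structure(list(theta = theta, free = names(theta),
                   jacobian = diag(1 / se, n), wssres = n, df = n),
              class = "cho_fit")
  }
  thA <- c(a = 0.5, b = 1.0)
  se <- c(a = 0.1, b = 0.2)
  cmpAA <- compare_fits(fake(thA, se), fake(thA, se))
  expect_equal(cmpAA$p, c(1, 1))
  thB <- thA + 1.959964 * sqrt(2) * se
  cmpAB <- compare_fits(fake(thA, se), fake(thB, se))
  expect_equal(cmpAB$p, c(0.05, 0.05), tolerance = 1e-4)
  expect_error(compare_fits(fake(thA, se), fake(c(a = 1, c = 2), se[1:2])),
               "different free parameter")
})
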