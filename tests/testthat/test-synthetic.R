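test_that("clone specifications apply multiplicative overrides once", {
  base <- fx_params()
  # empty overrides: output equals base
  p_par <- make_clone(clone_spec("parental"), base)
  expect_equal(p_par$vmax[names(base$vmax) != "vmaxmAb"],
               base$vmax[names(base$vmax) != "vmaxmAb"])

  # an explicit +75% pyruvate-dehydrogenase override scales exactly that entry
  sp <- clone_spec("pdh_up", overrides = c(vmaxPDH = 1.75),
                   mab_vmax_multiplier = 1, leaky_fraction = 0.1)
  p_up <- make_clone(sp, base)
  expect_equal(p_up$vmax[["vmaxPDH"]], base$vmax[["vmaxPDH"]] * 1.75)
  others <- setdiff(names(base$vmax), c("vmaxPDH", "vmaxmAb"))
  expect_equal(p_up$vmax[others], base$vmax[others])

  # applying the same spec twice is refused (overrides are multiplicative)
  expect_error(make_clone(sp, p_up), "already applied")
  expect_error(make_clone(clone_spec("x", overrides = c(nosuch = 2),
                                     mab_vmax_multiplier = 1,
                                     leaky_fraction = 0),
                          base), "unknown parameter")
})

test_that("experiment generation is seeded and noise-calibrated", {
  sch <- cho_schedule(induced = FALSE)
  # cv = 0 reproduces the truth exactly
  ex0 <- generate_experiment(clone_spec("parental"), sch,
                             noise_model(cv = 0, floor = 0), seed = 5,
                             base = fx_params(), net = fx_net())
  m <- ex0$observations$means
  for (v in unique(m$variable)) {
    i <- m$variable == v
    expect_equal(m$value[i],
                 chometab:::.traj_value(ex0$truth, v, m$time_h[i]),
                 tolerance = 1e-12)
  }

  # same seed -> identical observation sets; different seed -> different
  exA <- generate_experiment(clone_spec("parental"), sch, noise_model(),
                             seed = 8, base = fx_params(), net = fx_net())
  exB <- generate_experiment(clone_spec("parental"), sch, noise_model(),
                             seed = 8, base = fx_params(), net = fx_net())
  exC <- generate_experiment(clone_spec("parental"), sch, noise_model(),
                             seed = 9, base = fx_params(), net = fx_net())
  expect_identical(exA$observations$records, exB$observations$records)
  expect_false(identical(exA$observations$records, exC$observations$records))

  # ground truth is always recoverable through the objective
  expect_equal(wssres(ex0$observations, ex0$truth), 0)
})

test_that("empirical replicate noise matches the 5% CV model", {
  sch <- cho_schedule(induced = FALSE)
  # Monte-Carlo: pooled empirical CV over seeds within [0.03, 0.07],
  # and approximately unbiased in the log domain
  vals <- NULL
  for (s in 1:10) {
    ex <- generate_experiment(clone_spec("parental"), sch,
                              noise_model(cv = 0.05, replicates = 2),
                              seed = 100 + s, observed = c("GLC", "Xv"),
                              base = fx_params(), net = fx_net())
    rec <- ex$observations$records
    tru <- rbind(
      data.frame(variable = "GLC",
                 time_h = sch$sample_times,
                 truth = chometab:::.traj_value(ex$truth, "GLC",
                                                sch$sample_times)),
      data.frame(variable = "Xv",
                 time_h = sch$sample_times,
                 truth = chometab:::.traj_value(ex$truth, "Xv",
                                                sch$sample_times)))
    mm <- merge(rec, tru)
    vals <- rbind(vals, mm[mm$truth > 0.5, ])  # avoid floor-dominated rows
  }
  ratio <- vals$value / vals$truth
  expect_gt(sd(log(ratio)), 0.03)
  expect_lt(sd(log(ratio)), 0.07)
  expect_lt(abs(mean(log(ratio))), 0.01)
})

test_that("the reference panel reproduces the five-culture design", {
  panel <- reference_panel(seed = 2, noise = noise_model(cv = 0.05))
  expect_length(panel, 5)
  expect_setequal(names(panel), c("parental", "low_induced", "low_control",
                                  "high_induced", "high_control"))
  expect_false(panel$parental$truth$schedule$induced)
  expect_true(panel$high_induced$truth$schedule$induced)
  # leaky expression: the non-induced high producer still secretes mAb
  mab_ctrl <- panel$high_control$truth$states[, "mAb"]
  expect_gt(max(mab_ctrl), 1)
  # induced and control share the clone's metabolic parameters
  vA <- param_vector(panel$high_induced$params)
  vB <- param_vector(panel$high_control$params)
  expect_equal(vA, vB)
})

test_that("noise-free fixtures satisfy the culture phenomenology", {
  par_truth <- fx_parental_truth()$truth
  hp <- fx_high_pair()$induced

  for (traj in list(par_truth, hp)) {
    gln <- traj$states[, "GLN"]
    t_dep <- traj$times[min(which(gln < 0.1))]
    expect_lt(t_dep, 120)                         # glutamine depleted in time
    expect_gt(min(traj$states[, "GLC"]), 5)       # glucose never limiting
    # growth arrested within 12 h of depletion
    mu_exp <- max(traj$fluxes[, "growth"])
    i_post <- traj$times >= t_dep + 12
    expect_lt(max(traj$fluxes[i_post, "growth"]), 0.1 * mu_exp)
  }

  # the high producer switches to net lactate consumption after depletion
  t_dep_h <- hp$times[min(which(hp$states[, "GLN"] < 0.1))]
  expect_lt(min(hp$fluxes[hp$times > t_dep_h + 6, "LDH"]), 0)
  # while the parental keeps producing lactate throughout
  expect_gt(min(par_truth$fluxes[, "LDH"]), 0)
})
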