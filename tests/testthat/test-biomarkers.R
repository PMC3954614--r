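mkflux <- function(...) {
  base <- setNames(rep(0, 35), fx_net()$reaction_ids)
  ov <- c(...)
  base[names(ov)] <- ov
  base
}

test_that("lactate/glucose ratio follows its defining formula", {
  expect_equal(lactate_glucose_ratio(mkflux(HK = 1, LDH = 0)), 0)
  expect_equal(lactate_glucose_ratio(mkflux(HK = 2e-5, LDH = 2e-5)), 1)
  expect_equal(lactate_glucose_ratio(mkflux(HK = 1, LDH = -0.5)), -0.5)
  expect_true(is.na(lactate_glucose_ratio(mkflux(HK = 0, LDH = 1))))
})

test_that("pyruvate branch point counts only positive inflows", {
  expect_equal(pyruvate_branch_point(mkflux(PK = 1, PDH = 1)), 1)
  expect_equal(pyruvate_branch_point(mkflux(PK = 1)), 0)
  # a cataplerotic (negative) malic-enzyme flux is excluded
  expect_equal(pyruvate_branch_point(mkflux(PK = 1, PDH = 0.5, ME = -2)),
               pyruvate_branch_point(mkflux(PK = 1, PDH = 0.5, ME = 0)))
  # alanine uptake (negative AlaTA) feeds the pool
  expect_equal(pyruvate_branch_point(mkflux(PK = 1, AlaTA = -1, PDH = 1)), 0.5)
  expect_true(is.na(pyruvate_branch_point(mkflux(PDH = 1))))
  expect_equal(pct_pyruvate_from_glucose(mkflux(PK = 3, SAL = 1)), 75)
})

test_that("TCA contributions are clamped shares summing to one", {
  eq <- mkflux(PDH = 1, ASTA = 1, GLDH = 1, LYSILELEUVALTYRTA = 1, PC = 1)
  tc <- tca_contributions(eq)
  expect_equal(unname(tc["glc"]), 0.2)
  expect_equal(unname(tc["gln"]), 0.2)
  expect_equal(unname(tc["other_aa"]), 0.4)
  expect_equal(unname(tc["pc"]), 0.2)
  expect_equal(sum(tc), 1)

  only_pdh <- tca_contributions(mkflux(PDH = 2))
  expect_equal(unname(only_pdh["glc"]), 1)
  expect_equal(sum(only_pdh[-1]), 0)

  # glutamate-producing (reversed) GLDH contributes nothing
  rev_gldh <- tca_contributions(mkflux(PDH = 1, GLDH = -3))
  expect_equal(unname(rev_gldh["gln"]), 0)
  expect_equal(unname(rev_gldh["glc"]), 1)
  expect_true(all(is.na(tca_contributions(mkflux()))))
})

test_that("ATP turnover sums the caption terms with clamping", {
  po <- 1.25
  expect_equal(atp_turnover(mkflux(resp = 2e-4), po), 2 * po * 2e-4)
  expect_equal(atp_turnover(mkflux(), po), 0)
  fl <- c(mkflux(PGK = 1e-4, PK = 1.1e-4, SCOAS = 2e-5, resp = 3e-4),
          GLNSr = 4e-6, CKf = 5e-6, AKr = 6e-6)
  by_hand <- 1e-4 + 1.1e-4 + 2e-5 + 4e-6 + 5e-6 + 6e-6 + 2 * po * 3e-4
  expect_equal(atp_turnover(fl, po), by_hand, tolerance = 1e-12)
  # ATP-consuming directions of the buffering reactions are clamped out
  fl2 <- c(mkflux(PGK = 1e-4), GLNSr = -1, CKf = -1, AKr = -1)
  expect_equal(atp_turnover(fl2, po), 1e-4)
})

test_that("ATP partitioning implements the caption percentages", {
  to <- 1e-3
  fl <- mkflux(growth = 0.03, mAb = 5e-9)
  ap <- atp_partition(fl, to)
  expect_equal(unname(ap["pct_biomass"]), 100 * 0.00043 * 3.78 * 0.03 / to)
  expect_equal(unname(ap["pct_mab"]), 100 * 4 * 5e-9 / to)
  expect_equal(unname(atp_partition(mkflux(growth = 0), to)["pct_biomass"]), 0)
  # doubling the turnover halves both shares
  ap2 <- atp_partition(fl, 2 * to)
  expect_equal(unname(ap2), unname(ap) / 2)
  # 4 * v(mAb) = 2% of turnover -> 2%
  ap3 <- atp_partition(mkflux(mAb = 0.02 * to / 4), to)
  expect_equal(unname(ap3["pct_mab"]), 2)
  expect_true(all(is.na(atp_partition(fl, 0))))
})

test_that("panel entries are pure functions of the stored trajectory", {
  traj <- fx_high_pair()$induced
  p1 <- biomarker_panel(traj, times = seq(0, 144, by = 24))
  p2 <- biomarker_panel(traj, times = seq(0, 144, by = 24))
  expect_identical(p1, p2)
  # clamping: no share below 0 or above 1
  shares <- as.matrix(p1[, c("contrib_glc_tca", "contrib_gln_tca",
                             "contrib_other_aa_tca", "contrib_pc_tca")])
  expect_true(all(shares >= 0 & shares <= 1, na.rm = TRUE))
  expect_error(biomarker_panel(traj, times = 13.37), "not on the trajectory")
})

test_that("high-producer lactate/glucose ratio stays below one after mid-culture", {
  pa <- biomarker_panel(fx_high_pair()$induced, times = seq(48, 144, by = 24))
  expect_true(all(pa$lac_glc_ratio < 1))
})

test_that("induced/control panel is ~1 except for the mAb entries", {
  hp <- fx_high_pair()
  rp <- induction_ratio_panel(hp$induced, hp$control,
                              times = seq(24, 144, by = 24))
  # core metabolic fluxes and ratios are unchanged by induction (~1 at every
  # time point); growth-linked entries (mu, ATP-to-biomass, glutamine-linked
  # shares) deviate a few percent around growth arrest, as they become
  # ratios of vanishing quantities
  core <- c("qGlc", "glycolytic_flux", "pyr_branch_point",
            "pct_pyr_from_glc", "contrib_glc_tca", "contrib_pc_tca",
            "tca_flux", "atp_turnover")
  vals <- unlist(rp[core])
  expect_true(all(abs(vals[is.finite(vals)] - 1) < 0.01))
  pre <- rp$time <= 72
  rest <- setdiff(names(rp), c("time", "qmAb", "pct_atp_mab"))
  vpre <- unlist(rp[pre, rest])
  expect_true(all(abs(vpre[is.finite(vpre)] - 1) < 0.05))
  expect_true(all(rp$qmAb[rp$time > 48] > 1))

  # identical trajectories give exactly 1 everywhere (where defined)
  self <- induction_ratio_panel(hp$induced, hp$induced)
  v <- unlist(self[setdiff(names(self), "time")])
  expect_true(all(abs(v[is.finite(v)] - 1) < 1e-12))

  # a control without any mAb flux yields missing, not infinite, ratios
  p0 <- hp$params
  p0$vmax["vmaxmAb"] <- 0
  sch <- cho_schedule(induced = FALSE, leaky_fraction = 0)
  ctl0 <- simulate_batch(p0, sch, fx_net(), times = seq(0, 144, by = 24))
  ind <- simulate_batch(hp$params,
                        cho_schedule(induced = TRUE,
                                     leaky_fraction = hp$spec$leaky_fraction),
                        fx_net(), times = seq(0, 144, by = 24))
  rp0 <- induction_ratio_panel(ind, ctl0)
  expect_true(all(is.na(rp0$qmAb)))
})

test_that("mAb carbon load reproduces the published worked estimate", {
  expect_equal(mab_carbon_fraction(q_mab = 0), 0)
  expect_error(mab_carbon_fraction(q_mab = -1), "positive")
  expect_error(mab_carbon_fraction(mu = 0), "positive")
  # equal carbon mass rates in numerator and growth term -> 50%
  expect_equal(mab_carbon_fraction(q_mab = 1, mw_mab = 1, mu = 1,
                                   dcw = 1000, carbon_frac_mab = 0.5,
                                   carbon_frac_x = 0.5), 50)
  # the published inputs give at most 5% of total carbon uptake
  est <- mab_carbon_fraction()
  expect_gt(est, 0)
  expect_lte(est, 5)
})
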