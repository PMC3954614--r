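test_that("elementary kinetic terms behave as hyperbolic laws", {
  expect_equal(saturation_term(2, 2), 0.5)
  expect_equal(saturation_term(0, 2), 0)
  expect_equal(saturation_term(99 * 3, 3), 0.99)
  expect_error(saturation_term(1, 0), "positive")
  expect_error(saturation_term(-1, 1), "non-negative")

  expect_equal(inhibition_factor(0, 5), 1)
  expect_equal(inhibition_factor(5, 5), 0.5)
  expect_lt(inhibition_factor(1e9, 5), 1e-6)
  expect_error(inhibition_factor(1, -1), "positive")

  expect_equal(activation_factor(1.5, 1.5), 0.5)
  expect_equal(activation_factor(0, 1.5), 0)
  eff <- seq(0, 10, by = 0.5)
  expect_true(all(diff(activation_factor(eff, 2)) > 0))  # monotone
})

test_that("glutamine threshold activation is a calibrated switch", {
  expect_equal(threshold_activation(0.3, 0.3), 0.5)
  expect_gt(threshold_activation(0, 0.3), 0.99)
  expect_lt(threshold_activation(4, 0.3), 0.01)  # media-level glutamine
  g <- seq(0, 4, by = 0.1)
  expect_true(all(diff(threshold_activation(g, 0.3)) <= 0))
})

test_that("regulation scenarios enable exactly the configured terms", {
  expect_equal(as.logical(regulation_config("none")), rep(FALSE, 5))
  expect_equal(unname(which(regulation_config("I"))), 1L)
  expect_equal(as.logical(regulation_config("I+II")),
               c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_true(all(regulation_config("all")))
  rc <- regulation_config("none", enable = "V")
  expect_true(rc[["V"]] && !any(rc[c("I", "II", "III", "IV")]))
})

test_that("reaction rates follow the multiplicative MM structure", {
  net <- fx_net()
  p <- fx_params()
  st <- fx_op_state()

  # saturation limit: substrates >> Km and saturated cofactor drive
  st_sat <- st
  st_sat["ASN"] <- 1e7
  v <- reaction_rate("ASX", st_sat, p, net, "none")
  expect_equal(v, unname(p$vmax[["vmaxASX"]]), tolerance = 1e-5)

  # term I at half-inhibition with everything else saturating
  st_hk <- st
  st_hk["GLC"] <- 1e9
  st_hk["ATP"] <- 1e9; st_hk["ADP"] <- 1e-6
  st_hk["G6P"] <- p$regulatory[["Ki_HK_G6P"]]
  v_hk <- reaction_rate("HK", st_hk, p, net, regulation_config("none", enable = "I"))
  expect_equal(v_hk, unname(p$vmax[["vmaxHK"]]) / 2, tolerance = 1e-6)

  # LDH symmetry: equal forward and reverse factor products cancel
  p_sym <- p
  p_sym$vmax["vmaxrLDH"] <- p_sym$vmax[["vmaxfLDH"]]
  p_sym$affinity["Km_LDH_LAC"] <- p_sym$affinity[["Km_LDH_PYR"]]
  st_sym <- st
  st_sym["LAC"] <- st_sym[["PYR"]]
  st_sym["NADH"] <- st_sym[["NAD"]]
  st_sym["GLN"] <- 0  # depletion gate fully open on the reverse side
  expect_equal(reaction_rate("LDH", st_sym, p_sym, net, "none"), 0,
               tolerance = 1e-12)

  expect_error(reaction_rate("NOPE", st, p, net), "unknown reaction")
  st_bad <- st; st_bad["GLC"] <- -1
  expect_error(reaction_rate("HK", st_bad, p, net), "negative")
})

test_that("flux_vector equals element-wise reaction_rate and zero vmax gives zero", {
  net <- fx_net()
  p <- fx_params()
  st <- fx_op_state()
  v <- flux_vector(st, p, net)
  for (id in c("HK", "LDH", "GLNS", "resp", "growth"))
    expect_equal(v[[id]], reaction_rate(id, st, p, net))

  p0 <- p
  p0$vmax[] <- 1e-300
  expect_true(all(abs(flux_vector(st, p0, net)) < 1e-250))
})

test_that("hand-computed hexokinase rate matches the engine", {
  p <- fx_params()
  st <- fx_op_state()
  r_atp <- st[["ATP"]] / st[["ADP"]]
  by_hand <- p$vmax[["vmaxHK"]] *
    st[["GLC"]] / (p$affinity[["Km_HK_GLC"]] + st[["GLC"]]) *
    (r_atp / (1 + r_atp)) *
    1 / (1 + st[["G6P"]] / p$regulatory[["Ki_HK_G6P"]])
  expect_equal(reaction_rate("HK", st, p, fx_net(), "I+II"), unname(by_hand),
               tolerance = 1e-12)
})

test_that("enabled regulation factors only attenuate the regulated flux", {
  # every term multiplies by a factor in (0,1]: an enabled inhibition OR
  # activation requirement can only reduce the flux relative to the
  # unregulated law, and removing it restores the larger value
  net <- fx_net()
  p <- fx_params()
  set.seed(11)
  for (i in 1:10) {
    st <- fx_op_state() * exp(stats::rnorm(46, 0, 0.3))
    all_on <- flux_vector(st, p, net, "all")
    for (term in c("I", "II", "III", "IV", "V")) {
      off <- flux_vector(st, p, net, regulation_config("all", disable = term))
      tgt <- switch(term, I = "HK", II = "PGI", III = "PFK", IV = "PK",
                    V = "LDH")
      expect_gte(off[[tgt]] - all_on[[tgt]], -1e-15)
    }
    expect_true(all(is.finite(all_on)))
  }
})

test_that("scenario none reproduces the unregulated MM product exactly", {
  net <- fx_net()
  p <- fx_params()
  st <- fx_op_state()
  v_none <- flux_vector(st, p, net, "none")
  # HK without regulation = vmax * sat(GLC) * ATP/ADP drive
  r_atp <- st[["ATP"]] / st[["ADP"]]
  expect_equal(v_none[["HK"]],
               p$vmax[["vmaxHK"]] *
                 st[["GLC"]] / (p$affinity[["Km_HK_GLC"]] + st[["GLC"]]) *
                 r_atp / (1 + r_atp),
               tolerance = 1e-12)
})

test_that("compiled flux engine matches the R reference at random states", {
  net <- fx_net()
  p <- fx_params()
  set.seed(99)
  for (scen in c("none", "I+II", "all")) {
    states <- t(replicate(5, fx_op_state() * exp(stats::rnorm(46, 0, 0.5))))
    colnames(states) <- net$species$id
    pack <- chometab:::.pack_model(net, p, scen, mab_scale = 1)
    vc <- chometab:::cpp_fluxes(pack, states)
    for (i in 1:5) {
      vr <- flux_vector(states[i, ], p, net, scen)
      expect_equal(unname(vc[i, ]), unname(vr), tolerance = 1e-12)
    }
  }
})
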