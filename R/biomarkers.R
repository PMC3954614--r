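# Metabolic flux-ratio biomarkers. All quantities are pure functions of the
# flux vector (plus the caption constants), evaluated per time point:
#   lactate/glucose ratio      (vfLDH - vrLDH) / vHK
#   pyruvate branch point      (vPDH + vPC) / (positive inflows to pyruvate)
#   % pyruvate from glucose    100 * vPK / (same denominator)
#   TCA-entry contributions    vPDH | vGLDH | (vLYS..TA + vASTA) | vPC over
#                              (vPDH + vASTA + vGLDH + vLYS..TA + vPC)
#   TCA cycle flux             v(SDH/FUM)
#   ATP turnover               vPGK + vPK + vSCOAS + vr(GLNS) + vf(CK)
#                              + vr(AK) + 2*(P/O)*v(resp)
#   ATP partitioning           100 * 0.00043*3.78*v(growth) / turnover and
#                              100 * 4*v(mAb) / turnover
# Negative entry fluxes are clamped to zero wherever a share of a pool is
# formed, so no contribution is ever negative or exceeds one.

.BIOMASS_ATP_COEFS <- c(0.00043, 3.78)  # caption constants, kept verbatim
.MAB_ATP_COEF <- 4

.pos <- function(x) pmax(x, 0)

# positive inflows to the pyruvate pool: glycolysis, serine lyase, the
# lumped pyruvate-family transaminase, malic enzyme and reverse alanine
# aminotransferase (the latter two only when they feed pyruvate)
.pyr_inflow <- function(fl) {
  .pos(fl["PK"]) + .pos(fl["SAL"]) + .pos(fl["AAPYRTA"]) + .pos(fl["ME"]) +
    .pos(-fl["AlaTA"])
}

#' Lactate production-to-glucose consumption ratio
#'
#' @param fluxes named flux vector (needs `LDH` net flux and `HK`).
#' @return dimensionless ratio; negative under net lactate consumption;
#'   `NA` when the glucose uptake flux is not positive.
#' @export
lactate_glucose_ratio <- function(fluxes) {
  hk <- fluxes[["HK"]]
  if (!is.finite(hk) || hk <= 0) return(NA_real_)
  fluxes[["LDH"]] / hk
}

#' Pyruvate branch point ratio
#'
#' Fraction of the total flux into the pyruvate pool that is routed into
#' the TCA cycle through pyruvate dehydrogenase and pyruvate carboxylase.
#'
#' @param fluxes named flux vector.
#' @return ratio in `[0, Inf)`; `NA` when no flux feeds pyruvate.
#' @export
pyruvate_branch_point <- function(fluxes) {
  den <- .pyr_inflow(fluxes)
  if (!is.finite(den) || den <= 0) return(NA_real_)
  unname((.pos(fluxes["PDH"]) + .pos(fluxes["PC"])) / den)
}

#' Percentage of pyruvate derived from glucose
#'
#' @param fluxes named flux vector.
#' @return percentage in `[0, 100]`; `NA` when no flux feeds pyruvate.
#' @export
pct_pyruvate_from_glucose <- function(fluxes) {
  den <- .pyr_inflow(fluxes)
  if (!is.finite(den) || den <= 0) return(NA_real_)
  unname(100 * .pos(fluxes["PK"]) / den)
}

#' Contributions of glucose, glutamine, other amino acids and anaplerosis
#' to the TCA cycle
#'
#' Shares of the total flux channelled into the TCA cycle through its entry
#' points: pyruvate dehydrogenase (glucose), glutamate dehydrogenase
#' (glutamine), the lumped amino-acid transaminases plus the
#' aspartate/oxaloacetate exchange (other amino acids) and pyruvate
#' carboxylase. Entry fluxes running backwards (e.g. glutamate-producing
#' GLDH) are clamped to zero, so the four shares are in `[0, 1]` and sum
#' to 1.
#'
#' @param fluxes named flux vector.
#' @return named numeric: `glc`, `gln`, `other_aa`, `pc`; all `NA` when no
#'   entry flux is positive.
#' @export
tca_contributions <- function(fluxes) {
  pdh <- .pos(fluxes[["PDH"]]); asta <- .pos(fluxes[["ASTA"]])
  gldh <- .pos(fluxes[["GLDH"]]); lys <- .pos(fluxes[["LYSILELEUVALTYRTA"]])
  pc <- .pos(fluxes[["PC"]])
  den <- pdh + asta + gldh + lys + pc
  if (!is.finite(den) || den <= 0)
    return(c(glc = NA_real_, gln = NA_real_, other_aa = NA_real_,
             pc = NA_real_))
  c(glc = pdh / den, gln = gldh / den, other_aa = (lys + asta) / den,
    pc = pc / den)
}

#' ATP turnover rate
#'
#' Sum of the ATP-forming fluxes: phosphoglycerate kinase, pyruvate kinase,
#' succinyl-CoA synthetase, the reverse glutaminase ("GlnT") flux, forward
#' creatine kinase, reverse adenylate kinase, and oxidative phosphorylation
#' as `2 * (P/O) * v(resp)`. Each substrate-level term is clamped at zero
#' from below (only ATP-forming direction counts).
#'
#' @param fluxes named flux vector; directional components `GLNSr`, `CKf`
#'   and `AKr` are used when present (as supplied by [biomarker_panel()]),
#'   otherwise the clamped net fluxes stand in.
#' @param po_ratio P/O ratio (ATP per oxygen atom) of the respiration lump.
#' @return ATP turnover in mmol/(1e6 cells)/h.
#' @export
atp_turnover <- function(fluxes, po_ratio = 1.25) {
  comp <- function(nm, alt) {
    if (nm %in% names(fluxes)) .pos(fluxes[[nm]]) else .pos(alt)
  }
  unname(.pos(fluxes["PGK"]) + .pos(fluxes["PK"]) + .pos(fluxes["SCOAS"]) +
    comp("GLNSr", -fluxes[["GLNS"]]) +
    comp("CKf", fluxes[["CK"]]) +
    comp("AKr", -fluxes[["AK"]]) +
    2 * po_ratio * .pos(fluxes["resp"]))
}

#' ATP partitioning between biomass and mAb synthesis
#'
#' Percentage of the ATP turnover consumed by biomass synthesis
#' (`0.00043 * 3.78 * v(growth)`) and by antibody synthesis
#' (`4 * v(mAb)`).
#'
#' @param fluxes named flux vector (needs `growth` and `mAb`).
#' @param turnover ATP turnover from [atp_turnover()].
#' @return named numeric `pct_biomass`, `pct_mab`; `NA` when the turnover
#'   is not positive.
#' @export
atp_partition <- function(fluxes, turnover) {
  if (!is.finite(turnover) || turnover <= 0)
    return(c(pct_biomass = NA_real_, pct_mab = NA_real_))
  c(pct_biomass = 100 * .BIOMASS_ATP_COEFS[1] * .BIOMASS_ATP_COEFS[2] *
      .pos(fluxes[["growth"]]) / turnover,
    pct_mab = 100 * .MAB_ATP_COEF * .pos(fluxes[["mAb"]]) / turnover)
}

# gross directional components needed by the turnover formula, evaluated
# with the reference R kinetics on the stored trajectory states
.gross_components <- function(traj) {
  p <- traj$params; net <- traj$net
  vr <- function(vmax_name, factors) {
    apply(traj$states, 1, function(st) {
      p$vmax[[vmax_name]] *
        .factor_product(factors, list(), "rev", st, p,
                        regulation_config("none"))
    })
  }
  rx <- stats::setNames(net$reactions, net$reaction_ids)
  cbind(GLNSr = vr("vmaxrGLNS", rx$GLNS$rev),
        CKf = apply(traj$states, 1, function(st)
          p$vmax[["vmaxfCK"]] *
            .factor_product(rx$CK$fwd, list(), "fwd", st, p,
                            regulation_config("none"))),
        AKr = vr("vmaxrAK", rx$AK$rev))
}

#' Biomarker panel along a trajectory
#'
#' Evaluates every flux-ratio biomarker at each time point of a simulated
#' culture.
#'
#' @param traj a [simulate_batch()] trajectory.
#' @param times optional subset of times (defaults to the trajectory grid).
#' @return data frame with one row per time point: specific rates (qGlc,
#'   glycolytic flux, TCA flux, glutamine uptake, growth, qmAb), the
#'   lactate/glucose ratio, pyruvate branch point, percentage of pyruvate
#'   from glucose, TCA-entry contributions, ATP turnover and ATP
#'   partitioning.
#' @export
biomarker_panel <- function(traj, times = NULL) {
  keep <- if (is.null(times)) seq_along(traj$times)
          else match(times, traj$times)
  if (any(is.na(keep))) stop("requested times not on the trajectory grid")
  gross <- .gross_components(traj)
  po <- traj$params$po_ratio
  out <- lapply(keep, function(i) {
    fl <- c(traj$fluxes[i, ], gross[i, ])
    tc <- tca_contributions(fl)
    to <- atp_turnover(fl, po)
    ap <- atp_partition(fl, to)
    data.frame(
      time = traj$times[i],
      qGlc = fl[["HK"]], glycolytic_flux = fl[["PK"]],
      lac_glc_ratio = lactate_glucose_ratio(fl),
      pyr_branch_point = pyruvate_branch_point(fl),
      pct_pyr_from_glc = pct_pyruvate_from_glucose(fl),
      contrib_glc_tca = tc[["glc"]], contrib_gln_tca = tc[["gln"]],
      contrib_other_aa_tca = tc[["other_aa"]], contrib_pc_tca = tc[["pc"]],
      tca_flux = fl[["SDHFUM"]], gln_uptake = fl[["GLNS"]],
      atp_turnover = to, pct_atp_biomass = ap[["pct_biomass"]],
      pct_atp_mab = ap[["pct_mab"]],
      mu = fl[["growth"]], qmAb = fl[["mAb"]])
  })
  do.call(rbind, out)
}

#' Induced-to-control normalised biomarker panel
#'
#' Element-wise ratio of each specific flux and biomarker in the induced
#' culture to its value in the non-induced control at the same time point;
#' identical trajectories give 1 everywhere. Entries whose control value is
#' (numerically) zero are reported missing rather than infinite.
#'
#' @param traj_induced,traj_control trajectories on matching time grids.
#' @param times optional subset of times.
#' @return data frame of ratios, same columns as [biomarker_panel()].
#' @export
induction_ratio_panel <- function(traj_induced, traj_control, times = NULL) {
  pi_ <- biomarker_panel(traj_induced, times)
  pc_ <- biomarker_panel(traj_control, times)
  if (!isTRUE(all.equal(pi_$time, pc_$time)))
    stop("trajectories are on different time grids")
  out <- pi_
  for (cn in setdiff(names(out), "time")) {
    den <- pc_[[cn]]
    ratio <- pi_[[cn]] / den
    ratio[!is.finite(den) | abs(den) < 1e-300] <- NA_real_
    out[[cn]] <- ratio
  }
  out
}

#' Carbon load of mAb production relative to growth
#'
#' Share of the cellular carbon uptake committed to recombinant antibody
#' production: the carbon mass flux into mAb over the total carbon mass
#' accumulation (growth plus mAb). Pure arithmetic on the stated inputs
#' (no simulation). Defaults are the published worked estimate: specific
#' productivity 1e-6 mmol/(1e6 cells)/h, growth rate 0.04 1/h, dry cell
#' weight 350 pg/cell, and a molecular weight of 150 g/mol taken verbatim
#' from the printed estimate (see the methods vignette for discussion of
#' this figure).
#'
#' @param q_mab specific mAb productivity, mmol/(1e6 cells)/h.
#' @param mw_mab molecular weight used for the carbon bookkeeping, g/mol.
#' @param mu specific growth rate, 1/h.
#' @param dcw dry cell weight, pg/cell.
#' @param carbon_frac_mab,carbon_frac_x carbon mass fractions (g/g) of mAb
#'   protein and biomass.
#' @return percentage of total carbon uptake.
#' @examples
#' mab_carbon_fraction()  # ~1.4%, consistent with the "at most 5%" bound
#' @export
mab_carbon_fraction <- function(q_mab = 1e-6, mw_mab = 150, mu = 0.04,
                                dcw = 350, carbon_frac_mab = 0.53,
                                carbon_frac_x = 0.45) {
  if (q_mab < 0 ||
      any(c(mw_mab, mu, dcw, carbon_frac_mab, carbon_frac_x) <= 0))
    stop("all inputs must be positive")
  # q_mab * mw: mg of mAb per 1e6 cells per h; mu * dcw: pg/cell/h = ug per
  # 1e6 cells per h = 1e-3 mg per 1e6 cells per h
  mab_c <- q_mab * mw_mab * carbon_frac_mab
  x_c <- mu * dcw * 1e-3 * carbon_frac_x
  100 * mab_c / (x_c + mab_c)
}
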