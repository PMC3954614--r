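# Reconstructed default parameter set. The supplementary parameter tables of
# the source model are not redistributable, so defaults are generated by
# inverting each rate law at a documented mid-exponential operating state
# against target fluxes of the printed order of magnitude (qGlc ~ 7.7e-5,
# glycolytic flux ~ 1.35e-4, net lactate ~ 8.7e-5 mmol/1e6 cells/h, growth
# ~ 0.035 1/h), under the default regulation scenario (terms I+II). This
# makes the design point an exact fixed point of the rate laws by
# construction and keeps every value strictly positive.

# mid-exponential design state (units: Xv 1e6 cells/mL, mAb mg/L,
# extracellular mM, intracellular nmol/1e6 cells)
.op_state <- function() {
  c(Xv = 1, mAb = 20,
    GLC = 25, LAC = 8, NH4 = 1.5,
    ALA = 1.5, ARG = 1.0, ASN = 0.5, ASP = 0.5, CYS = 0.35, GLN = 2,
    GLU_x = 1.0, GLY = 0.7, HIS = 0.45, ILE = 0.9, LEU = 1.1, LYS = 0.9,
    MET = 0.35, PHE = 0.55, PRO = 0.7, SER = 0.6, THR = 0.9, TRP = 0.18,
    TYR = 0.55, VAL = 0.9,
    G6P = 24, F6P = 9, GAP = 12, PEP = 12, PYR = 30, R5P = 9, ACCOA = 9,
    CIT = 18, AKG = 18, SUC = 12, MAL = 18, OAA = 12, GLU = 150,
    ATP = 1200, ADP = 120, AMP = 18, NAD = 600, NADH = 30, NADP = 12,
    NADPH = 150, PCR = 240)
}

# design-point fluxes in mmol/(1e6 cells)/h, one entry per vmax parameter
.design_fluxes <- function() {
  u <- 1e-5
  c(vmaxHK = 7.7 * u, vmaxPGI = 6.3 * u, vmaxPFK = 6.9 * u,
    vmaxPGK = 14.2 * u, vmaxPK = 14.0 * u,
    vmaxfLDH = 10.0 * u, vmaxrLDH = 2.3 * u,
    vmaxG6PDH = 1.2 * u, vmaxEP = 0.9 * u, vmaxPDH = 4.3 * u,
    vmaxCS = 3.9 * u, vmaxCITS = 3.9 * u, vmaxAKGDH = 6.1 * u,
    vmaxSCOAS = 4.0 * u, vmaxSDHFUM = 6.8 * u, vmaxMLD = 3.9 * u,
    vmaxPC = 0.45 * u, vmaxME = 2.2 * u,
    vmaxfGLNS = 3.6 * u, vmaxrGLNS = 0.3 * u,
    vmaxfGLDH = 0.15 * u, vmaxrGLDH = 0.1 * u,
    vmaxfAlaTA = 2.5 * u, vmaxrAlaTA = 1.2 * u,
    vmaxfASTA = 0.35 * u, vmaxrASTA = 0.05 * u,
    vmaxASX = 0.5 * u, vmaxGluT = 0.7 * u, vmaxSAL = 0.4 * u,
    vmaxAAPYRTA = 0.4 * u, vmaxHISARGTA = 0.3 * u,
    vmaxLYSILELEUVALTYRTA = 0.55 * u,
    vmaxresp = 26.3 * u, vmaxleak = 4.64 * u, vmaxATPase = 76.9 * u,
    vmaxNADPHox = 1.85 * u,
    vmaxfCK = 0.5 * u, vmaxrCK = 0.5 * u, vmaxfAK = 0.3 * u,
    vmaxrAK = 0.3 * u,
    vmaxgrowth = 0.033, vmaxmAb = 1e-11)
}

.default_affinity <- function() {
  c(Km_HK_GLC = 10, Km_PGI_G6P = 24, Km_PGI_F6P = 54, Km_PFK_F6P = 9,
    Km_PGK_GAP = 12, Km_PK_PEP = 12, Km_LDH_PYR = 30, Km_LDH_LAC = 15,
    Km_G6PDH_G6P = 24, Km_EP_R5P = 9, Km_PDH_PYR = 30, Km_CS_ACCOA = 9,
    Km_CS_OAA = 12, Km_CITS_CIT = 18, Km_AKGDH_AKG = 18, Km_SCOAS_SUC = 12,
    Km_SDHFUM_SUC = 12, Km_MLD_MAL = 18, Km_MLD_OAA = 48, Km_PC_PYR = 60,
    Km_ME_MAL = 18, Km_GLNS_GLN = 0.5, Km_GLNS_GLU = 150, Km_GLDH_GLU = 150,
    Km_GLDH_AKG = 18, Km_GLDH_NH4 = 1.5, Km_AlaTA_PYR = 30, Km_AlaTA_ALA = 1.0,
    Km_ASTA_ASP = 0.5, Km_ASTA_AKG = 18, Km_ASTA_OAA = 12, Km_ASX_ASN = 0.5,
    Km_GluT_GLU = 150, Km_SAL_SER = 0.6, Km_AAPYRTA_pool = 2,
    Km_HISARGTA_pool = 2, Km_LYSTA_pool = 4,
    K_resp_NADH = 0.02, K_resp_ADP = 0.05, K_leak_NADH = 0.05,
    Km_NADPHox_NADPH = 150, Km_CK_PCR = 240, Km_CK_CR = 360, Km_AK_AMP = 18,
    Km_AK_ADP = 120, Km_growth_GLN = 0.25, Km_growth_AA = 0.02,
    Km_mAb_AA = 0.02)
}

.default_regulatory <- function() {
  c(Ki_HK_G6P = 48, Ki_PGI_PEP = 24, Ki_PFK_G6P = 72, Ka_PK_F6P = 9,
    Ki_LDH_LAC = 30)
}

#' Default (reconstructed) parameter set for the canonical network
#'
#' Builds the bundled parameter set: 42 maximum reaction rates, 48 affinity
#' constants and 5 regulatory constants (95 kinetic parameters), plus the
#' P/O ratio, the extracellular-glutamine threshold gating alanine uptake,
#' the conserved creatine total, and the biomass/mAb composition vectors.
#' Maximum rates are derived by inverting the rate laws at the documented
#' mid-exponential operating state (see the methods vignette) so that the
#' design-point fluxes are met exactly under the given regulation scenario.
#'
#' @param net a [cho_network()] object.
#' @param regulation regulation scenario assumed when inverting for the
#'   maximum rates; the package default is `"I+II"`, the best-performing
#'   scenario retained for the final model.
#' @return object of class `cho_params`: a list with elements `vmax`,
#'   `affinity`, `regulatory`, `po_ratio`, `gln_threshold`, `gln_hill`,
#'   `creatine_total`, `mw_mab`, `biomass_coeffs`, `mab_coeffs`.
#' @examples
#' p <- cho_parameters()
#' length(p$vmax); length(p$affinity)
#' @export
cho_parameters <- function(net = cho_network(), regulation = "I+II") {
  nAA <- length(AA_SHARED)
  params <- structure(list(
    vmax = .design_fluxes(),          # placeholder, overwritten below
    affinity = .default_affinity(),
    regulatory = .default_regulatory(),
    po_ratio = 1.25,
    gln_threshold = 0.3,
    gln_hill = 4,
    creatine_total = 600,
    mw_mab = 150000,                  # g/mol, for titer unit conversion
    biomass_coeffs = c(
      stats::setNames(rep(-1.2e-4, nAA), AA_SHARED),
      GLN = -3e-4, G6P = -5e-5, R5P = -8e-5, ACCOA = -8e-5, OAA = -1e-4,
      GLU = -1e-4, ATP = -1.625e-3, ADP = 1.625e-3, NADPH = -3e-4,
      NADP = 3e-4),
    mab_coeffs = c(
      stats::setNames(rep(-65, nAA), AA_SHARED),
      GLN = -70, ATP = -4, ADP = 4)
  ), class = "cho_params")

  # invert rate laws at the design state for the vmax values; threshold
  # factors are excluded (they are ~0 at 2 mM glutamine by design)
  reg <- regulation_config(regulation)
  st <- .op_state()
  tgt <- .design_fluxes()
  for (r in net$reactions) {
    ff <- .factor_product(r$fwd, r$reg, "fwd", st, params, reg,
                          skip_thresh = TRUE)
    if (is.null(r$vmax_r)) {
      params$vmax[r$vmax] <- tgt[r$vmax] / ff
    } else if (!r$pair) {
      # single-vmax reversible: target is the net flux
      fr <- .factor_product(r$rev, r$reg, "rev", st, params, reg,
                            skip_thresh = TRUE)
      params$vmax[r$vmax] <- tgt[r$vmax] / (ff - fr)
    } else {
      fr <- .factor_product(r$rev, r$reg, "rev", st, params, reg,
                            skip_thresh = TRUE)
      params$vmax[r$vmax] <- tgt[r$vmax] / ff
      params$vmax[r$vmax_r] <- tgt[r$vmax_r] / fr
    }
  }
  params$vmax["vmaxgrowth"] <- tgt["vmaxgrowth"] /
    .factor_product(net$reactions[[which(net$reaction_ids == "growth")]]$fwd,
                    list(), "fwd", st, params, reg)
  params
}

#' @export
print.cho_params <- function(x, ...) {
  cat("CHO model parameter set\n")
  cat(sprintf("  vmax: %d  affinity: %d  regulatory: %d  (total kinetic: %d)\n",
              length(x$vmax), length(x$affinity), length(x$regulatory),
              length(x$vmax) + length(x$affinity) + length(x$regulatory)))
  cat(sprintf("  P/O ratio %.2f, glutamine threshold %.2g mM\n",
              x$po_ratio, x$gln_threshold))
  invisible(x)
}

# ---- flat named-vector access (used by fitting and sweeps) ----------------

#' Get kinetic parameters as a flat named vector
#'
#' @param params a `cho_params` object.
#' @param which subset of blocks, any of `"vmax"`, `"affinity"`,
#'   `"regulatory"`.
#' @return named numeric vector.
#' @export
param_vector <- function(params, which = c("vmax", "affinity", "regulatory")) {
  unlist(lapply(which, function(b) params[[b]]))
}

#' Replace kinetic parameters from a flat named vector
#'
#' @param params a `cho_params` object.
#' @param values named numeric vector; names must be existing kinetic
#'   parameter names.
#' @return modified `cho_params` object.
#' @export
param_update <- function(params, values) {
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("'values' must be a named vector")
  for (nm in names(values)) {
    hit <- FALSE
    for (b in c("vmax", "affinity", "regulatory")) {
      if (nm %in% names(params[[b]])) {
        params[[b]][nm] <- values[[nm]]
        hit <- TRUE
        break
      }
    }
    if (!hit) stop("unknown parameter: ", nm)
  }
  params
}
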