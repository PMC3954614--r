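# Canonical CHO-cell metabolic network: 35 lumped reactions over 46 state
# variables (cell density, mAb titer, 23 extracellular metabolites, 21
# intracellular pools). Cofactors enter rate laws as nucleotide ratios;
# carbon lumping keeps CoA, fumarate, CO2, O2 and Pi out of the state.

AA_EXTRACELLULAR <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU_x",
                      "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                      "PRO", "SER", "THR", "TRP", "TYR", "VAL")

# amino acids entering growth/mAb kinetics individually (glutamine has its
# own affinity constant; all others share one, as lumped protein precursors)
AA_SHARED <- setdiff(AA_EXTRACELLULAR, c("GLN", "GLU_x"))

.cho_species <- function() {
  intr <- c("G6P", "F6P", "GAP", "PEP", "PYR", "R5P", "ACCOA", "CIT", "AKG",
            "SUC", "MAL", "OAA", "GLU", "ATP", "ADP", "AMP", "NAD", "NADH",
            "NADP", "NADPH", "PCR")
  cof <- c("ATP", "ADP", "AMP", "NAD", "NADH", "NADP", "NADPH", "PCR")
  sp <- data.frame(
    id = c("Xv", "mAb", "GLC", "LAC", "NH4", AA_EXTRACELLULAR, intr),
    compartment = c("culture", "culture",
                    rep("extracellular", 3 + length(AA_EXTRACELLULAR)),
                    rep("intracellular", length(intr))),
    stringsAsFactors = FALSE
  )
  sp$unit <- ifelse(sp$id == "Xv", "1e6 cells/mL",
             ifelse(sp$id == "mAb", "mg/L",
             ifelse(sp$compartment == "extracellular", "mM",
                    "nmol/1e6 cells")))
  sp$measured <- sp$id %in% c("Xv", "mAb", "GLC", "LAC", "NH4", "GLN",
                              "GLU_x", "ALA", "ASP", "ASN", "SER",
                              "G6P", "PEP", "PYR", "SUC", "AKG", "MAL")
  # growth dilution applies to carbon intermediates, not to cofactor moieties
  sp$dilution_applies <- sp$compartment == "intracellular" & !(sp$id %in% cof)
  grp <- c(ALA = "PYR", SER = "PYR", GLY = "PYR", THR = "PYR", CYS = "PYR",
           TRP = "PYR", HIS = "GLU", ARG = "GLU", PRO = "GLU", LYS = "SUC",
           ILE = "SUC", LEU = "SUC", VAL = "SUC", TYR = "SUC", MET = "SUC",
           PHE = "SUC", ASN = "OAA", ASP = "OAA")
  sp$aa_group <- unname(grp[sp$id])
  sp
}

# ---- kinetic factor constructors (shared by the R and C++ flux engines) ----
.f_sat     <- function(sp, km) list(type = "sat", sp = sp, km = km)
.f_satpool <- function(sps, km) list(type = "satpool", sp = sps, km = km)
.f_satprod <- function(sps, km) list(type = "satprod", sp = sps, km = km)
.f_rsat    <- function(num, den, km) list(type = "rsat", sp = c(num, den), km = km)
.f_runit   <- function(num, den) list(type = "runit", sp = c(num, den), km = NA)
.f_satcr   <- function(km) list(type = "satcr", sp = "PCR", km = km)
.f_thresh  <- function() list(type = "thresh", sp = "GLN", km = NA)
# regulation factors carry the term id so scenarios can switch them off
.f_inhib <- function(term, sp, k) list(type = "inhib", sp = sp, km = k, term = term)
.f_act   <- function(term, sp, k) list(type = "act", sp = sp, km = k, term = term)

.rxn <- function(id, stoich, vmax, fwd, vmax_r = NULL, rev = NULL,
                 pair = FALSE, reg = list()) {
  list(id = id, stoich = stoich, vmax = vmax, fwd = fwd,
       vmax_r = vmax_r, rev = rev, pair = pair, reg = reg)
}

.cho_reactions <- function() {
  nAA <- length(AA_SHARED)
  aa_b <- stats::setNames(rep(-1.2e-4, nAA), AA_SHARED)   # biomass drain / unit growth
  aa_m <- stats::setNames(rep(-65, nAA), AA_SHARED)       # mmol AA per mmol mAb
  list(
    .rxn("HK", c(GLC = -1, G6P = 1, ATP = -1, ADP = 1), "vmaxHK",
         list(.f_sat("GLC", "Km_HK_GLC"), .f_runit("ATP", "ADP")),
         reg = list(.f_inhib("I", "G6P", "Ki_HK_G6P"))),
    # single-vmax reversible: net = vmax * (fwd factors - rev factors)
    .rxn("PGI", c(G6P = -1, F6P = 1), "vmaxPGI",
         list(.f_sat("G6P", "Km_PGI_G6P")),
         vmax_r = "vmaxPGI", rev = list(.f_sat("F6P", "Km_PGI_F6P")),
         reg = list(.f_inhib("II", "PEP", "Ki_PGI_PEP"))),
    .rxn("PFK", c(F6P = -1, GAP = 2, ATP = -1, ADP = 1), "vmaxPFK",
         list(.f_sat("F6P", "Km_PFK_F6P"), .f_runit("ATP", "ADP")),
         reg = list(.f_inhib("III", "G6P", "Ki_PFK_G6P"))),
    # lumped GAPDH..enolase: 1 NADH and 1 ATP per triose
    .rxn("PGK", c(GAP = -1, PEP = 1, NAD = -1, NADH = 1, ADP = -1, ATP = 1),
         "vmaxPGK",
         list(.f_sat("GAP", "Km_PGK_GAP"), .f_runit("NAD", "NADH"),
              .f_runit("ADP", "ATP"))),
    .rxn("PK", c(PEP = -1, PYR = 1, ADP = -1, ATP = 1), "vmaxPK",
         list(.f_sat("PEP", "Km_PK_PEP"), .f_runit("ADP", "ATP")),
         reg = list(.f_act("IV", "F6P", "Ka_PK_F6P"))),
    .rxn("LDH", c(PYR = -1, LAC = 1, NADH = -1, NAD = 1), "vmaxfLDH",
         list(.f_sat("PYR", "Km_LDH_PYR"), .f_runit("NADH", "NAD")),
         vmax_r = "vmaxrLDH",
         # lactate uptake, like alanine uptake, is a compensation for
         # glutamine depletion: the reverse direction carries the same
         # depletion-threshold gate as reverse AlaTA
         rev = list(.f_sat("LAC", "Km_LDH_LAC"), .f_runit("NAD", "NADH"),
                    .f_thresh()),
         pair = TRUE,
         reg = list(.f_inhib("V", "LAC", "Ki_LDH_LAC"))),
    # oxidative PPP lumped to R5P + 2 NADPH (CO2 out)
    .rxn("G6PDH", c(G6P = -1, R5P = 1, NADP = -2, NADPH = 2), "vmaxG6PDH",
         list(.f_sat("G6P", "Km_G6PDH_G6P"), .f_runit("NADP", "NADPH"))),
    # non-oxidative PPP: 3 R5P -> 2 F6P + GAP
    .rxn("EP", c(R5P = -1, F6P = 2 / 3, GAP = 1 / 3), "vmaxEP",
         list(.f_sat("R5P", "Km_EP_R5P"))),
    .rxn("PDH", c(PYR = -1, ACCOA = 1, NAD = -1, NADH = 1), "vmaxPDH",
         list(.f_sat("PYR", "Km_PDH_PYR"), .f_runit("NAD", "NADH"))),
    .rxn("CS", c(ACCOA = -1, OAA = -1, CIT = 1), "vmaxCS",
         list(.f_sat("ACCOA", "Km_CS_ACCOA"), .f_sat("OAA", "Km_CS_OAA"))),
    # aconitase + isocitrate dehydrogenase lumped
    .rxn("CITS", c(CIT = -1, AKG = 1, NAD = -1, NADH = 1), "vmaxCITS",
         list(.f_sat("CIT", "Km_CITS_CIT"), .f_runit("NAD", "NADH"))),
    # AKG dehydrogenase lumped through succinyl-CoA to succinate
    .rxn("AKGDH", c(AKG = -1, SUC = 1, NAD = -1, NADH = 1), "vmaxAKGDH",
         list(.f_sat("AKG", "Km_AKGDH_AKG"), .f_runit("NAD", "NADH"))),
    # substrate-level phosphorylation at the succinyl-CoA node; carbon carried
    # by AKGDH, SUC acts as the kinetic effector only
    .rxn("SCOAS", c(ADP = -1, ATP = 1), "vmaxSCOAS",
         list(.f_sat("SUC", "Km_SCOAS_SUC"), .f_runit("ADP", "ATP"))),
    # SDH + fumarase lumped; FADH2 folded into the NADH pool
    .rxn("SDHFUM", c(SUC = -1, MAL = 1, NAD = -1, NADH = 1), "vmaxSDHFUM",
         list(.f_sat("SUC", "Km_SDHFUM_SUC"), .f_runit("NAD", "NADH"))),
    .rxn("MLD", c(MAL = -1, OAA = 1, NAD = -1, NADH = 1), "vmaxMLD",
         list(.f_sat("MAL", "Km_MLD_MAL"), .f_runit("NAD", "NADH")),
         vmax_r = "vmaxMLD",
         rev = list(.f_sat("OAA", "Km_MLD_OAA"), .f_runit("NADH", "NAD"))),
    .rxn("PC", c(PYR = -1, OAA = 1, ATP = -1, ADP = 1), "vmaxPC",
         list(.f_sat("PYR", "Km_PC_PYR"), .f_runit("ATP", "ADP"))),
    .rxn("ME", c(MAL = -1, PYR = 1, NADP = -1, NADPH = 1), "vmaxME",
         list(.f_sat("MAL", "Km_ME_MAL"), .f_runit("NADP", "NADPH"))),
    # forward = glutaminase-side uptake of extracellular glutamine; reverse
    # (glutamine synthesis, "GlnT") regenerates it from intracellular GLU
    .rxn("GLNS", c(GLN = -1, GLU = 1, NH4 = 1), "vmaxfGLNS",
         list(.f_sat("GLN", "Km_GLNS_GLN")),
         vmax_r = "vmaxrGLNS", rev = list(.f_sat("GLU", "Km_GLNS_GLU")),
         pair = TRUE),
    # glutamate dehydrogenase; reverse flux is the NH4-detoxifying direction
    .rxn("GLDH", c(GLU = -1, AKG = 1, NH4 = 1, NAD = -1, NADH = 1),
         "vmaxfGLDH",
         list(.f_sat("GLU", "Km_GLDH_GLU"), .f_runit("NAD", "NADH")),
         vmax_r = "vmaxrGLDH",
         rev = list(.f_sat("AKG", "Km_GLDH_AKG"), .f_sat("NH4", "Km_GLDH_NH4"),
                    .f_runit("NADH", "NAD")),
         pair = TRUE),
    # forward produces alanine; reverse (alanine uptake) is gated by the
    # extracellular-glutamine depletion threshold
    .rxn("AlaTA", c(PYR = -1, GLU = -1, ALA = 1, AKG = 1), "vmaxfAlaTA",
         list(.f_sat("PYR", "Km_AlaTA_PYR")),
         vmax_r = "vmaxrAlaTA",
         rev = list(.f_sat("ALA", "Km_AlaTA_ALA"), .f_thresh()),
         pair = TRUE),
    # exchange of extracellular aspartate for intracellular oxaloacetate
    .rxn("ASTA", c(ASP = -1, AKG = -1, OAA = 1, GLU = 1), "vmaxfASTA",
         list(.f_sat("ASP", "Km_ASTA_ASP"), .f_sat("AKG", "Km_ASTA_AKG")),
         vmax_r = "vmaxrASTA", rev = list(.f_sat("OAA", "Km_ASTA_OAA")),
         pair = TRUE),
    .rxn("ASX", c(ASN = -1, ASP = 1, NH4 = 1), "vmaxASX",
         list(.f_sat("ASN", "Km_ASX_ASN"))),
    .rxn("GluT", c(GLU = -1, GLU_x = 1), "vmaxGluT",
         list(.f_sat("GLU", "Km_GluT_GLU"))),
    .rxn("SAL", c(SER = -1, PYR = 1), "vmaxSAL",
         list(.f_sat("SER", "Km_SAL_SER"))),
    # lumped catabolism of the pyruvate-family pool (ALA via AlaTA, SER via
    # SAL have dedicated reactions)
    .rxn("AAPYRTA",
         c(GLY = -0.25, THR = -0.25, CYS = -0.25, TRP = -0.25, PYR = 1),
         "vmaxAAPYRTA",
         list(.f_satpool(c("GLY", "THR", "CYS", "TRP"), "Km_AAPYRTA_pool"))),
    .rxn("HISARGTA",
         c(HIS = -1 / 3, ARG = -1 / 3, PRO = -1 / 3, GLU = 1),
         "vmaxHISARGTA",
         list(.f_satpool(c("HIS", "ARG", "PRO"), "Km_HISARGTA_pool"))),
    .rxn("LYSILELEUVALTYRTA",
         c(LYS = -1 / 7, ILE = -1 / 7, LEU = -1 / 7, VAL = -1 / 7,
           TYR = -1 / 7, MET = -1 / 7, PHE = -1 / 7, SUC = 1,
           NAD = -1, NADH = 1),
         "vmaxLYSILELEUVALTYRTA",
         list(.f_satpool(c("LYS", "ILE", "LEU", "VAL", "TYR", "MET", "PHE"),
                         "Km_LYSTA_pool"))),
    # oxidative phosphorylation: ATP coefficient 2*(P/O) filled from params
    .rxn("resp", c(NADH = -1, NAD = 1, ADP = NA, ATP = NA), "vmaxresp",
         list(.f_rsat("NADH", "NAD", "K_resp_NADH"),
              .f_rsat("ADP", "ATP", "K_resp_ADP"))),
    # mitochondrial proton leak: NADH oxidation uncoupled from ATP
    .rxn("leak", c(NADH = -1, NAD = 1), "vmaxleak",
         list(.f_rsat("NADH", "NAD", "K_leak_NADH"))),
    .rxn("ATPase", c(ATP = -1, ADP = 1), "vmaxATPase",
         list(.f_runit("ATP", "ADP"))),
    .rxn("NADPHox", c(NADPH = -1, NADP = 1), "vmaxNADPHox",
         list(.f_sat("NADPH", "Km_NADPHox_NADPH"))),
    # creatine kinase; forward is the ATP-forming direction (PCr + ADP)
    .rxn("CK", c(PCR = -1, ADP = -1, ATP = 1), "vmaxfCK",
         list(.f_sat("PCR", "Km_CK_PCR"), .f_runit("ADP", "ATP")),
         vmax_r = "vmaxrCK",
         rev = list(.f_satcr("Km_CK_CR"), .f_runit("ATP", "ADP")),
         pair = TRUE),
    # adenylate kinase; reverse (2 ADP -> ATP + AMP) is ATP-forming
    .rxn("AK", c(ATP = -1, AMP = -1, ADP = 2), "vmaxfAK",
         list(.f_sat("AMP", "Km_AK_AMP")),
         vmax_r = "vmaxrAK", rev = list(.f_sat("ADP", "Km_AK_ADP")),
         pair = TRUE),
    # growth: flux equals the specific growth rate mu (1/h); precursor and
    # amino-acid coefficients filled from the biomass composition parameters
    .rxn("growth", c(Xv = 1), "vmaxgrowth",
         list(.f_sat("GLN", "Km_growth_GLN"),
              .f_satprod(AA_SHARED, "Km_growth_AA"),
              .f_runit("ATP", "ADP"))),
    .rxn("mAb", c(mAb = 1), "vmaxmAb",
         list(.f_satprod(AA_SHARED, "Km_mAb_AA"),
              .f_runit("ATP", "ADP")))
  )
}

#' Build the canonical CHO metabolic network
#'
#' Assembles the bundled reconstruction of the regulated CHO-cell central
#' carbon and energy metabolism network: glycolysis, pentose phosphate
#' pathway, TCA cycle, glutaminolysis, lumped amino-acid catabolism (three
#' groups entering the TCA cycle via succinate, oxaloacetate and
#' alpha-ketoglutarate, plus a pyruvate-family pool), respiration with proton
#' leak, energy buffering (creatine and adenylate kinases), growth and mAb
#' synthesis. The network has exactly 35 reactions and 46 state variables;
#' 7 reactions carry independent forward/reverse maximum rates, giving 42
#' maximum-rate parameters.
#'
#' @return An object of class `cho_network` with elements `species`
#'   (data frame), `reactions` (list), `moieties` (conserved cofactor
#'   groups) and `aliases` (alternative reaction names used in the
#'   literature for the same lumped steps).
#' @examples
#' net <- cho_network()
#' net
#' @export
cho_network <- function() {
  sp <- .cho_species()
  rx <- .cho_reactions()
  net <- structure(list(
    species = sp,
    reactions = rx,
    reaction_ids = vapply(rx, `[[`, "", "id"),
    moieties = list(
      adenylate = c("ATP", "ADP", "AMP"),
      nad = c("NAD", "NADH"),
      nadp = c("NADP", "NADPH"),
      creatine = "PCR"  # CR is implicit: creatine_total - PCR
    ),
    aa_groups = split(sp$id[!is.na(sp$aa_group)],
                      sp$aa_group[!is.na(sp$aa_group)]),
    aliases = c(GlnT = "GLNS", LYSILELEUHISVALTYRTA = "LYSILELEUVALTYRTA",
                `SDH/FUM` = "SDHFUM", ML = "MLD")
  ), class = "cho_network")
  net
}

#' @export
print.cho_network <- function(x, ...) {
  cat("CHO kinetic-metabolic network reconstruction\n")
  cat(sprintf("  species   : %d (%d extracellular, %d intracellular)\n",
              nrow(x$species), sum(x$species$compartment == "extracellular"),
              sum(x$species$compartment == "intracellular")))
  np <- sum(vapply(x$reactions, `[[`, FALSE, "pair"))
  cat(sprintf("  reactions : %d (%d reversible pairs -> %d vmax parameters)\n",
              length(x$reactions), np, length(x$reactions) + np))
  invisible(x)
}

#' Stoichiometric matrix of the network
#'
#' Returns the signed species-by-reaction stoichiometric matrix. Reversible
#' reactions appear once (net-flux convention). The respiration column's
#' ATP/ADP coefficients equal `2 * po_ratio`, and the growth/mAb columns are
#' filled from the biomass and mAb composition vectors, so the matrix is a
#' function of the parameter set.
#'
#' @param net a [cho_network()] object.
#' @param params a [cho_parameters()] parameter set.
#' @return numeric matrix with `species` rows and `reaction` columns.
#' @export
stoichiometric_matrix <- function(net, params = cho_parameters()) {
  sp_ids <- net$species$id
  S <- matrix(0, nrow(net$species), length(net$reactions),
              dimnames = list(sp_ids, net$reaction_ids))
  for (j in seq_along(net$reactions)) {
    st <- net$reactions[[j]]$stoich
    bad <- setdiff(names(st), sp_ids)
    if (length(bad))
      stop("unknown species id in reaction ", net$reaction_ids[j], ": ",
           paste(bad, collapse = ", "))
    S[names(st), j] <- st
  }
  S["ATP", "resp"] <- 2 * params$po_ratio
  S["ADP", "resp"] <- -2 * params$po_ratio
  b <- params$biomass_coeffs
  S[names(b), "growth"] <- S[names(b), "growth"] + b
  m <- params$mab_coeffs
  S[names(m), "mAb"] <- S[names(m), "mAb"] + m
  S
}

# all affinity-constant names referenced by the kinetic specification,
# in reaction order; must number exactly 48
.affinity_names <- function(net = cho_network()) {
  out <- character(0)
  for (r in net$reactions) {
    for (f in c(r$fwd, r$rev))
      if (!is.na(f$km[1]) && f$type != "thresh") out <- c(out, f$km)
  }
  unique(out)
}

.regulatory_names <- function(net = cho_network()) {
  out <- character(0)
  for (r in net$reactions) for (f in r$reg) out <- c(out, f$km)
  unique(out)
}

#' Validate the network and parameter set against the canonical counts
#'
#' Checks the structural contract of the bundled model: 35 reactions, 46
#' state variables, 7 reversible pairs (42 maximum-rate parameters), 48
#' affinity constants and 5 regulatory constants (95 kinetic parameters in
#' total), conservation of the cofactor moiety groups by every reaction
#' except growth and mAb synthesis, and full catabolic-group coverage of the
#' amino acids. Returns a report rather than raising on failure.
#'
#' @param net a [cho_network()] object.
#' @param params a [cho_parameters()] parameter set.
#' @return data frame with columns `check`, `expected`, `found`, `pass`.
#' @examples
#' rep <- validate_network(cho_network(), cho_parameters())
#' all(rep$pass)
#' @export
validate_network <- function(net, params = cho_parameters()) {
  rows <- list()
  add <- function(check, expected, found)
    rows[[length(rows) + 1]] <<- data.frame(
      check = check, expected = expected, found = found,
      pass = isTRUE(all.equal(expected, found)), stringsAsFactors = FALSE)

  add("reactions", 35, length(net$reactions))
  add("species", 46, nrow(net$species))
  npair <- sum(vapply(net$reactions, `[[`, FALSE, "pair"))
  add("reversible pairs", 7, npair)
  add("vmax parameters", 42, length(params$vmax))
  add("affinity constants", 48, length(params$affinity))
  add("regulatory constants", 5, length(params$regulatory))
  add("kinetic parameters", 95,
      length(params$vmax) + length(params$affinity) + length(params$regulatory))

  S <- tryCatch(stoichiometric_matrix(net, params), error = function(e) NULL)
  if (!is.null(S)) {
    keep <- !(colnames(S) %in% c("growth", "mAb"))
    mo <- net$moieties
    closure <- c(
      adenylate = max(abs(colSums(S[mo$adenylate, keep, drop = FALSE]))),
      nad = max(abs(colSums(S[mo$nad, keep, drop = FALSE]))),
      nadp = max(abs(colSums(S[mo$nadp, keep, drop = FALSE])))
    )
    add("moiety closure (max |net coeff|)", 0, unname(max(closure)))
  } else add("moiety closure (max |net coeff|)", 0, NA_real_)

  aa <- net$species[net$species$id %in% AA_EXTRACELLULAR, ]
  ungrouped <- aa$id[is.na(aa$aa_group) & !(aa$id %in% c("GLN", "GLU_x"))]
  add("ungrouped amino acids", 0, length(ungrouped))
  add("positive parameters", 0, sum(unlist(
    params[c("vmax", "affinity", "regulatory")]) <= 0))
  do.call(rbind, rows)
}
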