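# Rate laws: every flux is vmax times a product of dimensionless factors —
# one Michaelis-Menten saturation term per kinetic substrate, a
# nucleotide-ratio driving force, and any enabled regulation factors.
# Reversible steps return (forward - reverse). This R engine defines the
# reference semantics; the compiled integrator mirrors it and is tested
# against it.

#' Michaelis-Menten saturation term
#'
#' @param conc substrate concentration (>= 0).
#' @param km half-saturation constant (> 0), in the substrate's units.
#' @return `conc / (km + conc)`, in `[0, 1)`.
#' @examples
#' saturation_term(2, 2)   # 0.5
#' @export
saturation_term <- function(conc, km) {
  if (any(km <= 0)) stop("'km' must be positive")
  if (any(conc < 0)) stop("'conc' must be non-negative")
  conc / (km + conc)
}

#' Hyperbolic inhibition factor
#'
#' @param effector inhibitor concentration (>= 0).
#' @param ki inhibition constant (> 0).
#' @return `1 / (1 + effector/ki)`, in `(0, 1]`.
#' @export
inhibition_factor <- function(effector, ki) {
  if (any(ki <= 0)) stop("'ki' must be positive")
  if (any(effector < 0)) stop("'effector' must be non-negative")
  1 / (1 + effector / ki)
}

#' Hyperbolic activation factor
#'
#' @param effector activator concentration (>= 0).
#' @param ka activation constant (> 0).
#' @return `effector / (ka + effector)`, in `[0, 1)`.
#' @export
activation_factor <- function(effector, ka) {
  if (any(ka <= 0)) stop("'ka' must be positive")
  if (any(effector < 0)) stop("'effector' must be non-negative")
  effector / (ka + effector)
}

#' Glutamine-depletion threshold activation
#'
#' Smooth switch that turns on alanine uptake once extracellular glutamine
#' falls below a threshold concentration: a decreasing Hill sigmoid equal to
#' 0.5 at the threshold, ~1 at depletion and ~0 at media-level glutamine.
#'
#' @param gln_ext extracellular glutamine (mM, >= 0).
#' @param threshold threshold concentration (mM, > 0; default 0.3).
#' @param hill Hill steepness (default 4).
#' @return value in `[0, 1]`.
#' @examples
#' threshold_activation(0.3, 0.3)  # 0.5 at the midpoint
#' @export
threshold_activation <- function(gln_ext, threshold = 0.3, hill = 4) {
  if (any(threshold <= 0)) stop("'threshold' must be positive")
  1 / (1 + (gln_ext / threshold)^hill)
}

#' Regulation scenario configuration
#'
#' The model carries five glycolytic regulation terms: hexokinase inhibition
#' by G6P (I), phosphoglucose isomerase inhibition by PEP (II),
#' phosphofructokinase inhibition by G6P (III), pyruvate kinase activation
#' by F6P (IV) and inhibition of the lactate dehydrogenase forward reaction
#' (V). Scenarios mirror the four simulated cases used to fine-tune the
#' model structure: none, term I only, terms I+II, or all five.
#'
#' @param scenario one of `"none"`, `"I"`, `"I+II"`, `"all"`.
#' @param enable,disable optional character vectors of term ids overriding
#'   the scenario for individual terms.
#' @return object of class `cho_regulation`: named logical vector over
#'   terms I..V.
#' @examples
#' regulation_config("I+II")
#' @export
regulation_config <- function(scenario = c("I+II", "none", "I", "all"),
                              enable = NULL, disable = NULL) {
  scenario <- match.arg(scenario)
  terms <- c("I", "II", "III", "IV", "V")
  on <- switch(scenario,
               none = character(0),
               I = "I",
               `I+II` = c("I", "II"),
               all = terms)
  flags <- stats::setNames(terms %in% on, terms)
  if (!is.null(enable)) flags[enable] <- TRUE
  if (!is.null(disable)) flags[disable] <- FALSE
  structure(flags, scenario = scenario, class = "cho_regulation")
}

# look up an affinity/regulatory constant by name
.kval <- function(params, name) {
  if (name %in% names(params$affinity)) return(params$affinity[[name]])
  if (name %in% names(params$regulatory)) return(params$regulatory[[name]])
  stop("unknown kinetic constant: ", name)
}

.eval_factor <- function(f, state, params) {
  switch(f$type,
    sat = saturation_term(state[[f$sp]], .kval(params, f$km)),
    satpool = saturation_term(sum(state[f$sp]), .kval(params, f$km)),
    satprod = prod(saturation_term(state[f$sp], .kval(params, f$km))),
    rsat = {
      r <- state[[f$sp[1]]] / max(state[[f$sp[2]]], 1e-12)
      r / (.kval(params, f$km) + r)
    },
    runit = {
      r <- state[[f$sp[1]]] / max(state[[f$sp[2]]], 1e-12)
      r / (1 + r)
    },
    inhib = inhibition_factor(state[[f$sp]], .kval(params, f$km)),
    act = activation_factor(state[[f$sp]], .kval(params, f$km)),
    thresh = threshold_activation(state[[f$sp]], params$gln_threshold,
                                  params$gln_hill),
    satcr = saturation_term(max(params$creatine_total - state[["PCR"]], 0),
                            .kval(params, f$km)),
    stop("unknown factor type: ", f$type)
  )
}

# product of kinetic factors and enabled regulation factors for one
# direction of a reaction
.factor_product <- function(factors, reg, dir, state, params, regcfg,
                            skip_thresh = FALSE) {
  v <- 1
  for (f in factors) {
    if (skip_thresh && f$type == "thresh") next
    v <- v * .eval_factor(f, state, params)
  }
  if (dir == "fwd") {
    for (f in reg) {
      if (isTRUE(regcfg[[f$term]])) v <- v * .eval_factor(f, state, params)
    }
  }
  v
}

#' Rate of a single reaction at a given state
#'
#' @param rxn reaction id (see [cho_network()]).
#' @param state named non-negative state vector (46 entries, or any vector
#'   containing the species the reaction uses).
#' @param params a [cho_parameters()] object.
#' @param net a [cho_network()] object.
#' @param regulation a [regulation_config()] object or scenario string.
#' @return net flux in mmol/(1e6 cells)/h, positive in the forward
#'   (arrow) direction.
#' @export
reaction_rate <- function(rxn, state, params = cho_parameters(),
                          net = cho_network(), regulation = "I+II") {
  if (is.character(regulation)) regulation <- regulation_config(regulation)
  j <- match(rxn, net$reaction_ids)
  if (is.na(j)) stop("unknown reaction id: ", rxn)
  if (any(state < 0)) stop("negative concentration in 'state'")
  r <- net$reactions[[j]]
  v <- params$vmax[[r$vmax]] *
    .factor_product(r$fwd, r$reg, "fwd", state, params, regulation)
  if (!is.null(r$vmax_r))
    v <- v - params$vmax[[r$vmax_r]] *
      .factor_product(r$rev, r$reg, "rev", state, params, regulation)
  unname(v)
}

#' All 35 reaction fluxes at a given state
#'
#' @inheritParams reaction_rate
#' @return named numeric vector of net fluxes in network reaction order,
#'   mmol/(1e6 cells)/h.
#' @examples
#' net <- cho_network(); p <- cho_parameters(net)
#' v <- flux_vector(chometab:::.op_state(), p, net)
#' v["HK"]
#' @export
flux_vector <- function(state, params = cho_parameters(),
                        net = cho_network(), regulation = "I+II") {
  if (is.character(regulation)) regulation <- regulation_config(regulation)
  vapply(net$reaction_ids, reaction_rate, 0, state = state, params = params,
         net = net, regulation = regulation)
}
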