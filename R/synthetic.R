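# In-silico experiments with known ground truth: clone specifications
# (parental, low- and high-producer), duplicate-flask sampling and
# multiplicative log-normal measurement noise, emulating the shake-flask
# design the model was built for (seed 2e5 cells/mL, 30 mM glucose, 4 mM
# glutamine, cumate induction at 48 h, sampling every 24 h for 6 days,
# duplicate flasks).

#' Clone specification
#'
#' A clone is the parental parameter set with multiplicative overrides on
#' named kinetic parameters plus its mAb expression characteristics. The
#' bundled specifications echo the reported clonal differences: the
#' high-producer raises pyruvate dehydrogenase, pyruvate carboxylase,
#' glutamate-dehydrogenase-forward and reverse-LDH rates (net pyruvate flux
#' into the TCA cycle up, lactate switch to consumption after glutamine
#' depletion) and lowers forward LDH and malic enzyme; the low-producer
#' mainly changes reverse LDH and the lumped ATPase; and the high-producer
#' carries a leakier inducible switch.
#'
#' @param name one of `"parental"`, `"low"`, `"high"`, or any label when
#'   `overrides` is given explicitly.
#' @param overrides named numeric vector of multiplicative parameter
#'   overrides (relative to parental defaults).
#' @param mab_vmax_multiplier multiplier on the induced mAb maximum rate.
#' @param leaky_fraction pre-/non-induced mAb rate as a fraction of induced.
#' @return object of class `clone_spec`.
#' @examples
#' clone_spec("high")
#' @export
clone_spec <- function(name = c("parental", "low", "high"),
                       overrides = NULL, mab_vmax_multiplier = NULL,
                       leaky_fraction = NULL) {
  if (is.null(overrides) || is.null(mab_vmax_multiplier) ||
      is.null(leaky_fraction)) {
    name <- match.arg(name)
    def <- switch(name,
      parental = list(ov = c(), mult = 1, leak = 0.1),
      low = list(ov = c(vmaxrLDH = 1.6, vmaxATPase = 1.2),
                 mult = 120, leak = 0.08),
      high = list(ov = c(vmaxrLDH = 12, vmaxATPase = 2.4, vmaxPDH = 2.2,
                         vmaxPC = 1.6, vmaxfGLDH = 1.5, vmaxfASTA = 1.7,
                         vmaxfLDH = 0.55, vmaxME = 0.6, vmaxfGLNS = 1.25,
                         vmaxresp = 2.2, vmaxCS = 1.8, vmaxCITS = 1.8,
                         vmaxAKGDH = 1.5, vmaxSDHFUM = 1.6, vmaxMLD = 1.5),
                  mult = 500, leak = 0.35))
    if (is.null(overrides)) overrides <- def$ov
    if (is.null(mab_vmax_multiplier)) mab_vmax_multiplier <- def$mult
    if (is.null(leaky_fraction)) leaky_fraction <- def$leak
  } else if (length(name) > 1) name <- name[1]
  stopifnot(all(overrides > 0), mab_vmax_multiplier > 0,
            leaky_fraction >= 0, leaky_fraction <= 1)
  structure(list(name = name, overrides = overrides,
                 mab_vmax_multiplier = mab_vmax_multiplier,
                 leaky_fraction = leaky_fraction),
            class = "clone_spec")
}

#' Apply a clone specification to a base parameter set
#'
#' @param spec a [clone_spec()].
#' @param base parental [cho_parameters()].
#' @return a `cho_params` object with the multiplicative overrides applied
#'   (tagged so the same spec is not applied twice).
#' @export
make_clone <- function(spec, base = cho_parameters()) {
  stopifnot(inherits(spec, "clone_spec"))
  if (identical(attr(base, "clone"), spec$name) && spec$name != "parental")
    stop("clone spec '", spec$name, "' already applied to this parameter set")
  p <- base
  if (length(spec$overrides)) {
    bad <- setdiff(names(spec$overrides), names(param_vector(p)))
    if (length(bad)) stop("unknown parameter in overrides: ",
                          paste(bad, collapse = ", "))
    cur <- param_vector(p)[names(spec$overrides)]
    p <- param_update(p, cur * spec$overrides)
  }
  p$vmax["vmaxmAb"] <- p$vmax["vmaxmAb"] * spec$mab_vmax_multiplier
  attr(p, "clone") <- spec$name
  p
}

#' Measurement-noise model
#'
#' Multiplicative log-normal noise (concentrations are positive) with a
#' per-variable-class coefficient of variation and a small absolute floor
#' for near-zero signals, duplicate flasks by default.
#'
#' @param cv relative standard deviation (default 0.05, i.e. 5%).
#' @param replicates number of replicate flasks (default 2).
#' @param floor absolute minimum standard deviation, in each variable's
#'   units (applied additively on the measurement scale).
#' @return object of class `noise_model`.
#' @export
noise_model <- function(cv = 0.05, replicates = 2, floor = 1e-3) {
  stopifnot(cv >= 0, replicates >= 1, floor >= 0)
  structure(list(cv = cv, replicates = replicates, floor = floor),
            class = "noise_model")
}

# default measured variables for a synthetic experiment: the assayed
# extracellular metabolites, cell density and titer, two intracellular
# sugar phosphates / organic acids, nucleotide ratios and respiration
.default_observed <- function() {
  c("Xv", "GLC", "GLN", "LAC", "NH4", "ALA", "SER", "ASP", "GLU_x", "mAb",
    "G6P", "PEP", "PYR", "SUC", "ATP_ADP", "NADH_NAD", "qO2")
}

#' Generate a synthetic shake-flask experiment
#'
#' Simulates a clone under the given schedule, samples the measured
#' variables at the schedule's sample times, and draws replicate noisy
#' copies with multiplicative log-normal noise. Returns both the noisy
#' observation set (with per-variable pooled variances) and the noise-free
#' ground truth.
#'
#' @param spec a [clone_spec()].
#' @param schedule a [cho_schedule()]; its leaky fraction is taken from the
#'   clone spec.
#' @param noise a [noise_model()].
#' @param seed integer RNG seed; the draw is reproducible given the seed.
#' @param observed character vector of observed variable names (state ids
#'   or derived quantities `ATP_ADP`, `NADH_NAD`, `NADPH_NADP`, `qO2`).
#' @param base parental parameter set.
#' @param net,regulation model inputs.
#' @return list with `observations` (a `cho_obs` object), `truth` (the
#'   noise-free `cho_trajectory`), `params` (ground-truth parameters) and
#'   `spec`.
#' @examples
#' \donttest{
#' exp1 <- generate_experiment(clone_spec("parental"), seed = 1)
#' head(exp1$observations$records)
#' }
#' @export
generate_experiment <- function(spec = clone_spec("parental"),
                                schedule = cho_schedule(),
                                noise = noise_model(), seed = 1,
                                observed = .default_observed(),
                                base = cho_parameters(),
                                net = cho_network(), regulation = "I+II") {
  schedule$leaky_fraction <- spec$leaky_fraction
  if (spec$name == "parental") schedule$induced <- FALSE
  params <- make_clone(spec, base)
  truth <- simulate_batch(params, schedule, net, regulation)
  tt <- schedule$sample_times
  rec <- list()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  sdlog <- sqrt(log(1 + noise$cv^2))
  for (v in observed) {
    y <- .traj_value(truth, v, tt)
    for (r in seq_len(noise$replicates)) {
      # unbiased in the log domain; additive floor keeps near-zero signals
      # from collapsing to exactly zero spread
      val <- y * exp(stats::rnorm(length(y), -sdlog^2 / 2, sdlog)) +
        stats::rnorm(length(y), 0, noise$floor)
      rec[[length(rec) + 1]] <- data.frame(
        time_h = tt, variable = v, replicate = r, value = val,
        stringsAsFactors = FALSE)
    }
  }
  obs <- cho_observations(do.call(rbind, rec))
  list(observations = obs, truth = truth, params = params, spec = spec)
}

#' Reference panel of five synthetic cultures
#'
#' The experimental design being emulated: the parental clone plus the
#' high- and low-producer clones each with and without induction, all in
#' duplicate flasks. Clone parameters are shared between the induced and
#' non-induced cultures of the same clone; only the mAb rate schedule
#' differs.
#'
#' @param seed integer; seeds for the five datasets are derived from it.
#' @param noise a [noise_model()].
#' @param ... passed to [generate_experiment()].
#' @return named list of five experiment objects: `parental`,
#'   `low_induced`, `low_control`, `high_induced`, `high_control`.
#' @export
reference_panel <- function(seed = 1, noise = noise_model(), ...) {
  cases <- list(
    parental = list(spec = clone_spec("parental"), induced = FALSE),
    low_induced = list(spec = clone_spec("low"), induced = TRUE),
    low_control = list(spec = clone_spec("low"), induced = FALSE),
    high_induced = list(spec = clone_spec("high"), induced = TRUE),
    high_control = list(spec = clone_spec("high"), induced = FALSE)
  )
  out <- list()
  for (i in seq_along(cases)) {
    sch <- cho_schedule(induced = cases[[i]]$induced)
    out[[names(cases)[i]]] <- generate_experiment(
      cases[[i]]$spec, schedule = sch, noise = noise,
      seed = seed * 100 + i, ...)
  }
  out
}
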