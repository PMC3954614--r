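# Batch-culture integration. Mass balances:
#   dXv/dt    = mu * Xv                         (viable density, 1e6 cells/mL)
#   dC/dt     = s * v * Xv * 1000               (extracellular, mM/h)
#   dc/dt     = s * v * 1e6 - [dilution] mu * c (intracellular, nmol/1e6c/h)
#   d[mAb]/dt = v_mAb * Xv * 1000 * MW          (titer, mg/L/h)
# with fluxes v in mmol/(1e6 cells)/h. Induction switches the mAb maximum
# rate by restarting the integration at the induction time.

#' Default seeding state for a shake-flask batch culture
#'
#' Seed density 0.2e6 cells/mL in medium with 30 mM glucose and 4 mM
#' glutamine; other amino acids at typical chemically-defined-medium levels;
#' intracellular pools at the model's design operating point.
#'
#' @param net a [cho_network()] object.
#' @return named state vector (46 entries).
#' @export
initial_state <- function(net = cho_network()) {
  st <- .op_state()
  st[c("Xv", "mAb", "GLC", "GLN", "LAC", "NH4", "GLU_x", "ALA")] <-
    c(0.2, 0, 30, 4, 0.3, 0.1, 0.3, 0.3)
  st[c("ASP", "ASN", "SER")] <- c(0.6, 0.6, 0.8)
  # low-abundance amino acids start at media levels comfortably above the
  # biomass drain so that glutamine, not a trace amino acid, limits growth
  st[c("TRP", "CYS", "MET", "HIS", "PHE", "TYR", "PRO", "GLY")] <-
    c(0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.9, 1.0)
  st[net$species$id]
}

#' Batch-culture schedule
#'
#' Encodes the experimental design being emulated: 6-day shake-flask batch,
#' sampling every 24 h, optional cumate induction at 48 h.
#'
#' @param t_end culture duration (h).
#' @param induction_time induction event time (h), in `(0, t_end)`.
#' @param induced logical; if `FALSE` the mAb maximum rate stays at its leaky
#'   fraction for the whole culture.
#' @param leaky_fraction pre-induction (and non-induced) mAb rate as a
#'   fraction of the induced maximum.
#' @param sample_times observation times (h), within `[0, t_end]`.
#' @param initial_state starting state; see [initial_state()].
#' @return object of class `cho_schedule`.
#' @export
cho_schedule <- function(t_end = 144, induction_time = 48, induced = TRUE,
                         leaky_fraction = 0.1,
                         sample_times = seq(0, t_end, by = 24),
                         initial_state = chometab::initial_state()) {
  stopifnot(t_end > 0, induction_time > 0, induction_time < t_end,
            all(sample_times >= 0), all(sample_times <= t_end),
            leaky_fraction >= 0, leaky_fraction <= 1)
  structure(list(t_end = t_end, induction_time = induction_time,
                 induced = induced, leaky_fraction = leaky_fraction,
                 sample_times = sort(unique(sample_times)),
                 initial_state = initial_state),
            class = "cho_schedule")
}

# factor type codes shared with src/model.cpp
.FTYPE <- c(sat = 1L, satpool = 2L, satprod = 3L, rsat = 4L, runit = 5L,
            inhib = 6L, act = 7L, thresh = 8L, satcr = 9L)

# flatten network + parameters + regulation into the arrays the compiled
# engine consumes; mab_scale rescales the mAb maximum rate for the current
# induction phase
.pack_model <- function(net, params, regulation, mab_scale = 1) {
  if (is.character(regulation)) regulation <- regulation_config(regulation)
  sp_ids <- net$species$id
  idx <- function(id) match(id, sp_ids) - 1L
  nr <- length(net$reactions)
  vmax_f <- numeric(nr); vmax_r <- numeric(nr)
  fr <- fd <- ft <- fi1 <- fi2 <- integer(0)
  fc1 <- fc2 <- numeric(0)
  pools <- list()
  add_factor <- function(f, j, dir) {
    type <- .FTYPE[[f$type]]
    i1 <- i2 <- -1L; c1 <- c2 <- 0
    if (f$type %in% c("satpool", "satprod")) {
      pools[[length(pools) + 1]] <<- idx(f$sp)
      i1 <- length(pools) - 1L
      c1 <- .kval(params, f$km)
    } else if (f$type %in% c("rsat", "runit")) {
      i1 <- idx(f$sp[1]); i2 <- idx(f$sp[2])
      if (f$type == "rsat") c1 <- .kval(params, f$km)
    } else if (f$type == "thresh") {
      i1 <- idx("GLN"); c1 <- params$gln_threshold; c2 <- params$gln_hill
    } else if (f$type == "satcr") {
      i1 <- idx("PCR"); c1 <- .kval(params, f$km); c2 <- params$creatine_total
    } else {
      i1 <- idx(f$sp); c1 <- .kval(params, f$km)
    }
    fr <<- c(fr, j - 1L); fd <<- c(fd, if (dir == "fwd") 0L else 1L)
    ft <<- c(ft, type); fi1 <<- c(fi1, i1); fi2 <<- c(fi2, i2)
    fc1 <<- c(fc1, c1); fc2 <<- c(fc2, c2)
  }
  for (j in seq_len(nr)) {
    r <- net$reactions[[j]]
    vmax_f[j] <- params$vmax[[r$vmax]]
    if (r$id == "mAb") vmax_f[j] <- vmax_f[j] * mab_scale
    for (f in r$fwd) add_factor(f, j, "fwd")
    for (f in r$reg) if (isTRUE(regulation[[f$term]])) add_factor(f, j, "fwd")
    if (!is.null(r$vmax_r)) {
      vmax_r[j] <- params$vmax[[r$vmax_r]]
      for (f in r$rev) add_factor(f, j, "rev")
    }
  }
  kind <- ifelse(sp_ids == "Xv", 0L,
          ifelse(sp_ids == "mAb", 3L,
          ifelse(net$species$compartment == "extracellular", 1L, 2L)))
  list(S = stoichiometric_matrix(net, params),
       kind = as.integer(kind),
       dil = as.integer(net$species$dilution_applies),
       vmax_f = vmax_f, vmax_r = vmax_r,
       growth = match("growth", net$reaction_ids) - 1L,
       mw = params$mw_mab,
       fr = fr, fd = fd, ft = ft, fi1 = fi1, fi2 = fi2,
       fc1 = fc1, fc2 = fc2,
       pool_off = as.integer(c(0, cumsum(lengths(pools)))[seq_along(pools)]),
       pool_len = as.integer(lengths(pools)),
       pool_sp = as.integer(unlist(pools)))
}

#' Time derivative of the batch-culture state (reference implementation)
#'
#' Pure-R right-hand side of the culture mass balances; used as the
#' reference semantics for the compiled integrator and by the fixed-step
#' oracle in the test suite.
#'
#' @param t time (h); the mAb rate uses the leaky fraction before
#'   `schedule$induction_time` (and throughout if not induced).
#' @param state named non-negative state vector.
#' @param params,net,regulation model inputs as in [flux_vector()].
#' @param schedule a [cho_schedule()] object.
#' @param S optional precomputed [stoichiometric_matrix()].
#' @return named derivative vector, same layout as `state`.
#' @export
state_derivative <- function(t, state, params = cho_parameters(),
                             net = cho_network(), regulation = "I+II",
                             schedule = cho_schedule(), S = NULL) {
  xc <- pmax(state, 0)
  scale <- if (schedule$induced && t >= schedule$induction_time) 1
           else schedule$leaky_fraction
  p2 <- params
  p2$vmax["vmaxmAb"] <- p2$vmax["vmaxmAb"] * scale
  v <- flux_vector(xc, p2, net, regulation)
  if (is.null(S)) S <- stoichiometric_matrix(net, params)
  acc <- drop(S %*% v)
  mu <- v[["growth"]]
  kind <- ifelse(net$species$id == "Xv", 0L,
          ifelse(net$species$id == "mAb", 3L,
          ifelse(net$species$compartment == "extracellular", 1L, 2L)))
  dy <- numeric(length(state))
  Xv <- xc[["Xv"]]
  for (i in seq_along(state)) {
    dy[i] <- switch(kind[i] + 1L,
      acc[i] * Xv,
      acc[i] * Xv * 1000,
      acc[i] * 1e6 - if (net$species$dilution_applies[i]) mu * xc[i] else 0,
      acc[i] * Xv * 1000 * params$mw_mab)
  }
  names(dy) <- names(state)
  dy
}

#' Simulate a batch culture
#'
#' Integrates the 46 mass balances over the culture schedule with the
#' compiled adaptive Runge-Kutta solver, restarting at the induction time to
#' switch the mAb maximum rate, and evaluates all 35 fluxes and the derived
#' quantities along the returned grid.
#'
#' @param params a [cho_parameters()] object.
#' @param schedule a [cho_schedule()] object.
#' @param net a [cho_network()] object.
#' @param regulation a [regulation_config()] object or scenario string.
#' @param times output times (h); defaults to an hourly grid merged with the
#'   schedule's sample times.
#' @param rtol,atol relative/absolute solver tolerances.
#' @return object of class `cho_trajectory`: list with `times`, `states`
#'   (time x species matrix), `fluxes` (time x reaction), `derived` (data
#'   frame with qO2, nucleotide ratios, growth rate) and the call inputs.
#' @examples
#' \donttest{
#' traj <- simulate_batch(cho_parameters(), cho_schedule(induced = FALSE))
#' plot(traj, c("Xv", "GLC", "GLN", "LAC"))
#' }
#' @export
simulate_batch <- function(params = cho_parameters(),
                           schedule = cho_schedule(),
                           net = cho_network(), regulation = "I+II",
                           times = NULL, rtol = 1e-7, atol = 1e-9) {
  if (is.null(times))
    times <- sort(unique(c(seq(0, schedule$t_end, by = 1),
                           schedule$sample_times, schedule$induction_time)))
  stopifnot(all(diff(times) > 0), times[1] >= 0,
            times[length(times)] <= schedule$t_end)
  if (schedule$induced)
    times <- sort(unique(c(times, schedule$induction_time)))
  y0 <- schedule$initial_state[net$species$id]
  if (any(is.na(y0))) stop("initial state is missing species")

  phases <- if (schedule$induced) {
    list(list(scale = schedule$leaky_fraction,
              times = times[times <= schedule$induction_time]),
         list(scale = 1, times = times[times >= schedule$induction_time]))
  } else list(list(scale = schedule$leaky_fraction, times = times))

  states <- NULL
  for (ph in phases) {
    if (length(ph$times) < 2) {
      if (is.null(states)) states <- matrix(y0, 1,
                                            dimnames = list(NULL, names(y0)))
      next
    }
    pack <- .pack_model(net, params, regulation, mab_scale = ph$scale)
    res <- cpp_simulate(pack, y0, ph$times, rtol, atol,
                        hmax = 1, maxsteps = 500000L)
    if (!isTRUE(res$ok))
      stop(sprintf("integration failed at t = %.3f h: %s", res$t, res$msg))
    seg <- res$states
    colnames(seg) <- net$species$id
    states <- if (is.null(states)) seg else rbind(states, seg[-1, , drop = FALSE])
    y0 <- seg[nrow(seg), ]
  }
  rownames(states) <- NULL

  # fluxes along the trajectory, honouring the induction phases
  fl <- matrix(NA_real_, length(times), length(net$reaction_ids),
               dimnames = list(NULL, net$reaction_ids))
  pre <- if (schedule$induced) times < schedule$induction_time else
    rep(TRUE, length(times))
  pack_pre <- .pack_model(net, params, regulation,
                          mab_scale = schedule$leaky_fraction)
  if (any(pre)) fl[pre, ] <- cpp_fluxes(pack_pre, states[pre, , drop = FALSE])
  if (any(!pre)) {
    pack_post <- .pack_model(net, params, regulation, mab_scale = 1)
    fl[!pre, ] <- cpp_fluxes(pack_post, states[!pre, , drop = FALSE])
  }

  derived <- data.frame(
    time = times,
    qO2 = 0.5 * (fl[, "resp"] + fl[, "leak"]),
    ATP_ADP = states[, "ATP"] / pmax(states[, "ADP"], 1e-12),
    NADH_NAD = states[, "NADH"] / pmax(states[, "NAD"], 1e-12),
    NADPH_NADP = states[, "NADPH"] / pmax(states[, "NADP"], 1e-12),
    mu = fl[, "growth"]
  )
  structure(list(times = times, states = states, fluxes = fl,
                 derived = derived, schedule = schedule, params = params,
                 regulation = regulation, net = net),
            class = "cho_trajectory")
}

#' @export
print.cho_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("CHO batch-culture trajectory: %d time points over %.0f h\n",
              n, x$times[n]))
  cat(sprintf("  final Xv %.2f e6/mL, GLC %.1f mM, GLN %.3f mM, LAC %.1f mM, mAb %.1f mg/L\n",
              x$states[n, "Xv"], x$states[n, "GLC"], x$states[n, "GLN"],
              x$states[n, "LAC"], x$states[n, "mAb"]))
  invisible(x)
}

#' @export
as.data.frame.cho_trajectory <- function(x, ...) {
  long <- function(m, kind) data.frame(
    time_h = rep(x$times, ncol(m)),
    variable = rep(colnames(m), each = nrow(m)),
    value = as.vector(m), kind = kind, stringsAsFactors = FALSE)
  der <- as.matrix(x$derived[, -1])
  rbind(long(x$states, "state"), long(x$fluxes, "flux"),
        data.frame(time_h = rep(x$times, ncol(der)),
                   variable = rep(colnames(der), each = nrow(der)),
                   value = as.vector(der), kind = "derived",
                   stringsAsFactors = FALSE))
}

#' @export
plot.cho_trajectory <- function(x, variables = c("Xv", "GLC", "GLN", "LAC"),
                                ...) {
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(variables)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (v in variables) {
    y <- if (v %in% colnames(x$states)) x$states[, v]
         else if (v %in% colnames(x$fluxes)) x$fluxes[, v]
         else x$derived[[v]]
    graphics::plot(x$times, y, type = "l", xlab = "time (h)", ylab = v, ...)
  }
  invisible(x)
}

#' Cell-specific rates along a trajectory
#'
#' @param traj a [simulate_batch()] trajectory.
#' @return data frame with time and the specific rates qGlc, qGln (forward
#'   minus reverse glutaminase flux), qLac (net LDH), qO2
#'   (`0.5 * (resp + leak)`), growth rate mu and qmAb, all in
#'   mmol/(1e6 cells)/h (mu in 1/h).
#' @export
specific_rates <- function(traj) {
  fl <- traj$fluxes
  data.frame(
    time = traj$times,
    qGlc = fl[, "HK"],
    qGln = fl[, "GLNS"],
    qLac = fl[, "LDH"],
    qO2 = 0.5 * (fl[, "resp"] + fl[, "leak"]),
    mu = fl[, "growth"],
    qmAb = fl[, "mAb"]
  )
}

# interpolate a trajectory variable (state, flux or derived) at given times
.traj_value <- function(traj, variable, times) {
  y <- if (variable %in% colnames(traj$states)) traj$states[, variable]
  else if (variable %in% colnames(traj$fluxes)) traj$fluxes[, variable]
  else if (variable %in% names(traj$derived)) traj$derived[[variable]]
  else stop("unknown trajectory variable: ", variable)
  stats::approx(traj$times, y, xout = times, rule = 2)$y
}
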