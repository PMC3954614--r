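# Shared fixtures, built in code. Expensive objects are memoised per session.
.fix <- new.env()

fx_net <- function() {
  if (is.null(.fix$net)) .fix$net <- cho_network()
  .fix$net
}
fx_params <- function() {
  if (is.null(.fix$params)) .fix$params <- cho_parameters(fx_net())
  .fix$params
}
fx_op_state <- function() chometab:::.op_state()[fx_net()$species$id]

# noise-free parental experiment on the default schedule (shared)
fx_parental_truth <- function() {
  if (is.null(.fix$parental)) {
    .fix$parental <- generate_experiment(
      clone_spec("parental"), cho_schedule(induced = FALSE),
      noise_model(cv = 0, floor = 0), seed = 1,
      base = fx_params(), net = fx_net())
  }
  .fix$parental
}

# noise-free induced/control high-producer truths (shared)
fx_high_pair <- function() {
  if (is.null(.fix$high_pair)) {
    spec <- clone_spec("high")
    p <- make_clone(spec, fx_params())
    ind <- simulate_batch(p, cho_schedule(induced = TRUE,
                                          leaky_fraction = spec$leaky_fraction),
                          fx_net())
    ctl <- simulate_batch(p, cho_schedule(induced = FALSE,
                                          leaky_fraction = spec$leaky_fraction),
                          fx_net())
    .fix$high_pair <- list(spec = spec, params = p, induced = ind,
                           control = ctl)
  }
  .fix$high_pair
}

# independent fixed-step classical RK4 integrator over the R reference rhs
rk4_solve <- function(params, schedule, net, times, dt,
                      regulation = "I+II") {
  y <- schedule$initial_state[net$species$id]
  out <- matrix(NA_real_, length(times), length(y),
                dimnames = list(NULL, names(y)))
  out[1, ] <- y
  t <- times[1]
  for (k in 2:length(times)) {
    while (t < times[k] - 1e-12) {
      h <- min(dt, times[k] - t)
      k1 <- state_derivative(t, y, params, net, regulation, schedule)
      k2 <- state_derivative(t + h / 2, y + h / 2 * k1, params, net,
                             regulation, schedule)
      k3 <- state_derivative(t + h / 2, y + h / 2 * k2, params, net,
                             regulation, schedule)
      k4 <- state_derivative(t + h, y + h * k3, params, net, regulation,
                             schedule)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[k, ] <- y
  }
  out
}

# brute-force double-loop WSSRES accumulation (independent of wssres())
wssres_bruteforce <- function(obs, traj) {
  total <- 0
  for (v in unique(obs$means$variable)) {
    var_m <- obs$variance[[v]]
    rows <- obs$means[obs$means$variable == v, ]
    for (k in seq_len(nrow(rows))) {
      sim <- stats::approx(traj$times, chometab:::.traj_value(traj, v, traj$times),
                           xout = rows$time_h[k], rule = 2)$y
      total <- total + (sim - rows$value[k])^2 / var_m
    }
  }
  total
}
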