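# Weighted-least-squares calibration. The objective is the weighted sum of
# squared residuals between measured and simulated values,
#   WSSRES = sum_m sum_k (Xsim[m,k] - Xmea[m,k])^2 / var_m ,
# with one pooled replicate variance per measured variable. Optimisation is
# Levenberg-Marquardt on log10-scaled free parameters (rates are positive
# and span decades); confidence intervals are asymptotic linearised
# intervals from the weighted residual Jacobian.

#' Construct an observation set
#'
#' @param records data frame with columns `time_h`, `variable`, `replicate`,
#'   `value`. Variables are state ids or derived quantities (`ATP_ADP`,
#'   `NADH_NAD`, `NADPH_NADP`, `qO2`).
#' @param variance optional named per-variable variance; by default the
#'   replicate variances are pooled over time per variable.
#' @return object of class `cho_obs` with elements `records`, `means`
#'   (per variable/time replicate means) and `variance`.
#' @export
cho_observations <- function(records, variance = NULL) {
  need <- c("time_h", "variable", "replicate", "value")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("observation records lack column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(records$value))
    stop("column 'value' must be numeric")
  agg <- stats::aggregate(value ~ variable + time_h, records, mean)
  if (is.null(variance)) {
    pv <- stats::aggregate(value ~ variable + time_h, records,
                           function(x) if (length(x) > 1) stats::var(x) else NA)
    variance <- tapply(pv$value, pv$variable, mean, na.rm = TRUE)
    variance[!is.finite(variance)] <- NA
    # fall back to a 5% CV guess when replicates are absent
    fallback <- tapply(agg$value, agg$variable, function(x) (0.05 * mean(abs(x)))^2)
    variance[is.na(variance)] <- fallback[is.na(variance)]
    variance <- pmax(unlist(variance), 1e-12)
  } else {
    variance <- unlist(variance)
    if (any(variance <= 0)) stop("variances must be positive")
  }
  vars <- unique(records$variable)
  if (!all(vars %in% names(variance)))
    stop("variance missing for: ",
         paste(setdiff(vars, names(variance)), collapse = ", "))
  structure(list(records = records, means = agg,
                 variance = variance[vars]),
            class = "cho_obs")
}

#' @export
print.cho_obs <- function(x, ...) {
  cat(sprintf("CHO culture observations: %d variables, %d time points, %d records\n",
              length(unique(x$records$variable)),
              length(unique(x$records$time_h)), nrow(x$records)))
  invisible(x)
}

# weighted residual vector (sim - mea)/sd_m over all (variable, time) pairs
.wresiduals <- function(obs, traj) {
  m <- obs$means
  sd_m <- sqrt(obs$variance[m$variable])
  sim <- numeric(nrow(m))
  for (v in unique(m$variable)) {
    i <- m$variable == v
    sim[i] <- .traj_value(traj, v, m$time_h[i])
  }
  (sim - m$value) / sd_m
}

#' Weighted sum of squared residuals between observations and a simulation
#'
#' @param obs a [cho_observations()] object.
#' @param traj a [simulate_batch()] trajectory spanning the observation
#'   times; simulated values are linearly interpolated to them.
#' @return non-negative number.
#' @export
wssres <- function(obs, traj) {
  if (max(obs$means$time_h) > max(traj$times) + 1e-9)
    stop("observation times extend beyond the simulated span")
  sum(.wresiduals(obs, traj)^2)
}

# simulate with a flat parameter override (values on natural scale)
.sim_with <- function(values, base, obs_times, schedule, net, regulation,
                      rtol = 1e-7, atol = 1e-9) {
  p <- if (length(values)) param_update(base, values) else base
  times <- sort(unique(c(0, obs_times, schedule$induction_time)))
  simulate_batch(p, schedule, net, regulation, times = times,
                 rtol = rtol, atol = atol)
}

#' Fit kinetic parameters to culture observations
#'
#' Bounded Levenberg-Marquardt least squares on log10-scaled parameters,
#' minimising the WSSRES objective. Returns a classed fit object with the
#' usual modelling methods (`print`, `summary`, `coef`, `confint`,
#' `predict`, `residuals`).
#'
#' @param obs a [cho_observations()] object.
#' @param start starting [cho_parameters()] (the reported estimates reuse
#'   this as initial values, mirroring practice of warm-starting from a
#'   previously calibrated cell line).
#' @param free character vector of free parameter names (any of the 95
#'   kinetic parameters); typically the sensitive subset from
#'   [screen_parameters()].
#' @param schedule,net,regulation simulation inputs describing the culture.
#' @param bounds multiplicative bounds around the start value (default
#'   `[start/100, start*100]`).
#' @param control list: `maxit` (outer iterations, default 12), `ftol`
#'   (relative objective tolerance, 1e-8), `h` (log10 finite-difference
#'   step, 1e-3), `rtol`/`atol` solver tolerances during fitting.
#' @return object of class `cho_fit`.
#' @export
fit_culture <- function(obs, start = cho_parameters(), free,
                        schedule = cho_schedule(), net = cho_network(),
                        regulation = "I+II", bounds = 100,
                        control = list()) {
  ctl <- utils::modifyList(list(maxit = 12L, ftol = 1e-8, h = 1e-3,
                                rtol = 1e-6, atol = 1e-8), control)
  p0 <- param_vector(start)
  bad <- setdiff(free, names(p0))
  if (length(bad)) stop("unknown free parameter(s): ",
                        paste(bad, collapse = ", "))
  obs_times <- sort(unique(obs$means$time_h))
  rfun <- function(theta) {
    vals <- stats::setNames(10^theta, free)
    traj <- .sim_with(vals, start, obs_times, schedule, net, regulation,
                      ctl$rtol, ctl$atol)
    .wresiduals(obs, traj)
  }
  theta <- log10(p0[free])
  lo <- theta - log10(bounds); hi <- theta + log10(bounds)

  r <- rfun(theta)
  ssr <- sum(r^2)
  ssr0 <- ssr
  nfree <- length(free)
  trace <- ssr
  J <- NULL
  converged <- TRUE
  done <- FALSE
  if (nfree > 0) {
    lambda <- 1e-3
    for (it in seq_len(ctl$maxit)) {
      if (done) break
      J <- matrix(0, length(r), nfree)
      for (j in seq_len(nfree)) {
        tj <- theta; tj[j] <- min(tj[j] + ctl$h, hi[j] + ctl$h)
        J[, j] <- (rfun(tj) - r) / (tj[j] - theta[j])
      }
      g <- crossprod(J, r)
      if (max(abs(g)) < 1e-10) break
      A <- crossprod(J)
      improved <- FALSE
      for (inner in 1:10) {
        M <- A + lambda * diag(diag(A) + 1e-12, nfree)
        delta <- tryCatch(drop(solve(M, -g)), error = function(e) NULL)
        if (is.null(delta)) { lambda <- lambda * 10; next }
        thn <- pmin(pmax(theta + delta, lo), hi)
        rn <- rfun(thn)
        ssrn <- sum(rn^2)
        if (is.finite(ssrn) && ssrn < ssr) {
          theta <- thn; r <- rn
          impr <- (ssr - ssrn) / max(ssr, 1e-300)
          ssr <- ssrn
          trace <- c(trace, ssr)
          lambda <- max(lambda / 3, 1e-10)
          improved <- TRUE
          if (impr < ctl$ftol) done <- TRUE
          break
        }
        lambda <- lambda * 5
      }
      if (!improved) break
    }
    # final Jacobian at the optimum for the covariance
    J <- matrix(0, length(r), nfree)
    for (j in seq_len(nfree)) {
      tj <- theta; tj[j] <- tj[j] + ctl$h
      J[, j] <- (rfun(tj) - r) / ctl$h
    }
    colnames(J) <- free
  }
  if (ssr > ssr0 + 1e-12) converged <- FALSE

  est <- stats::setNames(10^theta, free)
  fit <- structure(list(
    estimates = if (nfree) param_update(start, est) else start,
    theta = theta, free = free, start = start,
    wssres = ssr, wssres_start = ssr0, trace = trace,
    jacobian = J, residuals = r,
    df = length(r) - nfree,
    obs = obs, schedule = schedule, net = net, regulation = regulation,
    converged = converged
  ), class = "cho_fit")
  fit
}

# asymptotic linearised intervals from a residual Jacobian; returns the
# standard errors (same scale as the fitted coefficients) and the half-width
# t-quantile factor. Rank-deficient directions get infinite SEs.
.wald_se <- function(J, rss, df) {
  p <- ncol(J)
  s2 <- rss / df
  A <- crossprod(J)
  cv <- tryCatch(solve(A), error = function(e) NULL)
  rankdef <- FALSE
  if (is.null(cv)) {
    sv <- svd(A)
    pos <- sv$d > max(sv$d) * 1e-12
    rankdef <- any(!pos)
    dinv <- ifelse(pos, 1 / sv$d, Inf)
    cv <- sv$v %*% (dinv * t(sv$u))
  }
  se <- sqrt(pmax(diag(cv) * s2, 0))
  if (rankdef)
    warning("rank-deficient Jacobian: infinite intervals reported for unidentifiable directions")
  list(se = se, cov = cv * s2, rankdef = rankdef)
}

#' @export
coef.cho_fit <- function(object, ...) {
  stats::setNames(10^object$theta, object$free)
}

#' @export
residuals.cho_fit <- function(object, ...) object$residuals

#' Confidence intervals for fitted kinetic parameters
#'
#' Asymptotic linearised intervals: t-quantile times the standard error from
#' the weighted-Jacobian covariance, computed on the log10 scale the
#' optimiser works on and transformed back.
#'
#' @param object a [fit_culture()] fit.
#' @param parm optional subset of free parameter names.
#' @param level confidence level (default 0.95).
#' @param ... unused.
#' @return matrix with columns `estimate`, `low`, `high`, `se_log10`.
#' @export
confint.cho_fit <- function(object, parm = object$free, level = 0.95, ...) {
  if (!length(object$free)) return(matrix(numeric(0), 0, 4))
  w <- .wald_se(object$jacobian, object$wssres, object$df)
  tq <- stats::qt(1 - (1 - level) / 2, object$df)
  th <- object$theta
  out <- cbind(estimate = 10^th,
               low = 10^(th - tq * w$se),
               high = 10^(th + tq * w$se),
               se_log10 = w$se)
  rownames(out) <- object$free
  out[parm, , drop = FALSE]
}

#' Predict culture trajectories from a fit
#'
#' @param object a [fit_culture()] fit.
#' @param variables trajectory variables to return.
#' @param times prediction times (h); defaults to the observation times.
#' @param interval `"none"` or `"confidence"` (delta-method 95% band on the
#'   model prediction, using the same linearisation as the parameter
#'   intervals).
#' @param level confidence level.
#' @param ... unused.
#' @return data frame with `time_h`, `variable`, `fit` and, with a
#'   confidence interval, `low`/`high`.
#' @export
predict.cho_fit <- function(object, variables = unique(object$obs$means$variable),
                            times = NULL, interval = c("none", "confidence"),
                            level = 0.95, ...) {
  interval <- match.arg(interval)
  if (is.null(times)) times <- sort(unique(object$obs$means$time_h))
  sim <- function(vals) .sim_with(vals, object$start, times, object$schedule,
                                  object$net, object$regulation)
  est <- coef(object)
  traj <- sim(est)
  out <- do.call(rbind, lapply(variables, function(v) data.frame(
    time_h = times, variable = v, fit = .traj_value(traj, v, times),
    stringsAsFactors = FALSE)))
  if (interval == "confidence" && length(object$free)) {
    w <- .wald_se(object$jacobian, object$wssres, object$df)
    h <- 1e-3
    G <- matrix(0, nrow(out), length(object$free))
    for (j in seq_along(object$free)) {
      ej <- est; ej[j] <- ej[j] * 10^h
      tj <- sim(ej)
      pj <- unlist(lapply(variables, function(v) .traj_value(tj, v, times)))
      G[, j] <- (pj - out$fit) / h
    }
    sep <- sqrt(pmax(rowSums((G %*% w$cov) * G), 0))
    tq <- stats::qt(1 - (1 - level) / 2, object$df)
    out$low <- out$fit - tq * sep
    out$high <- out$fit + tq * sep
  }
  out
}

#' @export
print.cho_fit <- function(x, ...) {
  cat("CHO batch-culture kinetic fit\n")
  cat(sprintf("  free parameters: %d; WSSRES %.4g (start %.4g)%s\n",
              length(x$free), x$wssres, x$wssres_start,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (length(x$free)) print(signif(coef(x), 4))
  invisible(x)
}

#' @export
summary.cho_fit <- function(object, ...) {
  ci <- confint(object)
  cat("CHO batch-culture kinetic fit\n")
  cat(sprintf("  observations: %d residuals, %d free parameters, WSSRES %.4g\n",
              length(object$residuals), length(object$free), object$wssres))
  if (length(object$free)) {
    print(signif(ci, 4))
  }
  invisible(ci)
}

#' @export
plot.cho_fit <- function(x, variables = c("Xv", "GLC", "GLN", "LAC"), ...) {
  pr <- predict(x, variables = variables,
                times = seq(0, x$schedule$t_end, by = 2))
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(variables)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (v in variables) {
    pv <- pr[pr$variable == v, ]
    ov <- x$obs$records[x$obs$records$variable == v, ]
    graphics::plot(pv$time_h, pv$fit, type = "l", xlab = "time (h)",
                   ylab = v, ylim = range(c(pv$fit, ov$value)), ...)
    graphics::points(ov$time_h, ov$value, pch = 1)
  }
  invisible(x)
}

#' Screen parameters by one-at-a-time sensitivity of the objective
#'
#' Each candidate parameter is perturbed over a relative-deviation grid,
#' the WSSRES recomputed, and the parameter ranked by the maximum relative
#' change of the normalised objective. Parameters whose maximum deviation
#' stays below the threshold are frozen at their initial value for the
#' optimisation cycle.
#'
#' @param obs a [cho_observations()] object.
#' @param params parameter set around which to screen.
#' @param parameters candidate parameter names (default: all 42 maximum
#'   rates).
#' @param grid relative deviations (default the global sweep grid).
#' @param threshold sensitivity threshold on `|normalised WSSRES - 1|`
#'   (default 0.15, i.e. deviations of 15% and higher count as sensitive).
#' @param schedule,net,regulation simulation inputs.
#' @return list with `sensitive`, `frozen` (character vectors, `sensitive`
#'   ordered by decreasing influence) and `map` (the underlying
#'   `sens_map`).
#' @export
screen_parameters <- function(obs, params = cho_parameters(),
                              parameters = names(params$vmax),
                              grid = c(-0.85, -0.5, -0.25, -0.1, 0,
                                       0.1, 0.25, 0.5, 1, 2, 3),
                              threshold = 0.15,
                              schedule = cho_schedule(), net = cho_network(),
                              regulation = "I+II") {
  map <- global_sweep(obs, params, parameters = parameters, grid = grid,
                      schedule = schedule, net = net, regulation = regulation)
  cls <- classify_sensitive(map, threshold)
  dev <- apply(abs(map$values - 1), 1, max, na.rm = TRUE)
  list(sensitive = cls$sensitive[order(-dev[cls$sensitive])],
       frozen = cls$insensitive, map = map)
}

#' Compare two fitted parameter sets (clone comparison)
#'
#' Two-sided Wald z-tests on the log10-scale estimates,
#' `z = (thetaA - thetaB) / sqrt(seA^2 + seB^2)`, one per shared free
#' parameter; mirrors the pairwise clone-versus-control comparison of
#' calibrated parameter values.
#'
#' @param fitA,fitB two [fit_culture()] objects with identical free
#'   parameter sets.
#' @param alpha significance level for the flagged set (default 0.1,
#'   matching the `p < 0.1` annotation convention).
#' @return data frame with estimates, z and p per parameter, plus the
#'   flagged significant set as attribute `"significant"`.
#' @export
compare_fits <- function(fitA, fitB, alpha = 0.1) {
  if (!identical(sort(fitA$free), sort(fitB$free)))
    stop("fits have different free parameter sets")
  o <- match(fitA$free, fitB$free)
  seA <- .wald_se(fitA$jacobian, fitA$wssres, fitA$df)$se
  seB <- .wald_se(fitB$jacobian, fitB$wssres, fitB$df)$se[o]
  z <- (fitA$theta - fitB$theta[o]) / sqrt(seA^2 + seB^2)
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(parameter = fitA$free,
                    estimateA = 10^fitA$theta,
                    estimateB = 10^fitB$theta[o],
                    z = z, p = p, significant = p < alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "significant") <- out$parameter[out$significant]
  out
}
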