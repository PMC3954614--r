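# One-at-a-time sensitivity sweeps: parameters varied from -85% to +300% of
# their reference value, WSSRES recomputed for each perturbation and
# normalised to the unperturbed (0% change) objective.

#' Global one-at-a-time sensitivity sweep
#'
#' @param obs a [cho_observations()] object supplying the objective.
#' @param params reference parameter set (ideally at an optimum).
#' @param parameters parameter names to sweep (default: all 42 maximum
#'   rates).
#' @param grid relative deviations; the default spans -85% to +300%.
#' @param variable optional variable name: restrict the objective to that
#'   single measured variable (the per-variable partial sweep).
#' @param schedule,net,regulation simulation inputs.
#' @return object of class `sens_map`: list with `grid`, `values`
#'   (parameter x grid matrix of normalised WSSRES; failed simulations are
#'   `NA`) and `wssres0`.
#' @export
global_sweep <- function(obs, params = cho_parameters(),
                         parameters = names(params$vmax),
                         grid = c(-0.85, -0.5, -0.25, -0.1, 0,
                                  0.1, 0.25, 0.5, 1, 2, 3),
                         variable = NULL,
                         schedule = cho_schedule(), net = cho_network(),
                         regulation = "I+II") {
  if (!length(grid)) stop("'grid' must be non-empty")
  if (!is.null(variable)) {
    keep <- obs$records$variable %in% variable
    if (!any(keep)) stop("unknown variable: ", variable)
    obs <- cho_observations(obs$records[keep, ],
                            variance = obs$variance[variable])
  }
  obs_times <- sort(unique(obs$means$time_h))
  p0 <- param_vector(params)
  bad <- setdiff(parameters, names(p0))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  obj <- function(vals) {
    traj <- tryCatch(
      .sim_with(vals, params, obs_times, schedule, net, regulation),
      error = function(e) NULL)
    if (is.null(traj)) NA_real_ else wssres(obs, traj)
  }
  w0 <- obj(stats::setNames(numeric(0), character(0)))
  if (!is.finite(w0) || w0 <= 0)
    w0 <- max(w0, .Machine$double.eps)  # exact-fit reference degenerates
  vals <- matrix(NA_real_, length(parameters), length(grid),
                 dimnames = list(parameters, paste0(grid * 100, "%")))
  for (i in seq_along(parameters)) {
    for (g in seq_along(grid)) {
      if (grid[g] == 0) { vals[i, g] <- 1; next }
      v <- stats::setNames(p0[parameters[i]] * (1 + grid[g]), parameters[i])
      vals[i, g] <- obj(v) / w0
    }
  }
  structure(list(grid = grid, values = vals, wssres0 = w0,
                 variable = variable), class = "sens_map")
}

#' Per-variable partial sensitivity sweep
#'
#' As [global_sweep()] but with the objective restricted to a single
#' measured variable; the unnormalised per-variable objectives sum to the
#' unnormalised global objective.
#'
#' @inheritParams global_sweep
#' @param variable measured variable name.
#' @export
partial_sweep <- function(obs, variable, params = cho_parameters(),
                          parameters = names(params$vmax),
                          grid = c(-0.85, -0.5, -0.25, -0.1, 0,
                                   0.1, 0.25, 0.5, 1, 2, 3),
                          schedule = cho_schedule(), net = cho_network(),
                          regulation = "I+II") {
  global_sweep(obs, params, parameters = parameters, grid = grid,
               variable = variable, schedule = schedule, net = net,
               regulation = regulation)
}

#' Classify parameters as sensitive or insensitive
#'
#' A parameter counts as sensitive when its normalised WSSRES deviates from
#' 1 by at least the threshold anywhere on the sweep grid (deviations of
#' +/-15% and higher by default).
#'
#' @param map a [global_sweep()] result.
#' @param threshold sensitivity threshold (default 0.15).
#' @return list with character vectors `sensitive` and `insensitive`.
#' @export
classify_sensitive <- function(map, threshold = 0.15) {
  stopifnot(inherits(map, "sens_map"))
  dev <- apply(abs(map$values - 1), 1, max, na.rm = TRUE)
  list(sensitive = rownames(map$values)[dev >= threshold],
       insensitive = rownames(map$values)[dev < threshold])
}

#' @export
print.sens_map <- function(x, ...) {
  cat(sprintf("Sensitivity map: %d parameters x %d grid points (%s to %s)%s\n",
              nrow(x$values), length(x$grid),
              paste0(min(x$grid) * 100, "%"), paste0(max(x$grid) * 100, "%"),
              if (is.null(x$variable)) "" else
                paste0(" [variable: ", x$variable, "]")))
  invisible(x)
}

#' @export
plot.sens_map <- function(x, ...) {
  v <- log10(pmax(x$values, 1e-6))
  graphics::image(x = seq_len(nrow(v)), y = seq_along(x$grid), z = v,
                  xlab = "parameter", ylab = "relative change",
                  axes = FALSE, ...)
  graphics::axis(1, at = seq_len(nrow(v)), labels = rownames(v), las = 2,
                 cex.axis = 0.6)
  graphics::axis(2, at = seq_along(x$grid),
                 labels = paste0(x$grid * 100, "%"), las = 1, cex.axis = 0.7)
  invisible(x)
}

#' @export
as.data.frame.sens_map <- function(x, ...) {
  data.frame(parameter = rep(rownames(x$values), ncol(x$values)),
             change = rep(x$grid, each = nrow(x$values)),
             normalized_wssres = as.vector(x$values),
             stringsAsFactors = FALSE)
}
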