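# File interchange: tidy long-format CSV for observations and trajectories,
# a single JSON document for the model (species, reactions, parameters,
# moieties, amino-acid groups), and a JSON run manifest for reproducibility.

#' Write / read culture observations as tidy CSV
#'
#' Columns: `time_h`, `variable`, `replicate`, `value`. The round trip is
#' lossless to full double precision.
#'
#' @param obs a [cho_observations()] object.
#' @param path file path.
#' @return `read_observations` returns a `cho_obs` object.
#' @export
write_observations <- function(obs, path) {
  stopifnot(inherits(obs, "cho_obs"))
  utils::write.csv(format(obs$records, digits = 17, trim = TRUE,
                          scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "variable", "replicate", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("observation file lacks column(s): ", paste(miss, collapse = ", "))
  for (cn in c("time_h", "value"))
    if (!is.numeric(df[[cn]]))
      stop("column '", cn, "' failed to parse as numeric ",
           "(check the decimal separator: files must use '.')")
  cho_observations(df)
}

#' Write / read a simulated trajectory as tidy CSV
#'
#' Columns: `time_h`, `variable`, `value`, `kind` (state, flux or derived).
#'
#' @param traj a [simulate_batch()] trajectory.
#' @param path file path.
#' @return `read_trajectory` returns a data frame in the same tidy layout;
#'   `as_trajectory` rebuilds the matrix form needed by
#'   [biomarker_panel()] from it.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "variable", "value", "kind")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trajectory file lacks column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(df$value) || !is.numeric(df$time_h))
    stop("numeric columns failed to parse ",
         "(check the decimal separator: files must use '.')")
  df
}

#' Serialise the model (network + parameters) to a JSON document
#'
#' One machine-readable document holding the species table, reaction
#' stoichiometries, all 95 kinetic parameters plus the structural constants,
#' the conserved moiety groups and the amino-acid catabolic groups. The
#' parameter round trip is exact.
#'
#' @param params a [cho_parameters()] object.
#' @param path file path.
#' @param net a [cho_network()] object.
#' @return `read_model_json` returns a list with elements `params` (a
#'   `cho_params` object) and `document` (the full parsed document).
#' @export
write_model_json <- function(params, path, net = cho_network()) {
  doc <- list(
    format = "chometab-model",
    version = 1L,
    species = net$species,
    reactions = lapply(net$reactions, function(r) list(
      id = r$id, stoichiometry = as.list(r$stoich),
      reversible_pair = r$pair,
      vmax = r$vmax, vmax_reverse = r$vmax_r,
      regulation_terms = vapply(r$reg, `[[`, "", "term"))),
    moieties = net$moieties,
    aa_groups = net$aa_groups,
    aliases = as.list(net$aliases),
    parameters = list(
      vmax = as.list(params$vmax),
      affinity = as.list(params$affinity),
      regulatory = as.list(params$regulatory),
      po_ratio = params$po_ratio,
      gln_threshold = params$gln_threshold,
      gln_hill = params$gln_hill,
      creatine_total = params$creatine_total,
      mw_mab = params$mw_mab,
      biomass_coeffs = as.list(params$biomass_coeffs),
      mab_coeffs = as.list(params$mab_coeffs))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "chometab-model"))
    stop("not a chometab model document: ", path)
  pp <- doc$parameters
  params <- cho_parameters()
  for (b in c("vmax", "affinity", "regulatory", "biomass_coeffs",
              "mab_coeffs"))
    params[[b]] <- unlist(pp[[b]])
  for (b in c("po_ratio", "gln_threshold", "gln_hill", "creatine_total",
              "mw_mab"))
    params[[b]] <- pp[[b]]
  list(params = params, document = doc)
}

# small stable content hash (FNV-1a over the serialised object); enough to
# identify a configuration in run manifests without extra dependencies
.config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2)[-(1:14)])  # skip header
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.write_manifest <- function(dir, command, config, seed = NULL) {
  manifest <- list(
    command = command,
    package = "chometab",
    version = as.character(utils::packageVersion("chometab")),
    seed = seed,
    config_hash = .config_hash(config),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Command-line interface
#'
#' Thin wrapper over the package functions, invoked by the bundled
#' `inst/cli/chometab` Rscript. Subcommands: `validate` (structural
#' conformance report), `simulate` (trajectory CSV), `synth` (synthetic
#' experiment CSVs + manifest), `fit`, `sweep`, `biomarkers`, `compare`.
#' Every run writes a `manifest.json` (package version, seed, config hash)
#' into the output directory.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code (0 success, 2 usage/config error), invisibly.
#' @export
cho_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: chometab <command> [options]",
    "commands:",
    "  validate                      structural conformance report",
    "  simulate --out DIR [--clone parental|low|high] [--induced]",
    "           [--regulation none|I|I+II|all]",
    "  synth    --out DIR [--clone ...] [--induced] [--seed N] [--cv X]",
    "  fit      --obs FILE --out DIR [--free p1,p2,...] [--clone ...]",
    "           [--induced]",
    "  sweep    --obs FILE --out DIR [--params p1,...] [--variable V]",
    "  biomarkers --out DIR [--clone ...] [--induced]",
    "  compare  --obsA FILE --obsB FILE --out DIR --free p1,... [--alpha X]",
    sep = "\n")
  fail <- function(...) { message(...); invisible(2L) }
  if (!length(args)) return(fail(usage))
  cmd <- args[1]
  opts <- list()
  rest <- args[-1]
  i <- 1
  while (i <= length(rest)) {
    a <- rest[i]
    if (!startsWith(a, "--")) return(fail("unexpected argument: ", a))
    key <- substring(a, 3)
    if (key %in% c("induced")) { opts[[key]] <- TRUE; i <- i + 1 }
    else if (i < length(rest)) { opts[[key]] <- rest[i + 1]; i <- i + 2 }
    else return(fail("missing value for --", key))
  }
  outdir <- opts$out %||% "."
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  clone <- opts$clone %||% "parental"
  induced <- isTRUE(opts$induced)
  regulation <- opts$regulation %||% "I+II"
  seed <- as.integer(opts$seed %||% 1)

  res <- tryCatch(switch(cmd,
    validate = {
      rep <- validate_network(cho_network(), cho_parameters())
      print(rep)
      if (all(rep$pass)) 0L else 1L
    },
    simulate = {
      spec <- clone_spec(clone)
      sch <- cho_schedule(induced = induced,
                          leaky_fraction = spec$leaky_fraction)
      traj <- simulate_batch(make_clone(spec), sch, regulation = regulation)
      write_trajectory(traj, file.path(outdir, "trajectory.csv"))
      .write_manifest(outdir, "simulate", list(clone, induced, regulation))
      0L
    },
    synth = {
      spec <- clone_spec(clone)
      sch <- cho_schedule(induced = induced)
      noise <- noise_model(cv = as.numeric(opts$cv %||% 0.05))
      ex <- generate_experiment(spec, sch, noise, seed = seed,
                                regulation = regulation)
      write_observations(ex$observations,
                         file.path(outdir, "observations.csv"))
      write_trajectory(ex$truth, file.path(outdir, "truth.csv"))
      .write_manifest(outdir, "synth", list(clone, induced, seed), seed)
      0L
    },
    fit = {
      if (is.null(opts$obs)) return(fail("fit requires --obs"))
      obs <- read_observations(opts$obs)
      free <- strsplit(opts$free %||% "vmaxHK,vmaxfLDH,vmaxrLDH", ",")[[1]]
      spec <- clone_spec(clone)
      sch <- cho_schedule(induced = induced,
                          leaky_fraction = spec$leaky_fraction)
      fit <- fit_culture(obs, free = free, schedule = sch,
                         regulation = regulation)
      ci <- confint(fit)
      jsonlite::write_json(
        list(estimates = as.list(coef(fit)), wssres = fit$wssres,
             wssres_trace = fit$trace,
             ci95 = apply(ci, 1, as.list, simplify = FALSE)),
        file.path(outdir, "fit.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
      .write_manifest(outdir, "fit", list(free, clone, induced))
      0L
    },
    sweep = {
      if (is.null(opts$obs)) return(fail("sweep requires --obs"))
      obs <- read_observations(opts$obs)
      pars <- if (is.null(opts$params)) names(cho_parameters()$vmax)
              else strsplit(opts$params, ",")[[1]]
      map <- global_sweep(obs, parameters = pars, variable = opts$variable)
      utils::write.csv(map$values, file.path(outdir, "sweep.csv"))
      .write_manifest(outdir, "sweep", list(pars, opts$variable))
      0L
    },
    biomarkers = {
      spec <- clone_spec(clone)
      sch <- cho_schedule(induced = induced,
                          leaky_fraction = spec$leaky_fraction)
      traj <- simulate_batch(make_clone(spec), sch, regulation = regulation)
      panel <- biomarker_panel(traj, times = sch$sample_times)
      utils::write.csv(panel, file.path(outdir, "biomarkers.csv"),
                       row.names = FALSE)
      .write_manifest(outdir, "biomarkers", list(clone, induced))
      0L
    },
    compare = {
      if (is.null(opts$obsA) || is.null(opts$obsB))
        return(fail("compare requires --obsA and --obsB"))
      if (is.null(opts$free)) return(fail("compare requires --free"))
      free <- strsplit(opts$free, ",")[[1]]
      fitA <- fit_culture(read_observations(opts$obsA), free = free)
      fitB <- fit_culture(read_observations(opts$obsB), free = free)
      cmp <- compare_fits(fitA, fitB,
                          alpha = as.numeric(opts$alpha %||% 0.1))
      utils::write.csv(cmp, file.path(outdir, "comparison.csv"),
                       row.names = FALSE)
      .write_manifest(outdir, "compare", list(free))
      0L
    },
    fail("unknown command: ", cmd, "\n", usage)
  ), error = function(e) { message("error: ", conditionMessage(e)); 2L })
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
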