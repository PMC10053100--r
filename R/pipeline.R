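#' Run the full analysis pipeline
#'
#' Executes the standard workflow of an urban-soil heavy-metal study in
#' order: summary statistics, enrichment factors, correlations, PMF
#' (factor-number scan then the final fit), deterministic HRA, Monte
#' Carlo HRA, and IDW surfaces, writing one CSV (or `.asc`) per stage
#' plus a JSON run manifest. All randomness derives from the single root
#' `seed` (split deterministically per stage), so a rerun with the same
#' inputs reproduces every stochastic output bit-identically.
#'
#' @param samples a [sample_table()] or a CSV path for [read_samples()].
#' @param config a `soilrisk_config` or a JSON path for [load_config()].
#' @param out_dir output directory (created if needed).
#' @param seed root integer seed.
#' @param k PMF factor count for the final fit (default 4).
#' @param k_range factor counts scanned for diagnostics.
#' @param n_runs PMF random restarts.
#' @param n_iter Monte Carlo iterations.
#' @param idw_metals metals to interpolate (default: all analytes).
#' @param idw_cells grid columns across the study area.
#' @param verbose print stage progress to stderr.
#' @return the run manifest (list), invisibly written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(samples, config, out_dir, seed = 42, k = 4,
                         k_range = 2:5, n_runs = 20, n_iter = 10000,
                         idw_metals = NULL, idw_cells = 25,
                         verbose = FALSE) {
  t0 <- Sys.time()
  if (is.character(samples)) samples <- read_samples(samples)
  if (is.character(config)) {
    config_path <- config
    config <- load_config(config)
  } else config_path <- NA_character_
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[soilrisk] ", ...)
  outputs <- character(0)
  emit <- function(obj, file) {
    path <- file.path(out_dir, file)
    utils::write.csv(obj, path, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  say("indices")
  stage("indices", {
    emit(summarize_metals(samples, config$reference), "summary.csv")
  })

  say("enrichment factors")
  stage("ef", {
    ef <- enrichment_factor(samples, config$reference,
                            class_bounds = config$ef_class_bounds)
    tab <- data.frame(site_id = rownames(ef$ef), ef$ef,
                      check.names = FALSE)
    emit(tab, "ef.csv")
    cls <- data.frame(site_id = rownames(ef$class), ef$class,
                      check.names = FALSE)
    emit(cls, "ef_class.csv")
  })

  say("correlations")
  stage("correlation", {
    cm <- correlation_matrix(samples)
    emit(data.frame(metal = rownames(cm$r), cm$r, check.names = FALSE),
         "correlation.csv")
  })

  say("PMF scan + fit")
  pmf_seed <- derive_seed(seed, "pmf")
  stage("pmf", {
    X <- conc_matrix(samples)
    U <- build_uncertainty(samples, config$reference, config$error_fraction)
    scan <- scan_factors(X, U, k_range, n_runs = n_runs, seed = pmf_seed)
    emit(scan, "pmf_diagnostics.csv")
    sol <- fit_pmf(X, U, k, n_runs = n_runs, seed = pmf_seed)
    emit(data.frame(site_id = rownames(sol$G), sol$G, check.names = FALSE),
         "G.csv")
    emit(data.frame(factor = rownames(sol$F), sol$F, check.names = FALSE),
         "F.csv")
    rep <- source_report(sol)
    emit(data.frame(factor = rownames(rep$metal_shares), rep$metal_shares,
                    contribution_percent = rep$factor_contribution,
                    check.names = FALSE),
         "pmf_report.csv")
  })

  say("deterministic HRA")
  stage("hra", {
    if (!length(config$toxicity$rfd))
      stop("no RfD entries configured")
    hra <- run_hra(samples, config)
    rows <- do.call(rbind, lapply(names(hra$noncancer), function(pop)
      data.frame(population = pop,
                 HI = hra$noncancer[[pop]]$HI,
                 TCR = hra$cancer[[pop]]$TCR,
                 band = hra$cancer[[pop]]$band)))
    emit(rows, "hra.csv")
  })

  say("Monte Carlo HRA (", n_iter, " iterations)")
  mc_seed <- derive_seed(seed, "mc")
  stage("mc_hra", {
    mc <- run_mc_hra(samples, config, n_iter = n_iter, seed = mc_seed)
    summ <- do.call(rbind, lapply(SOILRISK_POPULATIONS, function(pop)
      cbind(population = pop, mc$dist[[pop]]$summary)))
    emit(summ, "mc_summary.csv")
    contrib <- do.call(rbind, lapply(SOILRISK_POPULATIONS, function(pop) {
      co <- mc$contributions[[pop]]
      rbind(data.frame(population = pop, quantity = "HI",
                       metal = names(co$hi_shares),
                       share_percent = unname(co$hi_shares)),
            data.frame(population = pop, quantity = "TCR",
                       metal = names(co$tcr_shares),
                       share_percent = unname(co$tcr_shares)))
    }))
    emit(contrib, "mc_contributions.csv")
  })

  say("IDW surfaces")
  stage("spatial", {
    if (is.null(idw_metals)) idw_metals <- metals_of(samples)
    span <- max(diff(range(samples$x)), diff(range(samples$y)), 1)
    grid <- grid_over_samples(samples, cell = span / idw_cells)
    for (met in idw_metals) {
      surf <- idw_interpolate(samples, met, grid = grid)
      path <- file.path(out_dir, paste0("idw_", met, ".asc"))
      write_ascii_grid(surf, path)
      outputs <- c(outputs, path)
    }
  })

  manifest <- list(
    package = "soilrisk",
    version = as.character(utils::packageVersion("soilrisk")),
    created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_path = config_path,
    seed = seed,
    stage_seeds = list(pmf = pmf_seed, mc = mc_seed),
    parameters = list(k = k, k_range = k_range, n_runs = n_runs,
                      n_iter = n_iter),
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  missing_out <- outputs[!file.exists(outputs)]
  if (length(missing_out))
    stop("run_pipeline: manifest lists missing output(s): ",
         paste(missing_out, collapse = ", "))
  invisible(manifest)
}

#' Command-line entry point
#'
#' Minimal argument parser so the pipeline can be driven from `Rscript`
#' (see `inst/cli/soilrisk.R`). Subcommands:
#' \describe{
#'   \item{run}{`--samples s.csv --config c.json --out dir [--seed n]
#'     [--k n] [--iters n] [--runs n]` — full pipeline.}
#'   \item{synth}{`--mode factors|matched --out s.csv [--k n] [--n n]
#'     [--noise-cv x] [--seed n]` — synthetic sample tables; `matched`
#'     uses the shipped demo summary.}
#' }
#'
#' @param args character vector, default `commandArgs(trailingOnly=TRUE)`.
#' @return exit status (0 on success), invisibly.
#' @export
soilrisk_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: soilrisk <run|synth> [options]")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  get <- function(name, default = NULL, num = FALSE) {
    v <- opts[[name]]
    if (is.null(v)) return(default)
    if (num) as.numeric(v) else v
  }
  if (cmd == "run") {
    for (req in c("samples", "config", "out"))
      if (is.null(opts[[req]])) stop("run: --", req, " is required")
    run_pipeline(get("samples"), get("config"), get("out"),
                 seed = get("seed", 42, num = TRUE),
                 k = get("k", 4, num = TRUE),
                 n_runs = get("runs", 20, num = TRUE),
                 n_iter = get("iters", 10000, num = TRUE),
                 verbose = TRUE)
  } else if (cmd == "synth") {
    if (is.null(opts$out)) stop("synth: --out is required")
    mode <- get("mode", "matched")
    seed <- get("seed", 1, num = TRUE)
    n <- get("n", 40, num = TRUE)
    tab <- if (mode == "factors") {
      generate_factor_samples(k = get("k", 4, num = TRUE), n_sites = n,
                              noise_cv = get("noise-cv", 0.1, num = TRUE),
                              seed = seed)$samples
    } else {
      generate_matched_samples(demo_summary(), n_sites = n, seed = seed)
    }
    write_samples(tab, get("out"))
  } else {
    stop("unknown subcommand: ", cmd)
  }
  invisible(0L)
}

## "--name value" and "--flag" pairs to a named list.
parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    name <- substring(a, 3)
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      opts[[name]] <- args[i + 1L]
      i <- i + 2L
    } else {
      opts[[name]] <- TRUE
      i <- i + 1L
    }
  }
  opts
}
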