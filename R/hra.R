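#' Average daily dose for one exposure route
#'
#' Evaluates the EPA soil-exposure dose equations, in mg kg-1 d-1:
#' \deqn{ADD_{ing} = C \cdot IngR \cdot EFreq \cdot ED / (BW \cdot AT) \cdot 10^{-6}}
#' \deqn{ADD_{derm} = C \cdot SA \cdot AF \cdot ABS \cdot EFreq \cdot ED / (BW \cdot AT) \cdot 10^{-6}}
#' \deqn{ADD_{inh} = C \cdot InhR \cdot EFreq \cdot ED / (PEF \cdot BW \cdot AT) \cdot 10^{-6}}
#' with C the soil concentration (mg kg-1) and AT the noncancer
#' (`AT_nc`) or cancer (`AT_ca`) averaging time in days. All arguments are
#' vectorised, so the same code path serves the deterministic assessment
#' (scalars) and the Monte Carlo engine (draw vectors).
#'
#' @param C concentration(s), mg kg-1, >= 0.
#' @param params named list/vector of exposure parameter values (fields
#'   IngR, InhR, EFreq, ED, BW, AT_nc, AT_ca, SA, AF, ABS, PEF), point
#'   values or draw vectors of a common length.
#' @param route `"ingestion"`, `"dermal"` or `"inhalation"`.
#' @param averaging `"nc"` (noncancer, AT_nc) or `"ca"` (cancer, AT_ca).
#' @return dose(s) in mg kg-1 d-1.
#' @export
average_daily_dose <- function(C, params, route = SOILRISK_ROUTES,
                               averaging = c("nc", "ca")) {
  route <- match.arg(route)
  averaging <- match.arg(averaging)
  params <- as.list(params)
  needed <- switch(route,
    ingestion = c("IngR", "EFreq", "ED", "BW"),
    dermal = c("SA", "AF", "ABS", "EFreq", "ED", "BW"),
    inhalation = c("InhR", "EFreq", "ED", "PEF", "BW"))
  needed <- c(needed, if (averaging == "nc") "AT_nc" else "AT_ca")
  for (f in needed)
    if (is.null(params[[f]]) || !is.numeric(params[[f]]))
      stop(sprintf("average_daily_dose: missing exposure parameter '%s'", f),
           call. = FALSE)
  if (any(C < 0)) stop("average_daily_dose: C must be >= 0")
  AT <- if (averaging == "nc") params[["AT_nc"]] else params[["AT_ca"]]
  p <- params
  switch(route,
    ingestion =
      C * p[["IngR"]] * p[["EFreq"]] * p[["ED"]] / (p[["BW"]] * AT) * 1e-6,
    dermal =
      C * p[["SA"]] * p[["AF"]] * p[["ABS"]] * p[["EFreq"]] * p[["ED"]] /
        (p[["BW"]] * AT) * 1e-6,
    inhalation =
      C * p[["InhR"]] * p[["EFreq"]] * p[["ED"]] /
        (p[["PEF"]] * p[["BW"]] * AT) * 1e-6)
}

#' Doses for all metals, routes and populations
#'
#' @param conc named concentration vector (mg kg-1), one entry per metal.
#' @param exposure an `exposure_params` object; distributions are
#'   collapsed to their means ([collapse_exposure()]).
#' @return data.frame with columns `population`, `metal`, `route`,
#'   `add_nc`, `add_ca`.
#' @export
compute_doses <- function(conc, exposure) {
  pts <- collapse_exposure(exposure)
  grid <- expand.grid(population = names(pts), metal = names(conc),
                      route = SOILRISK_ROUTES, stringsAsFactors = FALSE)
  grid$add_nc <- mapply(function(pop, met, rt)
    average_daily_dose(conc[[met]], pts[[pop]], rt, "nc"),
    grid$population, grid$metal, grid$route)
  grid$add_ca <- mapply(function(pop, met, rt)
    average_daily_dose(conc[[met]], pts[[pop]], rt, "ca"),
    grid$population, grid$metal, grid$route)
  grid
}

#' Noncancer hazard quotients and hazard index
#'
#' HQ = ADD / RfD per metal and route with a configured reference dose;
#' the hazard index HI is their sum. HI > 1 flags potential noncancer
#' effects. Metal-route combinations without an RfD are skipped.
#'
#' @param doses data.frame from [compute_doses()] (uses `add_nc`).
#' @param tox a `toxicity_table`.
#' @return list per population: `hq` (data.frame metal/route/hq),
#'   `hi_per_metal` (named vector), `HI` (scalar), `exceeds_one` flag.
#' @export
hazard_index <- function(doses, tox) {
  out <- lapply(split(doses, doses$population), function(d) {
    d$rfd <- mapply(function(met, rt) {
      v <- tox$rfd[[met]][rt]
      if (is.null(v) || is.na(v)) NA_real_ else v
    }, d$metal, d$route)
    d <- d[!is.na(d$rfd), , drop = FALSE]
    d$hq <- d$add_nc / d$rfd
    hi_pm <- tapply(d$hq, d$metal, sum)
    hi_pm <- hi_pm[order(-hi_pm)]
    HI <- sum(d$hq)
    list(hq = d[, c("metal", "route", "hq")],
         hi_per_metal = hi_pm, HI = HI, exceeds_one = HI > 1)
  })
  out
}

#' Cancer risks and total carcinogenic risk
#'
#' CR = ADD x SF per metal and route with a configured slope factor; the
#' total carcinogenic risk TCR is their sum. Risks below 1e-6 are
#' conventionally negligible, 1e-6 to 1e-4 acceptable, above 1e-4
#' unacceptable.
#'
#' @param doses data.frame from [compute_doses()] (uses `add_ca`).
#' @param tox a `toxicity_table`.
#' @return list per population: `cr` (data.frame metal/route/cr),
#'   `tcr_per_metal`, `TCR`, `band` (one of "negligible", "acceptable",
#'   "unacceptable").
#' @export
cancer_risk <- function(doses, tox) {
  lapply(split(doses, doses$population), function(d) {
    d$sf <- mapply(function(met, rt) {
      v <- tox$sf[[met]][rt]
      if (is.null(v) || is.na(v)) NA_real_ else v
    }, d$metal, d$route)
    d <- d[!is.na(d$sf), , drop = FALSE]
    if (nrow(d) == 0)
      return(list(cr = data.frame(metal = character(), route = character(),
                                  cr = numeric()),
                  tcr_per_metal = numeric(0), TCR = 0,
                  band = "negligible"))
    d$cr <- d$add_ca * d$sf
    tcr_pm <- tapply(d$cr, d$metal, sum)
    tcr_pm <- tcr_pm[order(-tcr_pm)]
    TCR <- sum(d$cr)
    list(cr = d[, c("metal", "route", "cr")],
         tcr_per_metal = tcr_pm, TCR = TCR,
         band = risk_band(TCR))
  })
}

risk_band <- function(tcr) {
  if (tcr < 1e-6) "negligible" else if (tcr <= 1e-4) "acceptable"
  else "unacceptable"
}

#' Deterministic health risk assessment
#'
#' Point assessment at a chosen concentration statistic: doses, hazard
#' quotients/index, cancer risks/total risk for both populations.
#'
#' @param samples a [sample_table()], or a named concentration vector.
#' @param config a `soilrisk_config`.
#' @param stat summary statistic of the per-metal concentrations when
#'   `samples` is a table: `"mean"` (default) or `"p95"`.
#' @return list of class `hra_result` with `conc`, `doses`, `noncancer`,
#'   `cancer`.
#' @export
run_hra <- function(samples, config, stat = c("mean", "p95")) {
  stat <- match.arg(stat)
  conc <- if (inherits(samples, "sample_table")) {
    X <- conc_matrix(samples)
    if (stat == "mean") colMeans(X)
    else apply(X, 2, stats::quantile, probs = 0.95, names = FALSE)
  } else {
    if (is.null(names(samples)))
      stop("run_hra: concentration vector must be named")
    samples
  }
  doses <- compute_doses(conc, config$exposure)
  structure(list(conc = conc, doses = doses,
                 noncancer = hazard_index(doses, config$toxicity),
                 cancer = cancer_risk(doses, config$toxicity)),
            class = "hra_result")
}

#' @export
print.hra_result <- function(x, ...) {
  cat("<hra_result>\n")
  for (pop in names(x$noncancer)) {
    cat(sprintf("  %s: HI = %.4g (%s), TCR = %.4g (%s)\n", pop,
                x$noncancer[[pop]]$HI,
                if (x$noncancer[[pop]]$exceeds_one) "HI > 1" else "HI < 1",
                x$cancer[[pop]]$TCR, x$cancer[[pop]]$band))
  }
  invisible(x)
}
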