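#' Lognormal concentration distributions fitted to a sample table
#'
#' Each metal's Monte Carlo concentration distribution is a lognormal
#' moment-matched to the arithmetic mean and SD of the observed (or
#' published) concentrations — the standard geochemical assumption for
#' right-skewed soil concentrations. No truncation is applied: truncating
#' at the observed range would bias the matched moments.
#'
#' @param samples a [sample_table()], or a summary data.frame with columns
#'   `metal`, `mean`, `sd` (e.g. [demo_summary()]).
#' @return named list of [dist_spec()] per metal.
#' @export
conc_distributions <- function(samples) {
  if (inherits(samples, "sample_table")) {
    X <- conc_matrix(samples)
    means <- colMeans(X); sds <- apply(X, 2, stats::sd)
    metals <- colnames(X)
  } else {
    stopifnot(is.data.frame(samples),
              all(c("metal", "mean", "sd") %in% names(samples)))
    means <- samples$mean; sds <- samples$sd; metals <- samples$metal
  }
  specs <- mapply(function(m, s) {
    if (s == 0) dist_spec("point", value = m)
    else dist_spec("lognormal", mean = m, sd = s)
  }, means, sds, SIMPLIFY = FALSE)
  names(specs) <- metals
  specs
}

#' Draw Monte Carlo input samples
#'
#' Draws `n_iter` independent realisations of every metal concentration
#' and every exposure parameter for both populations. All quantities are
#' sampled independently (no correlation structure is imposed), each from
#' its [dist_spec()]; the whole table is reproducible from `seed`.
#'
#' @param conc_dists named list of [dist_spec()] per metal
#'   ([conc_distributions()]).
#' @param exposure an `exposure_params` object.
#' @param n_iter number of iterations (default 10000).
#' @param seed integer seed.
#' @return list of class `mc_draws`: `conc` (n_iter x metals matrix),
#'   `params` (per population, list of n_iter-long parameter vectors),
#'   `n_iter`, `seed`.
#' @export
sample_inputs <- function(conc_dists, exposure, n_iter = 10000, seed = 1) {
  stopifnot(n_iter >= 1)
  for (nm in names(conc_dists))
    if (!inherits(conc_dists[[nm]], "dist_spec"))
      stop("sample_inputs: conc_dists[['", nm, "']] is not a dist_spec")
  rng <- local_rng(seed)
  conc <- vapply(conc_dists, sample_dist, numeric(n_iter), n = n_iter)
  conc <- matrix(conc, nrow = n_iter,
                 dimnames = list(NULL, names(conc_dists)))
  params <- lapply(exposure, function(p)
    lapply(p, function(spec) sample_dist(spec, n_iter)))
  rng()
  structure(list(conc = conc, params = params, n_iter = n_iter, seed = seed),
            class = "mc_draws")
}

#' Run the Monte Carlo risk simulation
#'
#' Applies the dose, hazard-quotient and cancer-risk equations to every
#' iteration of the draw table and summarises the resulting HI and TCR
#' distributions: mean, SD, percentiles (5/10/25/50/75/90/95, linear
#' interpolation between order statistics, R type 7) and the exceedance
#' probabilities P(HI > 1), P(TCR > 1e-6), P(TCR > 1e-4).
#'
#' @param draws an `mc_draws` object ([sample_inputs()]).
#' @param tox a `toxicity_table`.
#' @return object of class `risk_distribution`: per population a list with
#'   `HI`, `TCR` (draw vectors), `hq_metal`, `cr_metal` (n_iter x metal
#'   matrices, summed over routes), `summary` (data.frame for HI and TCR),
#'   plus `n_iter` and `seed` at the top level.
#' @export
run_mc <- function(draws, tox) {
  stopifnot(inherits(draws, "mc_draws"))
  metals <- colnames(draws$conc)
  out <- lapply(names(draws$params), function(pop) {
    p <- draws$params[[pop]]
    n <- draws$n_iter
    hq <- matrix(0, n, length(metals), dimnames = list(NULL, metals))
    cr <- matrix(0, n, length(metals), dimnames = list(NULL, metals))
    for (met in metals) {
      C <- draws$conc[, met]
      for (rt in SOILRISK_ROUTES) {
        rfd <- tox$rfd[[met]][rt]
        if (!is.null(rfd) && !is.na(rfd))
          hq[, met] <- hq[, met] + average_daily_dose(C, p, rt, "nc") / rfd
        sf <- tox$sf[[met]][rt]
        if (!is.null(sf) && !is.na(sf))
          cr[, met] <- cr[, met] + average_daily_dose(C, p, rt, "ca") * sf
      }
    }
    HI <- rowSums(hq)
    TCR <- rowSums(cr)
    list(HI = HI, TCR = TCR, hq_metal = hq, cr_metal = cr,
         summary = summarize_draws(HI, TCR))
  })
  names(out) <- names(draws$params)
  structure(c(out, list(n_iter = draws$n_iter, seed = draws$seed)),
            class = "risk_distribution")
}

MC_PROBS <- c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95)

summarize_draws <- function(HI, TCR) {
  row <- function(x, name, thresholds) {
    q <- stats::quantile(x, MC_PROBS, names = FALSE, type = 7)
    d <- data.frame(quantity = name, mean = mean(x), sd = stats::sd(x))
    for (i in seq_along(MC_PROBS))
      d[[sprintf("p%02d", round(100 * MC_PROBS[i]))]] <- q[i]
    for (t in names(thresholds))
      d[[t]] <- mean(x > thresholds[[t]])
    d
  }
  hi <- row(HI, "HI", list(p_exceed_1 = 1))
  tcr <- row(TCR, "TCR", list(p_exceed_1e6 = 1e-6, p_exceed_1e4 = 1e-4))
  hi$p_exceed_1e6 <- NA_real_; hi$p_exceed_1e4 <- NA_real_
  tcr$p_exceed_1 <- NA_real_
  rbind(hi, tcr[, names(hi)])
}

#' Per-metal contribution to mean HI and mean TCR
#'
#' Share of metal j = mean over iterations of its summed HQ (or CR)
#' divided by the mean HI (or TCR), in percent; shares sum to 100 by
#' construction.
#'
#' @param dist a `risk_distribution` ([run_mc()]).
#' @return list per population with `hi_shares` and `tcr_shares` (named
#'   percentage vectors, descending); a zero mean TCR yields `NA` shares.
#' @export
contribution_report <- function(dist) {
  stopifnot(inherits(dist, "risk_distribution"))
  pops <- intersect(names(dist), SOILRISK_POPULATIONS)
  out <- lapply(pops, function(pop) {
    d <- dist[[pop]]
    share <- function(mat, tot) {
      if (mean(tot) == 0) {
        s <- rep(NA_real_, ncol(mat)); names(s) <- colnames(mat)
        return(s)
      }
      s <- 100 * colMeans(mat) / mean(tot)
      sort(s, decreasing = TRUE)
    }
    list(hi_shares = share(d$hq_metal, d$HI),
         tcr_shares = share(d$cr_metal, d$TCR))
  })
  names(out) <- pops
  out
}

#' Full probabilistic risk assessment
#'
#' Convenience wrapper: fit concentration distributions, draw inputs, run
#' the simulation and compute contribution shares.
#'
#' @param samples a [sample_table()] or summary data.frame
#'   (see [conc_distributions()]).
#' @param config a `soilrisk_config`.
#' @param n_iter iterations (default 10000).
#' @param seed integer seed.
#' @return list with `dist` (a `risk_distribution`) and `contributions`.
#' @export
run_mc_hra <- function(samples, config, n_iter = 10000, seed = 1) {
  cd <- conc_distributions(samples)
  cd <- cd[intersect(names(cd), names(config$reference$background))]
  draws <- sample_inputs(cd, config$exposure, n_iter = n_iter, seed = seed)
  dist <- run_mc(draws, config$toxicity)
  list(dist = dist, contributions = contribution_report(dist))
}

#' @export
print.risk_distribution <- function(x, ...) {
  cat(sprintf("<risk_distribution> %d iterations, seed %s\n",
              x$n_iter, format(x$seed)))
  for (pop in intersect(names(x), SOILRISK_POPULATIONS)) {
    s <- x[[pop]]$summary
    cat(sprintf("  %s: mean HI = %.4g  P(HI>1) = %.3f | mean TCR = %.3g  P(TCR>1e-6) = %.3f\n",
                pop, s$mean[s$quantity == "HI"],
                s$p_exceed_1[s$quantity == "HI"],
                s$mean[s$quantity == "TCR"],
                s$p_exceed_1e6[s$quantity == "TCR"]))
  }
  invisible(x)
}
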