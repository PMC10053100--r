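test_that("degenerate draws collapse to the deterministic assessment", {
  cfg <- load_config()
  conc <- c(Cd = 2.52, Cr = 58.74, Cu = 31.39, Zn = 186.28, Ni = 27.0,
            Pb = 34.89)
  ## freeze every exposure parameter at its mean, make concentrations points
  pts <- collapse_exposure(cfg$exposure)
  exp_point <- structure(lapply(pts, function(p)
    sapply(names(p), function(f) dist_spec("point", value = p[[f]]),
           simplify = FALSE)), class = "exposure_params")
  conc_dists <- sapply(names(conc), function(m)
    dist_spec("point", value = conc[[m]]), simplify = FALSE)
  draws <- sample_inputs(conc_dists, exp_point, n_iter = 50, seed = 1)
  ## every draw identical
  expect_true(all(apply(draws$conc, 2, function(v) all(v == v[1]))))
  dist <- run_mc(draws, cfg$toxicity)
  det <- run_hra(conc, cfg)
  for (pop in c("adult", "child")) {
    expect_equal(dist[[pop]]$summary$mean[1], det$noncancer[[pop]]$HI,
                 tolerance = 1e-12)
    expect_equal(dist[[pop]]$summary$mean[2], det$cancer[[pop]]$TCR,
                 tolerance = 1e-12)
    expect_equal(stats::sd(dist[[pop]]$HI), 0)
  }
})

test_that("lognormal input sampling matches its analytic mean", {
  spec <- dist_spec("lognormal", mean = 2.52, sd = 4.31)
  set.seed(10)
  x <- sample_dist(spec, 100000)
  expect_equal(mean(x), 2.52, tolerance = 0.02)
  p <- lognormal_params(2.52, 4.31)
  ## absolute check: 4 standard errors of the log-scale mean
  expect_lt(abs(mean(log(x)) - p$meanlog), 4 * p$sdlog / sqrt(100000))
})

test_that("draw tables are reproducible and summaries are self-consistent", {
  cfg <- load_config()
  cd <- conc_distributions(demo_summary())
  a <- sample_inputs(cd, cfg$exposure, n_iter = 400, seed = 11)
  b <- sample_inputs(cd, cfg$exposure, n_iter = 400, seed = 11)
  expect_identical(a$conc, b$conc)
  expect_identical(a$params, b$params)
  dist <- run_mc(a, cfg$toxicity)
  for (pop in c("adult", "child")) {
    s <- dist[[pop]]$summary
    ## stored draws reproduce the reported summaries exactly
    expect_equal(s$mean[s$quantity == "HI"], mean(dist[[pop]]$HI))
    expect_equal(s$p_exceed_1[s$quantity == "HI"],
                 mean(dist[[pop]]$HI > 1))
    expect_equal(s$p_exceed_1e6[s$quantity == "TCR"],
                 mean(dist[[pop]]$TCR > 1e-6))
    ## percentiles monotone in level
    q <- unlist(s[s$quantity == "TCR",
                  c("p05", "p10", "p25", "p50", "p75", "p90", "p95")])
    expect_true(all(diff(q) >= 0))
    ## HI equals the row sum of per-metal HQ draws
    expect_equal(dist[[pop]]$HI, rowSums(dist[[pop]]$hq_metal),
                 tolerance = 1e-12)
  }
})

test_that("MC mean HI converges to the closed-form expectation", {
  ## all exposure parameters at points, C lognormal: HI is linear in C so
  ## E[HI] has a closed form from the product of expectations
  cfg <- load_config()
  pts <- collapse_exposure(cfg$exposure)
  exp_point <- structure(lapply(pts, function(p)
    sapply(names(p), function(f) dist_spec("point", value = p[[f]]),
           simplify = FALSE)), class = "exposure_params")
  summ <- demo_summary()
  cd <- conc_distributions(summ)
  draws <- sample_inputs(cd, exp_point, n_iter = 100000, seed = 13)
  dist <- run_mc(draws, cfg$toxicity)
  hi_analytic <- run_hra(stats::setNames(summ$mean, summ$metal), cfg)
  for (pop in c("adult", "child"))
    expect_equal(dist[[pop]]$summary$mean[1],
                 hi_analytic$noncancer[[pop]]$HI, tolerance = 0.01)
})

test_that("doubling the iteration count moves the mean by < 3 MC SE", {
  cfg <- load_config()
  cd <- conc_distributions(demo_summary())
  d1 <- run_mc(sample_inputs(cd, cfg$exposure, n_iter = 4000, seed = 19),
               cfg$toxicity)
  d2 <- run_mc(sample_inputs(cd, cfg$exposure, n_iter = 8000, seed = 23),
               cfg$toxicity)
  for (pop in c("adult", "child")) {
    se <- stats::sd(d1[[pop]]$HI) / sqrt(4000)
    expect_lt(abs(mean(d1[[pop]]$HI) - mean(d2[[pop]]$HI)), 3 * se)
  }
})

test_that("contribution shares behave at the degenerate limits", {
  exposure <- tiny_exposure()
  tox <- tiny_toxicity(rfd = list(Cd = c(ingestion = 1e-3)))
  cd <- list(Cd = dist_spec("lognormal", mean = 2.5, sd = 1))
  dist <- run_mc(sample_inputs(cd, exposure, n_iter = 200, seed = 3), tox)
  co <- contribution_report(dist)
  expect_equal(unname(co$child$hi_shares[["Cd"]]), 100, tolerance = 1e-12)
  ## two metals with identical doses and RfDs -> 50/50
  tox2 <- tiny_toxicity(rfd = list(A = c(ingestion = 1e-3),
                                   B = c(ingestion = 1e-3)))
  cd2 <- list(A = dist_spec("point", value = 5), B = dist_spec("point", value = 5))
  dist2 <- run_mc(sample_inputs(cd2, exposure, n_iter = 50, seed = 4), tox2)
  co2 <- contribution_report(dist2)
  expect_equal(unname(co2$adult$hi_shares), c(50, 50), tolerance = 1e-12)
  ## no slope factors -> zero TCR -> shares undefined (NA)
  expect_true(all(is.na(co2$adult$tcr_shares)))
  ## shares sum to 100
  cfg <- load_config()
  full <- run_mc_hra(demo_summary(), cfg, n_iter = 500, seed = 6)
  for (pop in c("adult", "child")) {
    expect_equal(sum(full$contributions[[pop]]$hi_shares), 100,
                 tolerance = 1e-6)
    expect_equal(sum(full$contributions[[pop]]$tcr_shares), 100,
                 tolerance = 1e-6)
  }
})

test_that("shipped defaults give child-dominant risk with Cr leading HI", {
  cfg <- load_config()
  mc <- run_mc_hra(demo_summary(), cfg, n_iter = 4000, seed = 29)
  child_tcr <- mc$dist$child$summary$mean[2]
  adult_tcr <- mc$dist$adult$summary$mean[2]
  expect_gt(child_tcr, adult_tcr)
  ## Cr carries the largest single share of child HI
  shares <- mc$contributions$child$hi_shares
  expect_identical(names(shares)[1], "Cr")
})
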