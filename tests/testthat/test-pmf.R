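test_that("uncertainty matrix follows the MDL branch rule", {
  df <- data.frame(site_id = c("a", "b", "c"), x = 1:3, y = 1:3,
                   Cd = c(10, 1, 2), Mn = c(500, 500, 500))
  s <- sample_table(df, metals = "Cd")
  ref <- structure(list(background = c(Cd = 0.17), guide = c(Cd = 0.6),
                        mdl = c(Cd = 2), mn_background = 583),
                   class = "reference_values")
  U <- build_uncertainty(s, ref, error_fraction = 0.1)
  expect_equal(U["a", "Cd"], sqrt(1^2 + 2^2))       # c > MDL
  expect_equal(U["b", "Cd"], 5 / 6 * 2)             # c < MDL
  expect_equal(U["c", "Cd"], 5 / 6 * 2)             # c == MDL takes Eq.5 branch
  expect_true(all(U > 0))
  ref$mdl <- c(Zn = 1)
  expect_error(build_uncertainty(s, ref), "MDL")
})

test_that("noiseless low-rank data is factorized exactly", {
  gen <- generate_factor_samples(k = 2, n_sites = 30, noise_cv = 0, seed = 3)
  X <- conc_matrix(gen$samples)
  U <- matrix(1, nrow(X), ncol(X))
  sol <- fit_pmf(X, U, k = 2, n_runs = 5, seed = 1)
  expect_true(sol$converged)
  expect_lt(sol$Q_true, 1e-6 * nrow(X) * ncol(X))
  Xhat <- sol$G %*% sol$F
  expect_lt(max(abs(Xhat - X) / pmax(X, 1e-12)), 1e-6)
})

test_that("rank-1 identity: identical rows recover the common profile", {
  profile <- c(Cd = 2, Cr = 50, Cu = 30, Zn = 150, Ni = 25, Pb = 35)
  X <- matrix(rep(profile, each = 10), nrow = 10,
              dimnames = list(NULL, names(profile)))
  sol <- fit_pmf(X, matrix(1, 10, 6), k = 1, n_runs = 3, seed = 2)
  expect_true(sol$converged)
  ## normalised profile equals the normalised common row
  expect_equal(unname(sol$F[1, ]), unname(profile / sum(profile)),
               tolerance = 1e-6)
})

test_that("fit is reproducible, validates k, flags non-convergence", {
  gen <- generate_factor_samples(k = 2, n_sites = 15, noise_cv = 0.1, seed = 5)
  X <- conc_matrix(gen$samples)
  U <- matrix(1, nrow(X), ncol(X))
  a <- fit_pmf(X, U, k = 2, n_runs = 3, seed = 7)
  b <- fit_pmf(X, U, k = 2, n_runs = 3, seed = 7)
  expect_identical(a$G, b$G)
  expect_identical(a$Q_true, b$Q_true)
  expect_error(fit_pmf(X, U, k = 6, n_runs = 1, seed = 1), "k must satisfy")
  expect_error(fit_pmf(X, U[1:3, ], k = 2), "same shape")
  expect_warning(nc <- fit_pmf(X, U, k = 2, n_runs = 1, seed = 1,
                               max_iter = 5), "converge")
  expect_false(nc$converged)
})

test_that("objective descends monotonically within a run", {
  gen <- generate_factor_samples(k = 3, n_sites = 25, noise_cv = 0.15, seed = 9)
  X <- conc_matrix(gen$samples)
  U <- build_uncertainty(gen$samples, load_config()$reference, 0.1)
  sol <- fit_pmf(X, U, k = 3, n_runs = 2, seed = 4)
  q <- sol$Q_trace[seq(1, length(sol$Q_trace), by = 10)]
  expect_true(all(diff(q) <= 1e-8 * q[-length(q)]))
})

test_that("reported quantities are invariant to the internal scaling", {
  ## GF, Q and percentage reports must not depend on how mass is split
  ## between G and F; the normalisation makes F rows sum to 1
  gen <- generate_factor_samples(k = 2, n_sites = 20, noise_cv = 0.05, seed = 6)
  X <- conc_matrix(gen$samples)
  U <- matrix(1, nrow(X), ncol(X))
  sol <- fit_pmf(X, U, k = 2, n_runs = 4, seed = 3)
  expect_equal(unname(rowSums(sol$F)), c(1, 1), tolerance = 1e-12)
  expect_equal(sol$Q_true, sum(((X - sol$G %*% sol$F) / U)^2), tolerance = 1e-12)
})

test_that("robust downweighting follows the EPA convention", {
  U <- matrix(1, 4, 3)
  E <- matrix(0, 4, 3)
  sol <- structure(list(residuals = E, U = U), class = "pmf_solution")
  expect_equal(robust_downweight(sol, 4), U)            # no outliers
  E2 <- E; E2[2, 2] <- 16                               # scaled residual 16
  sol2 <- structure(list(residuals = E2, U = U), class = "pmf_solution")
  U2 <- robust_downweight(sol2, 4)
  expected <- U; expected[2, 2] <- 2                    # sqrt(16/4)
  expect_equal(U2, expected)
})

test_that("a gross outlier makes Q_robust < Q_true", {
  gen <- generate_factor_samples(k = 2, n_sites = 20, noise_cv = 0.05, seed = 8)
  X <- conc_matrix(gen$samples)
  X[5, 3] <- X[5, 3] * 20                               # corrupt one cell
  U <- matrix(1, nrow(X), ncol(X))
  sol <- fit_pmf(X, U, k = 2, n_runs = 4, seed = 2)
  expect_lt(sol$Q_robust, sol$Q_true)
})

test_that("source report normalises shares and handles ground truth", {
  ## two factors with disjoint metal support: shares must split ~100/0
  set.seed(31)
  G <- cbind(stats::rlnorm(30, 3, 0.5), stats::rlnorm(30, 3, 0.5))
  ## anchor sites where only one source is active make the
  ## factorization essentially unique (separability)
  G[1:6, 2] <- 0
  G[7:12, 1] <- 0
  F_true <- rbind(c(1, 1, 0, 0) / 2, c(0, 0, 1, 1) / 2)
  colnames(F_true) <- c("Cd", "Cr", "Zn", "Pb")
  X <- G %*% F_true
  sol <- fit_pmf(X, matrix(1, 30, 4), k = 2, n_runs = 6, seed = 5)
  rep <- source_report(sol)
  expect_equal(unname(colSums(rep$metal_shares)), rep(100, 4),
               tolerance = 1e-3)
  expect_equal(sum(rep$factor_contribution), 100, tolerance = 1e-3)
  top <- apply(rep$metal_shares, 2, max)
  expect_true(all(top > 99))                            # disjoint support found
  ## k = 1: every share is 100%
  sol1 <- fit_pmf(X, matrix(1, 30, 4), k = 1, n_runs = 2, seed = 1)
  rep1 <- source_report(sol1)
  expect_equal(unname(rep1$metal_shares[1, ]), rep(100, 4))
  expect_equal(unname(rep1$factor_contribution), 100)
  ## non-converged solutions are refused
  nc <- sol; nc$converged <- FALSE
  expect_error(source_report(nc), "converge")
})

test_that("factor-number scan is deterministic and finds noiseless elbows", {
  gen <- generate_factor_samples(k = 3, n_sites = 30, noise_cv = 0, seed = 12)
  X <- conc_matrix(gen$samples)
  U <- matrix(1, nrow(X), ncol(X))
  scan <- scan_factors(X, U, 2:4, n_runs = 5, seed = 3)
  expect_identical(scan, scan_factors(X, U, 2:4, n_runs = 5, seed = 3))
  expect_equal(nrow(scan_factors(X, U, 3, n_runs = 2, seed = 1)), 1)
  ## orders-of-magnitude drop at the true rank, then plateau
  q <- scan$Q_true
  expect_gt(q[scan$k == 2] / q[scan$k == 3], 1e3)
  expect_lt(q[scan$k == 3], 1e-6 * nrow(X) * ncol(X))
})

test_that("unit-uncertainty PMF matches the established NMF oracle", {
  ## 12 x 5, unit uncertainties: both minimise the same unweighted objective
  set.seed(17)
  G <- matrix(stats::rlnorm(12 * 2, 1, 0.6), 12, 2)
  F_ <- matrix(stats::runif(2 * 5, 0.1, 1), 2, 5)
  X <- G %*% F_ + matrix(stats::runif(60, 0, 0.05), 12, 5)
  sol <- fit_pmf(X, matrix(1, 12, 5), k = 2, n_runs = 10, seed = 21)
  q_oracle <- sklearn_nmf_objective(X, k = 2, n_init = 10)
  expect_lt(abs(sol$Q_true - q_oracle) / q_oracle, 0.01)
})
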