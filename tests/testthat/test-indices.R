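test_that("summary statistics and strict exceedance counting", {
  cfg <- load_config()
  ## constructed fixture: 10 sites, exactly 3 strictly above background,
  ## one sitting exactly on the threshold (must not count)
  n <- 10
  df <- data.frame(site_id = paste0("S", 1:n), x = 1:n, y = 1:n)
  for (m in metals_of(fixture_samples())) df[[m]] <- rep(1, n)
  df$Mn <- rep(500, n)
  df$Cu <- c(40, 35, 31, rep(10, 6), 30.7)   # bg Cu = 30.7
  s <- sample_table(df)
  out <- summarize_metals(s, cfg$reference)
  expect_equal(out$er_background_percent[out$metal == "Cu"], 30)
  expect_equal(out$mean[out$metal == "Cu"], mean(df$Cu))
  expect_equal(out$sd[out$metal == "Cu"], stats::sd(df$Cu))
  ## constant column: sd 0, cv 0
  expect_equal(out$sd[out$metal == "Cd"], 0)
  expect_equal(out$cv_percent[out$metal == "Cd"], 0)
  expect_error(summarize_metals(s[1, ], cfg$reference), "2 sites")
})

test_that("CV helper is consistent with published mean/SD pairs", {
  expect_equal(round(cv_percent(58.74, 20.18), 1), 34.4)
  expect_equal(round(cv_percent(186.28, 66.92), 1), 35.9)
})

test_that("enrichment factors: identity, linearity and brute-force oracle", {
  cfg <- load_config()
  ref <- cfg$reference
  metals <- names(ref$background)
  ## site at exactly background composition -> EF 1 everywhere;
  ## doubled concentrations at background Mn -> EF 2
  df <- data.frame(site_id = c("bg", "x2"), x = 0:1, y = 0:1)
  for (m in metals) df[[m]] <- c(ref$background[[m]], 2 * ref$background[[m]])
  df$Mn <- rep(ref$mn_background, 2)
  e <- enrichment_factor(sample_table(df), ref)
  expect_equal(unname(e$ef["bg", ]), rep(1, 6), tolerance = 1e-12)
  expect_equal(unname(e$ef["x2", ]), rep(2, 6), tolerance = 1e-12)

  s <- fixture_samples(n = 5)
  e2 <- enrichment_factor(s, ref)
  expect_equal(e2$ef, oracle_ef(s, ref), tolerance = 1e-10)
})

test_that("EF is scale-covariant exactly when backgrounds scale too", {
  cfg <- load_config()
  s <- fixture_samples(n = 6)
  base <- enrichment_factor(s, cfg$reference)$ef
  lam <- 3.7
  df <- as.data.frame(s)
  for (m in c(metals_of(s), "Mn")) df[[m]] <- df[[m]] * lam
  scaled <- sample_table(df)
  ## scaling samples alone leaves EF unchanged (double ratio)
  expect_equal(enrichment_factor(scaled, cfg$reference)$ef, base,
               tolerance = 1e-12)
  ## scaling the backgrounds identically also leaves EF unchanged
  ref2 <- cfg$reference
  ref2$background <- ref2$background * lam
  ref2$mn_background <- ref2$mn_background * lam
  expect_equal(enrichment_factor(s, ref2)$ef, base, tolerance = 1e-12)
  ## scaling backgrounds but not Mn background changes EF
  ref3 <- cfg$reference
  ref3$background <- ref3$background * lam
  expect_false(isTRUE(all.equal(enrichment_factor(s, ref3)$ef, base)))
})

test_that("sites without reference element are excluded with a warning", {
  df <- as.data.frame(fixture_samples(n = 4))
  df$Mn[2] <- 0
  s <- sample_table(df)
  cfg <- load_config()
  expect_warning(e <- enrichment_factor(s, cfg$reference), "P2")
  expect_identical(e$excluded_sites, "P2")
  expect_equal(nrow(e$ef), 3)
})

test_that("Sutherland classification: bounds, boundaries, monotonicity", {
  expect_identical(classify_ef(1.0), "deficient-to-minimal")
  expect_identical(classify_ef(2.0), "moderate")      # left-closed
  expect_identical(classify_ef(5.0), "significant")   # left-closed
  expect_identical(classify_ef(19.999), "significant")
  expect_identical(classify_ef(20), "very high")
  expect_identical(classify_ef(41), "extreme")
  expect_error(classify_ef(0), "positive")
  ## monotone: class index never decreases along sorted EF values
  set.seed(7)
  ef <- sort(stats::rlnorm(300, 1, 1.5))
  idx <- match(classify_ef(ef), soilrisk:::ef_class_labels())
  expect_true(all(diff(idx) >= 0))
})

test_that("Pearson correlations match the textbook oracle", {
  s <- fixture_samples(n = 10, seed = 21)
  cm <- correlation_matrix(s)
  expect_equal(unname(diag(cm$r)), rep(1, 6))
  expect_equal(cm$r, t(cm$r))
  X <- conc_matrix(s)
  for (pair in list(c(1, 2), c(3, 5), c(2, 6))) {
    o <- oracle_pearson(X[, pair[1]], X[, pair[2]])
    expect_equal(cm$r[pair[1], pair[2]], o$r, tolerance = 1e-10)
    expect_equal(cm$p[pair[1], pair[2]], o$p, tolerance = 1e-10)
  }
  ## exact linear relations
  df <- as.data.frame(fixture_samples(n = 8))
  df$Cr <- 2 * df$Cd
  df$Cu <- 200 - df$Cd  # negative slope, values stay positive
  s2 <- sample_table(df)
  cm2 <- correlation_matrix(s2)
  expect_equal(cm2$r["Cd", "Cr"], 1, tolerance = 1e-12)
  expect_equal(cm2$r["Cd", "Cu"], -1, tolerance = 1e-12)
})

test_that("constant columns are flagged, not silently zeroed", {
  df <- as.data.frame(fixture_samples(n = 6))
  df$Zn <- rep(5, 6)
  s <- sample_table(df)
  expect_warning(cm <- correlation_matrix(s), "Zn")
  expect_identical(cm$degenerate, "Zn")
  expect_true(all(is.na(cm$r["Zn", setdiff(colnames(cm$r), "Zn")])))
  expect_error(correlation_matrix(fixture_samples(n = 2)), "3 sites")
})
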