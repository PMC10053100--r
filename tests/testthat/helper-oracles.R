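## Independent oracles and fixture builders shared across the suite.
## Everything here is deliberately naive (double loops, direct formulas,
## numerical integration) so it cannot share defects with the package code
## it checks.

## deterministic small sample table
fixture_samples <- function(n = 5, seed = 99, metals = c("Cd", "Cr", "Cu",
                                                         "Zn", "Ni", "Pb")) {
  set.seed(seed)
  df <- data.frame(site_id = paste0("P", seq_len(n)),
                   x = runif(n, 0, 1000), y = runif(n, 0, 1000))
  for (m in metals) df[[m]] <- round(runif(n, 0.5, 120), 3)
  df$Mn <- round(runif(n, 300, 900), 2)
  sample_table(df, metals = metals)
}

## minimal hand-built config objects for HRA tests (simple round numbers)
tiny_exposure <- function() {
  mk <- function(IngR, InhR, EFreq, ED, BW, AT_nc, AT_ca, SA, AF, ABS, PEF) {
    sapply(c(IngR = IngR, InhR = InhR, EFreq = EFreq, ED = ED, BW = BW,
             AT_nc = AT_nc, AT_ca = AT_ca, SA = SA, AF = AF, ABS = ABS,
             PEF = PEF),
           function(v) dist_spec("point", value = v), simplify = FALSE)
  }
  structure(list(adult = mk(100, 10, 350, 24, 70, 8760, 25550,
                            5700, 0.07, 0.001, 1.36e9),
                 child = mk(200, 7.5, 350, 6, 15, 2190, 25550,
                            2800, 0.2, 0.001, 1.36e9)),
            class = "exposure_params")
}

tiny_toxicity <- function(rfd = list(), sf = list()) {
  structure(list(rfd = rfd, sf = sf), class = "toxicity_table")
}

## brute-force enrichment factor: explicit loops over sites and metals
oracle_ef <- function(samples, ref) {
  df <- as.data.frame(samples)
  metals <- metals_of(samples)
  out <- matrix(NA_real_, nrow(df), length(metals),
                dimnames = list(df$site_id, metals))
  for (i in seq_len(nrow(df))) {
    for (m in metals) {
      num <- df[[m]][i] / df$Mn[i]
      den <- ref$background[[m]] / ref$mn_background
      out[i, m] <- num / den
    }
  }
  out
}

## textbook Pearson r and two-sided p-value
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

## direct-formula dose for one route
oracle_add <- function(C, p, route, AT) {
  if (route == "ingestion")
    C * p[["IngR"]] * p[["EFreq"]] * p[["ED"]] / (p[["BW"]] * AT) * 1e-6
  else if (route == "dermal")
    C * p[["SA"]] * p[["AF"]] * p[["ABS"]] * p[["EFreq"]] * p[["ED"]] /
      (p[["BW"]] * AT) * 1e-6
  else
    C * p[["InhR"]] * p[["EFreq"]] * p[["ED"]] /
      (p[["PEF"]] * p[["BW"]] * AT) * 1e-6
}

## brute-force IDW at arbitrary points
oracle_idw <- function(sx, sy, z, px, py, power) {
  vapply(seq_along(px), function(i) {
    d <- sqrt((sx - px[i])^2 + (sy - py[i])^2)
    if (any(d < 1e-9)) return(z[which(d < 1e-9)[1]])
    w <- d^(-power)
    sum(w * z) / sum(w)
  }, numeric(1))
}

## truncated lognormal moments by numerical integration (moment-matched
## to arithmetic mean/sd, truncated to [lo, hi])
oracle_trunc_lnorm <- function(mean, sd, lo, hi) {
  s2 <- log(1 + (sd / mean)^2); sl <- sqrt(s2); ml <- log(mean) - s2 / 2
  Z <- stats::plnorm(hi, ml, sl) - stats::plnorm(lo, ml, sl)
  m1 <- stats::integrate(function(x) x * stats::dlnorm(x, ml, sl) / Z,
                         lo, hi, rel.tol = 1e-10)$value
  m2 <- stats::integrate(function(x) x^2 * stats::dlnorm(x, ml, sl) / Z,
                         lo, hi, rel.tol = 1e-10)$value
  list(mean = m1, sd = sqrt(m2 - m1^2), removed_mass = 1 - Z)
}

## all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i) {
    lapply(all_perms(n - 1L), function(p) c(i, (seq_len(n)[-i])[p]))
  }))
}

## best mean row-cosine similarity between estimated and true profiles
## over all factor permutations
best_perm_cosine <- function(F_hat, F_true) {
  k <- nrow(F_hat)
  rn <- function(M) M / sqrt(rowSums(M^2))
  S <- rn(F_hat) %*% t(rn(F_true))
  max(vapply(all_perms(k), function(p) mean(S[cbind(seq_len(k), p)]),
             numeric(1)))
}

## established NMF oracle: scikit-learn, squared Frobenius objective,
## best of several random restarts
sklearn_nmf_objective <- function(X, k, n_init = 10, max_iter = 5000) {
  fx <- tempfile(fileext = ".csv")
  utils::write.table(X, fx, row.names = FALSE, col.names = FALSE, sep = ",")
  code <- sprintf(paste0(
    "import numpy as np\n",
    "from sklearn.decomposition import NMF\n",
    "X = np.loadtxt(%s, delimiter=',')\n",
    "best = None\n",
    "for s in range(%d):\n",
    "    m = NMF(n_components=%d, init='random', random_state=s,\n",
    "            max_iter=%d, tol=1e-12)\n",
    "    W = m.fit_transform(X); H = m.components_\n",
    "    q = float(((X - W @ H)**2).sum())\n",
    "    best = q if best is None or q < best else best\n",
    "print(repr(best))\n"),
    deparse(fx), n_init, k, max_iter)
  out <- suppressWarnings(system2("python", c("-c", shQuote(code)),
                                  stdout = TRUE, stderr = FALSE))
  q <- suppressWarnings(as.numeric(out[length(out)]))
  if (!length(out) || is.na(q))
    stop("sklearn NMF oracle failed to run")
  q
}

## write a mutated copy of the shipped config, return its path
modified_config <- function(mutate) {
  raw <- jsonlite::read_json(default_config_path(), simplifyVector = FALSE)
  raw <- mutate(raw)
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA)
  path
}
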