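#' Shipped demo summary statistics
#'
#' Per-metal min, max, arithmetic mean and SD (mg kg-1) of a published
#' 40-site survey of urban-park surface soils in central China; used as
#' the emulation target of [generate_matched_samples()] and as the
#' concentration input of the demo risk assessment. The optional reference
#' element row (Mn) is a synthetic stand-in built from the configured Mn
#' background with a 20% CV, since surveys rarely tabulate the reference
#' element.
#'
#' @param include_reference append a synthetic Mn row.
#' @param mn_background Mn background used for the synthetic Mn row.
#' @return data.frame with columns `metal`, `min`, `max`, `mean`, `sd`.
#' @export
demo_summary <- function(include_reference = FALSE, mn_background = 583) {
  path <- system.file("extdata", "demo_summary.csv", package = "soilrisk",
                      mustWork = TRUE)
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (include_reference) {
    s <- rbind(s, data.frame(metal = "Mn", min = mn_background * 0.4,
                             max = mn_background * 2.5, mean = mn_background,
                             sd = mn_background * 0.2))
  }
  s
}

#' Generate factor-structured soil samples
#'
#' Draws a nonnegative ground-truth contribution matrix G (sites x k) and
#' profile matrix F (k x metals), forms X = G F + E with elementwise noise
#' sd equal to `noise_cv` times the noise-free value, clips negative draws
#' to zero, and returns both the sample table and the ground truth. The
#' construction mirrors the receptor-model decomposition used for source
#' apportionment, so factorization code can be tested against known truth.
#'
#' Profiles are sparse compositions (each factor loads strongly on a small
#' random subset of metals), which is what distinguishable emission sources
#' look like chemically and what makes the factorization identifiable.
#' Contributions are lognormal, reflecting the right-skew of source
#' activity across sites. Column scales are set so that per-metal mean
#' concentrations are of realistic magnitude (tens of mg kg-1).
#'
#' @param k number of sources (>= 1).
#' @param n_sites number of sites (>= k).
#' @param metals analyte names (length > k for identifiability).
#' @param noise_cv coefficient of variation of the additive noise (>= 0).
#' @param seed integer seed; the generator is fully reproducible.
#' @param ref_element name for the generated reference-element column; it
#'   is simulated independently (lognormal, mean `ref_mean`, 20% CV).
#' @param ref_mean mean of the reference element, mg kg-1.
#' @param conc_scale target average concentration per metal, mg kg-1.
#' @return list with `samples` (a [sample_table()]) and `truth` (list with
#'   `G_true`, `F_true`, `noise_sd`).
#' @export
generate_factor_samples <- function(k, n_sites, metals = SOILRISK_METALS,
                                    noise_cv = 0.1, seed = 1,
                                    ref_element = SOILRISK_REF_ELEMENT,
                                    ref_mean = 583, conc_scale = 50) {
  stopifnot(k >= 1, n_sites >= k, noise_cv >= 0)
  m <- length(metals)
  if (k >= min(n_sites, m))
    stop("generate_factor_samples: k must be < min(n_sites, n_metals) ",
         "for an identifiable factorization", call. = FALSE)
  rng <- local_rng(seed)

  ## sparse profiles: each factor dominated by ceil(m/k)+1 metals
  F_true <- matrix(0, k, m, dimnames = list(paste0("F", seq_len(k)), metals))
  lead <- split(sample.int(m), rep_len(seq_len(k), m))
  for (f in seq_len(k)) {
    w <- stats::runif(m, 0.01, 0.08)       # trace presence everywhere
    w[lead[[f]]] <- stats::runif(length(lead[[f]]), 0.6, 1)
    F_true[f, ] <- w / sum(w)
  }
  ## lognormal contributions, mean scaled so column means ~ conc_scale
  G_true <- matrix(stats::rlnorm(n_sites * k, meanlog = 0, sdlog = 0.7),
                   n_sites, k)
  total <- mean(colSums(G_true %*% F_true) / n_sites)
  G_true <- G_true * (conc_scale / total)

  X0 <- G_true %*% F_true
  noise_sd <- noise_cv * X0
  E <- matrix(stats::rnorm(length(X0), 0, 1), nrow(X0), ncol(X0)) * noise_sd
  X <- pmax(X0 + E, 0)
  colnames(X) <- metals

  ref <- stats::rlnorm(n_sites,
                       lognormal_params(ref_mean, 0.2 * ref_mean)$meanlog,
                       lognormal_params(ref_mean, 0.2 * ref_mean)$sdlog)
  df <- data.frame(site_id = sprintf("S%02d", seq_len(n_sites)),
                   x = stats::runif(n_sites, 0, 10000),
                   y = stats::runif(n_sites, 0, 10000))
  df <- cbind(df, as.data.frame(X))
  df[[ref_element]] <- ref
  rng()  # restore RNG state

  list(samples = sample_table(df, metals = metals, ref_element = ref_element),
       truth = list(G_true = G_true, F_true = F_true,
                    noise_sd = apply(noise_sd, 2, stats::median)))
}

#' Generate samples matched to published summary statistics
#'
#' Each metal is drawn from a lognormal whose *arithmetic* mean and SD
#' match the target summary (moment matching on the log scale), truncated
#' to the reported `[min, max]` range by rejection resampling. Sample
#' moments converge to the targets as `n_sites` grows, up to the (small)
#' bias introduced by truncation.
#'
#' @param summary data.frame with columns `metal`, `min`, `max`, `mean`,
#'   `sd` — e.g. [demo_summary()].
#' @param n_sites number of sites to draw.
#' @param seed integer seed.
#' @param ref_element,ref_mean reference element column: if `ref_element`
#'   is not a row of `summary`, it is simulated as lognormal with mean
#'   `ref_mean` and 20% CV.
#' @return a [sample_table()].
#' @export
generate_matched_samples <- function(summary, n_sites = 40, seed = 1,
                                     ref_element = SOILRISK_REF_ELEMENT,
                                     ref_mean = 583) {
  stopifnot(is.data.frame(summary),
            all(c("metal", "min", "max", "mean", "sd") %in% names(summary)))
  if (any(summary$mean <= 0) || any(summary$sd < 0))
    stop("generate_matched_samples: mean must be > 0 and sd >= 0")
  if (any(summary$max < summary$min))
    stop("generate_matched_samples: max < min for metal ",
         summary$metal[which(summary$max < summary$min)[1]])
  rng <- local_rng(seed)

  draw_one <- function(mn, mx, m, s) {
    if (s == 0) return(rep(m, n_sites))
    spec <- dist_spec("lognormal", mean = m, sd = s,
                      trunc_min = mn, trunc_max = mx)
    sample_dist(spec, n_sites)
  }
  cols <- lapply(seq_len(nrow(summary)), function(i)
    draw_one(summary$min[i], summary$max[i], summary$mean[i], summary$sd[i]))
  names(cols) <- summary$metal

  if (!ref_element %in% summary$metal) {
    cols[[ref_element]] <- sample_dist(
      dist_spec("lognormal", mean = ref_mean, sd = 0.2 * ref_mean), n_sites)
  }
  df <- data.frame(site_id = sprintf("S%02d", seq_len(n_sites)),
                   x = stats::runif(n_sites, 0, 10000),
                   y = stats::runif(n_sites, 0, 10000))
  df <- cbind(df, as.data.frame(cols))
  rng()
  sample_table(df, metals = setdiff(summary$metal, ref_element),
               ref_element = ref_element)
}

## Seed the RNG restorably: returns a restore function.
local_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    invisible(NULL)
  }
}

## Stage-specific child seed derived from a root seed (kept below 2^31).
derive_seed <- function(seed, stage) {
  offsets <- c(synthetic = 101L, pmf = 211L, mc = 307L, pipeline = 401L)
  off <- offsets[[stage]]
  if (is.null(off)) off <- 997L
  (as.integer(seed) * 1009L + off) %% 2147483647L
}
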