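#' Per-metal summary statistics with exceedance screening
#'
#' Computes min, max, arithmetic mean, sample SD (n-1 denominator), the
#' coefficient of variation in percent (100 sd/mean) and the exceedance
#' rates: the share of sites whose concentration strictly exceeds the
#' geochemical background and the regulatory guide (screening) value.
#'
#' @param samples a [sample_table()].
#' @param ref a `reference_values` object ([load_config()]); may be `NULL`,
#'   in which case the exceedance columns are `NA`.
#' @return data.frame (one row per metal) with columns `metal`, `min`,
#'   `max`, `mean`, `sd`, `cv_percent`, `er_background_percent`,
#'   `er_guide_percent`.
#' @export
summarize_metals <- function(samples, ref = NULL) {
  if (nrow(samples) < 2)
    stop("summarize_metals: at least 2 sites required (sample SD undefined)")
  metals <- metals_of(samples)
  X <- conc_matrix(samples)
  out <- data.frame(
    metal = metals,
    min = apply(X, 2, min),
    max = apply(X, 2, max),
    mean = colMeans(X),
    sd = apply(X, 2, stats::sd),
    row.names = NULL)
  out$cv_percent <- ifelse(out$mean > 0, 100 * out$sd / out$mean, 0)
  if (!is.null(ref)) {
    bg <- ref$background[metals]
    gd <- ref$guide[metals]
    out$er_background_percent <-
      100 * colMeans(sweep(X, 2, bg, ">"))
    out$er_guide_percent <-
      100 * colMeans(sweep(X, 2, gd, ">"))
  } else {
    out$er_background_percent <- NA_real_
    out$er_guide_percent <- NA_real_
  }
  out
}

#' Coefficient of variation from a mean/SD pair
#'
#' Convenience used when checking published tables for internal
#' consistency: `100 * sd / mean`, in percent.
#'
#' @param mean,sd arithmetic mean (> 0) and SD.
#' @return CV in percent.
#' @export
cv_percent <- function(mean, sd) {
  stopifnot(all(mean > 0))
  100 * sd / mean
}

#' Enrichment factors relative to a crustal reference element
#'
#' EF for metal i at a site is the double ratio
#' \deqn{EF = (C_i / C_{ref})_{sample} / (C_i / C_{ref})_{background}}
#' with the site's own reference-element concentration (Mn here) in the
#' numerator and the regional backgrounds in the denominator. EF near 1
#' indicates crustal origin; larger values indicate anthropogenic
#' enrichment. Sites with zero reference-element concentration cannot be
#' assessed and are excluded with a warning.
#'
#' @param samples a [sample_table()].
#' @param ref a `reference_values` object with `background` and
#'   `mn_background`.
#' @param class_bounds Sutherland cut points (increasing), default
#'   2/5/20/40.
#' @return list with `ef` (sites x metals matrix), `class` (same shape,
#'   character labels), `excluded_sites` (character).
#' @export
enrichment_factor <- function(samples, ref, class_bounds = c(2, 5, 20, 40)) {
  metals <- metals_of(samples)
  ref_el <- attr(samples, "ref_element")
  if (is.null(ref_el) || !ref_el %in% names(samples))
    stop("enrichment_factor: sample table has no reference-element column")
  cr <- as.data.frame(samples)[[ref_el]]
  bad <- cr <= 0
  if (any(bad)) {
    warning(sprintf("enrichment_factor: %d site(s) with non-positive %s excluded: %s",
                    sum(bad), ref_el,
                    paste(samples$site_id[bad], collapse = ", ")))
  }
  keep <- !bad
  X <- conc_matrix(samples)[keep, , drop = FALSE]
  crk <- cr[keep]
  bg_ratio <- ref$background[metals] / ref$mn_background
  ef <- sweep(X / crk, 2, bg_ratio, "/")
  cls <- apply(ef, c(1, 2), classify_ef, bounds = class_bounds)
  list(ef = ef, class = cls,
       excluded_sites = samples$site_id[bad])
}

ef_class_labels <- function() {
  c("deficient-to-minimal", "moderate", "significant", "very high", "extreme")
}

#' Sutherland enrichment class of an EF value
#'
#' Left-closed intervals over the default cut points 2/5/20/40:
#' EF < 2 deficient-to-minimal, 2 <= EF < 5 moderate, 5 <= EF < 20
#' significant, 20 <= EF < 40 very high, EF >= 40 extreme.
#'
#' @param ef_value positive EF value (vectorised).
#' @param bounds increasing cut points, length 4 for the standard scheme.
#' @return character class label(s).
#' @export
classify_ef <- function(ef_value, bounds = c(2, 5, 20, 40)) {
  if (any(ef_value <= 0) || any(!is.finite(ef_value)))
    stop("classify_ef: EF values must be positive and finite")
  stopifnot(length(bounds) == 4, !is.unsorted(bounds))
  labels <- ef_class_labels()
  labels[findInterval(ef_value, bounds) + 1L]
}

#' Pearson correlation matrix with p-values
#'
#' Pairwise Pearson correlations between metal concentrations, with
#' two-sided p-values from the t-distribution. Constant columns have no
#' defined correlation; their entries are `NA` and the affected metals are
#' returned in `degenerate`.
#'
#' @param samples a [sample_table()].
#' @return list with `r` and `p` (symmetric matrices, unit diagonal) and
#'   `degenerate` (character vector of constant metals).
#' @export
correlation_matrix <- function(samples) {
  if (nrow(samples) < 3)
    stop("correlation_matrix: at least 3 sites required")
  X <- conc_matrix(samples)
  m <- ncol(X)
  metals <- colnames(X)
  const <- metals[apply(X, 2, stats::sd) == 0]
  r <- diag(1, m); p <- matrix(NA_real_, m, m)
  dimnames(r) <- dimnames(p) <- list(metals, metals)
  diag(p) <- 0
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    if (metals[i] %in% const || metals[j] %in% const) {
      r[i, j] <- r[j, i] <- NA_real_
      next
    }
    ct <- stats::cor.test(X[, i], X[, j], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  if (length(const))
    warning("correlation_matrix: constant column(s): ",
            paste(const, collapse = ", "))
  list(r = r, p = p, degenerate = const)
}
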