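#' Distribution specification for Monte Carlo inputs
#'
#' A `dist_spec` describes how a scalar model input varies: a degenerate
#' point value or a parametric family, optionally truncated. Lognormal
#' specs are parameterised by their *arithmetic* mean and standard
#' deviation (the scale on which soil surveys report concentrations);
#' the log-scale parameters are recovered by moment matching
#' \eqn{\mu = \log(m^2/\sqrt{m^2+s^2})}, \eqn{\sigma^2 = \log(1+s^2/m^2)}.
#'
#' @param family one of `"point"`, `"normal"`, `"lognormal"`, `"uniform"`,
#'   `"triangular"`.
#' @param value point value (family `"point"`).
#' @param mean,sd arithmetic mean and standard deviation (families
#'   `"normal"`, `"lognormal"`).
#' @param min,max support bounds (families `"uniform"`, `"triangular"`).
#' @param mode mode (family `"triangular"`).
#' @param trunc_min,trunc_max optional truncation bounds applied by
#'   rejection; the truncated support must stay positive for families that
#'   model positive quantities.
#' @return an object of class `dist_spec`.
#' @export
#' @examples
#' dist_spec("lognormal", mean = 2.52, sd = 4.31)
#' dist_spec("triangular", min = 100, mode = 200, max = 300)
dist_spec <- function(family, value = NULL, mean = NULL, sd = NULL,
                      min = NULL, max = NULL, mode = NULL,
                      trunc_min = NULL, trunc_max = NULL) {
  family <- match.arg(family,
                      c("point", "normal", "lognormal", "uniform", "triangular"))
  spec <- list(family = family, value = value, mean = mean, sd = sd,
               min = min, max = max, mode = mode,
               trunc_min = trunc_min, trunc_max = trunc_max)
  class(spec) <- "dist_spec"
  validate_dist_spec(spec)
  spec
}

validate_dist_spec <- function(spec) {
  fam <- spec$family
  need <- function(field) {
    v <- spec[[field]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("dist_spec(%s): parameter '%s' must be a finite number",
                   fam, field), call. = FALSE)
    v
  }
  switch(fam,
    point = need("value"),
    normal = {
      need("mean")
      if (need("sd") < 0) stop("dist_spec(normal): sd must be >= 0", call. = FALSE)
    },
    lognormal = {
      if (need("mean") <= 0) stop("dist_spec(lognormal): mean must be > 0", call. = FALSE)
      if (need("sd") < 0) stop("dist_spec(lognormal): sd must be >= 0", call. = FALSE)
    },
    uniform = ,
    triangular = {
      lo <- need("min"); hi <- need("max")
      if (hi < lo) stop(sprintf("dist_spec(%s): max < min", fam), call. = FALSE)
      if (fam == "triangular") {
        m <- need("mode")
        if (m < lo || m > hi)
          stop("dist_spec(triangular): mode outside [min, max]", call. = FALSE)
      }
    })
  if (!is.null(spec$trunc_min) && !is.null(spec$trunc_max) &&
      spec$trunc_max < spec$trunc_min)
    stop("dist_spec: trunc_max < trunc_min", call. = FALSE)
  invisible(spec)
}

#' Moment-matched log-scale parameters of a lognormal
#'
#' @param mean,sd arithmetic mean (> 0) and standard deviation (>= 0).
#' @return list with `meanlog` and `sdlog`.
#' @export
lognormal_params <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  if (sd == 0) return(list(meanlog = log(mean), sdlog = 0))
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

## Inverse-CDF draw from a triangular(min, mode, max).
rtriangular <- function(n, min, mode, max) {
  if (max == min) return(rep(min, n))
  u <- stats::runif(n)
  fc <- (mode - min) / (max - min)
  ifelse(u < fc,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

#' Draw from a distribution specification
#'
#' Truncation bounds, when present, are enforced by rejection resampling;
#' an error is raised if the acceptance rate falls below 1% (the truncated
#' region carries almost no mass and the spec is considered mis-stated).
#'
#' @param spec a [dist_spec()].
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @export
sample_dist <- function(spec, n) {
  if (!inherits(spec, "dist_spec")) stop("spec must be a dist_spec")
  stopifnot(n >= 0)
  draw <- switch(spec$family,
    point = function(m) rep(spec$value, m),
    normal = function(m) stats::rnorm(m, spec$mean, spec$sd),
    lognormal = function(m) {
      p <- lognormal_params(spec$mean, spec$sd)
      if (p$sdlog == 0) rep(spec$mean, m)
      else stats::rlnorm(m, p$meanlog, p$sdlog)
    },
    uniform = function(m) stats::runif(m, spec$min, spec$max),
    triangular = function(m) rtriangular(m, spec$min, spec$mode, spec$max))
  lo <- if (is.null(spec$trunc_min)) -Inf else spec$trunc_min
  hi <- if (is.null(spec$trunc_max)) Inf else spec$trunc_max
  if (!is.finite(lo) && !is.finite(hi)) return(draw(n))
  out <- numeric(0)
  tried <- 0
  while (length(out) < n) {
    m <- max(n - length(out), 100L)
    x <- draw(m)
    tried <- tried + m
    out <- c(out, x[x >= lo & x <= hi])
    if (tried >= 10000L && length(out) / tried < 0.01)
      stop("sample_dist: truncation acceptance rate below 1%; check bounds")
  }
  out[seq_len(n)]
}

#' Expected value of a distribution specification
#'
#' Closed forms for untruncated families; truncated specs are evaluated by
#' a deterministic quasi-random average (used only for reporting, never in
#' the simulation itself).
#'
#' @param spec a [dist_spec()].
#' @return scalar mean.
#' @export
dist_mean <- function(spec) {
  if (!inherits(spec, "dist_spec")) stop("spec must be a dist_spec")
  if (is.null(spec$trunc_min) && is.null(spec$trunc_max)) {
    return(switch(spec$family,
      point = spec$value,
      normal = spec$mean,
      lognormal = spec$mean,
      uniform = (spec$min + spec$max) / 2,
      triangular = (spec$min + spec$mode + spec$max) / 3))
  }
  ## grid average of the inverse CDF restricted to the truncation window
  q <- (seq_len(20000L) - 0.5) / 20000L
  x <- switch(spec$family,
    point = rep(spec$value, length(q)),
    normal = stats::qnorm(q, spec$mean, spec$sd),
    lognormal = {
      p <- lognormal_params(spec$mean, spec$sd)
      stats::qlnorm(q, p$meanlog, p$sdlog)
    },
    uniform = stats::qunif(q, spec$min, spec$max),
    triangular = {
      u <- q
      fc <- (spec$mode - spec$min) / (spec$max - spec$min)
      ifelse(u < fc,
             spec$min + sqrt(u * (spec$max - spec$min) * (spec$mode - spec$min)),
             spec$max - sqrt((1 - u) * (spec$max - spec$min) * (spec$max - spec$mode)))
    })
  lo <- if (is.null(spec$trunc_min)) -Inf else spec$trunc_min
  hi <- if (is.null(spec$trunc_max)) Inf else spec$trunc_max
  keep <- x >= lo & x <= hi
  if (!any(keep)) stop("dist_mean: truncation window has no mass")
  mean(x[keep])
}

## Coerce a config entry (bare number or list with a 'family' field) to a
## dist_spec; bare numbers become point specs.
as_dist_spec <- function(x, what = "parameter") {
  if (inherits(x, "dist_spec")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(dist_spec("point", value = x))
  if (is.list(x) && !is.null(x$family)) {
    return(dist_spec(x$family, value = x$value, mean = x$mean, sd = x$sd,
                     min = x$min, max = x$max, mode = x$mode,
                     trunc_min = x$trunc_min, trunc_max = x$trunc_max))
  }
  stop(sprintf("cannot interpret %s as a value or distribution", what),
       call. = FALSE)
}
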