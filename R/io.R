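#' Construct and validate a soil sample table
#'
#' A `sample_table` is a `data.frame` with one row per sampling site:
#' a `site_id` column (unique labels), planar coordinates `x` and `y`,
#' and one concentration column per analyte in mg kg-1. The reference
#' element used for enrichment factors (Mn by default) is carried as an
#' ordinary concentration column.
#'
#' @param df data.frame with columns `site_id`, `x`, `y` and the metals.
#' @param metals character vector of analyte column names.
#' @param ref_element reference element column name, or `NULL` if absent.
#' @return validated `sample_table` (a data.frame subclass).
#' @export
sample_table <- function(df, metals = SOILRISK_METALS,
                         ref_element = SOILRISK_REF_ELEMENT) {
  stopifnot(is.data.frame(df))
  needed <- c("site_id", "x", "y", metals, ref_element)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("sample_table: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$site_id))
    stop("sample_table: duplicate site_id values", call. = FALSE)
  for (cn in c("x", "y", metals, ref_element)) {
    v <- df[[cn]]
    if (!is.numeric(v))
      stop(sprintf("sample_table: column '%s' is not numeric", cn), call. = FALSE)
    if (any(!is.finite(v)))
      stop(sprintf("sample_table: non-finite value in '%s' (site %s)",
                   cn, df$site_id[which(!is.finite(v))[1]]), call. = FALSE)
  }
  for (cn in c(metals, ref_element)) {
    bad <- which(df[[cn]] < 0)
    if (length(bad))
      stop(sprintf("sample_table: negative concentration in '%s' (site %s)",
                   cn, df$site_id[bad[1]]), call. = FALSE)
  }
  out <- df[, needed, drop = FALSE]
  out$site_id <- as.character(out$site_id)
  attr(out, "metals") <- metals
  attr(out, "ref_element") <- ref_element
  class(out) <- c("sample_table", "data.frame")
  out
}

#' Metals carried by a sample table
#' @param samples a [sample_table()].
#' @return character vector of analyte names (reference element excluded).
#' @export
metals_of <- function(samples) attr(samples, "metals")

#' Concentration matrix of a sample table
#' @param samples a [sample_table()].
#' @param metals columns to extract (default: the analyte metals).
#' @return numeric matrix, sites x metals, site_id as rownames.
#' @export
conc_matrix <- function(samples, metals = metals_of(samples)) {
  m <- as.matrix(as.data.frame(samples)[, metals, drop = FALSE])
  rownames(m) <- samples$site_id
  m
}

#' Read a soil sample CSV
#'
#' Expects a comma-delimited UTF-8 file with a header row naming
#' `site_id`, `x`, `y` and one column per metal. Values below the method
#' detection limit are retained as reported; substitution (if any) is a
#' downstream choice.
#'
#' @param path CSV file path.
#' @param metals analyte columns required to be present.
#' @param ref_element reference element column, or `NULL`.
#' @return a [sample_table()].
#' @export
read_samples <- function(path, metals = SOILRISK_METALS,
                         ref_element = SOILRISK_REF_ELEMENT) {
  if (!file.exists(path)) stop("read_samples: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  sample_table(df, metals = metals, ref_element = ref_element)
}

#' Write a sample table to CSV
#' @param samples a [sample_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(as.data.frame(samples), path, row.names = FALSE)
  invisible(path)
}

#' Load a configuration file
#'
#' The configuration is a JSON document with blocks `reference` (background,
#' guide and MDL values per metal plus the Mn background), `toxicity`
#' (per-metal, per-route RfD and SF) and `exposure` (per-population exposure
#' factors, each a point value or a distribution). Optional top-level keys:
#' `error_fraction` (PMF measurement uncertainty, default 0.1) and
#' `ef_class_bounds` (Sutherland class cut points, default 2/5/20/40).
#'
#' @param path JSON config path; defaults to the EPA-conventional demo
#'   configuration shipped with the package (see
#'   `system.file("extdata", "default_config.json", package = "soilrisk")`).
#' @return list of class `soilrisk_config` with elements `reference`
#'   (class `reference_values`), `toxicity` (class `toxicity_table`),
#'   `exposure` (class `exposure_params`), `error_fraction`,
#'   `ef_class_bounds`.
#' @export
load_config <- function(path = default_config_path()) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (block in c("reference", "toxicity", "exposure"))
    if (is.null(raw[[block]]))
      stop("load_config: missing '", block, "' block", call. = FALSE)

  reference <- reference_values(raw$reference)
  toxicity <- toxicity_table(raw$toxicity)
  exposure <- exposure_params(raw$exposure)

  extra <- setdiff(names(toxicity$rfd), names(reference$background))
  extra <- union(extra, setdiff(names(toxicity$sf), names(reference$background)))
  if (length(extra))
    stop("load_config: toxicity entries for metal(s) absent from reference ",
         "block: ", paste(extra, collapse = ", "), call. = FALSE)

  ef <- raw$error_fraction
  ef <- if (is.null(ef)) 0.1 else as.numeric(ef)
  if (!is.finite(ef) || ef <= 0 || ef >= 1)
    stop("load_config: error_fraction must lie in (0, 1)", call. = FALSE)
  bounds <- raw$ef_class_bounds
  bounds <- if (is.null(bounds)) c(2, 5, 20, 40) else as.numeric(unlist(bounds))

  structure(list(reference = reference, toxicity = toxicity,
                 exposure = exposure, error_fraction = ef,
                 ef_class_bounds = bounds),
            class = "soilrisk_config")
}

#' Path of the shipped demo configuration
#' @return file path of the default JSON config.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.json", package = "soilrisk",
              mustWork = TRUE)
}

## --- reference block ------------------------------------------------------

reference_values <- function(ref) {
  if (is.null(ref$mn_background))
    stop("reference block: 'mn_background' is required (no default is ",
         "shipped for the reference-element background)", call. = FALSE)
  mn <- as.numeric(ref$mn_background)
  if (!is.finite(mn) || mn <= 0)
    stop("reference block: mn_background must be > 0", call. = FALSE)
  metals <- ref$metals
  if (is.null(metals) || !length(metals))
    stop("reference block: 'metals' table is required", call. = FALSE)
  take <- function(field) {
    v <- vapply(metals, function(m) {
      x <- m[[field]]
      if (is.null(x)) NA_real_ else as.numeric(x)
    }, numeric(1))
    if (any(is.na(v) | v <= 0))
      stop(sprintf("reference block: every metal needs a positive '%s'", field),
           call. = FALSE)
    v
  }
  structure(list(background = take("background"), guide = take("guide"),
                 mdl = take("mdl"), mn_background = mn),
            class = "reference_values")
}

## --- toxicity block -------------------------------------------------------

toxicity_table <- function(tox) {
  grab <- function(block, label) {
    if (is.null(block)) return(list())
    out <- lapply(block, function(routes) {
      v <- vapply(routes, as.numeric, numeric(1))
      bad <- names(v)[!v > 0]
      if (length(bad))
        stop(sprintf("toxicity block: non-positive %s value (%s)",
                     label, paste(bad, collapse = ", ")), call. = FALSE)
      unknown <- setdiff(names(v), SOILRISK_ROUTES)
      if (length(unknown))
        stop(sprintf("toxicity block: unknown route '%s' in %s",
                     unknown[1], label), call. = FALSE)
      v
    })
    out
  }
  structure(list(rfd = grab(tox$rfd, "RfD"), sf = grab(tox$sf, "SF")),
            class = "toxicity_table")
}

## --- exposure block -------------------------------------------------------

EXPOSURE_FIELDS <- c("IngR", "InhR", "EFreq", "ED", "BW", "AT_nc", "AT_ca",
                     "SA", "AF", "ABS", "PEF")

exposure_params <- function(exp) {
  pops <- names(exp)
  if (!setequal(pops, SOILRISK_POPULATIONS))
    stop("exposure block: populations must be exactly {adult, child}",
         call. = FALSE)
  out <- lapply(exp, function(p) {
    missing_f <- setdiff(EXPOSURE_FIELDS, names(p))
    if (length(missing_f))
      stop("exposure block: missing parameter(s): ",
           paste(missing_f, collapse = ", "), call. = FALSE)
    specs <- lapply(EXPOSURE_FIELDS, function(f) as_dist_spec(p[[f]], f))
    names(specs) <- EXPOSURE_FIELDS
    for (f in EXPOSURE_FIELDS) {
      s <- specs[[f]]
      if (s$family == "point" && s$value <= 0)
        stop(sprintf("exposure block: point value for '%s' must be > 0", f),
             call. = FALSE)
    }
    if (specs$AT_ca$family == "point" && specs$AT_nc$family == "point" &&
        specs$AT_ca$value < specs$AT_nc$value)
      stop("exposure block: AT_ca must be >= AT_nc", call. = FALSE)
    specs
  })
  structure(out[SOILRISK_POPULATIONS], class = "exposure_params")
}

#' Collapse exposure distributions to point values
#'
#' Deterministic risk assessment uses point parameters; distributions are
#' replaced by their means ([dist_mean()]).
#'
#' @param exposure an `exposure_params` object from [load_config()].
#' @return named list per population of named numeric parameter vectors.
#' @export
collapse_exposure <- function(exposure) {
  lapply(exposure, function(p) vapply(p, dist_mean, numeric(1)))
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("<sample_table> %d sites, metals: %s (reference %s)\n",
              nrow(x), paste(metals_of(x), collapse = ", "),
              attr(x, "ref_element")))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' @export
print.soilrisk_config <- function(x, ...) {
  cat("<soilrisk_config>\n")
  cat("  metals:", paste(names(x$reference$background), collapse = ", "), "\n")
  cat("  error_fraction:", x$error_fraction,
      " EF class bounds:", paste(x$ef_class_bounds, collapse = "/"), "\n")
  cat("  RfD entries:", sum(lengths(x$toxicity$rfd)),
      " SF entries:", sum(lengths(x$toxicity$sf)), "\n")
  invisible(x)
}
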