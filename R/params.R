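#' Calibration parameters for the quantification pipelines
#'
#' Bundles every user-tunable parameter shared by the quantification
#' functions. The two binarization thresholds drive hysteresis
#' (double-threshold) segmentation: pixels above `b1` seed the foreground and
#' pixels above `b2` join it when connected to a seed. The area and elongation
#' gates filter labeled components (spores, conidia, traps); the Gaussian
#' radius controls background estimation for mycelium images; `min_hyphae`
#' controls deletion of small skeleton components and pruning of short
#' terminal branches.
#'
#' @param b1 Strong binarization threshold, fraction in `[0, 1]`.
#' @param b2 Weak (hysteresis) binarization threshold, fraction in
#'   `[0, b1]`.
#' @param min_area Minimum component area kept, in pixels.
#' @param max_area Maximum component area kept, in pixels.
#' @param elongation_max Maximum allowed elongation (see
#'   [label_and_measure()]) for spore/trap components, fraction in `[0, 1]`.
#' @param gaussian_radius Standard deviation, in pixels, of the Gaussian
#'   kernel used for background estimation in the mycelium pipeline.
#' @param min_hyphae Pixel threshold below which skeleton components are
#'   deleted and terminal skeleton branches are pruned.
#' @param scale Physical scale in microns per pixel. The default `1` leaves
#'   all outputs in pixel units; lengths are multiplied by `scale` and areas
#'   by `scale^2`.
#'
#' @return An object of class `calibration_params` (a named list).
#' @seealso [preset_params()] for parameter sets matched to the synthetic
#'   scene generators, [read_config()]/[write_config()] for plain-text
#'   persistence.
#' @examples
#' p <- calibration_params(b1 = 0.6, b2 = 0.35, min_area = 50)
#' p$b1
#' @export
calibration_params <- function(b1 = 0.5, b2 = 0.3,
                               min_area = 30, max_area = 2000,
                               elongation_max = 0.7,
                               gaussian_radius = 20, min_hyphae = 10,
                               scale = 1) {
  p <- list(b1 = as.numeric(b1), b2 = as.numeric(b2),
            min_area = as.numeric(min_area), max_area = as.numeric(max_area),
            elongation_max = as.numeric(elongation_max),
            gaussian_radius = as.numeric(gaussian_radius),
            min_hyphae = as.numeric(min_hyphae), scale = as.numeric(scale))
  validate_params(p)
  structure(p, class = "calibration_params")
}

validate_params <- function(p) {
  stopifnot(is.list(p))
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  for (k in c("b1", "b2", "min_area", "max_area", "elongation_max",
              "gaussian_radius", "min_hyphae", "scale"))
    if (!num1(p[[k]])) stop("parameter '", k, "' must be a single finite number")
  if (p$b2 < 0 || p$b1 > 1 || p$b2 > p$b1)
    stop("thresholds must satisfy 0 <= b2 <= b1 <= 1 (got b1=", p$b1,
         ", b2=", p$b2, ")")
  if (p$min_area < 0 || p$min_area > p$max_area)
    stop("areas must satisfy 0 <= min_area <= max_area")
  if (p$elongation_max < 0 || p$elongation_max > 1)
    stop("elongation_max must be in [0, 1]")
  if (p$gaussian_radius < 0) stop("gaussian_radius must be >= 0")
  if (p$min_hyphae < 0) stop("min_hyphae must be >= 0")
  if (p$scale <= 0) stop("scale must be > 0")
  invisible(p)
}

#' @export
print.calibration_params <- function(x, ...) {
  cat("Calibration parameters:\n")
  for (k in names(x)) cat(sprintf("  %-15s %g\n", k, x[[k]]))
  invisible(x)
}

#' Parameter presets matched to the synthetic scene generators
#'
#' Shipped calibrations tuned against the default synthetic fixtures, one per
#' quantification function. They are sensible starting points for real
#' images of comparable contrast but are expected to be re-calibrated (see
#' [sweep_calibration()]) for any new acquisition setup.
#'
#' * `"spores"` — brightfield counting: dark conidia on a bright background.
#' * `"morphology"` — fluorescence morphometry: bright conidia, no inversion.
#' * `"mycelium"` — stained mycelium: bright hyphae, background subtraction.
#' * `"traps"` — trap counting: large dense clusters, strict area gate.
#'
#' @param mode One of `"spores"`, `"morphology"`, `"mycelium"`, `"traps"`.
#' @param ... Overrides passed on to [calibration_params()].
#' @return A `calibration_params` object.
#' @examples
#' preset_params("traps")$min_area
#' @export
preset_params <- function(mode = c("spores", "morphology", "mycelium", "traps"),
                          ...) {
  mode <- match.arg(mode)
  base <- switch(mode,
    spores     = list(b1 = 0.5, b2 = 0.3, min_area = 30, max_area = 2000,
                      elongation_max = 0.7, gaussian_radius = 20,
                      min_hyphae = 10),
    morphology = list(b1 = 0.5, b2 = 0.3, min_area = 30, max_area = 5000,
                      elongation_max = 0.7, gaussian_radius = 20,
                      min_hyphae = 10),
    mycelium   = list(b1 = 0.3, b2 = 0.15, min_area = 30, max_area = 1e7,
                      elongation_max = 1, gaussian_radius = 20,
                      min_hyphae = 10),
    traps      = list(b1 = 0.65, b2 = 0.45, min_area = 500, max_area = 20000,
                      elongation_max = 0.6, gaussian_radius = 20,
                      min_hyphae = 10))
  over <- list(...)
  base[names(over)] <- over
  do.call(calibration_params, base)
}

.config_keys <- c("b1", "b2", "min_area", "max_area", "elongation_max",
                  "gaussian_radius", "min_hyphae", "scale")

#' Read and write calibration parameters as plain-text key=value files
#'
#' The configuration dialect is one `key=value` pair per line with exactly
#' the keys `b1, b2, min_area, max_area, elongation_max, gaussian_radius,
#' min_hyphae, scale`. Blank lines and lines starting with `#` are ignored.
#' `write_config()` followed by `read_config()` is an identity.
#'
#' @param path File path.
#' @param params A `calibration_params` object.
#' @return `read_config()` returns a `calibration_params` object;
#'   `write_config()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' write_config(calibration_params(), f)
#' read_config(f)
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  vals <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    m <- regmatches(ln, regexec("^([A-Za-z_0-9]+)\\s*=\\s*(\\S+)$", ln))[[1]]
    if (length(m) != 3)
      stop("malformed config line ", i, ": '", lines[i], "'")
    key <- m[2]
    if (!key %in% .config_keys)
      stop("unknown config key '", key, "' at line ", i)
    val <- suppressWarnings(as.numeric(m[3]))
    if (is.na(val)) stop("non-numeric value for '", key, "' at line ", i)
    vals[[key]] <- val
  }
  missing <- setdiff(.config_keys, names(vals))
  if (length(missing))
    stop("config is missing key(s): ", paste(missing, collapse = ", "))
  do.call(calibration_params, vals[.config_keys])
}

#' @rdname read_config
#' @export
write_config <- function(params, path) {
  stopifnot(inherits(params, "calibration_params"))
  lines <- vapply(.config_keys,
                  function(k) sprintf("%s=%.10g", k, params[[k]]), "")
  writeLines(lines, path)
  invisible(path)
}
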