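# Spore/conidia counting and morphometry.

#' Count spores or conidia in a brightfield image
#'
#' Detects dark spores/conidia on a bright transparent background. The
#' image is inverted so the objects become bright, binarized with
#' hysteresis thresholds `b1`/`b2`, labeled, measured, and filtered by the
#' area and elongation gates; the surviving components are counted.
#' Touching spores merge into one component and count once (no declumping).
#'
#' @param img Numeric matrix in `[0, 1]`, dark objects on bright
#'   background.
#' @param params A `calibration_params` object.
#' @param image_name Identifier recorded in the result (used by the batch
#'   runner).
#' @return A list of class `spore_count` with elements `image_name`,
#'   `n_spores`, `components` (records of the kept components) and
#'   `binary` (the segmentation, for overlay rendering).
#' @seealso [measure_spores()] for fluorescence morphometry,
#'   [count_traps()] which applies the same selection at trap scale.
#' @export
count_spores <- function(img, params, image_name = "image") {
  stopifnot(inherits(params, "calibration_params"))
  bw <- hysteresis_binarize(invert_image(img), params$b1, params$b2)
  recs <- label_and_measure(bw, params$scale)
  kept <- filter_components(recs, params)
  structure(list(image_name = image_name, n_spores = nrow(kept),
                 components = kept, binary = bw),
            class = "spore_count")
}

#' @export
print.spore_count <- function(x, ...) {
  cat(x$image_name, ":", x$n_spores, "objects\n")
  invisible(x)
}

#' Per-spore morphometry from a fluorescence image
#'
#' For stained spores that already appear bright on a dark background, so
#' no inversion is applied. The segmentation and component filter are
#' identical to [count_spores()]; each kept component is reported with its
#' area, length (longest best-fit-ellipse axis), width (shortest axis) and
#' circularity, in physical units when `scale` is set (lengths times
#' `scale`, areas times `scale^2`).
#'
#' @inheritParams count_spores
#' @return A data frame with one row per spore: `image_name`, `spore_id`,
#'   `area`, `length`, `width`, `circularity` (zero rows for an empty
#'   image). The full component records are attached as attribute
#'   `"components"`.
#' @export
measure_spores <- function(img, params, image_name = "image") {
  stopifnot(inherits(params, "calibration_params"))
  bw <- hysteresis_binarize(img, params$b1, params$b2)
  recs <- label_and_measure(bw, params$scale)
  kept <- filter_components(recs, params)
  out <- data.frame(image_name = rep(image_name, nrow(kept)),
                    spore_id = seq_len(nrow(kept)),
                    area = kept$area, length = kept$length,
                    width = kept$width, circularity = kept$circularity)
  attr(out, "components") <- kept
  attr(out, "binary") <- bw
  out
}

#' Extrapolate a droplet count to a full dish
#'
#' Scales the number of spores counted in an imaged droplet to the whole
#' suspension: `n_droplet * suspension_volume / droplet_volume`, rounded to
#' the nearest integer. For example, 848 conidia counted in a 5 microliter
#' droplet of a 1 ml (1000 microliter) suspension correspond to 169600
#' conidia per dish.
#'
#' @param n_droplet Spores counted in the droplet.
#' @param droplet_volume Imaged droplet volume (same unit as
#'   `suspension_volume`, conventionally microliters).
#' @param suspension_volume Total suspension volume.
#' @return Integer-valued count.
#' @examples
#' droplet_to_dish(848, 5, 1000)
#' @export
droplet_to_dish <- function(n_droplet, droplet_volume, suspension_volume) {
  if (droplet_volume <= 0 || suspension_volume <= 0)
    stop("volumes must be > 0")
  if (n_droplet < 0) stop("n_droplet must be >= 0")
  round(n_droplet * suspension_volume / droplet_volume)
}

#' Signed percent error of an automated count against a manual count
#'
#' `100 * (n_auto - n_manual) / n_manual`: positive when the automated
#' count detects more objects than were counted manually, negative when it
#' misses objects.
#'
#' @param n_auto Automated count.
#' @param n_manual Manual reference count, `> 0`.
#' @return Signed percentage.
#' @examples
#' percent_error(95, 100)
#' @export
percent_error <- function(n_auto, n_manual) {
  if (any(n_manual <= 0))
    stop("percent error is undefined for a manual count of 0")
  100 * (n_auto - n_manual) / n_manual
}
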