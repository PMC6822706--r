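# Nematode-trap counting.

#' Count nematode-trap structures
#'
#' Adhesive-network traps appear as dense, compact, strongly absorbing
#' structures clearly distinct from the surrounding mycelium. They are
#' selected purely by morphology: the identical inversion, hysteresis
#' segmentation and area/elongation gating used by [count_spores()], run
#' with trap-scale parameters — a large `min_area` excludes single hyphae
#' and the elongation gate excludes straight hyphal runs. The function is a
#' named entry point for workflow clarity; `count_traps(img, p)` and
#' `count_spores(img, p)` are the same computation for any input.
#'
#' @inheritParams count_spores
#' @return A `spore_count` list; `n_spores` is the trap count.
#' @export
count_traps <- function(img, params, image_name = "image") {
  count_spores(img, params, image_name)
}
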