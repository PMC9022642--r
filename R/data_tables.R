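#' Published extreme warp-score pairs for the seven-river study
#'
#' The tabulated per-river extreme warp-score pairs (maximum-score and
#' minimum-score deformation magnitudes on shape PC1 and PC2), together with
#' the published principal score ratios, from a truss-morphometric study of
#' *Chitala chitala* across seven Indian rivers. Used to validate the PSR
#' arithmetic: [psr()] applied to each pair reproduces the published ratio
#' column.
#'
#' @return Data frame with columns `river`, `pc1_max`, `pc1_min`, `pc2_max`,
#'   `pc2_min`, `psr_pc1`, `psr_pc2`.
#' @examples
#' w <- warp_extreme_pairs()
#' all.equal(round(psr(w$pc1_max, w$pc1_min), 2), w$psr_pc1)
#' @export
warp_extreme_pairs <- function() {
  path <- system.file("extdata", "table7_warp_extremes.csv",
                      package = "trussmorph", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
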