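#' Region vocabulary for [11C]WAY100635 quantification
#'
#' Thirteen a-priori regions of interest with abundant 5-HT1A binding plus
#' cerebellar white matter, which is devoid of specific binding and serves
#' as the reference region supplying the non-displaceable volume of
#' distribution (V_ND = K1/k2).
#'
#' @return `roi_regions()` returns the 13 ROI labels; `reference_region()`
#'   the reference label; `all_regions()` both (14 labels).
#' @export
roi_regions <- function() {
  c(
    "raphe nuclei", "anterior cingulate", "cingulate",
    "dorsal prefrontal cortex", "hippocampus", "insula",
    "medial prefrontal cortex", "parietal cortex", "parahippocampal gyrus",
    "occipital cortex", "orbital cortex", "temporal cortex", "amygdala"
  )
}

#' @rdname roi_regions
#' @export
reference_region <- function() "cerebellar white matter"

#' @rdname roi_regions
#' @export
all_regions <- function() c(roi_regions(), reference_region())

#' Regions where recent stress is expected to relate to binding in MDD
#'
#' Default region sets used by the synthetic generator: recent-stress
#' slopes on log BP_F are injected in the amygdala, orbital cortex and
#' insula; -1007 CpG methylation slopes in seven of the thirteen ROIs.
#' @return character vector of region labels
#' @export
stress_effect_regions <- function() c("amygdala", "orbital cortex", "insula")

#' @rdname stress_effect_regions
#' @export
methylation_effect_regions <- function() {
  c(
    "raphe nuclei", "hippocampus", "cingulate", "dorsal prefrontal cortex",
    "medial prefrontal cortex", "orbital cortex", "parietal cortex"
  )
}
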