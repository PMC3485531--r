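#' Canonical 16-segment left-ventricular nomenclature
#'
#' Returns the 16 segment names of the standard (ASE) 16-segment LV model in
#' canonical order: segments 1-6 basal, 7-12 mid-ventricular, 13-16 apical.
#' All curve-set constructors, file readers and reports use exactly this
#' order, so per-segment vectors line up across functions.
#'
#' @return Character vector of length 16.
#' @export
#' @examples
#' lv_segments()
lv_segments <- function() {
  c("basal_anterior", "basal_anteroseptal", "basal_inferoseptal",
    "basal_inferior", "basal_inferolateral", "basal_anterolateral",
    "mid_anterior", "mid_anteroseptal", "mid_inferoseptal",
    "mid_inferior", "mid_inferolateral", "mid_anterolateral",
    "apical_anterior", "apical_septal", "apical_inferior", "apical_lateral")
}

N_SEGMENTS <- 16L
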