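# Desikan-Killiany cortical parcellation: 34 regions per hemisphere.
.dk_regions <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
  "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
  "lateralorbitofrontal", "lingual", "medialorbitofrontal", "middletemporal",
  "paracentral", "parahippocampal", "parsopercularis", "parsorbitalis",
  "parstriangularis", "pericalcarine", "postcentral", "posteriorcingulate",
  "precentral", "precuneus", "rostralanteriorcingulate",
  "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
  "superiortemporal", "supramarginal", "temporalpole", "transversetemporal"
)

.dk_temporal <- c(
  "bankssts", "entorhinal", "fusiform", "inferiortemporal", "middletemporal",
  "parahippocampal", "superiortemporal", "temporalpole", "transversetemporal"
)

.dk_frontal <- c(
  "caudalmiddlefrontal", "frontalpole", "lateralorbitofrontal",
  "medialorbitofrontal", "paracentral", "parsopercularis", "parsorbitalis",
  "parstriangularis", "precentral", "rostralmiddlefrontal", "superiorfrontal"
)

#' Desikan-Killiany ROI column names
#'
#' Returns the fixed, documented ROI order used by every thickness table in
#' the package: the 34 Desikan-Killiany regions, left hemisphere first, as
#' `lh_<region>_thickness` / `rh_<region>_thickness` (68 names).
#'
#' @return character vector of length 68
#' @export
#' @examples
#' head(dk_roi_names())
dk_roi_names <- function() {
  c(paste0("lh_", .dk_regions, "_thickness"),
    paste0("rh_", .dk_regions, "_thickness"))
}

#' Indices of a named lobe's ROIs (both hemispheres)
#'
#' @param lobe one of "temporal", "frontal", "all"
#' @return integer indices into [dk_roi_names()]
#' @export
dk_lobe_index <- function(lobe = c("temporal", "frontal", "all")) {
  lobe <- match.arg(lobe)
  if (lobe == "all") return(seq_along(dk_roi_names()))
  regions <- switch(lobe, temporal = .dk_temporal, frontal = .dk_frontal)
  which(sub("^(lh|rh)_(.*)_thickness$", "\\2", dk_roi_names()) %in% regions)
}
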