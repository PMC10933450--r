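# Default ROI vocabulary. Laterality is encoded by Left_/Right_ prefixes so
# the generator, the modelling subset and the lobe merge map agree.

subcortical_structures <- c("Hippocampus", "Amygdala", "Caudate", "Putamen",
                            "Pallidum", "Thalamus")

cortical_structures <- c(
  "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus", "entorhinal",
  "fusiform", "inferiorparietal", "inferiortemporal", "insula",
  "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
  "medialorbitofrontal", "middletemporal", "paracentral", "parahippocampal",
  "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
  "postcentral", "posteriorcingulate", "precentral", "precuneus",
  "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
  "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
  "transversetemporal")

bilateral <- function(x) as.vector(t(outer(c("Left_", "Right_"), x, paste0)))

#' Default regional vocabulary of the synthetic cohort
#'
#' 12 subcortical gray-matter volumes (mm^3) and 64 cortical thickness
#' regions (mm), all bilateral, 76 regions in total.
#'
#' @return Character vector of ROI names.
#' @export
default_roi_set <- function() {
  c(bilateral(subcortical_structures), bilateral(cortical_structures))
}

#' Default 23-region modelling subset
#'
#' The progression model is fitted on a reduced gray-matter subset:
#' bilateral hippocampus and thalamus plus 19 cortical regions repeatedly
#' implicated in mesial temporal lobe epilepsy. The amygdala is deliberately
#' excluded so that amygdala enlargement stays visible to the
#' characterization step without entering the trajectory model.
#'
#' @return Character vector of 23 ROI names.
#' @export
default_modeling_rois <- function() {
  c(bilateral(c("Hippocampus", "Thalamus")),
    bilateral(c("superiorfrontal", "caudalmiddlefrontal", "precentral",
                "entorhinal", "fusiform", "temporalpole",
                "precuneus", "paracentral", "lateraloccipital")),
    "Left_insula")
}

#' Default lobe merge map (23 features to 13)
#'
#' Down-samples the 23-region modelling subset by averaging cortical
#' regions within the same lobe and hemisphere; subcortical structures stay
#' as singletons.
#'
#' @return Named list mapping group name to member ROI names.
#' @export
default_lobe_map <- function() {
  list(
    Left_Hippocampus  = "Left_Hippocampus",
    Right_Hippocampus = "Right_Hippocampus",
    Left_Thalamus     = "Left_Thalamus",
    Right_Thalamus    = "Right_Thalamus",
    Left_frontal  = paste0("Left_",  c("superiorfrontal",
                                       "caudalmiddlefrontal", "precentral")),
    Right_frontal = paste0("Right_", c("superiorfrontal",
                                       "caudalmiddlefrontal", "precentral")),
    Left_temporal  = paste0("Left_",  c("entorhinal", "fusiform",
                                        "temporalpole")),
    Right_temporal = paste0("Right_", c("entorhinal", "fusiform",
                                        "temporalpole")),
    Left_parietal  = paste0("Left_",  c("precuneus", "paracentral")),
    Right_parietal = paste0("Right_", c("precuneus", "paracentral")),
    Left_occipital  = "Left_lateraloccipital",
    Right_occipital = "Right_lateraloccipital",
    Left_insula = "Left_insula")
}

is_volume_roi <- function(roi) {
  sub("^(Left|Right)_", "", roi) %in% subcortical_structures
}
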