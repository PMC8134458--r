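#' AAL-90 region labels
#'
#' Names of the 90 cortical and subcortical regions of the automated
#' anatomical labeling (AAL) parcellation, in the conventional index order
#' (odd = left hemisphere, even = right). These are the node labels of every
#' similarity matrix built by the package.
#'
#' @param n_regions Number of regions requested. For `n_regions = 90` the AAL
#'   names are returned; for any other count, generic `region_<i>` labels.
#' @return Character vector of length `n_regions`.
#' @export
aal90_labels <- function(n_regions = 90L) {
  base <- c(
    "Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
    "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
    "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area", "Olfactory",
    "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus", "Insula",
    "Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post", "Hippocampus",
    "ParaHippocampal", "Amygdala", "Calcarine", "Cuneus", "Lingual",
    "Occipital_Sup", "Occipital_Mid", "Occipital_Inf", "Fusiform",
    "Postcentral", "Parietal_Sup", "Parietal_Inf", "SupraMarginal",
    "Angular", "Precuneus", "Paracentral_Lobule", "Caudate", "Putamen",
    "Pallidum", "Thalamus", "Heschl", "Temporal_Sup", "Temporal_Pole_Sup",
    "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf")
  if (n_regions == 90L) {
    paste0(rep(base, each = 2L), c("_L", "_R"))
  } else {
    sprintf("region_%03d", seq_len(n_regions))
  }
}
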