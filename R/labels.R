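# Bundled region label list, Harvard-Oxford style: 48 bilateral cortical and
# 8 bilateral subcortical parcels, interleaved left/right so that regions
# (2k - 1, 2k) form a homotopic pair. For other region counts a generic
# interleaved label set is produced with the same pairing convention.

ho_base_names <- c(
  "Frontal Pole", "Insular Cortex", "Superior Frontal Gyrus",
  "Middle Frontal Gyrus", "Inferior Frontal Gyrus, pars triangularis",
  "Inferior Frontal Gyrus, pars opercularis", "Precentral Gyrus",
  "Temporal Pole", "Superior Temporal Gyrus, anterior",
  "Superior Temporal Gyrus, posterior", "Middle Temporal Gyrus, anterior",
  "Middle Temporal Gyrus, posterior", "Middle Temporal Gyrus, temporooccipital",
  "Inferior Temporal Gyrus, anterior", "Inferior Temporal Gyrus, posterior",
  "Inferior Temporal Gyrus, temporooccipital", "Postcentral Gyrus",
  "Superior Parietal Lobule", "Supramarginal Gyrus, anterior",
  "Supramarginal Gyrus, posterior", "Angular Gyrus",
  "Lateral Occipital Cortex, superior", "Lateral Occipital Cortex, inferior",
  "Intracalcarine Cortex", "Frontal Medial Cortex",
  "Juxtapositional Lobule Cortex", "Subcallosal Cortex", "Paracingulate Gyrus",
  "Cingulate Gyrus, anterior", "Cingulate Gyrus, posterior",
  "Precuneous Cortex", "Cuneal Cortex", "Frontal Orbital Cortex",
  "Parahippocampal Gyrus, anterior", "Parahippocampal Gyrus, posterior",
  "Lingual Gyrus", "Temporal Fusiform Cortex, anterior",
  "Temporal Fusiform Cortex, posterior", "Temporal Occipital Fusiform Cortex",
  "Occipital Fusiform Gyrus", "Frontal Operculum Cortex",
  "Central Opercular Cortex", "Parietal Operculum Cortex", "Planum Polare",
  "Heschl's Gyrus", "Planum Temporale", "Supracalcarine Cortex",
  "Occipital Pole", "Thalamus", "Caudate", "Putamen", "Pallidum",
  "Hippocampus", "Amygdala", "Accumbens", "Cerebellum"
)

#' Region labels for the bundled parcellation
#'
#' Returns region labels for an `n_regions`-parcel atlas with left/right
#' counterparts interleaved: region `2k - 1` is the left and region `2k` the
#' right member of homotopic pair `k`. For the default 112 regions the labels
#' are a Harvard-Oxford-style list of 48 cortical and 8 subcortical bilateral
#' parcels; other even counts get generic interleaved labels.
#'
#' @param n_regions Number of regions (default 112).
#' @return Character vector of length `n_regions`.
#' @examples
#' head(region_labels(112), 4)
#' @export
region_labels <- function(n_regions = 112L) {
  n_regions <- check_count(n_regions, "n_regions", min = 1L)
  if (n_regions == 112L) {
    return(as.vector(rbind(paste("L", ho_base_names), paste("R", ho_base_names))))
  }
  n_pairs <- ceiling(n_regions / 2)
  generic <- as.vector(rbind(sprintf("L Region %02d", seq_len(n_pairs)),
                             sprintf("R Region %02d", seq_len(n_pairs))))
  generic[seq_len(n_regions)]
}

# Index of the homotopic partner of each region under the interleaving
# convention (1 <-> 2, 3 <-> 4, ...). The last region of an odd-sized atlas
# has no partner (NA).
homotopic_partner <- function(n_regions) {
  idx <- seq_len(n_regions)
  partner <- ifelse(idx %% 2 == 1L, idx + 1L, idx - 1L)
  partner[partner > n_regions] <- NA_integer_
  partner
}
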