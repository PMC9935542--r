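#' Default 106-region parcellation label table
#'
#' A synthetic emulation of the 106-region cortical + subcortical
#' parcellation used for ROI-to-ROI connectivity analyses (the
#' Harvard-Oxford-style atlas of the Conn toolbox): 48 bilateral cortical
#' structures and 5 bilateral subcortical structures, 106 labels in total.
#' Region names follow the conventional Harvard-Oxford nomenclature so that
#' the a-priori region sets used throughout the package (striato-pallido-
#' thalamic, auditory-sensory-motor, superior-temporal, temporo-occipital)
#' resolve against it.
#'
#' @return A data.frame with columns \code{label} (integer 1..106),
#'   \code{name} (unique region name, e.g. "Cuneal Cortex l"),
#'   \code{hemisphere} ("l"/"r") and \code{structure} (bilateral structure
#'   name without hemisphere suffix).
#' @export
default_region_table <- function() {
  cortical <- c(
    "Frontal Pole", "Insular Cortex", "Superior Frontal Gyrus",
    "Middle Frontal Gyrus", "Inferior Frontal Gyrus pars triangularis",
    "Inferior Frontal Gyrus pars opercularis", "Precentral Gyrus",
    "Temporal Pole", "Anterior Superior Temporal Gyrus",
    "Posterior Superior Temporal Gyrus", "Anterior Middle Temporal Gyrus",
    "Posterior Middle Temporal Gyrus",
    "Temporooccipital Middle Temporal Gyrus",
    "Anterior Inferior Temporal Gyrus",
    "Posterior Inferior Temporal Gyrus",
    "Temporooccipital Inferior Temporal Gyrus", "Postcentral Gyrus",
    "Superior Parietal Lobule", "Anterior Supramarginal Gyrus",
    "Posterior Supramarginal Gyrus", "Angular Gyrus",
    "Superior Lateral Occipital Cortex",
    "Inferior Lateral Occipital Cortex", "Intracalcarine Cortex",
    "Frontal Medial Cortex", "Juxtapositional Lobule Cortex",
    "Subcallosal Cortex", "Paracingulate Gyrus", "Anterior Cingulate Gyrus",
    "Posterior Cingulate Gyrus", "Precuneous Cortex", "Cuneal Cortex",
    "Frontal Orbital Cortex", "Anterior Parahippocampal Gyrus",
    "Posterior Parahippocampal Gyrus", "Lingual Gyrus",
    "Anterior Temporal Fusiform Cortex",
    "Posterior Temporal Fusiform Cortex",
    "Temporal Occipital Fusiform Cortex", "Occipital Fusiform Gyrus",
    "Frontal Operculum Cortex", "Central Opercular Cortex",
    "Parietal Operculum Cortex", "Planum Polare", "Heschl's Gyrus",
    "Planum Temporale", "Supracalcarine Cortex", "Occipital Pole")
  subcortical <- c("Caudate", "Putamen", "Pallidum", "Thalamus",
                   "Hippocampus")
  base <- c(cortical, subcortical)
  data.frame(
    label = seq_len(2L * length(base)),
    name = paste(rep(base, each = 2L), rep(c("l", "r"), length(base))),
    hemisphere = rep(c("l", "r"), times = length(base)),
    structure = rep(base, each = 2L),
    stringsAsFactors = FALSE)
}

#' Resolve bilateral structure names to region labels
#'
#' @param structures character vector of bilateral structure names
#'   (e.g. "Caudate").
#' @param region_table region table, see [default_region_table()].
#' @param hemispheres hemispheres to include.
#' @return character vector of region names.
#' @export
resolve_regions <- function(structures, region_table = default_region_table(),
                            hemispheres = c("l", "r")) {
  missing <- setdiff(structures, region_table$structure)
  if (length(missing) > 0L) {
    stop("unknown structure(s): ", paste(missing, collapse = ", "))
  }
  keep <- region_table$structure %in% structures &
    region_table$hemisphere %in% hemispheres
  region_table$name[keep]
}

#' Define a named region set (network)
#'
#' @param name network name.
#' @param regions character vector of region names.
#' @param source how the network was defined.
#' @param region_table table the regions must resolve against (NULL skips
#'   validation).
#' @return An object of class \code{network_def}.
#' @export
network_def <- function(name, regions,
                        source = c("a_priori", "clustered"),
                        region_table = default_region_table()) {
  source <- match.arg(source)
  if (length(regions) == 0L) stop("network '", name, "' is empty")
  if (!is.null(region_table)) {
    bad <- setdiff(regions, region_table$name)
    if (length(bad) > 0L) {
      stop("network '", name, "' has unknown region(s): ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(name = name, regions = unique(regions), source = source),
            class = "network_def")
}

#' A-priori region sets used in the network-level analyses
#'
#' The striato-pallido-thalamic (SPT) set covers caudate, putamen, pallidum
#' and thalamus bilaterally; the auditory-sensory-motor (ASM) set covers
#' Heschl's gyrus, planum temporale, posterior superior temporal gyrus,
#' pre- and postcentral gyri, insular and central opercular cortex
#' bilaterally. The superior-temporal (STG) and temporo-occipital sets
#' support the auditory-visual hypo-connectivity analyses.
#'
#' @param region_table region table to resolve against.
#' @return Named list of [network_def()] objects: \code{spt}, \code{asm},
#'   \code{stg}, \code{temporo_occipital}.
#' @export
default_networks <- function(region_table = default_region_table()) {
  list(
    spt = network_def(
      "striato-pallido-thalamic",
      resolve_regions(c("Caudate", "Putamen", "Pallidum", "Thalamus"),
                      region_table),
      region_table = region_table),
    asm = network_def(
      "auditory-sensory-motor",
      resolve_regions(c("Heschl's Gyrus", "Planum Temporale",
                        "Posterior Superior Temporal Gyrus",
                        "Precentral Gyrus", "Postcentral Gyrus",
                        "Insular Cortex", "Central Opercular Cortex"),
                      region_table),
      region_table = region_table),
    stg = network_def(
      "superior-temporal",
      resolve_regions(c("Anterior Superior Temporal Gyrus",
                        "Posterior Superior Temporal Gyrus"),
                      region_table),
      region_table = region_table),
    temporo_occipital = network_def(
      "temporo-occipital",
      resolve_regions(c("Inferior Lateral Occipital Cortex",
                        "Occipital Fusiform Gyrus",
                        "Temporal Occipital Fusiform Cortex"),
                      region_table),
      region_table = region_table))
}
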