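#' Construct a region atlas
#'
#' A region atlas fixes the node ordering of every downstream matrix: region
#' `i` of the thickness table is node `i` of the network. The bundled
#' Destrieux parcellation ([load_destrieux_atlas()]) is the default; small
#' custom atlases are useful for simulation studies.
#'
#' @param region_id character vector of unique region labels.
#' @param hemisphere `"left"` or `"right"` per region.
#' @return A data.frame of class `region_atlas` with columns `region_id`,
#'   `hemisphere` and the 0-based node `index`.
#' @export
region_atlas <- function(region_id, hemisphere) {
  region_id <- as.character(region_id)
  hemisphere <- as.character(hemisphere)
  if (length(region_id) < 1) stop("atlas must contain at least one region")
  if (length(hemisphere) != length(region_id))
    stop("'hemisphere' must have one entry per region")
  if (anyDuplicated(region_id))
    stop("duplicated region_id: ", region_id[duplicated(region_id)][1])
  if (!all(hemisphere %in% c("left", "right")))
    stop("hemisphere must be 'left' or 'right'")
  out <- data.frame(region_id = region_id, hemisphere = hemisphere,
                    index = seq_along(region_id) - 1L,
                    stringsAsFactors = FALSE)
  class(out) <- c("region_atlas", "data.frame")
  out
}

#' Load the bundled Destrieux cortical atlas
#'
#' The Destrieux sulco-gyral parcellation divides the cortical surface into
#' 148 regions, 74 per hemisphere. The bundled list (FreeSurfer
#' `aparc.a2009s` naming, `lh_`/`rh_` prefixes) defines the canonical node
#' ordering used throughout the package: left hemisphere first, then right,
#' each in anatomical label order.
#'
#' @return A `region_atlas` with 148 rows.
#' @export
load_destrieux_atlas <- function() {
  path <- system.file("extdata", "destrieux_148.tsv", package = "scnet")
  if (!nzchar(path) || !file.exists(path))
    stop("bundled Destrieux atlas file not found")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("region_id", "hemisphere") %in% names(df)))
    stop("bundled Destrieux atlas file is corrupted: missing columns")
  atlas <- region_atlas(df$region_id, df$hemisphere)
  if (nrow(atlas) != 148 || sum(atlas$hemisphere == "left") != 74)
    stop("bundled Destrieux atlas file is corrupted: wrong region counts")
  atlas
}
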