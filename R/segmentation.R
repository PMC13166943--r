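#' Segment nuclei from the nuclear-stain channel
#'
#' Thresholds the DAPI channel (Otsu by default, or a fixed cutoff), fills
#' interior holes, removes components smaller than
#' \code{minNucleusAreaUm2}, and optionally splits touching nuclei by
#' distance-transform watershed. The returned count is the number of
#' retained components under the configured connectivity.
#'
#' @param stack a [ChannelStack-class] with a \code{nuclear_stain} channel.
#' @param params a [SegmentationParams-class].
#' @return list with \code{mask} (logical), \code{count} (integer) and
#'   \code{labels} (integer matrix).
#' @examples
#' sc <- generateScene(sceneSpec(nCells = 4, seed = 1))
#' seg <- segmentNuclei(sc$stack, segmentationParams())
#' seg$count
#' @export
segmentNuclei <- function(stack, params = segmentationParams()) {
  if (!hasChannel(stack, "nuclear_stain"))
    stopf("field '%s' has no nuclear_stain channel", fieldId(stack))
  ch <- getChannel(stack, "nuclear_stain")
  thr <- switch(params@nuclearThresholdMethod,
                otsu = otsuThreshold(ch),
                fixed = params@nuclearFixedThreshold)
  mask <- ch > thr
  mask <- fillHoles(mask, params@connectivity)
  lab <- labelComponents(mask, params@connectivity)
  if (lab$count > 0) {
    pxArea <- pixelSize(stack)^2
    areas <- tabulate(lab$labels[lab$labels > 0], lab$count) * pxArea
    keep <- which(areas >= params@minNucleusAreaUm2)
    mask <- matrix(lab$labels %in% keep, nrow(mask), ncol(mask))
    lab <- labelComponents(mask, params@connectivity)
  }
  if (params@splitTouchingNuclei && lab$count > 0)
    lab <- watershedSplit(mask, params@connectivity)
  list(mask = mask, count = as.integer(lab$count), labels = lab$labels)
}

#' Segment the plasma membrane from the membrane-marker channel
#'
#' Na+/K+-ATPase staining outlines the plasma membrane; the mask is the
#' set of membrane-marker-positive pixels under the configured threshold.
#' No morphological post-processing is applied: the %MAP endpoints are
#' ratios within this mask, so its exact morphology cancels to first
#' order.
#'
#' @param stack a [ChannelStack-class] with a \code{membrane_marker}
#'   channel.
#' @param params a [SegmentationParams-class].
#' @param threshold a [PositivityThreshold-class] for the membrane marker;
#'   required when the method is \code{"control_derived"}.
#' @return logical membrane mask.
#' @export
segmentMembrane <- function(stack, params = segmentationParams(),
                            threshold = NULL) {
  if (!hasChannel(stack, "membrane_marker"))
    stopf("field '%s' has no membrane_marker channel", fieldId(stack))
  ch <- getChannel(stack, "membrane_marker")
  thr <- switch(params@membraneThresholdMethod,
    otsu = otsuThreshold(ch),
    fixed = params@membraneFixedThreshold,
    control_derived = {
      if (is.null(threshold))
        stopf("control_derived membrane segmentation needs a PositivityThreshold")
      cutoff(threshold)
    })
  ch > thr
}

#' Build the tissue mask (denominator for area-per-cell)
#'
#' Default definition: the nuclear mask dilated by
#' \code{params@tissueDilationUm} (approximating the cytoplasmic extent
#' around each nucleus), unioned with the membrane mask. Always a superset
#' of the nuclear mask.
#'
#' @param stack a [ChannelStack-class].
#' @param params a [SegmentationParams-class].
#' @param nuclearMask optional precomputed nuclear mask (recomputed via
#'   [segmentNuclei()] when NULL).
#' @param membraneMask optional precomputed membrane mask (NULL = none).
#' @return logical tissue mask.
#' @export
buildTissueMask <- function(stack, params = segmentationParams(),
                            nuclearMask = NULL, membraneMask = NULL) {
  if (is.null(nuclearMask)) nuclearMask <- segmentNuclei(stack, params)$mask
  rPx <- params@tissueDilationUm / pixelSize(stack)
  tissue <- dilateDisk(nuclearMask, rPx)
  if (!is.null(membraneMask)) tissue <- tissue | membraneMask
  tissue
}

#' Run the full compartment segmentation for one field
#'
#' Convenience wrapper producing a [CompartmentMasks-class] from a
#' [ChannelStack-class]: nuclei ([segmentNuclei()]), plasma membrane
#' ([segmentMembrane()]) and tissue ([buildTissueMask()]).
#'
#' @inheritParams segmentMembrane
#' @param membraneThreshold optional [PositivityThreshold-class] for
#'   control-derived membrane segmentation.
#' @return a [CompartmentMasks-class].
#' @export
segmentCompartments <- function(stack, params = segmentationParams(),
                                membraneThreshold = NULL) {
  nuc <- segmentNuclei(stack, params)
  mem <- segmentMembrane(stack, params, membraneThreshold)
  tis <- buildTissueMask(stack, params, nuclearMask = nuc$mask,
                         membraneMask = mem)
  new("CompartmentMasks", nuclear = nuc$mask, membrane = mem, tissue = tis,
      nucleusCount = nuc$count, fieldId = fieldId(stack))
}
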