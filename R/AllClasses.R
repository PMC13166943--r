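#' @import methods
NULL

#' Recognized channel roles
#'
#' The four-plex design carries a nuclear counterstain (DAPI), a plasma
#' membrane marker (Na+/K+-ATPase alpha-1), total MET, and
#' Y1235-phosphorylated MET; an optional isotype-control channel carries
#' background staining for threshold derivation.
#'
#' @return character vector of valid channel-role names.
#' @export
channelRoles <- function() {
  c("nuclear_stain", "membrane_marker", "total_met", "phospho_met",
    "isotype_control")
}

#' ChannelStack: one registered multichannel image field
#'
#' Holds one microscopy field as a named list of 2-D intensity rasters
#' (numeric matrices, row-major with row 1 / column 1 at top-left), the
#' physical pixel size, and the acquisition bit depth. All rasters share
#' the same dimensions and channels are addressed by role, never by the
#' channel order of the source file.
#'
#' @slot fieldId character field identifier.
#' @slot channels named list of numeric matrices; names are channel roles.
#' @slot pixelSizeUm edge length of one pixel in micrometres.
#' @slot bitDepth integer, 8 or 16 (unsigned).
#'
#' @seealso [readMultichannelImage()], [generateScene()]
#' @export
setClass("ChannelStack",
  representation(fieldId = "character", channels = "list",
                 pixelSizeUm = "numeric", bitDepth = "integer"),
  prototype(fieldId = "field", channels = list(), pixelSizeUm = 0.5,
            bitDepth = 16L))

setValidity("ChannelStack", function(object) {
  ch <- object@channels
  if (length(ch) == 0) return("ChannelStack must contain at least one channel")
  rn <- names(ch)
  if (is.null(rn) || any(!nzchar(rn))) return("channels must be named by role")
  if (anyDuplicated(rn)) return("channel roles must be unique")
  bad <- setdiff(rn, channelRoles())
  if (length(bad))
    return(paste0("unknown channel role(s): ", paste(bad, collapse = ", ")))
  if (!all(vapply(ch, is.matrix, logical(1))))
    return("every channel must be a matrix")
  dims <- vapply(ch, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    return("all channel rasters must have identical dimensions")
  if (any(vapply(ch, function(m) any(m < 0), logical(1))))
    return("intensities must be non-negative")
  if (length(object@pixelSizeUm) != 1 || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    return("pixelSizeUm must be a single positive number")
  if (!object@bitDepth %in% c(8L, 16L))
    return("bitDepth must be 8 or 16")
  TRUE
})

#' Construct a ChannelStack
#'
#' @param channels named list of numeric matrices (names drawn from
#'   [channelRoles()]).
#' @param pixelSizeUm pixel edge length in micrometres (> 0).
#' @param fieldId field identifier.
#' @param bitDepth 8 or 16.
#' @return a validated [ChannelStack-class] object.
#' @examples
#' m <- matrix(0, 8, 8)
#' s <- channelStack(list(nuclear_stain = m), pixelSizeUm = 0.5)
#' dim(s)
#' @export
channelStack <- function(channels, pixelSizeUm, fieldId = "field",
                         bitDepth = 16L) {
  new("ChannelStack", fieldId = fieldId, channels = channels,
      pixelSizeUm = as.numeric(pixelSizeUm), bitDepth = as.integer(bitDepth))
}

#' @describeIn ChannelStack height and width of the field
#' @param x a ChannelStack.
#' @export
setMethod("dim", "ChannelStack", function(x) dim(x@channels[[1]]))

#' Accessors for ChannelStack
#'
#' @param x a [ChannelStack-class].
#' @param role a channel role name.
#' @return \code{getChannel} returns the intensity matrix for \code{role};
#'   \code{hasChannel} a logical; \code{pixelSize} the pixel edge in um;
#'   \code{fieldId} the field identifier; \code{stackRoles} the roles present.
#' @name ChannelStack-accessors
NULL

#' @rdname ChannelStack-accessors
#' @export
setGeneric("getChannel", function(x, role) standardGeneric("getChannel"))

#' @rdname ChannelStack-accessors
#' @export
setMethod("getChannel", "ChannelStack", function(x, role) {
  if (!role %in% names(x@channels))
    stopf("channel role '%s' is not present in field '%s'", role, x@fieldId)
  x@channels[[role]]
})

#' @rdname ChannelStack-accessors
#' @export
setGeneric("hasChannel", function(x, role) standardGeneric("hasChannel"))

#' @rdname ChannelStack-accessors
#' @export
setMethod("hasChannel", "ChannelStack",
          function(x, role) role %in% names(x@channels))

#' @rdname ChannelStack-accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname ChannelStack-accessors
#' @export
setMethod("pixelSize", "ChannelStack", function(x) x@pixelSizeUm)

#' @rdname ChannelStack-accessors
#' @export
setGeneric("fieldId", function(x) standardGeneric("fieldId"))

#' @rdname ChannelStack-accessors
#' @export
setMethod("fieldId", "ChannelStack", function(x) x@fieldId)

#' @rdname ChannelStack-accessors
#' @export
setGeneric("stackRoles", function(x) standardGeneric("stackRoles"))

#' @rdname ChannelStack-accessors
#' @export
setMethod("stackRoles", "ChannelStack", function(x) names(x@channels))

setMethod("show", "ChannelStack", function(object) {
  d <- dim(object)
  cat(sprintf("ChannelStack '%s': %d x %d px (%.3g um/px, %d-bit)\n",
              object@fieldId, d[1], d[2], object@pixelSizeUm,
              object@bitDepth))
  cat("  channels:", paste(names(object@channels), collapse = ", "), "\n")
})

#' CompartmentMasks: nuclear, membrane and tissue masks for one field
#'
#' Binary compartment masks produced by the segmentation stage, sharing the
#' source field's raster geometry, plus the number of retained nuclei.
#' The nuclear mask is always a subset of the tissue mask.
#'
#' @slot nuclear,membrane,tissue logical matrices.
#' @slot nucleusCount number of retained nuclear connected components.
#' @slot fieldId character field identifier.
#' @seealso [segmentCompartments()]
#' @export
setClass("CompartmentMasks",
  representation(nuclear = "matrix", membrane = "matrix", tissue = "matrix",
                 nucleusCount = "integer", fieldId = "character"))

setValidity("CompartmentMasks", function(object) {
  ms <- list(object@nuclear, object@membrane, object@tissue)
  if (!all(vapply(ms, is.logical, logical(1))))
    return("masks must be logical matrices")
  dims <- vapply(ms, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    return("all masks must share the same dimensions")
  if (object@nucleusCount < 0) return("nucleusCount must be >= 0")
  if (any(object@nuclear & !object@tissue))
    return("nuclear mask must be a subset of the tissue mask")
  TRUE
})

setMethod("show", "CompartmentMasks", function(object) {
  cat(sprintf("CompartmentMasks '%s': %d nuclei; nuclear %d px, membrane %d px, tissue %d px\n",
              object@fieldId, object@nucleusCount, sum(object@nuclear),
              sum(object@membrane), sum(object@tissue)))
})

#' @rdname CompartmentMasks-class
#' @param x a CompartmentMasks object.
#' @export
setGeneric("nucleusCount", function(x) standardGeneric("nucleusCount"))

#' @rdname CompartmentMasks-class
#' @export
setMethod("nucleusCount", "CompartmentMasks", function(x) x@nucleusCount)

#' @rdname CompartmentMasks-class
#' @param which one of \code{"nuclear"}, \code{"membrane"}, \code{"tissue"}.
#' @export
setGeneric("maskOf", function(x, which) standardGeneric("maskOf"))

#' @rdname CompartmentMasks-class
#' @export
setMethod("maskOf", "CompartmentMasks", function(x, which) {
  switch(match.arg(which, c("nuclear", "membrane", "tissue")),
         nuclear = x@nuclear, membrane = x@membrane, tissue = x@tissue)
})

#' PositivityThreshold: a per-marker intensity cutoff with provenance
#'
#' A pixel is called positive when its intensity is strictly greater than
#' \code{cutoff}. The slot \code{method} records how the cutoff was derived
#' (\code{mean_plus_k_sd} or \code{percentile} from control pixels, or
#' \code{fixed}); \code{parameter} holds k or the percentile;
#' \code{controlId} identifies the control specimen.
#'
#' @slot marker channel role the cutoff applies to.
#' @slot cutoff intensity cutoff (>= 0).
#' @slot method one of \code{"mean_plus_k_sd"}, \code{"percentile"},
#'   \code{"fixed"}.
#' @slot parameter numeric method parameter.
#' @slot controlId character provenance label.
#' @seealso [deriveThreshold()], [applyThreshold()]
#' @export
setClass("PositivityThreshold",
  representation(marker = "character", cutoff = "numeric",
                 method = "character", parameter = "numeric",
                 controlId = "character"))

setValidity("PositivityThreshold", function(object) {
  if (!object@marker %in% channelRoles()) return("unknown marker role")
  if (!is.finite(object@cutoff) || object@cutoff < 0)
    return("cutoff must be finite and >= 0")
  if (!object@method %in% c("mean_plus_k_sd", "percentile", "fixed"))
    return("method must be mean_plus_k_sd, percentile or fixed")
  if (object@method == "percentile" &&
      (object@parameter <= 0 || object@parameter > 100))
    return("percentile parameter must be in (0, 100]")
  if (object@method == "mean_plus_k_sd" && object@parameter < 0)
    return("k must be >= 0")
  TRUE
})

setMethod("show", "PositivityThreshold", function(object) {
  cat(sprintf("PositivityThreshold: %s > %.6g  [%s, parameter %.4g, control '%s']\n",
              object@marker, object@cutoff, object@method, object@parameter,
              object@controlId))
})

#' @rdname PositivityThreshold-class
#' @param x a PositivityThreshold.
#' @export
setGeneric("cutoff", function(x) standardGeneric("cutoff"))

#' @rdname PositivityThreshold-class
#' @export
setMethod("cutoff", "PositivityThreshold", function(x) x@cutoff)

#' SegmentationParams: tunables of the compartment segmentation stage
#'
#' @slot nuclearThresholdMethod \code{"otsu"} (default) or \code{"fixed"}.
#' @slot nuclearFixedThreshold intensity used when the nuclear method is
#'   \code{"fixed"} (NA otherwise).
#' @slot minNucleusAreaUm2 nuclei smaller than this are rejected as debris
#'   (default 10 um^2).
#' @slot splitTouchingNuclei logical; distance-transform watershed splitting
#'   of touching nuclei (default FALSE).
#' @slot membraneThresholdMethod \code{"otsu"}, \code{"fixed"} or
#'   \code{"control_derived"}.
#' @slot membraneFixedThreshold intensity for the fixed membrane method.
#' @slot connectivity 4 or 8 (default 8) for nuclear component labeling.
#' @slot tissueDilationUm radius in um by which the nuclear mask is dilated
#'   when building the tissue mask (default 5 um).
#' @seealso [segmentNuclei()], [segmentMembrane()], [buildTissueMask()]
#' @export
setClass("SegmentationParams",
  representation(nuclearThresholdMethod = "character",
                 nuclearFixedThreshold = "numeric",
                 minNucleusAreaUm2 = "numeric",
                 splitTouchingNuclei = "logical",
                 membraneThresholdMethod = "character",
                 membraneFixedThreshold = "numeric",
                 connectivity = "integer",
                 tissueDilationUm = "numeric"),
  prototype(nuclearThresholdMethod = "otsu", nuclearFixedThreshold = NA_real_,
            minNucleusAreaUm2 = 10, splitTouchingNuclei = FALSE,
            membraneThresholdMethod = "otsu",
            membraneFixedThreshold = NA_real_, connectivity = 8L,
            tissueDilationUm = 5))

setValidity("SegmentationParams", function(object) {
  if (!object@nuclearThresholdMethod %in% c("otsu", "fixed"))
    return("nuclearThresholdMethod must be otsu or fixed")
  if (object@nuclearThresholdMethod == "fixed" &&
      !is.finite(object@nuclearFixedThreshold))
    return("nuclearFixedThreshold required when nuclear method is fixed")
  if (!object@membraneThresholdMethod %in%
      c("otsu", "fixed", "control_derived"))
    return("membraneThresholdMethod must be otsu, fixed or control_derived")
  if (object@membraneThresholdMethod == "fixed" &&
      !is.finite(object@membraneFixedThreshold))
    return("membraneFixedThreshold required when membrane method is fixed")
  if (object@minNucleusAreaUm2 < 0) return("minNucleusAreaUm2 must be >= 0")
  if (!object@connectivity %in% c(4L, 8L))
    return("connectivity must be 4 or 8")
  if (object@tissueDilationUm < 0) return("tissueDilationUm must be >= 0")
  TRUE
})

#' Construct segmentation parameters
#'
#' @param nuclearThresholdMethod "otsu" or "fixed".
#' @param nuclearFixedThreshold intensity (fixed nuclear method only).
#' @param minNucleusAreaUm2 minimum retained nucleus area in um^2.
#' @param splitTouchingNuclei enable watershed declumping.
#' @param membraneThresholdMethod "otsu", "fixed" or "control_derived".
#' @param membraneFixedThreshold intensity (fixed membrane method only).
#' @param connectivity 4 or 8.
#' @param tissueDilationUm tissue-mask dilation radius in um.
#' @return a validated [SegmentationParams-class].
#' @export
segmentationParams <- function(nuclearThresholdMethod = "otsu",
                               nuclearFixedThreshold = NA_real_,
                               minNucleusAreaUm2 = 10,
                               splitTouchingNuclei = FALSE,
                               membraneThresholdMethod = "otsu",
                               membraneFixedThreshold = NA_real_,
                               connectivity = 8L,
                               tissueDilationUm = 5) {
  new("SegmentationParams",
      nuclearThresholdMethod = nuclearThresholdMethod,
      nuclearFixedThreshold = as.numeric(nuclearFixedThreshold),
      minNucleusAreaUm2 = as.numeric(minNucleusAreaUm2),
      splitTouchingNuclei = isTRUE(splitTouchingNuclei),
      membraneThresholdMethod = membraneThresholdMethod,
      membraneFixedThreshold = as.numeric(membraneFixedThreshold),
      connectivity = as.integer(connectivity),
      tissueDilationUm = as.numeric(tissueDilationUm))
}

#' GroupComparison: an unpaired Mann-Whitney comparison of two groups
#'
#' @slot groupA,groupB group labels.
#' @slot nA,nB group sizes.
#' @slot uStatistic Mann-Whitney U of group A (0 <= U <= nA*nB).
#' @slot pValue two-sided p-value.
#' @slot method \code{"exact"} (full null enumeration) or
#'   \code{"normal_approx"} (tie-corrected normal approximation).
#' @seealso [mannWhitney()]
#' @export
setClass("GroupComparison",
  representation(groupA = "character", groupB = "character", nA = "integer",
                 nB = "integer", uStatistic = "numeric", pValue = "numeric",
                 method = "character"))

setValidity("GroupComparison", function(object) {
  if (object@uStatistic < 0 || object@uStatistic > object@nA * object@nB)
    return("U must lie in [0, nA*nB]")
  if (object@pValue <= 0 || object@pValue > 1)
    return("p-value must lie in (0, 1]")
  if (!object@method %in% c("exact", "normal_approx"))
    return("method must be exact or normal_approx")
  TRUE
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("Mann-Whitney %s (n=%d) vs %s (n=%d): U = %g, p = %.4g [%s]\n",
              object@groupA, object@nA, object@groupB, object@nB,
              object@uStatistic, object@pValue, object@method))
})

#' Concordance: Spearman rank concordance between two paired assays
#'
#' @slot rho Spearman rank correlation (NA when an input is constant).
#' @slot pValue two-sided p-value from the large-sample t approximation.
#' @slot n number of pairs.
#' @slot method description of the p-value route.
#' @slot note QC note (e.g. constant input).
#' @seealso [spearmanConcordance()]
#' @export
setClass("Concordance",
  representation(rho = "numeric", pValue = "numeric", n = "integer",
                 method = "character", note = "character"))

setValidity("Concordance", function(object) {
  if (!is.na(object@rho) && abs(object@rho) > 1 + 1e-12)
    return("|rho| must be <= 1")
  if (object@n < 3) return("n must be >= 3")
  TRUE
})

setMethod("show", "Concordance", function(object) {
  cat(sprintf("Spearman concordance: rho = %.4g, p = %.4g (n = %d, %s)\n",
              object@rho, object@pValue, object@n, object@method))
  if (nzchar(object@note)) cat("  note:", object@note, "\n")
})
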