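#' Derive a per-marker positivity threshold from control pixels
#'
#' Positivity cutoffs are calibrated on isotype-control stains (or a
#' biologically negative cell line) and then applied uniformly to study
#' images. Two derivation rules are offered:
#' \describe{
#'   \item{\code{mean_plus_k_sd}}{cutoff = mean + k * SD of the control
#'     pixels, with the population (1/N) SD; default k = 3, the
#'     conventional background-exclusion rule.}
#'   \item{\code{percentile}}{nearest-rank percentile of the control
#'     pixels: the value at index \code{ceiling(p/100 * n)} of the sorted
#'     sample.}
#' }
#' \code{fixed} records an externally calibrated cutoff verbatim.
#'
#' @param control a [ChannelStack-class] (the marker channel is used) or a
#'   numeric vector/matrix of control pixel intensities.
#' @param marker channel role the threshold is for.
#' @param method \code{"mean_plus_k_sd"} (default), \code{"percentile"} or
#'   \code{"fixed"}.
#' @param parameter k (>= 0), the percentile in (0, 100], or the fixed
#'   cutoff.
#' @param controlId provenance label for the control specimen.
#' @return a [PositivityThreshold-class].
#' @examples
#' deriveThreshold(c(0, 10), "phospho_met", "mean_plus_k_sd", 1)  # cutoff 10
#' @export
deriveThreshold <- function(control, marker, method = "mean_plus_k_sd",
                            parameter = 3, controlId = "") {
  method <- match.arg(method, c("mean_plus_k_sd", "percentile", "fixed"))
  if (method == "fixed") {
    return(new("PositivityThreshold", marker = marker,
               cutoff = as.numeric(parameter), method = method,
               parameter = as.numeric(parameter), controlId = controlId))
  }
  px <- if (is(control, "ChannelStack")) {
    if (!hasChannel(control, marker))
      stopf("control has no '%s' channel", marker)
    as.vector(getChannel(control, marker))
  } else as.vector(control)
  if (length(px) == 0) stopf("empty control sample")
  cut <- switch(method,
    mean_plus_k_sd = {
      if (parameter < 0) stopf("k must be >= 0")
      mean(px) + parameter * popSd(px)
    },
    percentile = {
      if (parameter <= 0 || parameter > 100)
        stopf("percentile must be in (0, 100]")
      sort(px)[ceiling(parameter / 100 * length(px))]
    })
  new("PositivityThreshold", marker = marker, cutoff = as.numeric(cut),
      method = method, parameter = as.numeric(parameter),
      controlId = controlId)
}

#' Apply a positivity threshold to a marker channel
#'
#' A pixel is positive when its intensity is strictly greater than the
#' cutoff (so a zero-variance control yields an empty mask on itself).
#' When \code{within} is given the result is intersected with it;
#' thresholding and mask intersection commute.
#'
#' @param stack a [ChannelStack-class].
#' @param marker channel role to threshold.
#' @param threshold a [PositivityThreshold-class] for the same marker.
#' @param within optional logical mask restricting the result.
#' @return logical positivity mask.
#' @export
applyThreshold <- function(stack, marker, threshold, within = NULL) {
  if (threshold@marker != marker)
    stopf("threshold is for '%s' but applied to '%s'", threshold@marker,
          marker)
  mask <- getChannel(stack, marker) > cutoff(threshold)
  if (!is.null(within)) {
    stopifnot(identical(dim(within), dim(mask)))
    mask <- mask & within
  }
  mask
}

#' Serialize thresholds to / from a plain list (for the pipeline config)
#'
#' @param thresholds named list of [PositivityThreshold-class] objects.
#' @return \code{thresholdsToList}: a list of plain lists suitable for
#'   JSON; \code{thresholdsFromList}: the inverse.
#' @export
thresholdsToList <- function(thresholds) {
  lapply(thresholds, function(t) list(marker = t@marker, cutoff = t@cutoff,
                                      method = t@method,
                                      parameter = t@parameter,
                                      control_id = t@controlId))
}

#' @rdname thresholdsToList
#' @param x a list produced by \code{thresholdsToList} (or parsed from the
#'   config JSON).
#' @export
thresholdsFromList <- function(x) {
  out <- lapply(x, function(t) {
    new("PositivityThreshold", marker = t$marker,
        cutoff = as.numeric(t$cutoff), method = t$method,
        parameter = as.numeric(t$parameter),
        controlId = if (is.null(t$control_id)) "" else t$control_id)
  })
  names(out) <- vapply(out, function(t) t@marker, character(1))
  out
}
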