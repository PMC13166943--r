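## Endpoint metrics. All are binary-area fractions or areas: a pixel
## either counts or it does not, and undefined denominators propagate as
## NA (never 0) so that QC exclusions cannot bias group means downward.

checkSameDim <- function(...) {
  ms <- list(...)
  dims <- vapply(ms, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("masks must share the same dimensions")
  invisible(TRUE)
}

#' Marker-positive area per cell
#'
#' The marker-positive tissue area of a field divided by the number of
#' nuclei in the same field:
#' \code{|positive & tissue| * pixelSizeUm^2 / nucleusCount}, in um^2 per
#' cell. With zero nuclei the field has no evaluable cells and the value
#' is NA.
#'
#' @param positive logical marker-positivity mask.
#' @param tissue logical tissue mask (denominator region).
#' @param nucleusCount number of nuclei in the field.
#' @param pixelSizeUm pixel edge length in um.
#' @return area per cell in um^2/cell, or NA when \code{nucleusCount} is 0.
#' @examples
#' p <- matrix(FALSE, 20, 20); p[1:20, 1] <- TRUE
#' t <- matrix(TRUE, 20, 20)
#' markerAreaPerCell(p, t, nucleusCount = 10, pixelSizeUm = 0.5)  # 0.5
#' @export
markerAreaPerCell <- function(positive, tissue, nucleusCount, pixelSizeUm) {
  checkSameDim(positive, tissue)
  if (nucleusCount == 0) return(NA_real_)
  sum(positive & tissue) * pixelSizeUm^2 / nucleusCount
}

#' Percent membrane area positive (%MAP)
#'
#' \code{100 * |positive & membrane| / |membrane|}; NA when the membrane
#' mask is empty.
#'
#' @param positive logical marker-positivity mask.
#' @param membrane logical plasma-membrane mask.
#' @return percentage in [0, 100], or NA.
#' @export
percentMembraneAreaPositive <- function(positive, membrane) {
  checkSameDim(positive, membrane)
  den <- sum(membrane)
  if (den == 0) return(NA_real_)
  100 * sum(positive & membrane) / den
}

#' Percent membrane area dual-positive (colocalization)
#'
#' Fraction of membrane pixels positive for both markers simultaneously
#' (e.g. dual MET+ and pY1235-MET+):
#' \code{100 * |posA & posB & membrane| / |membrane|}; NA when the
#' membrane mask is empty. Always bounded above by each single %MAP.
#'
#' @param posA,posB logical positivity masks for the two markers.
#' @param membrane logical plasma-membrane mask.
#' @return percentage in [0, 100], or NA.
#' @export
percentMembraneAreaDualPositive <- function(posA, posB, membrane) {
  checkSameDim(posA, posB, membrane)
  den <- sum(membrane)
  if (den == 0) return(NA_real_)
  100 * sum(posA & posB & membrane) / den
}

#' Percent nuclear area positive (%NAP)
#'
#' \code{100 * |positive & nuclear| / |nuclear|}; NA when the nuclear mask
#' is empty.
#'
#' @param positive logical marker-positivity mask.
#' @param nuclear logical nuclear mask.
#' @return percentage in [0, 100], or NA.
#' @export
percentNuclearAreaPositive <- function(positive, nuclear) {
  checkSameDim(positive, nuclear)
  den <- sum(nuclear)
  if (den == 0) return(NA_real_)
  100 * sum(positive & nuclear) / den
}

#' Phospho/total ratio
#'
#' Ratio of the phospho-MET to total-MET area-per-cell endpoints.
#' NA when the total-MET area per cell is 0 (no total signal) or when
#' either input is missing.
#'
#' @param phosphoApc,totalApc area-per-cell values in um^2/cell.
#' @return dimensionless ratio, or NA.
#' @export
phosphoTotalRatio <- function(phosphoApc, totalApc) {
  if (is.na(phosphoApc) || is.na(totalApc) || totalApc == 0)
    return(NA_real_)
  phosphoApc / totalApc
}

cropMask <- function(m, rows, cols) m[rows[1]:rows[2], cols[1]:cols[2],
                                      drop = FALSE]

#' Quantify one field (or its rectangular ROIs)
#'
#' Computes the full endpoint row for each ROI: compartment areas,
#' per-marker positive areas, area-per-cell, %MAP, %NAP, dual %MAP, and
#' the phospho/total ratio. ROIs are rectangular sub-regions; the default
#' is the whole field as a single ROI \code{"full"}. The nucleus count of
#' an ROI counts the nuclear components retained after cropping.
#'
#' @param stack a [ChannelStack-class].
#' @param masks a [CompartmentMasks-class] for the same field.
#' @param thresholds named list of [PositivityThreshold-class], with
#'   entries \code{total_met} and \code{phospho_met}.
#' @param rois optional list of ROIs, each
#'   \code{list(roi_id =, rows = c(r0, r1), cols = c(c0, c1))} (1-based,
#'   inclusive).
#' @param specimenId specimen/animal identifier (for evaluability pooling).
#' @param group treatment-group label.
#' @param connectivity connectivity for per-ROI nucleus recount.
#' @return data.frame with one row per ROI (see the README for the column
#'   dictionary); undefined metrics are NA with a reason in
#'   \code{qc_notes}.
#' @seealso [assessEvaluability()], [writeQuantTable()]
#' @export
quantifyField <- function(stack, masks, thresholds, rois = NULL,
                          specimenId = fieldId(stack), group = "",
                          connectivity = 8L) {
  stopifnot(is(masks, "CompartmentMasks"))
  for (m in c("total_met", "phospho_met"))
    if (is.null(thresholds[[m]])) stopf("missing threshold for %s", m)
  d <- dim(stack)
  if (is.null(rois))
    rois <- list(list(roi_id = "full", rows = c(1L, d[1]),
                      cols = c(1L, d[2])))
  posTotal <- applyThreshold(stack, "total_met", thresholds$total_met)
  posPhospho <- applyThreshold(stack, "phospho_met", thresholds$phospho_met)
  px2 <- pixelSize(stack)^2
  rows <- lapply(rois, function(roi) {
    r <- roi$rows; cc <- roi$cols
    if (r[1] < 1 || r[2] > d[1] || cc[1] < 1 || cc[2] > d[2] ||
        r[1] > r[2] || cc[1] > cc[2])
      stopf("ROI '%s' is outside field '%s'", roi$roi_id, fieldId(stack))
    nuc <- cropMask(masks@nuclear, r, cc)
    mem <- cropMask(masks@membrane, r, cc)
    tis <- cropMask(masks@tissue, r, cc)
    pt <- cropMask(posTotal, r, cc)
    pp <- cropMask(posPhospho, r, cc)
    nNuc <- labelComponents(nuc, connectivity)$count
    notes <- character(0)
    if (nNuc == 0) notes <- c(notes, "no evaluable cells (0 nuclei)")
    if (sum(mem) == 0) notes <- c(notes, "empty membrane mask")
    if (sum(nuc) == 0) notes <- c(notes, "empty nuclear mask")
    apcT <- markerAreaPerCell(pt, tis, nNuc, pixelSize(stack))
    apcP <- markerAreaPerCell(pp, tis, nNuc, pixelSize(stack))
    ratio <- phosphoTotalRatio(apcP, apcT)
    if (!is.na(apcT) && apcT == 0)
      notes <- c(notes, "no total-MET signal; ratio undefined")
    data.frame(
      field_id = fieldId(stack), roi_id = roi$roi_id,
      specimen_id = specimenId, group = group,
      nucleus_count = nNuc,
      tissue_area_um2 = sum(tis) * px2,
      membrane_area_um2 = sum(mem) * px2,
      nuclear_area_um2 = sum(nuc) * px2,
      positive_area_um2_total_met = sum(pt & tis) * px2,
      positive_area_um2_phospho_met = sum(pp & tis) * px2,
      area_per_cell_um2_total_met = apcT,
      area_per_cell_um2_phospho_met = apcP,
      pct_map_total_met = percentMembraneAreaPositive(pt, mem),
      pct_map_phospho_met = percentMembraneAreaPositive(pp, mem),
      pct_map_dual = percentMembraneAreaDualPositive(pt, pp, mem),
      pct_nap_total_met = percentNuclearAreaPositive(pt, nuc),
      pct_nap_phospho_met = percentNuclearAreaPositive(pp, nuc),
      phospho_total_ratio = ratio,
      evaluable = NA,
      qc_notes = paste(notes, collapse = "; "),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Flag specimens with too few tumor cells as non-evaluable
#'
#' A specimen is evaluable when the nuclei summed over all its ROIs reach
#' \code{minCells} (default 3000 viable tumor cells, the fitness-for-
#' purpose floor for this class of assay); the flag is propagated to every
#' record of the specimen.
#'
#' @param records data.frame of quantitation records (must contain
#'   \code{specimen_id} and \code{nucleus_count}).
#' @param minCells minimum summed nucleus count per specimen (>= 0).
#' @return \code{records} with the \code{evaluable} column filled in and a
#'   QC note appended to non-evaluable rows.
#' @export
assessEvaluability <- function(records, minCells = 3000) {
  stopifnot(minCells >= 0)
  tot <- tapply(records$nucleus_count, records$specimen_id, sum)
  ok <- tot[records$specimen_id] >= minCells
  records$evaluable <- as.vector(ok)
  note <- sprintf("specimen below %d-cell evaluability floor", minCells)
  idx <- !records$evaluable
  records$qc_notes[idx] <- ifelse(nzchar(records$qc_notes[idx]),
                                  paste(records$qc_notes[idx], note,
                                        sep = "; "), note)
  records
}
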