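#' Build a channel map
#'
#' Maps channel roles to page indices of a multichannel TIFF (1-based), or
#' to separate per-channel files. Used by [readMultichannelImage()].
#'
#' @param ... named arguments \code{role = index}; names must be channel
#'   roles (see [channelRoles()]), values 1-based page indices.
#' @return named integer vector.
#' @examples
#' channelMap(nuclear_stain = 1, membrane_marker = 2,
#'            total_met = 3, phospho_met = 4)
#' @export
channelMap <- function(...) {
  m <- c(...)
  if (length(m) == 0) stopf("channel map must not be empty")
  bad <- setdiff(names(m), channelRoles())
  if (length(bad))
    stopf("unknown channel role(s): %s", paste(bad, collapse = ", "))
  if (anyDuplicated(names(m))) stopf("channel roles must be unique")
  if (anyDuplicated(m)) stopf("channel indices must be unique")
  if (any(m < 1) || any(m != round(m)))
    stopf("channel indices must be positive integers (1-based)")
  storage.mode(m) <- "integer"
  m
}

#' Read a multichannel microscopy image into a ChannelStack
#'
#' Accepts either one multi-page TIFF (with \code{map} giving the 1-based
#' page index of each role) or one single-page TIFF per role (with
#' \code{path} a named character vector of file paths, names = roles).
#' Channels in the returned stack are addressed by role; the page order of
#' the source file is irrelevant downstream.
#'
#' @param path a single TIFF path, or a named character vector of per-role
#'   paths.
#' @param map a [channelMap()] (ignored when \code{path} is per-role).
#' @param pixelSizeUm physical pixel edge length in um (required; the
#'   image files carry no trusted calibration).
#' @param fieldId field identifier (defaults to the file name).
#' @return a [ChannelStack-class].
#' @examples
#' p <- tempfile(fileext = ".tif")
#' writeTIFFGray(list(matrix(0L, 16, 16), matrix(1L, 16, 16)), p)
#' s <- readMultichannelImage(p, channelMap(nuclear_stain = 1, total_met = 2),
#'                            pixelSizeUm = 0.5)
#' stackRoles(s)
#' @export
readMultichannelImage <- function(path, map = NULL, pixelSizeUm,
                                  fieldId = NULL) {
  if (!is.numeric(pixelSizeUm) || length(pixelSizeUm) != 1 ||
      pixelSizeUm <= 0)
    stopf("pixelSizeUm must be a single positive number")
  if (length(path) > 1 || !is.null(names(path))) {
    bad <- setdiff(names(path), channelRoles())
    if (is.null(names(path)) || length(bad))
      stopf("per-role paths must be named by channel role")
    channels <- lapply(path, function(p) {
      r <- readTIFFGray(p)
      if (length(r$pages) != 1)
        stopf("per-role file %s must have exactly one page", p)
      r$pages[[1]]
    })
    bit <- readTIFFGray(path[[1]])$bitDepth
    if (is.null(fieldId)) fieldId <- sub("\\.[^.]*$", "", basename(path[[1]]))
  } else {
    if (is.null(map)) stopf("a channel map is required for multi-page input")
    r <- readTIFFGray(path)
    if (max(map) > length(r$pages))
      stopf("channel index out of range: map needs page %d but %s has %d",
            max(map), path, length(r$pages))
    channels <- lapply(as.list(map), function(i) r$pages[[i]])
    bit <- r$bitDepth
    if (is.null(fieldId)) fieldId <- sub("\\.[^.]*$", "", basename(path))
  }
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("mismatched channel shapes in %s", paste(path, collapse = ", "))
  channelStack(channels, pixelSizeUm = pixelSizeUm, fieldId = fieldId,
               bitDepth = bit)
}

#' Write a ChannelStack as a multi-page TIFF
#'
#' Pages are written in a fixed role order (the order of
#' [channelRoles()], restricted to roles present), so a written stack is
#' re-read with the channel map returned invisibly.
#'
#' @param stack a [ChannelStack-class].
#' @param path output path.
#' @return invisibly, the [channelMap()] describing the written page order.
#' @export
writeChannelStack <- function(stack, path) {
  roles <- intersect(channelRoles(), stackRoles(stack))
  pages <- lapply(roles, function(r) getChannel(stack, r))
  writeTIFFGray(pages, path, bitDepth = stack@bitDepth)
  invisible(do.call(channelMap, as.list(stats::setNames(seq_along(roles),
                                                        roles))))
}

#' Export a binary mask as an 8-bit TIFF (0/255) for visual QC
#'
#' @param mask logical matrix.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeMaskTIFF <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  writeTIFFGray(matrix(ifelse(mask, 255L, 0L), nrow(mask)), path,
                bitDepth = 8L)
}

#' Write the per-ROI endpoint table
#'
#' One row per field/ROI, comma-separated with a header row. Missing
#' (undefined-denominator) values are written as the token \code{NA} --
#' never as 0. Output is deterministic: identical records yield
#' byte-identical files.
#'
#' @param records data.frame of quantitation records
#'   (see [quantifyField()]).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @seealso [readQuantTable()]
#' @export
writeQuantTable <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stopf("records must be a non-empty data.frame")
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE,
                   na = "NA", eol = "\n")
  invisible(path)
}

#' Read back an endpoint table written by [writeQuantTable()]
#'
#' @param path CSV path.
#' @return data.frame with the same columns and types.
#' @export
readQuantTable <- function(path) {
  header <- utils::read.csv(path, nrows = 1, check.names = FALSE)
  textCols <- intersect(names(header),
                        c("field_id", "roi_id", "specimen_id", "group",
                          "qc_notes"))
  cls <- stats::setNames(rep("character", length(textCols)), textCols)
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA",
                  colClasses = cls)
}
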