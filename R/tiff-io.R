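## Minimal baseline TIFF codec for grayscale microscopy rasters.
##
## No TIFF package exists in the supported dependency set, so the package
## carries its own reader/writer for the subset the pipeline needs:
## uncompressed, single-sample (grayscale), unsigned 8- or 16-bit,
## single- or multi-page files. The writer always emits little-endian,
## single-strip pages; the reader additionally accepts big-endian files
## and multi-strip layouts.

TIFF_TAGS <- c(width = 256L, height = 257L, bits = 258L, compression = 259L,
               photometric = 262L, stripOffsets = 273L, samplesPerPixel = 277L,
               rowsPerStrip = 278L, stripByteCounts = 279L,
               sampleFormat = 339L)

u16le <- function(x) {
  x <- as.integer(x)
  as.raw(rbind(x %% 256L, x %/% 256L))
}

u32le <- function(x) {
  x <- as.numeric(x)
  as.raw(rbind(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
               (x %/% 16777216) %% 256))
}

## one 12-byte IFD entry; type 3 = SHORT, 4 = LONG; single value, inline
tiffEntry <- function(tag, type, value) {
  val <- if (type == 3L) c(u16le(value), as.raw(c(0, 0))) else u32le(value)
  c(u16le(tag), u16le(type), u32le(1), val)
}

#' Write grayscale matrices as an uncompressed multi-page TIFF
#'
#' Each matrix becomes one page, written row-major (row 1 at top). Values
#' must be integers in \code{[0, 2^bitDepth - 1]}.
#'
#' @param pages a matrix or list of matrices (all the same size).
#' @param path output file path.
#' @param bitDepth 8 or 16 (unsigned).
#' @return invisibly, \code{path}.
#' @seealso [readTIFFGray()]
#' @export
writeTIFFGray <- function(pages, path, bitDepth = 16L) {
  if (is.matrix(pages)) pages <- list(pages)
  bitDepth <- as.integer(bitDepth)
  if (!bitDepth %in% c(8L, 16L)) stopf("bitDepth must be 8 or 16")
  maxv <- 2^bitDepth - 1
  for (m in pages) {
    if (!is.matrix(m)) stopf("pages must be matrices")
    v <- as.vector(m)
    if (any(!is.finite(v)) || any(v < 0) || any(v > maxv) ||
        any(v != round(v)))
      stopf("pixel values must be integers in [0, %d]", maxv)
  }
  bytesPerSample <- bitDepth %/% 8L
  nIFD <- 10L
  ifdBytes <- 2L + nIFD * 12L + 4L
  chunks <- list(c(charToRaw("II"), u16le(42L), u32le(0)))  # offset patched below
  offset <- 8
  ifdOffsets <- numeric(length(pages))
  for (i in seq_along(pages)) {
    m <- pages[[i]]
    v <- as.integer(t(m))  # row-major
    dat <- if (bytesPerSample == 1L) as.raw(v) else
      as.raw(rbind(v %% 256L, v %/% 256L))
    dataOffset <- offset
    ifdOffsets[i] <- dataOffset + length(dat)
    ifd <- c(
      u16le(nIFD),
      tiffEntry(TIFF_TAGS[["width"]], 4L, ncol(m)),
      tiffEntry(TIFF_TAGS[["height"]], 4L, nrow(m)),
      tiffEntry(TIFF_TAGS[["bits"]], 3L, bitDepth),
      tiffEntry(TIFF_TAGS[["compression"]], 3L, 1L),
      tiffEntry(TIFF_TAGS[["photometric"]], 3L, 1L),  # BlackIsZero
      tiffEntry(TIFF_TAGS[["stripOffsets"]], 4L, dataOffset),
      tiffEntry(TIFF_TAGS[["samplesPerPixel"]], 3L, 1L),
      tiffEntry(TIFF_TAGS[["rowsPerStrip"]], 4L, nrow(m)),
      tiffEntry(TIFF_TAGS[["stripByteCounts"]], 4L, length(dat)),
      tiffEntry(TIFF_TAGS[["sampleFormat"]], 3L, 1L),  # unsigned
      u32le(0))  # next-IFD pointer, patched for all but the last page
    chunks[[length(chunks) + 1L]] <- dat
    chunks[[length(chunks) + 1L]] <- ifd
    offset <- ifdOffsets[i] + length(ifd)
  }
  out <- do.call(c, chunks)
  out[5:8] <- u32le(ifdOffsets[1])
  if (length(pages) > 1) {
    for (i in seq_len(length(pages) - 1L)) {
      at <- ifdOffsets[i] + 2L + nIFD * 12L
      out[(at + 1):(at + 4)] <- u32le(ifdOffsets[i + 1])
    }
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

rdU16 <- function(raw, at, le) {
  b <- as.integer(raw[(at + 1):(at + 2)])
  if (le) b[1] + 256 * b[2] else b[2] + 256 * b[1]
}

rdU32 <- function(raw, at, le) {
  b <- as.integer(raw[(at + 1):(at + 4)])
  if (le) b[1] + 256 * (b[2] + 256 * (b[3] + 256 * b[4]))
  else b[4] + 256 * (b[3] + 256 * (b[2] + 256 * b[1]))
}

## read the (possibly offset-stored) integer values of one IFD entry
tiffEntryValues <- function(raw, entryAt, le) {
  type <- rdU16(raw, entryAt + 2, le)
  count <- rdU32(raw, entryAt + 4, le)
  size <- switch(as.character(type), "1" = 1L, "3" = 2L, "4" = 4L,
                 stopf("unsupported TIFF entry type %d", type))
  at <- if (size * count <= 4) entryAt + 8 else rdU32(raw, entryAt + 8, le)
  vapply(seq_len(count) - 1L, function(k) {
    switch(as.character(size),
           "1" = as.integer(raw[at + k + 1]),
           "2" = rdU16(raw, at + 2 * k, le),
           "4" = rdU32(raw, at + 4 * k, le))
  }, numeric(1))
}

#' Read a grayscale (multi-page) TIFF
#'
#' Supports the uncompressed, single-sample, unsigned 8/16-bit baseline
#' subset in either byte order, with single- or multi-strip pages.
#'
#' @param path TIFF file path.
#' @return list with \code{pages} (list of numeric matrices, row 1 = top
#'   image row) and \code{bitDepth}.
#' @seealso [writeTIFFGray()]
#' @export
readTIFFGray <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  order <- rawToChar(raw[1:2])
  le <- order == "II"
  if (!order %in% c("II", "MM")) stopf("not a TIFF file: %s", path)
  if (rdU16(raw, 2, le) != 42L) stopf("bad TIFF magic in %s", path)
  ifdAt <- rdU32(raw, 4, le)
  pages <- list()
  bitDepth <- NA_integer_
  while (ifdAt != 0) {
    n <- rdU16(raw, ifdAt, le)
    tags <- list()
    for (i in seq_len(n)) {
      at <- ifdAt + 2 + (i - 1) * 12
      tags[[as.character(rdU16(raw, at, le))]] <- at
    }
    getv <- function(tag, default = NULL) {
      at <- tags[[as.character(tag)]]
      if (is.null(at)) {
        if (is.null(default)) stopf("TIFF tag %d missing", tag)
        return(default)
      }
      tiffEntryValues(raw, at, le)
    }
    w <- getv(256L); h <- getv(257L)
    bits <- getv(258L, 8)
    if (length(bits) != 1 || !bits %in% c(8, 16))
      stopf("only 8/16-bit single-sample TIFFs are supported")
    if (getv(259L, 1) != 1) stopf("compressed TIFFs are not supported")
    if (getv(277L, 1) != 1) stopf("only single-sample TIFFs are supported")
    if (getv(339L, 1) != 1) stopf("only unsigned sample format is supported")
    offs <- getv(273L)
    counts <- getv(279L, w * h * bits / 8)
    dat <- do.call(c, lapply(seq_along(offs), function(k) {
      raw[(offs[k] + 1):(offs[k] + counts[k])]
    }))
    vals <- if (bits == 8) as.numeric(dat) else {
      b <- matrix(as.integer(dat), nrow = 2)
      if (le) b[1, ] + 256 * b[2, ] else b[2, ] + 256 * b[1, ]
    }
    if (length(vals) != w * h) stopf("TIFF strip data does not match page size")
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, ncol = w,
                                          byrow = TRUE)
    bitDepth <- as.integer(bits)
    ifdAt <- rdU32(raw, ifdAt + 2 + n * 12, le)
  }
  if (length(pages) == 0) stopf("TIFF contains no pages: %s", path)
  list(pages = pages, bitDepth = bitDepth)
}
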