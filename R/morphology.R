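## Binary-image primitives used by the segmentation stage. Implemented in
## vectorized base R; rasters here are small microscopy fields, not whole
## slides, so O(n_pixels * diameter) label propagation is more than fast
## enough and keeps the package dependency-free.

#' Label connected components of a binary mask
#'
#' Iterative minimum-label propagation: every foreground pixel starts with
#' a unique id and repeatedly adopts the smallest id among its neighbors
#' until a fixed point; components are then renumbered 1..k in raster
#' order of their first pixel.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return list with \code{labels} (integer matrix, 0 = background) and
#'   \code{count}.
#' @export
labelComponents <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask), is.matrix(mask))
  connectivity <- as.integer(connectivity)
  lab <- matrix(Inf, nrow(mask), ncol(mask))
  lab[mask] <- which(mask)  # column-major unique ids
  offs <- neighborOffsets(connectivity)
  repeat {
    nb <- lab
    for (o in offs) nb <- pmin(nb, shiftMat(lab, o[1], o[2], Inf))
    nb[!mask] <- Inf
    if (identical(nb, lab)) break
    lab <- nb
  }
  out <- matrix(0L, nrow(mask), ncol(mask))
  count <- 0L
  if (any(mask)) {
    ids <- lab[mask]
    uid <- sort(unique(ids))
    out[mask] <- match(ids, uid)
    count <- length(uid)
  }
  list(labels = out, count = count)
}

#' Fill interior holes of a binary mask
#'
#' Background regions not connected to the image border are turned into
#' foreground. Background connectivity is the dual of the foreground
#' connectivity (4 for 8-connected foreground and vice versa), the usual
#' digital-topology pairing.
#'
#' @param mask logical matrix.
#' @param connectivity foreground connectivity, 4 or 8.
#' @return logical matrix.
#' @export
fillHoles <- function(mask, connectivity = 8L) {
  bgConn <- if (as.integer(connectivity) == 8L) 4L else 8L
  bg <- labelComponents(!mask, bgConn)$labels
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0]
  mask | (bg > 0 & !(bg %in% border))
}

#' Quasi-Euclidean distance to the nearest TRUE pixel
#'
#' Two-pass chamfer transform with weights 1 and sqrt(2); exact for
#' axis-aligned and diagonal paths, within ~8% of Euclidean otherwise.
#' Pixels of the mask itself have distance 0.
#'
#' @param mask logical matrix (the target set).
#' @return numeric matrix of distances (Inf where the mask is empty).
#' @export
chamferDistance <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  d <- matrix(Inf, nr, nc)
  d[mask] <- 0
  s2 <- sqrt(2)
  for (i in seq_len(nr)) {          # forward pass
    if (i > 1) {
      up <- d[i - 1, ] + 1
      ul <- c(Inf, d[i - 1, -nc] + s2)
      ur <- c(d[i - 1, -1] + s2, Inf)
      d[i, ] <- pmin(d[i, ], up, ul, ur)
    }
    run <- Inf
    row <- d[i, ]
    for (j in seq_len(nc)) {
      run <- min(run + 1, row[j])
      row[j] <- run
    }
    d[i, ] <- row
  }
  for (i in rev(seq_len(nr))) {     # backward pass
    if (i < nr) {
      dn <- d[i + 1, ] + 1
      dl <- c(Inf, d[i + 1, -nc] + s2)
      dr <- c(d[i + 1, -1] + s2, Inf)
      d[i, ] <- pmin(d[i, ], dn, dl, dr)
    }
    run <- Inf
    row <- d[i, ]
    for (j in rev(seq_len(nc))) {
      run <- min(run + 1, row[j])
      row[j] <- run
    }
    d[i, ] <- row
  }
  d
}

#' Dilate a binary mask by a disk
#'
#' A pixel is in the dilated mask iff its chamfer distance to the mask is
#' at most \code{radiusPx}. \code{radiusPx <= 0} returns the mask
#' unchanged; the result is always a superset of the input.
#'
#' @param mask logical matrix.
#' @param radiusPx dilation radius in pixels.
#' @return logical matrix.
#' @export
dilateDisk <- function(mask, radiusPx) {
  if (radiusPx <= 0 || !any(mask)) return(mask)
  chamferDistance(mask) <= radiusPx + 1e-9
}

#' Otsu's threshold
#'
#' Maximizes between-class variance over a 256-bin histogram of the
#' intensity range. Returns a cutoff on the original intensity scale;
#' pixels strictly above it are foreground.
#'
#' @param x numeric vector or matrix of intensities.
#' @param nbins histogram resolution (default 256).
#' @return numeric cutoff.
#' @export
otsuThreshold <- function(x, nbins = 256L) {
  v <- as.vector(x)
  lo <- min(v); hi <- max(v)
  if (hi <= lo)
    stopf("degenerate image: constant intensity, Otsu threshold undefined")
  bin <- pmin(nbins, 1L + floor((v - lo) / (hi - lo) * nbins))
  h <- tabulate(bin, nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  muT <- mu[nbins]
  sigmaB <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigmaB[!is.finite(sigmaB)] <- -Inf
  k <- which.max(sigmaB)  # first maximizing bin: deterministic tie-break
  lo + k / nbins * (hi - lo)
}

#' Split touching blobs by distance-transform watershed
#'
#' Seeds are the connected plateaus of local maxima of the distance
#' transform (distance to background); foreground pixels are then flooded
#' in order of decreasing distance, each adopting the smallest label among
#' already-labeled neighbors. Deterministic by construction.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return list with \code{labels} (integer matrix) and \code{count}.
#' @export
watershedSplit <- function(mask, connectivity = 8L) {
  if (!any(mask)) return(list(labels = matrix(0L, nrow(mask), ncol(mask)),
                              count = 0L))
  dt <- chamferDistance(!mask)
  dt[!mask] <- 0
  dtr <- round(dt, 6)
  nbMax <- matrix(-Inf, nrow(mask), ncol(mask))
  for (o in neighborOffsets(8L))
    nbMax <- pmax(nbMax, shiftMat(dtr, o[1], o[2], -Inf))
  seeds <- mask & dtr >= nbMax
  seedLab <- labelComponents(seeds, 8L)$labels
  labels <- seedLab
  offs <- neighborOffsets(as.integer(connectivity))
  idx <- which(mask & labels == 0L)
  ord <- idx[order(-dt[idx], idx)]
  nr <- nrow(mask); nc <- ncol(mask)
  remaining <- ord
  nextLabel <- max(labels) + 1L
  while (length(remaining)) {
    assignedAny <- FALSE
    still <- integer(0)
    for (p in remaining) {
      r <- (p - 1L) %% nr + 1L; cc <- (p - 1L) %/% nr + 1L
      best <- 0L
      for (o in offs) {
        rr <- r + o[1]; ccc <- cc + o[2]
        if (rr >= 1 && rr <= nr && ccc >= 1 && ccc <= nc) {
          l <- labels[rr, ccc]
          if (l > 0L && (best == 0L || l < best)) best <- l
        }
      }
      if (best > 0L) {
        labels[p] <- best
        assignedAny <- TRUE
      } else still <- c(still, p)
    }
    if (!assignedAny && length(still)) {
      labels[still[1]] <- nextLabel  # isolated plateau: new object
      nextLabel <- nextLabel + 1L
      still <- still[-1]
    }
    remaining <- still
  }
  list(labels = labels, count = length(unique(labels[labels > 0L])))
}
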