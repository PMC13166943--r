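#' SceneSpec: generative parameters for one synthetic multichannel field
#'
#' The generator emulates a field of tumor cells as non-overlapping disks
#' with an annular plasma membrane and an interior disk nucleus, rendered
#' into the four-plex channel layout (nuclear stain, membrane marker,
#' total MET, phospho MET). Marker positivity is painted as an exact
#' pixel subset -- \code{floor(fraction * compartment size)} pixels per
#' (marker, compartment) -- so ground-truth fractions are exact
#' rationals; additive zero-mean Gaussian noise (clipped at 0, quantized
#' to the bit depth) is applied last.
#'
#' @slot height,width field size in pixels.
#' @slot pixelSizeUm pixel edge in um.
#' @slot nCells number of cells.
#' @slot cellRadiusUm length-2 range of cell radii in um.
#' @slot membraneThicknessUm annulus thickness in um.
#' @slot nucleusRadiusFraction nucleus radius as a fraction of the cell
#'   radius, in (0, 1).
#' @slot backgroundMean,signalMean named per-role background and
#'   specific-stain intensities.
#' @slot positiveFraction named fractions, names \code{"marker:compartment"}
#'   with compartment one of membrane, nucleus, cytoplasm.
#' @slot noiseSd additive Gaussian noise SD (intensity units).
#' @slot allowTouching allow cells to touch (still non-overlapping).
#' @slot bitDepth 8 or 16.
#' @slot seed RNG seed; scenes are bit-reproducible given the seed.
#' @seealso [sceneSpec()], [generateScene()]
#' @export
setClass("SceneSpec",
  representation(height = "integer", width = "integer",
                 pixelSizeUm = "numeric", nCells = "integer",
                 cellRadiusUm = "numeric", membraneThicknessUm = "numeric",
                 nucleusRadiusFraction = "numeric",
                 backgroundMean = "numeric", signalMean = "numeric",
                 positiveFraction = "numeric", noiseSd = "numeric",
                 allowTouching = "logical", bitDepth = "integer",
                 seed = "integer"))

setValidity("SceneSpec", function(object) {
  if (object@height < 8 || object@width < 8)
    return("field must be at least 8 x 8 px")
  if (object@pixelSizeUm <= 0) return("pixelSizeUm must be > 0")
  if (object@nCells < 0) return("nCells must be >= 0")
  if (length(object@cellRadiusUm) != 2 || any(object@cellRadiusUm <= 0) ||
      object@cellRadiusUm[1] > object@cellRadiusUm[2])
    return("cellRadiusUm must be an increasing positive range")
  if (object@membraneThicknessUm <= 0)
    return("membraneThicknessUm must be > 0")
  if (object@nucleusRadiusFraction <= 0 || object@nucleusRadiusFraction >= 1)
    return("nucleusRadiusFraction must be in (0, 1)")
  if (object@nucleusRadiusFraction >=
      1 - object@membraneThicknessUm / object@cellRadiusUm[1])
    return("nucleus must fit inside the membrane annulus")
  if (any(object@positiveFraction < 0 | object@positiveFraction > 1))
    return("positive fractions must lie in [0, 1]")
  pfNames <- names(object@positiveFraction)
  if (length(object@positiveFraction) &&
      (is.null(pfNames) || !all(grepl("^(total_met|phospho_met):(membrane|nucleus|cytoplasm)$",
                                      pfNames))))
    return("positiveFraction names must be marker:compartment")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (!object@bitDepth %in% c(8L, 16L)) return("bitDepth must be 8 or 16")
  TRUE
})

#' Construct a synthetic scene specification
#'
#' Defaults describe a moderately MET-expressing field: a 64 x 64 um
#' (128 px at 0.5 um) field of 10 cells, radius 5-7 um, 1-um membrane
#' annulus, nucleus at 0.6 of the cell radius; 16-bit intensities with
#' background 100, specific stain 3000, noise SD 50.
#'
#' @param height,width field size in px.
#' @param pixelSizeUm pixel edge in um.
#' @param nCells number of cells.
#' @param cellRadiusUm radius range in um.
#' @param membraneThicknessUm membrane annulus thickness in um.
#' @param nucleusRadiusFraction nucleus/cell radius ratio.
#' @param backgroundMean,signalMean intensity levels (scalar, applied to
#'   all roles, or named per role).
#' @param positiveFraction named \code{"marker:compartment"} fractions.
#' @param noiseSd Gaussian noise SD.
#' @param allowTouching allow touching cells.
#' @param bitDepth 8 or 16.
#' @param seed RNG seed.
#' @return a validated [SceneSpec-class].
#' @export
sceneSpec <- function(height = 128L, width = 128L, pixelSizeUm = 0.5,
                      nCells = 10L, cellRadiusUm = c(5, 7),
                      membraneThicknessUm = 1,
                      nucleusRadiusFraction = 0.6,
                      backgroundMean = 100, signalMean = 3000,
                      positiveFraction = c(
                        "total_met:membrane" = 0.5,
                        "phospho_met:membrane" = 0.3,
                        "total_met:nucleus" = 0.2,
                        "phospho_met:nucleus" = 0.3,
                        "total_met:cytoplasm" = 0.3,
                        "phospho_met:cytoplasm" = 0.2),
                      noiseSd = 50, allowTouching = FALSE, bitDepth = 16L,
                      seed = 1L) {
  roles <- c("nuclear_stain", "membrane_marker", "total_met", "phospho_met")
  expandLevels <- function(x) {
    if (is.null(names(x))) {
      stopifnot(length(x) == 1)
      stats::setNames(rep(as.numeric(x), length(roles)), roles)
    } else {
      out <- stats::setNames(rep(as.numeric(x[1]), length(roles)), roles)
      out[names(x)] <- x
      out
    }
  }
  new("SceneSpec", height = as.integer(height), width = as.integer(width),
      pixelSizeUm = as.numeric(pixelSizeUm), nCells = as.integer(nCells),
      cellRadiusUm = as.numeric(cellRadiusUm),
      membraneThicknessUm = as.numeric(membraneThicknessUm),
      nucleusRadiusFraction = as.numeric(nucleusRadiusFraction),
      backgroundMean = expandLevels(backgroundMean),
      signalMean = expandLevels(signalMean),
      positiveFraction = positiveFraction, noiseSd = as.numeric(noiseSd),
      allowTouching = isTRUE(allowTouching), bitDepth = as.integer(bitDepth),
      seed = as.integer(seed))
}

#' GroundTruth: exact truth for a generated scene
#'
#' @slot cellMask,nuclearMask,membraneMask logical rasters of the painted
#'   geometry.
#' @slot nucleusCount number of cells placed.
#' @slot positiveMasks named list (\code{"marker:compartment"}) of the
#'   exact painted positivity masks.
#' @slot trueFraction named exact painted fractions (painted pixels /
#'   compartment pixels).
#' @slot trueAreaPerCellUm2 named per-marker painted area per cell in
#'   um^2/cell.
#' @export
setClass("GroundTruth",
  representation(cellMask = "matrix", nuclearMask = "matrix",
                 membraneMask = "matrix", nucleusCount = "integer",
                 positiveMasks = "list", trueFraction = "numeric",
                 trueAreaPerCellUm2 = "numeric"))

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d cells; cell %d px, nuclear %d px, membrane %d px\n",
              object@nucleusCount, sum(object@cellMask),
              sum(object@nuclearMask), sum(object@membraneMask)))
  if (length(object@trueFraction)) {
    cat("  painted fractions:\n")
    for (nm in names(object@trueFraction))
      cat(sprintf("    %-24s %.4f\n", nm, object@trueFraction[[nm]]))
  }
})

## rejection-sample non-overlapping disk centers; radii in px
placeCells <- function(spec) {
  rRange <- spec@cellRadiusUm / spec@pixelSizeUm
  gap <- if (spec@allowTouching) 0 else 2
  centers <- matrix(numeric(0), ncol = 3)  # row, col, radius
  maxAttempts <- 2000L
  for (k in seq_len(spec@nCells)) {
    placed <- FALSE
    for (a in seq_len(maxAttempts)) {
      r <- stats::runif(1, rRange[1], rRange[2])
      row <- stats::runif(1, 1 + r, spec@height - r)
      col <- stats::runif(1, 1 + r, spec@width - r)
      ok <- TRUE
      if (nrow(centers)) {
        d <- sqrt((centers[, 1] - row)^2 + (centers[, 2] - col)^2)
        ok <- all(d >= centers[, 3] + r + gap)
      }
      if (ok) {
        centers <- rbind(centers, c(row, col, r))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stopf("unplaceable geometry: could not place cell %d of %d after %d attempts",
            k, spec@nCells, maxAttempts)
  }
  centers
}

#' Generate a synthetic multichannel scene with exact ground truth
#'
#' Deterministic given \code{spec@seed}: the same spec yields a
#' bit-identical [ChannelStack-class] and [GroundTruth-class].
#'
#' @param spec a [SceneSpec-class].
#' @return list with \code{stack} (a [ChannelStack-class]) and
#'   \code{truth} (a [GroundTruth-class]).
#' @examples
#' sc <- generateScene(sceneSpec(nCells = 5, seed = 7))
#' sc$truth
#' @export
generateScene <- function(spec) {
  validObject(spec)
  withSeed(spec@seed, {
    h <- spec@height; w <- spec@width
    rowG <- matrix(seq_len(h), h, w)
    colG <- matrix(seq_len(w), h, w, byrow = TRUE)
    cellMask <- matrix(FALSE, h, w)
    nucMask <- matrix(FALSE, h, w)
    memMask <- matrix(FALSE, h, w)
    if (spec@nCells > 0) {
      centers <- placeCells(spec)
      memThickPx <- spec@membraneThicknessUm / spec@pixelSizeUm
      for (k in seq_len(nrow(centers))) {
        d <- sqrt((rowG - centers[k, 1])^2 + (colG - centers[k, 2])^2)
        r <- centers[k, 3]
        cellMask <- cellMask | (d <= r)
        memMask <- memMask | (d <= r & d > r - memThickPx)
        nucMask <- nucMask | (d <= r * spec@nucleusRadiusFraction)
      }
    }
    cytoMask <- cellMask & !memMask & !nucMask
    comp <- list(membrane = memMask, nucleus = nucMask,
                 cytoplasm = cytoMask)
    roles <- c("nuclear_stain", "membrane_marker", "total_met",
               "phospho_met")
    channels <- lapply(roles, function(rl)
      matrix(spec@backgroundMean[[rl]], h, w))
    names(channels) <- roles
    channels$nuclear_stain[nucMask] <- spec@signalMean[["nuclear_stain"]]
    channels$membrane_marker[memMask] <- spec@signalMean[["membrane_marker"]]
    positiveMasks <- list()
    trueFraction <- numeric(0)
    for (nm in names(spec@positiveFraction)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      marker <- parts[1]; compartment <- parts[2]
      idx <- which(comp[[compartment]])
      nPos <- floor(spec@positiveFraction[[nm]] * length(idx))
      pm <- matrix(FALSE, h, w)
      if (nPos > 0) {
        pick <- sample(idx, nPos)
        pm[pick] <- TRUE
        channels[[marker]][pick] <- spec@signalMean[[marker]]
      }
      positiveMasks[[nm]] <- pm
      trueFraction[nm] <- if (length(idx)) nPos / length(idx) else 0
    }
    maxv <- 2^spec@bitDepth - 1
    channels <- lapply(channels, function(ch) {
      if (spec@noiseSd > 0)
        ch <- ch + matrix(stats::rnorm(h * w, 0, spec@noiseSd), h, w)
      matrix(pmin(maxv, pmax(0, round(ch))), h, w)
    })
    px2 <- spec@pixelSizeUm^2
    markers <- unique(sub(":.*$", "", names(positiveMasks)))
    apc <- vapply(markers, function(m) {
      tot <- sum(vapply(positiveMasks[grep(paste0("^", m, ":"),
                                           names(positiveMasks))],
                        sum, numeric(1)))
      if (spec@nCells == 0) 0 else tot * px2 / spec@nCells
    }, numeric(1))
    truth <- new("GroundTruth", cellMask = cellMask, nuclearMask = nucMask,
                 membraneMask = memMask, nucleusCount = spec@nCells,
                 positiveMasks = positiveMasks, trueFraction = trueFraction,
                 trueAreaPerCellUm2 = apc)
    stack <- channelStack(channels, pixelSizeUm = spec@pixelSizeUm,
                          fieldId = sprintf("scene_seed%d", spec@seed),
                          bitDepth = spec@bitDepth)
    list(stack = stack, truth = truth)
  })
}

#' Scale the phospho fractions of a spec by a drug-inhibition factor
#' @noRd
scalePhospho <- function(spec, factor) {
  pf <- spec@positiveFraction
  idx <- grepl("^phospho_met:", names(pf))
  pf[idx] <- pf[idx] * factor
  initialize(spec, positiveFraction = pf)
}

#' Generate a dose-response series of scenes
#'
#' Emulates a TKI pharmacodynamic experiment: the phospho-MET positive
#' fractions are suppressed by the sigmoidal inhibition factor
#' \code{1 / (1 + (dose / ic50)^hill)} while the total-MET fractions are
#' unchanged. Replicate seeds are derived deterministically as
#' \code{seed + replicate counter}.
#'
#' @param base a [SceneSpec-class]; its phospho fractions are the
#'   vehicle (dose 0) level.
#' @param doses non-negative dose values.
#' @param ic50 half-maximal inhibitory dose (> 0).
#' @param hill Hill coefficient (> 0, default 1).
#' @param nReps replicates (animals) per dose group.
#' @param seed base RNG seed for the series.
#' @return list of entries, each
#'   \code{list(dose, rep, spec, stack, truth)}.
#' @export
generateDoseResponseSeries <- function(base, doses, ic50, hill = 1,
                                       nReps = 4L, seed = 1L) {
  if (any(doses < 0)) stopf("doses must be >= 0")
  if (ic50 <= 0 || hill <= 0) stopf("invalid pharmacology parameters")
  if (nReps < 1) stopf("nReps must be >= 1")
  counter <- 0L
  out <- list()
  for (d in doses) {
    factor <- 1 / (1 + (d / ic50)^hill)
    for (j in seq_len(nReps)) {
      sp <- scalePhospho(base, factor)
      sp@seed <- as.integer(seed + counter)
      counter <- counter + 1L
      sc <- generateScene(sp)
      out[[length(out) + 1L]] <- list(dose = d, rep = j, spec = sp,
                                      stack = sc$stack, truth = sc$truth)
    }
  }
  out
}

#' Generate an isotype-control scene
#'
#' Same geometry channels (nuclear stain, membrane marker) as the scene
#' the spec would generate -- the placement RNG stream is identical --
#' but with every marker positive-fraction forced to 0, so the MET
#' channels contain background plus noise only.
#'
#' @param spec a [SceneSpec-class].
#' @return a [ChannelStack-class].
#' @export
generateIsotypeControl <- function(spec) {
  pf <- spec@positiveFraction
  pf[] <- 0
  sc <- generateScene(initialize(spec, positiveFraction = pf))
  st <- sc$stack
  st@fieldId <- sprintf("isotype_seed%d", spec@seed)
  st
}

#' Named scene presets spanning the biological scenarios
#'
#' \describe{
#'   \item{negligible}{no MET expression (SNU-1-like): all marker
#'     fractions 0.}
#'   \item{weak}{weak expression, very weak activation
#'     (MDA-MB-231-like).}
#'   \item{moderate}{moderate expression and activation (HT29-like); the
#'     [sceneSpec()] defaults.}
#'   \item{high}{high, constitutively active expression (GTL-16 /
#'     SNU-5-like).}
#'   \item{nuclear-low / nuclear-high}{nuclear phospho fractions 0.3 vs
#'     0.6, the ligand-driven nuclear shift scenario.}
#' }
#'
#' @param name preset name.
#' @param seed RNG seed for the returned spec.
#' @return a [SceneSpec-class].
#' @export
scenePreset <- function(name, seed = 1L) {
  pf <- function(tm, pm, tn, pn, tc, pc) c(
    "total_met:membrane" = tm, "phospho_met:membrane" = pm,
    "total_met:nucleus" = tn, "phospho_met:nucleus" = pn,
    "total_met:cytoplasm" = tc, "phospho_met:cytoplasm" = pc)
  frac <- switch(name,
    "negligible" = pf(0, 0, 0, 0, 0, 0),
    "weak" = pf(0.15, 0.02, 0.05, 0.01, 0.10, 0.01),
    "moderate" = pf(0.5, 0.3, 0.2, 0.3, 0.3, 0.2),
    "high" = pf(0.8, 0.7, 0.3, 0.3, 0.5, 0.4),
    "nuclear-low" = pf(0.4, 0.3, 0.2, 0.3, 0.2, 0.1),
    "nuclear-high" = pf(0.4, 0.3, 0.2, 0.6, 0.2, 0.1),
    stopf("unknown preset '%s'", name))
  sceneSpec(positiveFraction = frac, seed = seed)
}
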