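#' Pixel-wise average of a frame stack
#'
#' ROIs are defined on the time-average of the acquisition, so the first step
#' is a plain arithmetic mean over frames, kept real-valued.
#'
#' @param stack 3-D array (rows x cols x frames) or a list of matrices of
#'   identical dimensions.
#' @return numeric matrix, the per-pixel mean.
#' @export
averageFrames <- function(stack) {
  if (is.list(stack)) {
    if (!length(stack)) stop("empty stack")
    d <- dim(stack[[1]])
    if (!all(vapply(stack, function(f) identical(dim(f), d), logical(1))))
      stop("all frames must share the same shape")
    return(Reduce(`+`, lapply(stack, function(f) {
      storage.mode(f) <- "double"; f
    })) / length(stack))
  }
  if (length(dim(stack)) == 2) {
    storage.mode(stack) <- "double"
    return(stack)
  }
  if (length(dim(stack)) != 3 || dim(stack)[3] < 1) stop("empty stack")
  storage.mode(stack) <- "double"
  apply(stack, c(1, 2), mean)
}

#' Detect astrocyte ROIs by local-maximum seeding and a size filter
#'
#' Seeds are local intensity maxima above a robust sensitivity level
#' `median(image) + sensitivity * mad(image)`. Each seed is grown (8-connected)
#' to the contiguous region above a seed-relative level
#' `background + growFraction * (seed intensity - background)`; pixels claimed
#' by several seeds go to the nearest seed (ties to the lower label). Regions
#' whose footprint falls outside `[sizeMin, sizeMax]` pixels are discarded;
#' retained ROIs are relabeled in order of descending area. Because both
#' levels are expressed relative to the background median, segmentation is
#' invariant to adding a constant offset to the image.
#'
#' @param meanImage 2-D numeric matrix (a time-averaged movie).
#' @param sensitivity multiples of the image MAD above the median a seed must
#'   reach (default 5); larger is stricter and never increases the ROI count.
#' @param sizeMin,sizeMax footprint bounds in pixels (defaults 600 and 6000).
#' @param growFraction fraction of the seed-above-background height at which
#'   the region is cut (default 0.5, i.e. half maximum above background).
#' @param pixelSize um per pixel (default 0.5).
#' @param smoothSigma Gaussian pre-smoothing sigma in px applied before
#'   seeding and growth (default 1; 0 disables). For astrocyte-scale regions
#'   (>= 600 px) this inflates the half-maximum footprint by well under 1%.
#' @return a [RoiSet]; empty (zero ROIs) when no maxima pass, never an error.
#' @export
detectRois <- function(meanImage, sensitivity = 5, sizeMin = 600,
                       sizeMax = 6000, growFraction = 0.5, pixelSize = 0.5,
                       smoothSigma = 1) {
  if (length(dim(meanImage)) != 2) stop("meanImage must be a 2-D matrix")
  img <- meanImage
  storage.mode(img) <- "double"
  if (smoothSigma > 0)
    img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                             sigma = smoothSigma))
  bg <- stats::median(img)
  spread <- stats::mad(img)
  if (spread == 0) spread <- stats::sd(img)
  seedLevel <- bg + sensitivity * spread
  nr <- nrow(img); nc <- ncol(img)
  fov <- nr * nc * (pixelSize / 1000)^2   # mm^2

  emptySet <- function() new("RoiSet",
    labelImage = matrix(0L, nr, nc),
    rois = data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
                      area_px = numeric(), is_perivascular = logical()),
    pixelSize = pixelSize, fovArea = fov, sizeRange = c(sizeMin, sizeMax))

  if (!is.finite(spread) || spread == 0) return(emptySet())

  # local maxima: pixel equals the 3x3 neighborhood maximum and passes the level
  dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(img),
                                            EBImage::makeBrush(3, "box")))
  isMax <- img >= dil & img >= seedLevel
  if (!any(isMax)) return(emptySet())
  # collapse plateau maxima: one seed per connected maxima group
  maxLab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(isMax * 1)))
  nSeed <- max(maxLab)
  seedXY <- matrix(NA_real_, nSeed, 2)
  seedVal <- numeric(nSeed)
  idx <- which(maxLab > 0, arr.ind = TRUE)
  for (s in seq_len(nSeed)) {
    px <- idx[maxLab[idx] == s, , drop = FALSE]
    seedXY[s, ] <- colMeans(px)
    seedVal[s] <- max(img[px])
  }
  ord <- order(seedVal, decreasing = TRUE)

  claim <- matrix(0L, nr, nc)        # winning seed per pixel
  claimDist <- matrix(Inf, nr, nc)   # distance to its winning seed
  rowIdx <- matrix(seq_len(nr), nr, nc)
  colIdx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (s in ord) {
    lev <- bg + growFraction * (seedVal[s] - bg)
    comp <- EBImage::imageData(EBImage::bwlabel(EBImage::Image((img >= lev) * 1)))
    home <- comp[round(seedXY[s, 1]), round(seedXY[s, 2])]
    if (home == 0) next
    inComp <- comp == home
    # a seed on the shoulder of a much brighter structure is not a region of
    # its own: skip seeds whose region holds pixels above twice their height
    if (max(img[inComp]) - bg > 2 * (seedVal[s] - bg)) next
    d2 <- (rowIdx - seedXY[s, 1])^2 + (colIdx - seedXY[s, 2])^2
    take <- inComp & (d2 < claimDist | (d2 == claimDist & claim > s))
    claim[take] <- s
    claimDist[take] <- d2[take]
  }

  areas <- tabulate(claim[claim > 0], nbins = nSeed)
  keep <- which(areas >= sizeMin & areas <= sizeMax)
  if (!length(keep)) return(emptySet())
  keep <- keep[order(areas[keep], decreasing = TRUE)]
  lab <- matrix(0L, nr, nc)
  recs <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    s <- keep[i]
    px <- which(claim == s, arr.ind = TRUE)
    lab[px] <- i
    w <- pmax(img[px] - bg, 0)
    if (sum(w) == 0) w <- rep(1, nrow(px))
    # intensity-weighted centroid, 0-based pixel indices scaled to um
    recs[[i]] <- data.frame(
      id = i,
      x_um = (sum((px[, 1] - 1) * w) / sum(w)) * pixelSize,
      y_um = (sum((px[, 2] - 1) * w) / sum(w)) * pixelSize,
      area_px = nrow(px),
      is_perivascular = FALSE)
  }
  new("RoiSet", labelImage = lab, rois = do.call(rbind, recs),
      pixelSize = pixelSize, fovArea = fov, sizeRange = c(sizeMin, sizeMax))
}

#' Pairwise centroid distances between ROIs
#'
#' Euclidean distance in micrometers between every unordered ROI pair,
#' computed on the X-Y plane.
#'
#' @param roiset a [RoiSet] with at least 2 ROIs.
#' @return data.frame with columns `roi_i`, `roi_j` (i < j), `distance_um`.
#' @export
pairwiseDistances <- function(roiset) {
  r <- rois(roiset)
  if (nrow(r) < 2) stop("need at least 2 ROIs")
  cmb <- utils::combn(nrow(r), 2)
  data.frame(
    roi_i = r$id[cmb[1, ]], roi_j = r$id[cmb[2, ]],
    distance_um = sqrt((r$x_um[cmb[1, ]] - r$x_um[cmb[2, ]])^2 +
                       (r$y_um[cmb[1, ]] - r$y_um[cmb[2, ]])^2))
}
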