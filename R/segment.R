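#' Segmentation parameters for wide-field gastruloid images
#'
#' Fixed-parameter pipeline settings: Gaussian blur sigma 5 px, morphology
#' radius 10 px, minimal marker separation 70 px, minimal object size
#' 1000 px, border-touching objects excluded.
#'
#' @param gaussian_sigma,morph_radius,marker_min_distance,min_object_size,exclude_border
#'   see description.
#' @return named list of class `"segmentation_params"`.
#' @export
segmentation_params <- function(gaussian_sigma = 5, morph_radius = 10,
                                marker_min_distance = 70,
                                min_object_size = 1000,
                                exclude_border = TRUE) {
  structure(list(gaussian_sigma = gaussian_sigma, morph_radius = morph_radius,
                 marker_min_distance = marker_min_distance,
                 min_object_size = min_object_size,
                 exclude_border = exclude_border),
            class = "segmentation_params")
}

#' Segment gastruloids in a wide-field image
#'
#' Deterministic pipeline: Gaussian blur (sigma 5) -> Otsu global threshold
#' on the blurred image -> dilation then opening (disc radius 10) ->
#' Euclidean distance transform of the foreground -> local maxima with
#' minimal separation 70 px as markers -> Scharr gradient magnitude of the
#' blurred image as elevation map -> marker-based watershed -> objects
#' smaller than 1000 px or touching the image border dropped.
#'
#' @param image single-channel 2D image, matrix `[x, y]`, any intensity
#'   scale (normalized internally).
#' @param params a [segmentation_params()].
#' @return list of binary masks (one per surviving object), each the full
#'   image size.
#' @export
segment_gastruloids <- function(image, params = segmentation_params()) {
  img <- as.matrix(image)
  rng <- range(img)
  if (diff(rng) <= 0) {
    warning("constant image: nothing to segment")
    return(list())
  }
  img <- (img - rng[1]) / diff(rng)
  blurred <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                      sigma = params$gaussian_sigma))
  th <- EBImage::otsu(EBImage::Image(blurred), range = c(0, 1))
  bin <- blurred > th
  if (!any(bin)) {
    warning("no foreground after Otsu threshold")
    return(list())
  }
  brush <- EBImage::makeBrush(2 * params$morph_radius + 1, shape = "disc")
  bin <- EBImage::dilate(bin, brush)
  bin <- EBImage::opening(bin, brush)
  if (!any(bin)) {
    warning("no foreground after morphology")
    return(list())
  }
  dm <- EBImage::distmap(EBImage::Image(bin * 1))
  markers <- distance_peaks(as.matrix(dm), params$marker_min_distance)
  if (nrow(markers) == 0) {
    warning("no markers found")
    return(list())
  }
  elevation <- scharr_magnitude(blurred)
  seeds <- matrix(0L, nrow(img), ncol(img))
  seeds[cbind(markers[, 1], markers[, 2])] <- seq_len(nrow(markers))
  bg <- nrow(markers) + 1L  # background marker: the image border ring
  seeds[1, ] <- seeds[nrow(img), ] <- bg
  seeds[, 1] <- seeds[, ncol(img)] <- bg
  lab <- watershed_markers_(elevation, seeds)
  lab[lab == bg] <- 0L
  keep_masks(lab, params)
}

# Scharr gradient magnitude (3x3), the elevation map of the watershed
scharr_magnitude <- function(img) {
  kx <- matrix(c(-3, -10, -3, 0, 0, 0, 3, 10, 3), 3, 3) / 16
  gx <- as.matrix(EBImage::filter2(EBImage::Image(img), kx))
  gy <- as.matrix(EBImage::filter2(EBImage::Image(img), t(kx)))
  sqrt(gx^2 + gy^2)
}

# local maxima of the distance map with a minimal mutual distance;
# plateaus are reduced to their centroids, then kept greedily by height
distance_peaks <- function(dm, min_distance) {
  half <- max(1L, floor(min_distance / 2))
  mx <- as.matrix(EBImage::dilate(EBImage::Image(dm),
                                  EBImage::makeBrush(2 * half + 1, "disc")))
  peak <- dm > 0 & dm >= mx - 1e-9
  if (!any(peak)) return(matrix(numeric(0), 0, 2))
  lab <- EBImage::bwlabel(peak * 1)
  ids <- seq_len(max(lab))
  cent <- t(vapply(ids, function(i) {
    w <- which(lab == i, arr.ind = TRUE)
    c(mean(w[, 1]), mean(w[, 2]), dm[w[1, 1], w[1, 2]])
  }, numeric(3)))
  cent <- cent[order(-cent[, 3]), , drop = FALSE]
  kept <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(cent))) {
    p <- cent[i, 1:2]
    if (nrow(kept) == 0 ||
        all((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2 >= min_distance^2))
      kept <- rbind(kept, p)
  }
  round(kept)
}

keep_masks <- function(lab, params) {
  W <- nrow(lab); H <- ncol(lab)
  out <- list()
  for (i in seq_len(max(lab))) {
    m <- lab == i
    sz <- sum(m)
    if (sz < params$min_object_size) next
    # the border ring itself carries the background marker, so an object
    # running off the image stops one pixel short of it: test a 2-px band
    if (params$exclude_border &&
        (any(m[1:2, ]) || any(m[(W - 1):W, ]) ||
         any(m[, 1:2]) || any(m[, (H - 1):H]))) next
    out[[length(out) + 1]] <- m
  }
  out
}

#' Binary mask of a time-lapse frame
#'
#' Converts a maximum-projection frame into a single tissue mask: Gaussian
#' blur (51 x 51 kernel), fixed threshold (default 40/255, overridable per
#' frame), then hole closing by 40 iterations of 5 x 5 dilation followed by
#' 40 iterations of 5 x 5 erosion. Already-binary simulated images skip the
#' blur/threshold and instead use 4 iterations of erosion then dilation to
#' remove single-site speckle.
#'
#' @param image matrix `[x, y]`; intensities on any scale (scaled to
#'   `[0, 1]` by its maximum if above 1).
#' @param threshold intensity threshold on the `[0, 1]` scale.
#' @param simulated logical: treat `image` as an already-binary simulated
#'   label/mask image.
#' @param iterations morphology iteration count (40 for microscopy, 4 for
#'   simulated input).
#' @return logical mask matrix.
#' @export
mask_from_timelapse_frame <- function(image, threshold = 40 / 255,
                                      simulated = FALSE,
                                      iterations = if (simulated) 4L else 40L) {
  img <- as.matrix(image)
  box5 <- EBImage::makeBrush(5, "box")
  if (simulated) {
    m <- img > 0
    for (i in seq_len(iterations)) m <- EBImage::erode(m, box5)
    for (i in seq_len(iterations)) m <- EBImage::dilate(m, box5)
  } else {
    if (max(img) > 1) img <- img / max(img)
    # 51 x 51 kernel: OpenCV's default sigma for that size is ~8 px
    blurred <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = 8))
    m <- blurred > threshold
    for (i in seq_len(iterations)) m <- EBImage::dilate(m, box5)
    for (i in seq_len(iterations)) m <- EBImage::erode(m, box5)
  }
  m <- as.matrix(m) > 0
  if (!any(m)) stop("empty mask after thresholding")
  m
}
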