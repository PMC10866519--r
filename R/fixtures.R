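#' Synthetic wide-field image with ground truth
#'
#' Renders soft-edged blobs (hard discs blurred with a Gaussian) plus
#' additive Gaussian noise, emulating a DAPI-stained gastruloid wide-field
#' image after denoising. Ground-truth masks are emitted alongside for
#' segmentation scoring. Deterministic at a fixed seed.
#'
#' @param width,height image size in pixels.
#' @param centers `k x 2` matrix of blob centers.
#' @param radii vector of blob radii (recycled).
#' @param blur_sigma edge softness (Gaussian sigma, px).
#' @param noise_sd additive noise SD on the `[0, 1]` intensity scale.
#' @param bit_depth quantization depth (16 mirrors microscope output).
#' @param seed integer seed.
#' @return list with `image` (matrix in `[0, 1]`, quantized) and `masks`
#'   (list of logical ground-truth masks).
#' @export
make_widefield_image <- function(width = 512, height = 512,
                                 centers = rbind(c(160, 256), c(370, 256)),
                                 radii = 60, blur_sigma = 4, noise_sd = 0.02,
                                 bit_depth = 16, seed = 1) {
  set.seed(seed)
  centers <- matrix(as.numeric(centers), ncol = 2)
  radii <- rep_len(radii, nrow(centers))
  img <- matrix(0, width, height)
  masks <- vector("list", nrow(centers))
  xs <- matrix(seq_len(width), width, height)
  ys <- matrix(seq_len(height), width, height, byrow = TRUE)
  for (i in seq_len(nrow(centers))) {
    d2 <- (xs - centers[i, 1])^2 + (ys - centers[i, 2])^2
    masks[[i]] <- d2 <= radii[i]^2
    img[masks[[i]]] <- 1
  }
  if (blur_sigma > 0)
    img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = blur_sigma))
  img <- img + stats::rnorm(length(img), sd = noise_sd)
  img <- pmin(pmax(img, 0), 1)
  levels <- 2^bit_depth - 1
  img <- round(img * levels) / levels
  list(image = img, masks = masks)
}

#' Analytic shape families with known lobe structure
#'
#' Generates contours (and rasterized masks) of shapes whose LOCO-EFA
#' spectra are known by construction: `circle` (no lobes), `ellipse`
#' (2-lobe dominant), `flower` with `lobes` lobes
#' (`r(theta) = R * (1 + amplitude * cos(lobes * theta))`), and `snowman`
#' (two overlapping discs, mixing 2- and 3-lobe content).
#'
#' @param kind `"circle"`, `"ellipse"`, `"flower"` or `"snowman"`.
#' @param radius base radius `R` (circle/flower/snowman).
#' @param axes semi-axes `c(a, b)` of the ellipse.
#' @param amplitude,lobes flower modulation amplitude and lobe count
#'   (`amplitude < 1/(lobes^2)` guards against self-intersection... the
#'   practical bound `amplitude <= 0.35` is enforced).
#' @param separation center separation of the snowman discs, in units of
#'   `radius` (< 2 so the discs overlap); the second disc has radius
#'   `0.75 * radius`.
#' @param n_points contour sampling density.
#' @param center shape center.
#' @param mask_dim `c(width, height)` of the rasterized mask (`NULL` picks a
#'   size fitting the shape).
#' @return list with `contour` (`n x 2`, counterclockwise) and `mask`
#'   (logical matrix).
#' @export
make_shape_family <- function(kind = c("circle", "ellipse", "flower", "snowman"),
                              radius = 50, axes = c(60, 30), amplitude = 0.2,
                              lobes = 3, separation = 1.2, n_points = 720,
                              center = NULL, mask_dim = NULL) {
  kind <- match.arg(kind)
  if (kind == "flower" && (amplitude < 0 || amplitude > 0.35))
    stop("flower amplitude outside [0, 0.35]: risk of self-intersection")
  if (kind == "snowman" && separation >= 2)
    stop("snowman discs must overlap (separation < 2)")
  th <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  ext <- switch(kind, circle = radius, ellipse = max(axes),
                flower = radius * (1 + amplitude),
                snowman = radius * (1 + separation))
  if (is.null(mask_dim)) mask_dim <- rep(ceiling(2 * ext + 20), 2)
  if (is.null(center)) center <- mask_dim / 2
  if (kind == "snowman") {
    c1 <- center - c(separation * radius / 2, 0)
    c2 <- center + c(separation * radius / 2, 0)
    r2 <- 0.75 * radius
    contour <- union_two_discs(c1, radius, c2, r2, n_points)
    xs <- matrix(seq_len(mask_dim[1]), mask_dim[1], mask_dim[2])
    ys <- matrix(seq_len(mask_dim[2]), mask_dim[1], mask_dim[2], byrow = TRUE)
    mask <- ((xs - c1[1])^2 + (ys - c1[2])^2 <= radius^2) |
      ((xs - c2[1])^2 + (ys - c2[2])^2 <= r2^2)
  } else {
    r <- switch(kind,
                circle = rep(radius, n_points),
                ellipse = axes[1] * axes[2] /
                  sqrt((axes[2] * cos(th))^2 + (axes[1] * sin(th))^2),
                flower = radius * (1 + amplitude * cos(lobes * th)))
    contour <- cbind(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
    xs <- matrix(seq_len(mask_dim[1]), mask_dim[1], mask_dim[2])
    ys <- matrix(seq_len(mask_dim[2]), mask_dim[1], mask_dim[2], byrow = TRUE)
    dx <- xs - center[1]; dy <- ys - center[2]
    mask <- switch(kind,
                   circle = dx^2 + dy^2 <= radius^2,
                   ellipse = (dx / axes[1])^2 + (dy / axes[2])^2 <= 1,
                   flower = {
                     rr <- sqrt(dx^2 + dy^2)
                     ang <- atan2(dy, dx)
                     rr <= radius * (1 + amplitude * cos(lobes * ang))
                   })
  }
  list(contour = contour, mask = mask)
}

# outline of the union of two overlapping discs, counterclockwise
union_two_discs <- function(c1, r1, c2, r2, n_points) {
  d <- sqrt(sum((c2 - c1)^2))
  stopifnot(d < r1 + r2, d > abs(r1 - r2))
  # intersection half-angle seen from each center
  a1 <- acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  base <- atan2(c2[2] - c1[2], c2[1] - c1[1])
  n1 <- max(8, round(n_points * (pi - a1) / pi))
  n2 <- max(8, round(n_points * (pi - a2) / pi))
  th1 <- seq(base + a1, base + 2 * pi - a1, length.out = n1)
  th2 <- seq(base + pi + a2, base + 3 * pi - a2, length.out = n2)
  p1 <- cbind(c1[1] + r1 * cos(th1), c1[2] + r1 * sin(th1))
  p2 <- cbind(c2[1] + r2 * cos(th2), c2[2] + r2 * sin(th2))
  pts <- rbind(p2, p1)
  if (polygon_area(pts[, 1], pts[, 2]) < 0) pts <- pts[nrow(pts):1, ]
  colnames(pts) <- c("x", "y")
  pts
}

#' Tracks advected by an incompressible stretch flow
#'
#' Cells inside an elliptical blob are advected by the area-preserving flow
#' `(x, y) -> (k_t * x, y / k_t)` with `k_t` interpolating geometrically
#' from 1 to `k`, optionally composed with a rigid rotation and drift and
#' with positional jitter -- a closed-form stand-in for convergent
#' extension used to validate the trajectory pipeline.
#'
#' @param k total stretch factor.
#' @param n_cells number of tracked cells.
#' @param frames number of frames.
#' @param rotation rigid rotation per frame (radians).
#' @param drift rigid translation per frame, `c(dx, dy)`.
#' @param jitter SD of positional jitter per frame.
#' @param blob_axes initial blob semi-axes.
#' @param mask_dim size of the emitted masks.
#' @param seed integer seed.
#' @return list with `tracks` (cell_id, frame, x, y), `masks` (one per
#'   frame), and `truth` (per-frame blob center, axes, angle).
#' @export
make_affine_flow_tracks <- function(k = 1.5, n_cells = 20, frames = 17,
                                    rotation = 0, drift = c(0, 0), jitter = 0,
                                    blob_axes = c(60, 60), mask_dim = c(320, 320),
                                    seed = 1) {
  set.seed(seed)
  ctr0 <- mask_dim / 2
  # rejection-sample initial positions inside the blob (away from the rim)
  pos <- matrix(NA_real_, 0, 2)
  while (nrow(pos) < n_cells) {
    cand <- cbind(stats::runif(n_cells, -1, 1), stats::runif(n_cells, -1, 1))
    cand <- cand[rowSums(cand^2) <= 0.9^2, , drop = FALSE]
    pos <- rbind(pos, cand)
  }
  pos <- pos[seq_len(n_cells), , drop = FALSE] %*% diag(blob_axes)
  kts <- k^(seq(0, 1, length.out = frames))
  tracks <- list(); masks <- vector("list", frames); truth <- list()
  for (f in seq_len(frames)) {
    kt <- kts[f]
    p <- cbind(pos[, 1] * kt, pos[, 2] / kt)
    ang <- rotation * (f - 1)
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    ctr <- ctr0 + drift * (f - 1)
    p <- p %*% t(R)
    p <- sweep(p, 2, ctr, "+")
    if (jitter > 0) p <- p + matrix(stats::rnorm(2 * n_cells, sd = jitter), ncol = 2)
    tracks[[f]] <- data.frame(cell_id = seq_len(n_cells), frame = f,
                              x = p[, 1], y = p[, 2])
    ax <- c(blob_axes[1] * kt, blob_axes[2] / kt)
    xs <- matrix(seq_len(mask_dim[1]), mask_dim[1], mask_dim[2])
    ys <- matrix(seq_len(mask_dim[2]), mask_dim[1], mask_dim[2], byrow = TRUE)
    dx <- xs - ctr[1]; dy <- ys - ctr[2]
    u <- cos(ang) * dx + sin(ang) * dy
    v <- -sin(ang) * dx + cos(ang) * dy
    masks[[f]] <- (u / ax[1])^2 + (v / ax[2])^2 <= 1
    truth[[f]] <- data.frame(frame = f, cx = ctr[1], cy = ctr[2],
                             long = max(ax), short = min(ax), angle = ang)
  }
  list(tracks = do.call(rbind, tracks), masks = masks,
       truth = do.call(rbind, truth))
}
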