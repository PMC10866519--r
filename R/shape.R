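#' Extract the outline of a binary mask
#'
#' Traces the 0.5-level boundary of the (largest) foreground object with a
#' marching-squares contour, giving sub-site resolution. The contour is
#' returned closed (first point not repeated) and oriented counterclockwise;
#' clockwise input is reversed silently.
#'
#' @param mask logical or 0/1 matrix, indexed `[x, y]`.
#' @param min_points minimal number of boundary points for a usable contour.
#' @param smooth_sigma light Gaussian smoothing of the mask before the
#'   level-set trace; sub-site interpolation across the smoothed edge
#'   suppresses the staircase bias of a hard binary boundary (0 disables).
#' @return a `K x 2` matrix of boundary points (class `"contour"` attribute
#'   kept informal), in the mask's coordinate system.
#' @export
extract_contour <- function(mask, min_points = 8, smooth_sigma = 1) {
  m <- (as.matrix(mask) > 0) * 1
  if (!any(m > 0)) stop("empty mask: no foreground")
  ncomp <- max(EBImage::bwlabel(m))
  if (ncomp > 1)
    warning("mask has ", ncomp, " components; taking the largest contour")
  pad <- max(2L, ceiling(3 * smooth_sigma))
  z <- matrix(0, nrow(m) + 2 * pad, ncol(m) + 2 * pad)
  z[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))] <- m
  if (smooth_sigma > 0)
    z <- as.matrix(EBImage::gblur(EBImage::Image(z), sigma = smooth_sigma))
  cl <- grDevices::contourLines(x = seq_len(nrow(z)), y = seq_len(ncol(z)),
                                z = z, levels = 0.5)
  if (length(cl) == 0) stop("no 0.5-level contour found")
  areas <- vapply(cl, function(cc) abs(polygon_area(cc$x, cc$y)), numeric(1))
  cc <- cl[[which.max(areas)]]
  pts <- cbind(cc$x - pad, cc$y - pad)
  if (nrow(pts) > 1 && all(abs(pts[1, ] - pts[nrow(pts), ]) < 1e-9))
    pts <- pts[-nrow(pts), , drop = FALSE]
  if (nrow(pts) < min_points)
    stop("degenerate object: contour has fewer than ", min_points, " points")
  if (polygon_area(pts[, 1], pts[, 2]) < 0) pts <- pts[nrow(pts):1, , drop = FALSE]
  colnames(pts) <- c("x", "y")
  pts
}

# signed area (shoelace); positive for counterclockwise
polygon_area <- function(x, y) {
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' Elliptic Fourier coefficients of a closed contour
#'
#' Kuhl-Giardina elliptic Fourier analysis of the arc-length parameterized
#' boundary: `x(t) = a0 + sum_n alpha_n cos(2*pi*n*t/T) + beta_n sin(...)`,
#' analogously `y(t)` with `gamma_n`, `delta_n`.
#'
#' @param contour `K x 2` matrix of boundary points (closed polygon, first
#'   point not repeated), e.g. from [extract_contour()].
#' @param n_harmonics number of harmonics.
#' @return list with `a0`, `c0` (the DC offsets), `coef` (an
#'   `n_harmonics x 4` matrix with columns `alpha`, `beta`, `gamma`,
#'   `delta`) and `perimeter`.
#' @export
efa_coefficients <- function(contour, n_harmonics = 20) {
  p <- as.matrix(contour)
  if (nrow(p) < 3) stop("need at least 3 contour points")
  dx <- c(diff(p[, 1]), p[1, 1] - p[nrow(p), 1])
  dy <- c(diff(p[, 2]), p[1, 2] - p[nrow(p), 2])
  dt <- sqrt(dx^2 + dy^2)
  keep <- dt > 1e-12
  if (sum(keep) < 3) stop("degenerate contour: zero perimeter")
  dx <- dx[keep]; dy <- dy[keep]; dt <- dt[keep]
  x1 <- p[keep, 1][1]; y1 <- p[keep, 2][1]
  tt <- cumsum(dt)
  Tp <- tt[length(tt)]
  t0 <- c(0, tt[-length(tt)])
  n <- seq_len(n_harmonics)
  w <- 2 * pi / Tp
  # outer products: rows = harmonics, cols = segments
  cos1 <- cos(outer(n, tt) * w); cos0 <- cos(outer(n, t0) * w)
  sin1 <- sin(outer(n, tt) * w); sin0 <- sin(outer(n, t0) * w)
  fac <- Tp / (2 * pi^2 * n^2)
  alpha <- fac * as.vector((cos1 - cos0) %*% (dx / dt))
  beta  <- fac * as.vector((sin1 - sin0) %*% (dx / dt))
  gamma <- fac * as.vector((cos1 - cos0) %*% (dy / dt))
  delta <- fac * as.vector((sin1 - sin0) %*% (dy / dt))
  # DC component (Kuhl & Giardina)
  xi  <- c(0, cumsum(dx)[-length(dx)]) - dx / dt * t0
  eta <- c(0, cumsum(dy)[-length(dy)]) - dy / dt * t0
  a0 <- x1 + sum(dx / (2 * dt) * (tt^2 - t0^2) + xi * (tt - t0)) / Tp
  c0 <- y1 + sum(dy / (2 * dt) * (tt^2 - t0^2) + eta * (tt - t0)) / Tp
  coef <- cbind(alpha = alpha, beta = beta, gamma = gamma, delta = delta)
  list(a0 = a0, c0 = c0, coef = coef, perimeter = Tp)
}

#' Reconstruct a contour from elliptic Fourier coefficients
#'
#' @param efa result of [efa_coefficients()].
#' @param n_points number of points of the reconstruction.
#' @param n_harmonics how many harmonics to use (defaults to all).
#' @return `n_points x 2` matrix.
#' @export
efa_reconstruct <- function(efa, n_points = 400, n_harmonics = nrow(efa$coef)) {
  t <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  n <- seq_len(n_harmonics)
  C <- cos(outer(t, n)); S <- sin(outer(t, n))
  x <- efa$a0 + C %*% efa$coef[n, "alpha"] + S %*% efa$coef[n, "beta"]
  y <- efa$c0 + C %*% efa$coef[n, "gamma"] + S %*% efa$coef[n, "delta"]
  cbind(x = as.vector(x), y = as.vector(y))
}

#' LOCO-EFA shape spectrum
#'
#' Decomposes each elliptic Fourier harmonic's coefficient matrix into two
#' counter-rotating circular phasors with amplitudes `lambda+` and
#' `lambda-`. Relative to the base traversal (the prograde first harmonic),
#' a prograde phasor of harmonic `l + 1` and a retrograde phasor of harmonic
#' `l - 1` both modulate the outline with `l` lobes, so the l-lobe mode
#' amplitude combines the two, including their phase interference:
#' `L_l = sqrt(lp^2 + lm^2 + 2*lp*lm*cos(zeta+_(l+1) + zeta-_(l-1) -
#' 2*zeta+_1))`. `L_1` is the base-circle amplitude and thus a measure of
#' linear size. The combination is invariant under rotation, translation and
#' starting-point shifts; an `r(theta) = R(1 + a*cos(l*theta))` flower gives
#' `L_l ~= a*R`.
#'
#' @param efa result of [efa_coefficients()] (needs at least
#'   `n_modes + 1` harmonics).
#' @param n_modes number of lobe modes to report.
#' @return object of class `"shape_spectrum"`: list with `L` (modes
#'   1..n_modes), `ratios` (`L_n/L_1` for n >= 2), and the per-harmonic
#'   phasor amplitudes.
#' @export
loco_efa <- function(efa, n_modes = 10) {
  cf <- efa$coef
  if (nrow(cf) < n_modes + 1)
    stop("need at least n_modes + 1 = ", n_modes + 1, " harmonics")
  al <- cf[, "alpha"]; be <- cf[, "beta"]; ga <- cf[, "gamma"]; de <- cf[, "delta"]
  lp <- 0.5 * sqrt((al + de)^2 + (ga - be)^2)
  lm <- 0.5 * sqrt((al - de)^2 + (ga + be)^2)
  zp <- atan2(ga - be, al + de)
  zm <- atan2(ga + be, al - de)
  L <- numeric(n_modes)
  L[1] <- lp[1]
  if (n_modes >= 2) {
    l <- 2:n_modes
    L[l] <- sqrt(lp[l + 1]^2 + lm[l - 1]^2 +
                   2 * lp[l + 1] * lm[l - 1] * cos(zp[l + 1] + zm[l - 1] - 2 * zp[1]))
  }
  structure(list(L = L, ratios = if (n_modes >= 2) L[-1] / L[1] else numeric(0),
                 lambda_plus = lp, lambda_minus = lm, n_modes = n_modes),
            class = "shape_spectrum")
}

#' @export
print.shape_spectrum <- function(x, ...) {
  cat("LOCO-EFA spectrum: L1 =", format(x$L[1], digits = 4), "\n")
  if (x$n_modes >= 3)
    cat(sprintf("  L2/L1 = %.4f, L3/L1 = %.4f\n", x$ratios[1], x$ratios[2]))
  invisible(x)
}

#' Scaled LOCO-EFA ratios
#'
#' Divides every `L_n` (n >= 2) by `L_1`, making the spectrum scale-free so
#' that simulated (lattice-unit) and measured (micron) shapes are
#' comparable.
#'
#' @param spectrum a `"shape_spectrum"` from [loco_efa()].
#' @return named numeric vector `L2_L1`, `L3_L1`, ...
#' @export
scaled_spectrum <- function(spectrum) {
  if (spectrum$L[1] <= 0) stop("degenerate spectrum: L1 = 0")
  r <- spectrum$ratios
  names(r) <- paste0("L", seq_along(r) + 1, "_L1")
  r
}

#' Shape spectrum of a mask or contour
#'
#' Convenience wrapper: outline extraction (for masks), elliptic Fourier
#' analysis and LOCO-EFA in one call.
#'
#' @param x binary mask matrix or a `K x 2` contour.
#' @param n_modes,n_harmonics see [loco_efa()] and [efa_coefficients()].
#' @return a `"shape_spectrum"`.
#' @export
shape_spectrum <- function(x, n_modes = 10, n_harmonics = 20) {
  contour <- if (is.matrix(x) && ncol(x) == 2 && !all(x %in% c(0, 1, FALSE, TRUE)))
    x else extract_contour(x)
  loco_efa(efa_coefficients(contour, n_harmonics), n_modes)
}

#' Rasterize a closed contour to a binary mask
#'
#' Even-odd scanline fill of the polygon; the inverse of
#' [extract_contour()] up to discretization.
#'
#' @param contour `K x 2` matrix.
#' @param dim `c(width, height)` of the output mask.
#' @return logical matrix `[x, y]`.
#' @export
rasterize_contour <- function(contour, dim) {
  px <- contour[, 1]; py <- contour[, 2]
  W <- dim[1]; H <- dim[2]
  m <- matrix(FALSE, W, H)
  x2 <- c(px[-1], px[1]); y2 <- c(py[-1], py[1])
  for (yy in seq_len(H)) {
    crosses <- ((py <= yy) & (y2 > yy)) | ((y2 <= yy) & (py > yy))
    if (!any(crosses)) next
    xi <- px[crosses] + (yy - py[crosses]) / (y2[crosses] - py[crosses]) *
      (x2[crosses] - px[crosses])
    xi <- sort(xi)
    for (k in seq(1, length(xi) - 1, by = 2)) {
      lo <- max(1L, ceiling(xi[k])); hi <- min(W, floor(xi[k + 1]))
      if (lo <= hi) m[lo:hi, yy] <- TRUE
    }
  }
  m
}

#' Shape spectra of a population of masks
#'
#' @param masks list of binary masks (or contours).
#' @param n_modes,n_harmonics see [loco_efa()].
#' @return data frame with one row per shape: `shape_id`, `L1..L<n>`,
#'   `L2_over_L1`, `L3_over_L1`.
#' @export
spectra_table <- function(masks, n_modes = 10, n_harmonics = 20) {
  rows <- lapply(seq_along(masks), function(i) {
    sp <- shape_spectrum(masks[[i]], n_modes, n_harmonics)
    out <- c(shape_id = i, stats::setNames(sp$L, paste0("L", seq_len(n_modes))),
             L2_over_L1 = sp$ratios[1], L3_over_L1 = sp$ratios[2])
    as.data.frame(as.list(out))
  })
  do.call(rbind, rows)
}
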