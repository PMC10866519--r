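#' Least-squares ellipse fit to a mask outline
#'
#' Direct least-squares conic fit (Fitzgibbon) to the boundary points of a
#' mask, returning center, semi-axes (long >= short) and the angle `theta`
#' of the long axis to the x-axis in `(-pi/2, pi/2]`. Near-circular masks
#' (axis ratio below `ratio_min`) get `theta_reliable = FALSE`, since their
#' orientation is ill-defined.
#'
#' @param mask binary matrix, or a `K x 2` matrix of boundary points.
#' @param ratio_min axis ratio under which `theta` is flagged unreliable.
#' @return list with `center`, `long`, `short` (semi-axes), `theta`,
#'   `theta_reliable`.
#' @export
fit_ellipse <- function(mask, ratio_min = 1.05) {
  pts <- if (is.matrix(mask) && ncol(mask) == 2 && nrow(mask) >= 5 &&
             !all(mask %in% c(0, 1))) mask else extract_contour(mask)
  x <- pts[, 1]; y <- pts[, 2]
  mx <- mean(x); my <- mean(y)
  x <- x - mx; y <- y - my
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  # keep the eigenvector satisfying the ellipse constraint 4ac - b^2 > 0
  cond <- 4 * Re(ev$vectors[1, ]) * Re(ev$vectors[3, ]) - Re(ev$vectors[2, ])^2
  a1 <- Re(ev$vectors[, which(cond > 0)[1]])
  if (length(a1) != 3 || any(!is.finite(a1))) stop("ellipse fit failed")
  par <- c(a1, Tm %*% a1)  # (A, B, C, D, E, F) of Ax^2+Bxy+Cy^2+Dx+Ey+F=0
  ell <- conic_to_ellipse(par)
  ell$center <- ell$center + c(mx, my)
  ratio <- ell$long / ell$short
  ell$theta_reliable <- is.finite(ratio) && ratio >= ratio_min
  ell
}

conic_to_ellipse <- function(p) {
  A <- p[1]; B <- p[2]; C <- p[3]; D <- p[4]; E <- p[5]; F <- p[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) stop("fitted conic is not an ellipse")
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 - B * D * E + den * F)
  s <- sqrt((A - C)^2 + B^2)
  a <- -sqrt(num * (A + C + s)) / den
  b <- -sqrt(num * (A + C - s)) / den
  theta <- if (abs(B) < 1e-12 && A <= C) 0
           else if (abs(B) < 1e-12) pi / 2
           else atan2(C - A - s, B)
  axes <- sort(c(a, b), decreasing = TRUE)
  # theta above is the angle of the axis with semi-length a; make it the long axis
  if (a < b) theta <- theta + pi / 2
  theta <- ((theta + pi / 2) %% pi) - pi / 2
  if (theta <= -pi / 2 + 1e-12) theta <- theta + pi
  list(center = c(cx, cy), long = axes[1], short = axes[2], theta = theta)
}

#' Ellipse fits of a mask time series, with angle disambiguation
#'
#' Fits an ellipse to each frame's mask and resolves the pi/2 ambiguity of
#' the reported orientation by choosing, per frame, the representative among
#' `theta + k*pi/2` closest to the previous frame's angle; the series is
#' additionally unwrapped so it is continuous (no pi jumps). Frames whose
#' fit fails get interpolated center/angle, with a warning.
#'
#' @param masks list of binary masks (one per frame).
#' @return data frame: `frame`, `cx`, `cy`, `long`, `short`, `theta`,
#'   `theta_reliable`.
#' @export
fit_ellipse_series <- function(masks) {
  n <- length(masks)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    fit <- tryCatch(fit_ellipse(masks[[i]]), error = function(e) NULL)
    rows[[i]] <- if (is.null(fit))
      data.frame(frame = i, cx = NA, cy = NA, long = NA, short = NA,
                 theta = NA, theta_reliable = FALSE)
    else
      data.frame(frame = i, cx = fit$center[1], cy = fit$center[2],
                 long = fit$long, short = fit$short, theta = fit$theta,
                 theta_reliable = fit$theta_reliable)
  }
  df <- do.call(rbind, rows)
  if (any(is.na(df$theta))) {
    warning("ellipse fit failed for ", sum(is.na(df$theta)),
            " frame(s); interpolating")
    for (col in c("cx", "cy", "long", "short", "theta"))
      df[[col]] <- stats::approx(df$frame, df[[col]], df$frame, rule = 2)$y
  }
  # pi/2 disambiguation against the previous frame
  for (i in seq_len(n)[-1]) {
    k <- round((df$theta[i - 1] - df$theta[i]) / (pi / 2))
    df$theta[i] <- df$theta[i] + k * pi / 2
  }
  df
}

#' Correct tracks for tissue rotation and drift
#'
#' Transforms tracked positions into the gastruloid frame: per frame the
#' fitted ellipse center is subtracted and positions are rotated by
#' `-theta`, so the long axis maps onto x and the short axis onto y.
#'
#' @param tracks data frame with columns `cell_id`, `frame`, `x`, `y`.
#' @param ellipses result of [fit_ellipse_series()] covering the tracked
#'   frames.
#' @return `tracks` with `x`, `y` replaced by gastruloid-frame coordinates.
#' @export
correct_rotation_drift <- function(tracks, ellipses) {
  stopifnot(all(c("cell_id", "frame", "x", "y") %in% names(tracks)))
  idx <- match(tracks$frame, ellipses$frame)
  if (any(is.na(idx))) stop("missing ellipse fit for some tracked frames")
  th <- ellipses$theta[idx]
  dx <- tracks$x - ellipses$cx[idx]
  dy <- tracks$y - ellipses$cy[idx]
  out <- tracks
  out$x <- cos(-th) * dx - sin(-th) * dy
  out$y <- sin(-th) * dx + cos(-th) * dy
  attr(out, "final_theta") <- ellipses$theta[nrow(ellipses)]
  out
}

#' Axis projections of corrected tracks
#'
#' For each cell, the net movement along the gastruloid's long axis
#' (`v_l = x_end - x_start`) and short axis (`v_s = y_end - y_start`) in
#' the rotation/drift-corrected frame, normalized by the tissue's long-axis
#' length `L = 2 * long` and short-axis length `S = 2 * short` of the final
#' ellipse. Cells are classified by their short-axis motion: `inward`
#' (towards the long axis), `outward`, or `crossing` (sign change).
#'
#' @param corrected corrected tracks from [correct_rotation_drift()].
#' @param final_ellipse one row (or list) with `long` and `short`
#'   semi-axes of the final frame.
#' @return data frame: one row per cell with start/end positions, `v_l`,
#'   `v_s`, `v_l_over_L`, `v_s_over_S`, `direction`.
#' @export
project_on_axes <- function(corrected, final_ellipse) {
  L <- 2 * final_ellipse$long
  S <- 2 * final_ellipse$short
  ord <- corrected[order(corrected$cell_id, corrected$frame), ]
  split_rows <- split(ord, ord$cell_id)
  rows <- lapply(split_rows, function(d) {
    first <- d[1, ]; last <- d[nrow(d), ]
    v_l <- last$x - first$x
    v_s <- last$y - first$y
    dir <- if (sign(first$y) != sign(last$y)) "crossing"
           else if (abs(last$y) < abs(first$y)) "inward" else "outward"
    data.frame(cell_id = first$cell_id, x_start = first$x, y_start = first$y,
               x_end = last$x, y_end = last$y, v_l = v_l, v_s = v_s,
               v_l_over_L = v_l / L, v_s_over_S = v_s / S, direction = dir)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Net movement vectors for plotting
#'
#' The per-cell net movement (end minus start, in the corrected frame)
#' anchored at the final position, with an optional arrow-length divisor
#' (the display convention uses 1/20 to avoid overlapping arrows).
#'
#' @param projections result of [project_on_axes()].
#' @param scale_divisor arrow shrink factor.
#' @return data frame: `cell_id`, `x`, `y`, `dx`, `dy`, `angle`.
#' @export
net_movement_vectors <- function(projections, scale_divisor = 20) {
  data.frame(cell_id = projections$cell_id,
             x = projections$x_end, y = projections$y_end,
             dx = projections$v_l / scale_divisor,
             dy = projections$v_s / scale_divisor,
             angle = atan2(projections$v_s, projections$v_l))
}

#' Principal-axis relative positions inside a mask
#'
#' Computes the principal axes of the mask's pixel coordinates, projects
#' `points` on both axes and min-max scales each projection to the mask's
#' own extent along that axis, yielding relative positions in `[0, 1]`.
#' Points projecting outside the mask extent are clipped, with a warning.
#'
#' @param points `n x 2` matrix of positions.
#' @param mask binary matrix `[x, y]`.
#' @return `n x 2` matrix with columns `long`, `short`.
#' @export
axis_relative_positions <- function(points, mask) {
  pix <- which(as.matrix(mask) > 0, arr.ind = TRUE)
  if (nrow(pix) < 2) stop("mask too small for principal axes")
  ctr <- colMeans(pix)
  pc <- eigen(stats::cov(pix), symmetric = TRUE)
  proj_mask <- sweep(pix, 2, ctr) %*% pc$vectors
  pts <- sweep(as.matrix(points), 2, ctr) %*% pc$vectors
  out <- matrix(NA_real_, nrow(pts), 2, dimnames = list(NULL, c("long", "short")))
  clipped <- FALSE
  for (k in 1:2) {
    rngk <- range(proj_mask[, k])
    v <- (pts[, k] - rngk[1]) / diff(rngk)
    if (any(v < 0 | v > 1)) clipped <- TRUE
    out[, k] <- pmin(pmax(v, 0), 1)
  }
  if (clipped) warning("some points fell outside the mask extent; clipped")
  out
}
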