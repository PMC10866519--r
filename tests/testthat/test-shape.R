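test_that("contour extraction is geometric and round-trips through masks", {
  disc <- make_shape_family("circle", radius = 50)
  ct <- extract_contour(disc$mask)
  per <- sum(sqrt(rowSums((ct - rbind(ct[-1, ], ct[1, , drop = FALSE]))^2)))
  expect_lt(abs(per - 2 * pi * 50) / (2 * pi * 50), 0.02)
  # counterclockwise orientation
  expect_gt(gastruloidCPM:::polygon_area(ct[, 1], ct[, 2]), 0)
  # round trip: mask -> contour -> rasterize -> mask
  ell <- make_shape_family("ellipse", axes = c(60, 40))
  m2 <- rasterize_contour(extract_contour(ell$mask), dim(ell$mask))
  iou <- sum(m2 & ell$mask) / sum(m2 | ell$mask)
  expect_gte(iou, 0.98)
  # degenerate objects are rejected
  tiny <- matrix(0, 20, 20); tiny[10, 10] <- 1
  expect_error(extract_contour(tiny))   # degenerate: no usable 0.5-contour
  expect_error(extract_contour(matrix(0, 10, 10)), "empty")
})

test_that("elliptic Fourier coefficients recover circles and ellipses", {
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  # circle: uniform angle IS arc length, so the recovery is exact
  cc <- cbind(40 * cos(th) + 7, 40 * sin(th) - 3)
  efc <- efa_coefficients(cc, 8)
  expect_equal(unname(efc$coef[1, ]), c(40, 0, 0, 40), tolerance = 1e-4)
  expect_lt(max(abs(efc$coef[-1, ])), 1e-3)
  expect_equal(efc$a0, 7, tolerance = 1e-3)
  expect_equal(efc$c0, -3, tolerance = 1e-3)
  # ellipse: the arc-length parameterization shifts a few percent of the
  # amplitude into higher odd harmonics (elliptic-integral effect)
  a <- 60; b <- 30
  ct <- cbind(a * cos(th) + 7, b * sin(th) - 3)
  ef <- efa_coefficients(ct, 8)
  expect_equal(unname(ef$coef[1, ]), c(a, 0, 0, b), tolerance = 0.1)
  expect_lt(max(abs(ef$coef[3:8, ])), 0.1 * a)
  # translation changes only the DC offsets
  ef2 <- efa_coefficients(ct + matrix(c(11, -4), nrow(ct), 2, byrow = TRUE), 8)
  expect_equal(ef$coef, ef2$coef, tolerance = 1e-9)
  expect_equal(ef2$a0 - ef$a0, 11, tolerance = 1e-9)
  # reconstruction of a smooth blob from 20 harmonics stays within 1% of L1
  fw <- make_shape_family("flower", radius = 50, amplitude = 0.25, lobes = 4)
  efs <- efa_coefficients(fw$contour, 20)
  rec <- efa_reconstruct(efs, n_points = 2000)
  L1 <- loco_efa(efs)$L[1]
  d <- apply(fw$contour, 1, function(p)
    min(sqrt((rec[, 1] - p[1])^2 + (rec[, 2] - p[2])^2)))
  expect_lt(max(d), 0.01 * L1)
})

test_that("LOCO-EFA assigns lobe modes correctly on analytic shapes", {
  sp_circle <- shape_spectrum(make_shape_family("circle", radius = 50)$contour)
  expect_lt(max(sp_circle$L[-1]), 1e-3 * sp_circle$L[1])
  expect_equal(sp_circle$L[1], 50, tolerance = 0.01)

  # n-lobed flowers: dominant mode n, amplitude ~ a * R
  for (lobes in 2:5) {
    sp <- shape_spectrum(make_shape_family("flower", radius = 50,
                                           amplitude = 0.15,
                                           lobes = lobes)$contour)
    expect_equal(which.max(sp$ratios) + 1, lobes)
    expect_equal(sp$L[lobes], 0.15 * 50, tolerance = 0.1)
  }

  # elongated ellipse: 2-lobe dominated, L2/L1 = (a - b)/(a + b) up to
  # the arc-length parameterization
  sp_ell <- shape_spectrum(make_shape_family("ellipse", axes = c(60, 20))$contour)
  expect_gt(sp_ell$ratios[1], sp_ell$ratios[2])
  expect_equal(sp_ell$ratios[1], (60 - 20) / (60 + 20), tolerance = 0.1)

  # snowman mixes 2- and 3-lobe content, both above a circle's
  sp_sn <- shape_spectrum(make_shape_family("snowman", radius = 50)$contour)
  expect_gt(sp_sn$ratios[1], 0.05)
  expect_gt(sp_sn$ratios[2], 0.05)

  # doubling the contour doubles every L and keeps the ratios
  c0 <- make_shape_family("flower", lobes = 3)$contour
  s1 <- shape_spectrum(c0); s2 <- shape_spectrum(c0 * 2)
  expect_equal(s2$L, 2 * s1$L, tolerance = 1e-9)
  expect_equal(s2$ratios, s1$ratios, tolerance = 1e-9)
})

test_that("scaled spectra are invariant to rotation, translation and start point", {
  rot <- function(pts, a, t = c(0, 0))
    cbind(cos(a) * pts[, 1] - sin(a) * pts[, 2] + t[1],
          sin(a) * pts[, 1] + cos(a) * pts[, 2] + t[2])
  set.seed(33)
  for (i in 1:5) {
    base <- make_shape_family(sample(c("flower", "ellipse", "snowman"), 1),
                              axes = c(60, 25), lobes = sample(2:5, 1),
                              amplitude = runif(1, 0.05, 0.3))$contour
    r0 <- scaled_spectrum(shape_spectrum(base))
    shifted <- rbind(base[201:nrow(base), ], base[1:200, ])
    moved <- rot(shifted, runif(1, 0, 2 * pi), runif(2, -40, 40))
    r1 <- scaled_spectrum(shape_spectrum(moved))
    expect_equal(r1, r0, tolerance = 1e-6)
  }
  expect_error(scaled_spectrum(structure(list(L = c(0, 1), ratios = 1),
                                         class = "shape_spectrum")),
               "degenerate")
})

test_that("low modes survive rasterization within 5 percent", {
  fam <- make_shape_family("flower", radius = 60, amplitude = 0.2, lobes = 3)
  cont_r <- scaled_spectrum(shape_spectrum(fam$contour))
  mask_r <- scaled_spectrum(shape_spectrum(fam$mask))
  expect_lt(abs(mask_r["L2_L1"] - cont_r["L2_L1"]),
            max(0.05 * cont_r["L2_L1"], 0.01))
  expect_lt(abs(mask_r["L3_L1"] - cont_r["L3_L1"]),
            max(0.05 * cont_r["L3_L1"], 0.01))
})

test_that("population spectra are tabulated per shape", {
  masks <- list(make_shape_family("circle", radius = 40)$mask,
                make_shape_family("ellipse", axes = c(50, 25))$mask)
  tab <- spectra_table(masks, n_modes = 5)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$shape_id, c(1, 2))
  expect_lt(tab$L2_over_L1[1], 0.02)
  expect_gt(tab$L2_over_L1[2], 0.2)
  expect_true(all(c("L1", "L5") %in% names(tab)))
})
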