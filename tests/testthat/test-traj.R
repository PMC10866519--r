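test_that("ellipse fits recover known masks and flag circles", {
  ell <- make_shape_family("ellipse", axes = c(60, 30))
  f <- fit_ellipse(ell$mask)
  expect_equal(f$long, 60, tolerance = 0.02)
  expect_equal(f$short, 30, tolerance = 0.02)
  expect_equal(f$theta, 0, tolerance = 0.02)
  expect_true(f$theta_reliable)
  fc <- fit_ellipse(make_shape_family("circle", radius = 40)$mask)
  expect_equal(fc$long, fc$short, tolerance = 0.03)
  expect_false(fc$theta_reliable)
})

test_that("a rotating ellipse series unwraps without quarter-turn jumps", {
  fl <- make_affine_flow_tracks(k = 1.4, rotation = 5 * pi / 180, frames = 12,
                                blob_axes = c(70, 45))
  es <- fit_ellipse_series(fl$masks)
  expect_equal(nrow(es), 12)
  d <- diff(es$theta)
  expect_true(all(abs(d) < pi / 4))              # no pi/2 flips survive
  expect_equal(es$theta, fl$truth$angle, tolerance = 0.02)
})

test_that("rigid drift and rotation are removed from tracks", {
  # pure rigid motion of a static blob: corrected tracks are constants
  fl <- make_affine_flow_tracks(k = 1, rotation = 4 * pi / 180,
                                drift = c(2, -1.5), frames = 10,
                                blob_axes = c(70, 45))
  es <- fit_ellipse_series(fl$masks)
  corr <- correct_rotation_drift(fl$tracks, es)
  for (id in unique(corr$cell_id)) {
    d <- corr[corr$cell_id == id, ]
    expect_lt(max(abs(d$x - d$x[1])), 1.5)
    expect_lt(max(abs(d$y - d$y[1])), 1.5)
  }
  pr <- project_on_axes(corr, es[nrow(es), ])
  expect_lt(max(abs(pr$v_l_over_L)), 0.02)
  expect_lt(max(abs(pr$v_s_over_S)), 0.02)
})

test_that("stretch-flow projections show the convergent-extension signature", {
  base <- make_affine_flow_tracks(k = 1.5, frames = 10, blob_axes = c(70, 55),
                                  seed = 2)
  esb <- fit_ellipse_series(base$masks)
  prb <- project_on_axes(correct_rotation_drift(base$tracks, esb),
                         esb[nrow(esb), ])
  # cells ending near the poles traveled further along the long axis
  expect_gt(stats::cor(abs(prb$x_end), abs(prb$v_l), method = "spearman"), 0.8)
  # v_l ~ x_end (1 - 1/k): near the center it vanishes and it is antisymmetric
  fit <- stats::lm(v_l ~ x_end, data = prb)
  expect_equal(unname(stats::coef(fit)[1]), 0, tolerance = 1.5)
  expect_gt(unname(stats::coef(fit)[2]), 0)
  # the same flow under an added rigid motion gives the same projections
  rig <- make_affine_flow_tracks(k = 1.5, frames = 10, blob_axes = c(70, 55),
                                 rotation = 3 * pi / 180, drift = c(1.5, -2),
                                 seed = 2)
  esr <- fit_ellipse_series(rig$masks)
  prr <- project_on_axes(correct_rotation_drift(rig$tracks, esr),
                         esr[nrow(esr), ])
  expect_equal(prr$v_l, prb$v_l, tolerance = 0.08)
  expect_equal(prr$v_s, prb$v_s, tolerance = 0.08)
})

test_that("mirror-symmetric tracks give an antisymmetric v_l profile", {
  tr <- data.frame(cell_id = rep(1:2, each = 2), frame = rep(1:2, 2),
                   x = c(10, 30, -10, -30), y = 0)
  es <- data.frame(frame = 1:2, cx = 0, cy = 0, long = 50, short = 25,
                   theta = 0, theta_reliable = TRUE)
  pr <- project_on_axes(correct_rotation_drift(tr, es), es[2, ])
  expect_equal(pr$v_l[1], -pr$v_l[2])
  # a stationary cell projects to (0, 0)
  tr0 <- data.frame(cell_id = 1, frame = 1:2, x = 5, y = 3)
  pr0 <- project_on_axes(correct_rotation_drift(tr0, es), es[2, ])
  expect_equal(c(pr0$v_l, pr0$v_s), c(0, 0))
})

test_that("cells are classified by their short-axis motion", {
  es <- data.frame(frame = 1:2, cx = 0, cy = 0, long = 50, short = 25,
                   theta = 0, theta_reliable = TRUE)
  tr <- data.frame(cell_id = rep(1:3, each = 2), frame = rep(1:2, 3),
                   x = 0,
                   y = c(10, 4,     # inward: towards the long axis
                         4, 10,     # outward
                         6, -8))    # crossing
  pr <- project_on_axes(correct_rotation_drift(tr, es), es[2, ])
  expect_equal(pr$direction, c("inward", "outward", "crossing"))
})

test_that("axis-relative positions scale to the mask extent", {
  ell <- make_shape_family("ellipse", axes = c(60, 30))
  ctr <- dim(ell$mask) / 2
  rel <- axis_relative_positions(rbind(ctr), ell$mask)
  expect_equal(unname(rel[1, ]), c(0.5, 0.5), tolerance = 0.02)
  ends <- rbind(ctr + c(59.5, 0), ctr - c(59.5, 0))
  rele <- axis_relative_positions(ends, ell$mask)
  expect_true(all(rele[, "long"] %in% range(rele[, "long"])))
  expect_equal(sort(unname(rele[, "long"])), c(0, 1), tolerance = 0.02)
  # uniform points in the ellipse: marginals approximately uniform
  set.seed(12)
  pts <- matrix(NA_real_, 0, 2)
  while (nrow(pts) < 300) {
    cand <- cbind(runif(200, -1, 1), runif(200, -1, 1))
    cand <- cand[rowSums(cand^2) <= 1, , drop = FALSE]
    pts <- rbind(pts, cand)
  }
  pts <- sweep(pts[1:300, ] %*% diag(c(60, 30)), 2, ctr, "+")
  rel2 <- suppressWarnings(axis_relative_positions(pts, ell$mask))
  # projection of a uniform disc is not uniform; compare against the
  # semicircle law instead of U(0,1)? the relative positions only need to
  # cover [0,1] symmetrically around 0.5
  expect_equal(mean(rel2[, "long"]), 0.5, tolerance = 0.05)
  expect_equal(mean(rel2[, "short"]), 0.5, tolerance = 0.05)
  expect_warning(axis_relative_positions(rbind(ctr + c(80, 0)), ell$mask),
                 "clipped")
})
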