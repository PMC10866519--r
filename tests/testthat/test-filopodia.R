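test_that("every filopodium satisfies the radius and double-cone predicates", {
  p <- cpm_params(model = "ce_one_type", n_cells = 50, width = 240,
                  height = 240, seed = 21, lambda_F = 15)
  mod <- cpm_model(p)
  run_mcs(mod, 60)             # includes refreshes at the 20-MCS cadence
  fl <- filopodia(mod)
  expect_gt(nrow(fl), 0)
  cells <- cpm_cells(mod)
  pol <- polarization(mod)
  rmax <- p$r_max * p$target_length
  for (i in seq_len(nrow(fl))) {
    s <- fl$source[i]; t <- fl$target[i]
    dx <- cells$x[t] - cells$x[s]
    dy <- cells$y[t] - cells$y[s]
    r <- sqrt(dx^2 + dy^2)
    expect_lte(r, rmax + 1e-9)
    cosang <- abs(dx * cos(pol[s]) + dy * sin(pol[s])) / r
    expect_gte(cosang, cos(p$theta_max * pi / 180) - 1e-9)
  }
  # no more than n_max outgoing filopodia per cell
  expect_lte(max(table(fl$source)), p$n_max)
})

test_that("forced geometry gives the expected links; isolated cells get none", {
  # two cells 15 sites apart along x, both polarized along x (r_max L_T = 20)
  m <- matrix(0L, 40, 40)
  m[8:12, 18:22] <- 1L
  m[23:27, 18:22] <- 2L
  mod <- toy_model(m, lambda_F = 15)
  set_polarization(mod, c(0, 0))
  refresh_filopodia(mod)
  fl <- filopodia(mod)
  expect_equal(nrow(fl), 2)    # one filopodium each way
  expect_setequal(paste(fl$source, fl$target), c("1 2", "2 1"))
  expect_equal(fl$length, rep(15, 2), tolerance = 1e-9)

  # same pair polarized perpendicular to their separation: outside the cone
  set_polarization(mod, c(pi / 2, pi / 2))
  refresh_filopodia(mod)
  expect_equal(nrow(filopodia(mod)), 0)

  # an isolated cell has no candidates
  m1 <- matrix(0L, 40, 40)
  m1[18:22, 18:22] <- 1L
  mod1 <- toy_model(m1, lambda_F = 15)
  refresh_filopodia(mod1)
  expect_equal(nrow(filopodia(mod1)), 0)
})

test_that("the pulling term equals lambda_F times the summed length change", {
  # single directed link via the yellow-all mask: only cell 2 (yellow) pulls
  m <- matrix(0L, 40, 40)
  m[8:12, 18:22] <- 1L
  m[23:27, 18:22] <- 2L
  p <- cpm_params(model = "ce_yellow_all", n_cells = 2, width = 40, height = 40,
                  lambda_F = 10, seed = 1)
  J <- matrix(10, 3, 3); J[1, 1] <- 0
  mod <- cpm_model(p, init = "spins", spins = m, cell_types = c(1L, 2L), J = J)
  mod0 <- cpm_model(p, init = "spins", spins = m, cell_types = c(1L, 2L), J = J,
                    filopodia = FALSE)
  set_polarization(mod, c(0, 0))
  refresh_filopodia(mod)
  fl <- filopodia(mod)
  expect_equal(nrow(fl), 1)
  expect_equal(fl$source, 2)
  # grow cell 1 by one site towards cell 2: its center moves 1/(A+1)/... in x;
  # the closed-form center shift fixes the length change exactly
  cells <- cpm_cells(mod)
  dh_pull <- propose_copy(mod, 13, 20, 4) - propose_copy(mod0, 13, 20, 4)
  A <- cells$area[1]
  new_cx <- (cells$x[1] * A + 13) / (A + 1)
  r_before <- abs(cells$x[2] - cells$x[1])
  r_after <- sqrt((cells$x[2] - new_cx)^2 + 0)
  expect_equal(dh_pull, 10 * (r_after - r_before), tolerance = 1e-9)
  expect_lt(dh_pull, 0)        # moving closer is favorable
})

test_that("proposals not touching a linked cell add no pulling term", {
  m <- matrix(0L, 60, 60)
  m[8:12, 18:22] <- 1L         # yellow pair, linked below
  m[23:27, 18:22] <- 2L
  m[40:44, 40:44] <- 3L        # distant unlinked cell
  p <- cpm_params(model = "ce_same_type", n_cells = 3, width = 60, height = 60,
                  lambda_F = 10, seed = 1)
  J <- matrix(10, 3, 3); J[1, 1] <- 0
  mk <- function(filo) cpm_model(p, init = "spins", spins = m,
                                 cell_types = c(2L, 2L, 1L), J = J,
                                 filopodia = filo)
  mod <- mk(TRUE); mod0 <- mk(FALSE)
  set_polarization(mod, c(0, 0, 0))
  refresh_filopodia(mod)
  expect_equal(sort(unique(c(filopodia(mod)$source, filopodia(mod)$target))),
               c(1, 2))
  # growing the unlinked cell 3 changes no filopodium length
  expect_equal(propose_copy(mod, 45, 42, 4), propose_copy(mod0, 45, 42, 4),
               tolerance = 1e-12)
})

test_that("pulling delta matches a full recomputation on a random blob", {
  p <- cpm_params(model = "ce_one_type", n_cells = 30, width = 200,
                  height = 200, seed = 31, lambda_F = 12)
  mod <- cpm_model(p)
  run_mcs(mod, 25)             # at least one refresh has happened
  sp0 <- cpm_spins(mod)
  mod_nof <- cpm_model(p, init = "spins", spins = sp0, filopodia = FALSE)
  fl <- filopodia(mod)
  expect_gt(nrow(fl), 0)
  all_coms <- function(spm, n) {
    idx <- which(spm > 0)
    s <- spm[idx]
    xy <- arrayInd(idx, dim(spm))
    cx <- tapply(xy[, 1], factor(s, levels = 1:n), mean)
    cy <- tapply(xy[, 2], factor(s, levels = 1:n), mean)
    cbind(cx, cy)
  }
  for (i in 1:40) {
    e <- sample_edge(mod)
    dh_full <- propose_copy(mod, e["x"], e["y"], e["nb"])
    dh_base <- propose_copy(mod_nof, e["x"], e["y"], e["nb"])
    # oracle: recompute every link length before/after from scratch
    src <- c(e["x"], e["y"]) + neighbor_offsets()[e["nb"], ]
    sp1 <- sp0
    sp1[e["x"], e["y"]] <- sp0[src[1], src[2]]
    c0 <- all_coms(sp0, 30); c1 <- all_coms(sp1, 30)
    dd <- 0
    for (li in seq_len(nrow(fl))) {
      u <- fl$source[li]; v <- fl$target[li]
      if (any(is.na(c1[u, ])) || any(is.na(c1[v, ]))) next  # dies with the cell
      dd <- dd + sqrt(sum((c1[u, ] - c1[v, ])^2)) -
        sqrt(sum((c0[u, ] - c0[v, ])^2))
    }
    expect_equal(dh_full - dh_base, 12 * dd, tolerance = 1e-8)
  }
})

test_that("polarization updates follow the memory-weighted circular blend", {
  # closed form: P = 0, one neighbor at pi/2, w = 0.99
  expect_equal(update_polarization_vicsek(0, pi / 2, 0.99),
               atan2(0.01, 0.99), tolerance = 1e-6)
  # no links or full memory: unchanged
  expect_equal(update_polarization_vicsek(1.2, numeric(0), 0.5), 1.2)
  expect_equal(update_polarization_vicsek(1.2, c(0, 3), 1), 1.2)
  # antipodal tie: circular sum has zero magnitude, direction kept
  expect_equal(update_polarization_vicsek(0.4, c(0, pi), 0.9), 0.4)
  # circular mean of several neighbors
  lp <- c(0.2, 0.5, 1.1)
  pavg <- Arg(sum(exp(1i * lp)))
  expect_equal(update_polarization_vicsek(2, lp, 0.7),
               Arg(0.7 * exp(2i) + 0.3 * exp(1i * pavg)) %% (2 * pi),
               tolerance = 1e-12)
})

test_that("location-based repolarization points towards the linked cells", {
  ctr <- c(5, 5)
  expect_equal(update_polarization_belmonte(1, ctr, rbind(c(9, 5)), 0), 0)
  # two linked cells symmetric about the x-axis through the center
  expect_equal(update_polarization_belmonte(0.3, ctr, rbind(c(9, 8), c(9, 2)), 0), 0)
  # vector-sum oracle on random link sets
  set.seed(8)
  for (i in 1:20) {
    lc <- matrix(runif(6, 0, 10), ncol = 2)
    v <- colSums(sweep(lc, 2, ctr))
    expect_equal(update_polarization_belmonte(0.9, ctr, lc, 0),
                 atan2(v[2], v[1]) %% (2 * pi), tolerance = 1e-12)
  }
  expect_equal(update_polarization_belmonte(0.9, ctr, NULL, 0.5), 0.9)
})

test_that("zero pulling force reproduces the base dynamics bitwise", {
  p <- cpm_params(model = "ce_one_type", n_cells = 20, width = 140,
                  height = 140, seed = 17, lambda_F = 0)
  with_filo <- cpm_model(p, filopodia = TRUE)
  without <- cpm_model(p, filopodia = FALSE)
  run_mcs(with_filo, 150)
  run_mcs(without, 150)
  expect_identical(cpm_spins(with_filo), cpm_spins(without))
  expect_gt(nrow(filopodia(with_filo)), 0)   # machinery did run
})

test_that("local polarization alignment emerges during a pulling run", {
  p <- cpm_params(model = "ce_one_type", n_cells = 40, width = 220,
                  height = 220, seed = 23, lambda_F = 15)
  mod <- cpm_model(p)
  a0 <- local_alignment(mod)                 # random angles: ~ 2/pi
  expect_lt(a0, 0.78)
  run_mcs(mod, 6000)
  a1 <- local_alignment(mod)
  expect_gt(a1, a0 + 0.05)
})
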