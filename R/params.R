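#' Simulation parameters
#'
#' Assemble the full parameter set of a simulation run. Defaults are the
#' standard conditions for an elongating-gastruloid run: temperature 50,
#' 200 cells of target area 100 (target length/diameter 10) with area and
#' length constraint strengths 5, uniform interfacial energies
#' `J(c,M) = J(c,c) = 10`, and filopodial-tension parameters
#' `theta_max` 45 degrees, `r_max` 2 target lengths, `n_max` 3 filopodia,
#' refresh interval 20 MCS and polarization memory `w = 0.99`.
#'
#' @param model model preset: `"ce_one_type"` (single-cell-type crawling CE),
#'   `"diff_adhesion"` (10-type adhesion gradient, no pulling), or one of the
#'   two-cell-type pulling variants `"ce_same_type"`, `"ce_all_all"`,
#'   `"ce_yellow_all"`, `"ce_yellow_yellow"`.
#' @param temperature Boltzmann temperature `T` controlling cell motility.
#' @param target_area,target_length target area (sites) and target length
#'   (major-axis extent, sites) per cell.
#' @param lambda_area,lambda_length strengths of the area and length
#'   constraints.
#' @param mcs number of Monte Carlo steps of the production run. Defaults to
#'   100,000 for the CE presets and 120,000 for `"diff_adhesion"`.
#' @param n_cells number of cells.
#' @param theta_max half-angle of the filopodial double cone, degrees.
#' @param r_max filopodium reach in multiples of `target_length`.
#' @param n_max maximal number of filopodia per cell.
#' @param t_interval filopodia refresh interval, MCS.
#' @param w polarization memory weight in `[0, 1]`.
#' @param lambda_F filopodial pulling force. Defaults to 15 for the CE presets
#'   and 0 for `"diff_adhesion"`.
#' @param J_cell_medium,J_cell_cell interfacial energies with the medium and
#'   between same-type cells.
#' @param gamma_12 surface tension between the two cell types of the two-type
#'   presets; `J(1,2) = gamma_12 + J_cell_cell`.
#' @param offset,slope offset `O` and slope `S` of the differential-adhesion
#'   gradient `J(tau, tau') = O + |tau - tau'| * S` (10 types,
#'   `J(tau, M) = 25`).
#' @param type2_fraction fraction of type-2 ("yellow") cells in the two-type
#'   presets.
#' @param repolarization_mode `"vicsek"` (circular mean of linked cells'
#'   polarizations) or `"belmonte"` (location-based: mean direction towards
#'   linked cells' centers).
#' @param width,height lattice size including the fixed frame; `NULL` picks a
#'   size proportional to the tissue (400 x 400 for 200 cells of area 100).
#' @param seed integer seed for the run.
#' @param snapshot_interval MCS between label-image snapshots when snapshots
#'   are requested.
#' @param burnin_mcs MCS of the growth phase in which single-site seeds grow
#'   to target area under area/adhesion terms only.
#' @return a named list of class `"cpm_params"`.
#' @export
cpm_params <- function(model = "ce_one_type",
                       temperature = 50,
                       target_area = 100,
                       target_length = 10,
                       lambda_area = 5,
                       lambda_length = 5,
                       mcs = NULL,
                       n_cells = 200,
                       theta_max = 45,
                       r_max = 2,
                       n_max = 3,
                       t_interval = 20,
                       w = 0.99,
                       lambda_F = NULL,
                       J_cell_medium = 10,
                       J_cell_cell = 10,
                       gamma_12 = -4,
                       offset = 25,
                       slope = 2.5,
                       type2_fraction = 0.5,
                       repolarization_mode = "vicsek",
                       width = NULL,
                       height = NULL,
                       seed = 1,
                       snapshot_interval = 5000,
                       burnin_mcs = 100) {
  model <- match.arg(model, c("ce_one_type", "diff_adhesion", "ce_same_type",
                              "ce_all_all", "ce_yellow_all", "ce_yellow_yellow"))
  repolarization_mode <- match.arg(repolarization_mode, c("vicsek", "belmonte"))
  if (is.null(mcs)) mcs <- if (model == "diff_adhesion") 120000L else 100000L
  if (is.null(lambda_F)) lambda_F <- if (model == "diff_adhesion") 0 else 15
  if (is.null(width)) {
    # room for a strongly elongated tissue: ~2.8 tissue diameters
    width <- max(100L, as.integer(ceiling(2.8 * sqrt(n_cells * target_area))))
  }
  if (is.null(height)) height <- width
  stopifnot(temperature > 0, target_area > 0, n_cells >= 1,
            w >= 0, w <= 1, t_interval >= 1)
  p <- list(model = model, temperature = temperature,
            target_area = target_area, target_length = target_length,
            lambda_area = lambda_area, lambda_length = lambda_length,
            mcs = as.integer(mcs), n_cells = as.integer(n_cells),
            theta_max = theta_max, r_max = r_max, n_max = as.integer(n_max),
            t_interval = as.integer(t_interval), w = w, lambda_F = lambda_F,
            J_cell_medium = J_cell_medium, J_cell_cell = J_cell_cell,
            gamma_12 = gamma_12, offset = offset, slope = slope,
            type2_fraction = type2_fraction,
            repolarization_mode = repolarization_mode,
            width = as.integer(width), height = as.integer(height),
            seed = as.integer(seed),
            snapshot_interval = as.integer(snapshot_interval),
            burnin_mcs = as.integer(burnin_mcs))
  class(p) <- "cpm_params"
  p
}

#' @export
print.cpm_params <- function(x, ...) {
  cat("CPM parameter set -- model:", x$model, "\n")
  cat(sprintf("  lattice %d x %d, %d cells (A_T = %g, L_T = %g), T = %g\n",
              x$width, x$height, x$n_cells, x$target_area, x$target_length,
              x$temperature))
  if (x$model == "diff_adhesion") {
    cat(sprintf("  adhesion gradient: offset %g, slope %g, %d MCS\n",
                x$offset, x$slope, x$mcs))
  } else {
    cat(sprintf("  pulling lambda_F = %g, theta_max = %g deg, r_max = %g L_T, n_max = %d, t_interval = %d, w = %g\n",
                x$lambda_F, x$theta_max, x$r_max, x$n_max, x$t_interval, x$w))
    cat(sprintf("  %d MCS, repolarization: %s\n", x$mcs, x$repolarization_mode))
  }
  invisible(x)
}

#' Surface tensions from an interfacial-energy table
#'
#' Computes `gamma(tau, tau') = J(tau, tau') - (J(tau, tau) + J(tau', tau'))/2`
#' for cell-type pairs and `gamma(c, M) = J(c, M) - J(c, c)/2` against the
#' medium (row/column 1 of `J`). Positive `gamma(c, M)` keeps the tissue
#' compact; positive `gamma(1, 2)` makes two cell types sort, negative makes
#' them mix.
#'
#' @param J symmetric interfacial-energy matrix including the medium as the
#'   first row/column (as built by [adhesion_matrix()] or the model presets).
#' @return a matrix of surface tensions with the same dimensions as `J`; the
#'   medium diagonal entry is 0 by convention.
#' @export
surface_tensions <- function(J) {
  J <- as.matrix(J)
  if (nrow(J) != ncol(J) || any(abs(J - t(J)) > 1e-9))
    stop("J must be a symmetric square matrix")
  d <- diag(J)
  g <- J - outer(d, d, "+") / 2
  # medium has no self-energy: gamma(c, M) = J(c, M) - J(c, c)/2
  g[1, ] <- J[1, ] - d / 2
  g[, 1] <- g[1, ]
  g[1, 1] <- 0
  dimnames(g) <- dimnames(J)
  g
}

#' Metropolis acceptance rule
#'
#' Accepts an energy change with probability 1 if `delta_h <= 0` and
#' `exp(-delta_h / temperature)` otherwise.
#'
#' @param delta_h numeric vector of proposed energy changes.
#' @param temperature Boltzmann temperature, `> 0`.
#' @return logical vector of acceptance decisions.
#' @export
metropolis_accept <- function(delta_h, temperature) {
  stopifnot(temperature > 0)
  delta_h <= 0 | stats::runif(length(delta_h)) < exp(-delta_h / temperature)
}

#' Cell length as major-axis extent
#'
#' The length `L(s)` entering the length constraint is estimated from the
#' covariance matrix of the cell's site coordinates as
#' `4 * sqrt(lambda_max)`; for a filled disc this equals its diameter.
#'
#' @param sites two-column matrix of site coordinates.
#' @return length in lattice sites (0 for a single site).
#' @export
cell_length <- function(sites) {
  sites <- as.matrix(sites)
  if (nrow(sites) < 1) stop("cell has no sites: length undefined")
  if (nrow(sites) == 1) return(0)
  cv <- stats::cov(sites) * (nrow(sites) - 1) / nrow(sites)  # population covariance
  lmax <- max(eigen(cv, symmetric = TRUE, only.values = TRUE)$values)
  4 * sqrt(max(lmax, 0))
}
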