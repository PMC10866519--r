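#' Create a Cellular Potts model
#'
#' Builds the lattice state for a parameter set. With `init = "blob"` (the
#' default) the cells are seeded as single sites scattered over a disc at the
#' lattice center and grown to target area during a short burn-in driven by
#' the area and adhesion terms only, mirroring the compact aggregate from
#' which a gastruloid elongates. With `init = "spins"` an explicit spin
#' matrix is registered instead (useful for toy configurations).
#'
#' The returned object holds a handle to mutable simulation state:
#' [run_mcs()] and related functions update it in place.
#'
#' @param params a [cpm_params()] parameter set.
#' @param init `"blob"` or `"spins"`.
#' @param spins integer `width x height` matrix of cell IDs (0 = medium) when
#'   `init = "spins"`; the lattice frame (first/last row/column) must be
#'   medium.
#' @param cell_types integer vector of types (one per cell ID) for
#'   `init = "spins"`; defaults to all type 1.
#' @param J optional interfacial-energy matrix overriding the preset's table
#'   (first row/column = medium).
#' @param sampler `"edge_list"` for the edge-list sampler (`|E|/n_NB` copy
#'   attempts per MCS, each drawn uniformly from the boundary-pair list) or
#'   `"conventional"` (`|Lambda|` random site-pair attempts per MCS).
#' @param filopodia enable the filopodial-tension machinery; `NULL` uses the
#'   preset's default (on for the CE models, off for `"diff_adhesion"`).
#'   With `lambda_F = 0` the machinery contributes no energy and the spin
#'   trajectory is identical to a run with `filopodia = FALSE` at the same
#'   seed.
#' @return an object of class `"cpm_model"`.
#' @export
cpm_model <- function(params = cpm_params(), init = c("blob", "spins"),
                      spins = NULL, cell_types = NULL, J = NULL,
                      sampler = c("edge_list", "conventional"),
                      filopodia = NULL) {
  init <- match.arg(init)
  sampler <- match.arg(sampler)
  stopifnot(inherits(params, "cpm_params"))
  if (is.null(filopodia)) filopodia <- params$model != "diff_adhesion"

  if (init == "blob") {
    set.seed(params$seed)
    blob <- seed_blob(params)
    centers <- blob$centers
    setup <- model_setup(params, centers)
    if (!is.null(J)) setup$J <- as.matrix(J)
  } else {
    if (is.null(spins)) stop("init = \"spins\" needs a spin matrix")
    spins <- as_spin_matrix(spins)
    ncell <- if (is.null(cell_types)) max(spins) else length(cell_types)
    if (ncell < max(spins)) stop("spin values exceed the registered cells")
    if (ncell < 1) stop("spin matrix contains no cells")
    if (is.null(cell_types)) cell_types <- rep(1L, ncell)
    if (length(cell_types) != ncell)
      stop("need one cell type per cell ID 1..", ncell)
    n_types <- max(cell_types)
    if (is.null(J)) {
      J <- matrix(params$J_cell_cell, n_types + 1, n_types + 1)
      J[1, ] <- J[, 1] <- params$J_cell_medium
      J[1, 1] <- 0
    }
    setup <- list(J = as.matrix(J), types = as.integer(cell_types),
                  n_types = as.integer(n_types))
  }

  ptr <- cpm_create_(params$width, params$height, setup$types, setup$n_types,
                     setup$J, params$temperature, params$lambda_area,
                     params$lambda_length, params$target_area,
                     params$target_length,
                     filopodia, params$lambda_F,
                     params$theta_max, params$r_max, params$n_max,
                     params$t_interval, params$w,
                     pulling_variant_code(params$model),
                     if (params$repolarization_mode == "belmonte") 1L else 0L,
                     if (sampler == "conventional") 1L else 0L,
                     as.double(params$seed),
                     as.double(params$seed) + 7777777)

  model <- structure(list(ptr = ptr, params = params, J = setup$J,
                          cell_types = setup$types, n_types = setup$n_types,
                          sampler = sampler),
                     class = "cpm_model")

  if (init == "blob") {
    cpm_set_spins_(ptr, blob$spins)
    if (params$burnin_mcs > 0) cpm_burnin_(ptr, params$burnin_mcs)
  } else {
    cpm_set_spins_(ptr, spins)
  }
  model
}

# compact disc-shaped tissue: random cell nuclei on a central disc, every
# disc site assigned to the nearest nucleus (Voronoi), so the aggregate is
# connected and cells start near target area
seed_blob <- function(params) {
  n <- params$n_cells
  r0 <- ceiling(1.06 * sqrt(n * params$target_area / pi))
  cx <- params$width / 2
  cy <- params$height / 2
  xs <- seq(max(2, floor(cx - r0)), min(params$width - 1, ceiling(cx + r0)))
  ys <- seq(max(2, floor(cy - r0)), min(params$height - 1, ceiling(cy + r0)))
  grid <- as.matrix(expand.grid(x = xs, y = ys))
  grid <- grid[(grid[, 1] - cx)^2 + (grid[, 2] - cy)^2 <= r0^2, , drop = FALSE]
  if (nrow(grid) < n)
    stop("lattice too small to seed ", n, " cells")
  centers <- grid[sample.int(nrow(grid), n), , drop = FALSE]
  d2 <- outer(grid[, 1], centers[, 1], "-")^2 + outer(grid[, 2], centers[, 2], "-")^2
  owner <- max.col(-d2, ties.method = "first")
  m <- matrix(0L, params$width, params$height)
  m[grid] <- owner
  list(spins = m, centers = centers)
}

as_spin_matrix <- function(spins) {
  spins <- as.matrix(spins)
  storage.mode(spins) <- "integer"
  frame <- c(spins[1, ], spins[nrow(spins), ], spins[, 1], spins[, ncol(spins)])
  if (any(frame != 0L))
    stop("the lattice frame must be medium (spin 0)")
  spins
}

#' @export
print.cpm_model <- function(x, ...) {
  cells <- cpm_cells_(x$ptr)
  cat(sprintf("CPM model (%s, %s sampler): %d x %d lattice, %d cells (%d alive), %d boundary edges, MCS %d\n",
              x$params$model, x$sampler, x$params$width, x$params$height,
              nrow(cells), sum(cells$alive), cpm_n_edges_(x$ptr),
              as.integer(cpm_mcs_(x$ptr))))
  invisible(x)
}

#' Advance a model by Monte Carlo steps
#'
#' Runs `mcs` Monte Carlo steps in place. With the edge-list sampler one MCS
#' is `ceiling(|E| / 8)` copy attempts, `|E|` being re-read as it changes;
#' with the conventional sampler it is `width * height` random site-pair
#' attempts. Filopodia are refreshed (and polarizations updated) every
#' `t_interval` MCS for the CE presets.
#'
#' @param model a [cpm_model()].
#' @param mcs number of Monte Carlo steps.
#' @return invisibly, a list with `mcs` (total simulated), `attempts` and
#'   `accepted` counts of this call.
#' @export
run_mcs <- function(model, mcs) {
  invisible(cpm_run_(model$ptr, as.integer(mcs)))
}

#' Lattice and cell-state accessors
#'
#' `cpm_spins()` returns the `width x height` integer matrix of cell IDs;
#' `cpm_cells()` the per-cell table (id, type, alive, area, center of mass,
#' length, polarization angle); `hamiltonian()` the full energy
#' (adhesion over unordered adjacent site pairs, excluding the lattice frame,
#' plus area and length constraint terms over all registered cells);
#' `cpm_mcs()` the Monte Carlo time; `sim_mask()` the binary tissue mask
#' (any cell vs medium).
#'
#' @param model a [cpm_model()].
#' @return see above.
#' @export
cpm_spins <- function(model) cpm_spins_(model$ptr)

#' @rdname cpm_spins
#' @export
cpm_cells <- function(model) cpm_cells_(model$ptr)

#' @rdname cpm_spins
#' @export
hamiltonian <- function(model) cpm_hamiltonian_(model$ptr)

#' @rdname cpm_spins
#' @export
cpm_mcs <- function(model) cpm_mcs_(model$ptr)

#' @rdname cpm_spins
#' @export
sim_mask <- function(model) cpm_spins_(model$ptr) > 0L

#' Propose or force a single spin copy
#'
#' `propose_copy()` returns the energy change `delta H` of copying the spin
#' of the neighbor in slot `nb` onto site `(x, y)` without applying it;
#' `apply_copy()` applies the copy unconditionally, updating all bookkeeping
#' and the edge list. Neighbor slots 1..8 enumerate the Moore neighborhood
#' row by row (NW, N, NE, W, E, SW, S, SE).
#'
#' @param model a [cpm_model()].
#' @param x,y 1-based site coordinates.
#' @param nb neighbor slot in 1..8.
#' @return `propose_copy()`: numeric `delta H`; `apply_copy()`: the model,
#'   invisibly.
#' @export
propose_copy <- function(model, x, y, nb) cpm_propose_(model$ptr, x, y, nb)

#' @rdname propose_copy
#' @export
apply_copy <- function(model, x, y, nb) {
  cpm_apply_(model$ptr, x, y, nb)
  invisible(model)
}

#' Verify internal consistency against a from-scratch recomputation
#'
#' Rebuilds the edge list and the per-cell bookkeeping (areas and coordinate
#' moments) from the raw spin field and reports deviations. Used by the
#' test suite after fuzzed runs.
#'
#' @param model a [cpm_model()].
#' @return list with `edges_ok` (edge set identical), `bijection_errors`
#'   (violations of the paired-array invariant) and `bookkeeping_dev`
#'   (largest absolute deviation of any incremental statistic).
#' @export
consistency_check <- function(model) cpm_check_(model$ptr)

#' Filopodia and polarization state
#'
#' `filopodia()` returns the current center-to-center links as a two-column
#' matrix (source, target cell ID) plus their lengths; `refresh_filopodia()`
#' forces a refresh (normally done every `t_interval` MCS);
#' `polarization()` and `set_polarization()` access the per-cell
#' polarization angles in `[0, 2*pi)`.
#'
#' @param model a [cpm_model()].
#' @param angles numeric vector of angles, one per cell.
#' @return see above.
#' @export
filopodia <- function(model) {
  m <- cpm_filopodia_(model$ptr)
  cells <- cpm_cells_(model$ptr)
  len <- if (nrow(m)) sqrt((cells$x[m[, 1]] - cells$x[m[, 2]])^2 +
                           (cells$y[m[, 1]] - cells$y[m[, 2]])^2) else numeric(0)
  data.frame(source = m[, 1], target = m[, 2], length = len)
}

#' @rdname filopodia
#' @export
refresh_filopodia <- function(model) {
  cpm_refresh_filopodia_(model$ptr)
  invisible(model)
}

#' @rdname filopodia
#' @export
polarization <- function(model) cpm_get_polarization_(model$ptr)

#' @rdname filopodia
#' @export
set_polarization <- function(model, angles) {
  cpm_set_polarization_(model$ptr, as.double(angles))
  invisible(model)
}
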