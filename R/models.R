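#' Differential-adhesion interfacial-energy table
#'
#' Builds the symmetric interfacial-energy matrix of the 10-type adhesion
#' gradient, `J(tau, tau') = O + |tau - tau'| * S` with `J(tau, M) = 25`,
#' giving surface tensions `gamma(tau, tau') = |tau - tau'| * S` and
#' `gamma(c, M) = 25 - O/2`.
#'
#' @param offset gradient offset `O`.
#' @param slope gradient slope `S` (non-negative).
#' @param n_types number of cell types in the gradient.
#' @param J_medium interfacial energy of every cell type with the medium.
#' @return a `(n_types + 1) x (n_types + 1)` matrix; row/column 1 is the
#'   medium.
#' @export
adhesion_matrix <- function(offset, slope, n_types = 10, J_medium = 25) {
  stopifnot(slope >= 0, n_types >= 1)
  tau <- seq_len(n_types)
  J <- matrix(0, n_types + 1, n_types + 1)
  J[-1, -1] <- offset + abs(outer(tau, tau, "-")) * slope
  J[1, -1] <- J[-1, 1] <- J_medium
  rn <- c("M", paste0("type", tau))
  dimnames(J) <- list(rn, rn)
  J
}

#' Filopodia attachment rule of the two-cell-type pulling variants
#'
#' Pure predicate on (source type, target type). Variants: `"same_type"`
#' (attach only to the own type), `"all_all"` (no restriction),
#' `"yellow_all"` (only type 2 extends filopodia), `"yellow_yellow"`
#' (type 2 extends filopodia only to type 2). Types: 1 = red, 2 = yellow.
#'
#' @param variant one of `"same_type"`, `"all_all"`, `"yellow_all"`,
#'   `"yellow_yellow"`.
#' @param tau_source,tau_target cell types in `{1, 2}` (vectorized).
#' @return logical: may `tau_source` attach a filopodium to `tau_target`?
#' @export
pulling_mask <- function(variant, tau_source, tau_target) {
  variant <- match.arg(variant, c("same_type", "all_all", "yellow_all",
                                  "yellow_yellow"))
  if (!all(tau_source %in% 1:2) || !all(tau_target %in% 1:2))
    stop("two-type pulling variants are defined for types 1 and 2 only")
  switch(variant,
         same_type = tau_source == tau_target,
         all_all = tau_source > 0 | tau_target > 0,
         yellow_all = tau_source == 2,
         yellow_yellow = tau_source == 2 & tau_target == 2)
}

# integer code used by the compiled core
pulling_variant_code <- function(model) {
  switch(model,
         ce_one_type = 0L, diff_adhesion = 0L,
         ce_same_type = 1L, ce_all_all = 2L,
         ce_yellow_all = 3L, ce_yellow_yellow = 4L,
         stop("unknown model variant: ", model))
}

#' Cell types of the presorted differential-adhesion initial state
#'
#' Assigns the `n_types` cell types in contiguous bands ordered 1 to
#' `n_types` along the x-axis of the initial blob, so that at MCS 0 types
#' `tau` and `tau'` with `|tau - tau'| > 1` share essentially no boundary.
#'
#' @param centers two-column matrix of initial cell center positions.
#' @param n_types number of types; cell counts per type differ by at most 1.
#' @return integer vector of types, one per row of `centers`.
#' @export
presorted_types <- function(centers, n_types = 10) {
  n <- nrow(centers)
  ord <- order(centers[, 1], centers[, 2])
  sizes <- rep(n %/% n_types, n_types)
  extra <- n %% n_types
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  types <- integer(n)
  types[ord] <- rep(seq_len(n_types), times = sizes)
  types
}

#' Random two-type assignment
#'
#' Each cell is independently assigned type 2 ("yellow") with probability
#' `fraction`, else type 1 ("red"). Proportions in the mosaic are not pinned
#' by the biology; 50/50 is the documented default.
#'
#' @param n_cells number of cells.
#' @param fraction probability of type 2.
#' @return integer vector of types in `{1, 2}`.
#' @export
two_type_assignment <- function(n_cells, fraction = 0.5) {
  stopifnot(fraction >= 0, fraction <= 1)
  ifelse(stats::runif(n_cells) < fraction, 2L, 1L)
}

# J table and type vector for a model preset; `centers` holds the seeded cell
# positions (needed by the presorted gradient)
model_setup <- function(params, centers) {
  model <- params$model
  if (model == "diff_adhesion") {
    J <- adhesion_matrix(params$offset, params$slope, n_types = 10)
    types <- presorted_types(centers, n_types = 10)
    list(J = J, types = types, n_types = 10L)
  } else if (model == "ce_one_type") {
    J <- matrix(c(0, params$J_cell_medium,
                  params$J_cell_medium, params$J_cell_cell), 2, 2)
    dimnames(J) <- list(c("M", "type1"), c("M", "type1"))
    list(J = J, types = rep(1L, nrow(centers)), n_types = 1L)
  } else {
    J12 <- params$gamma_12 + params$J_cell_cell
    J <- matrix(params$J_cell_medium, 3, 3)
    J[1, 1] <- 0
    J[2, 2] <- J[3, 3] <- params$J_cell_cell
    J[2, 3] <- J[3, 2] <- J12
    dimnames(J) <- list(c("M", "red", "yellow"), c("M", "red", "yellow"))
    types <- two_type_assignment(nrow(centers), params$type2_fraction)
    list(J = J, types = types, n_types = 2L)
  }
}
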