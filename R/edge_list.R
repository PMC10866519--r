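#' The edge list: paired arrays indexing boundary site pairs
#'
#' The sampler keeps every boundary pair -- a site and a Moore neighbor with
#' a different spin, lattice frame excluded -- in two mutually indexing
#' arrays. `edgelist` maps the flattened (site, neighbor-slot) index
#' `i = p * 8 + (nb - 1)` (with `p = (y - 1) * width + (x - 1)`; y outermost,
#' x middle, neighbor slot innermost) to an edge number, or -1 for
#' non-boundary slots. `edgeindices` holds, in its first `|E|` entries, the
#' slot index of each edge, and -1 beyond. Edges are stored directed (both
#' orientations present). Sampling an attempt is one uniform draw from the
#' dense `edgeindices` prefix; after an accepted copy only the changed
#' site's neighborhood is revisited and a removed edge is overwritten by the
#' edge from the last index, so the prefix never fragments.
#'
#' @param model a [cpm_model()].
#' @return `edge_list()`: list with `edgelist`, `edgeindices` and `n_edges`.
#' @export
edge_list <- function(model) cpm_edges_(model$ptr)

#' @rdname edge_list
#' @param x result of [edge_list()] (or any list with `edgelist` and
#'   `edgeindices` entries).
#' @return `is_valid_edge_list()`: `TRUE` when the 1-to-1 relationship holds:
#'   `edgelist[i] = k` iff `edgeindices[k] = i` (0-based values as stored),
#'   the `edgeindices` prefix is dense and everything beyond it is -1.
#' @export
is_valid_edge_list <- function(x) {
  el <- x$edgelist
  ei <- x$edgeindices
  nE <- sum(ei >= 0)
  if (any(ei[seq_len(nE)] < 0)) return(FALSE)            # dense prefix
  if (nE < length(ei) && any(ei[(nE + 1):length(ei)] != -1)) return(FALSE)
  if (sum(el >= 0) != nE) return(FALSE)
  if (nE == 0) return(TRUE)
  slots <- ei[seq_len(nE)]                               # 0-based slot of edge k
  all(el[slots + 1] == seq_len(nE) - 1)
}

#' @rdname edge_list
#' @return `n_edges()`: the current number of directed boundary pairs `|E|`.
#' @export
n_edges <- function(model) cpm_n_edges_(model$ptr)

#' @rdname edge_list
#' @return `sample_edge()`: one uniformly sampled edge, decoded to 1-based
#'   coordinates: named vector (x, y, nb, slot). Errors when `|E| = 0`
#'   (frozen simulation).
#' @export
sample_edge <- function(model) cpm_sample_edge_(model$ptr)

#' @rdname edge_list
#' @param file path of a CSV dump of both arrays (index, edgelist,
#'   edgeindices), for debugging and regression comparison.
#' @export
edge_list_dump <- function(model, file) {
  e <- edge_list(model)
  utils::write.csv(data.frame(index = seq_along(e$edgelist) - 1,
                              edgelist = e$edgelist,
                              edgeindices = e$edgeindices),
                   file, row.names = FALSE)
  invisible(file)
}

#' Moore neighbor-slot offsets
#'
#' The (dx, dy) offset of each neighbor slot 1..8, in the fixed enumeration
#' used by the flattened edge indexing.
#'
#' @return an 8 x 2 integer matrix.
#' @export
neighbor_offsets <- function() {
  cbind(dx = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L),
        dy = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L))
}
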