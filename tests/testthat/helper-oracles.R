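# Independent brute-force oracles used to pin the compiled implementation.

# full energy recomputed in R from the raw spin field: adhesion over
# unordered Moore-adjacent pairs (lattice frame excluded) + constraint terms
# for every cell that holds, or ever held, sites
brute_hamiltonian <- function(spins, types, J, lambda_area, lambda_length,
                              target_area, target_length,
                              ever_alive = sort(unique(spins[spins > 0]))) {
  W <- nrow(spins); H <- ncol(spins)
  type_of <- function(s) ifelse(s == 0, 0, types[s])
  Hadh <- 0
  for (x in 2:(W - 1)) {
    for (y in 2:(H - 1)) {
      for (off in list(c(1, 0), c(0, 1), c(1, 1), c(-1, 1))) {
        x2 <- x + off[1]; y2 <- y + off[2]
        if (x2 < 2 || x2 > W - 1 || y2 < 2 || y2 > H - 1) next
        s1 <- spins[x, y]; s2 <- spins[x2, y2]
        if (s1 != s2) Hadh <- Hadh + J[type_of(s1) + 1, type_of(s2) + 1]
      }
    }
  }
  Hcon <- 0
  for (s in ever_alive) {
    sites <- which(spins == s, arr.ind = TRUE)
    A <- nrow(sites)
    L <- if (A > 0) cell_length(sites) else 0
    Hcon <- Hcon + lambda_area * (A - target_area)^2 +
      lambda_length * (L - target_length)^2
  }
  Hadh + Hcon
}

# directed boundary-pair slots (0-based, slot = p * 8 + k) by exhaustive scan
brute_edge_slots <- function(spins) {
  W <- nrow(spins); H <- ncol(spins)
  offs <- neighbor_offsets()
  slots <- integer(0)
  for (y in 2:(H - 1)) for (x in 2:(W - 1)) for (k in 1:8) {
    x2 <- x + offs[k, 1]; y2 <- y + offs[k, 2]
    if (x2 < 2 || x2 > W - 1 || y2 < 2 || y2 > H - 1) next
    if (spins[x, y] != spins[x2, y2])
      slots <- c(slots, ((y - 1) * W + (x - 1)) * 8 + (k - 1))
  }
  sort(slots)
}

# Fasano-Franceschini D by direct looping (open quadrants, origin excluded)
brute_ks2d <- function(a, b) {
  quad_d <- function(origins) {
    d <- 0
    for (i in seq_len(nrow(origins))) {
      x0 <- origins[i, 1]; y0 <- origins[i, 2]
      fa <- c(mean(a[, 1] > x0 & a[, 2] > y0), mean(a[, 1] < x0 & a[, 2] > y0),
              mean(a[, 1] < x0 & a[, 2] < y0), mean(a[, 1] > x0 & a[, 2] < y0))
      fb <- c(mean(b[, 1] > x0 & b[, 2] > y0), mean(b[, 1] < x0 & b[, 2] > y0),
              mean(b[, 1] < x0 & b[, 2] < y0), mean(b[, 1] > x0 & b[, 2] < y0))
      d <- max(d, max(abs(fa - fb)))
    }
    d
  }
  (quad_d(a) + quad_d(b)) / 2
}

# small lattice with a few rectangular cells, for toy configurations
toy_spins <- function(W = 16, H = 16) {
  m <- matrix(0L, W, H)
  m[3:6, 3:7] <- 1L
  m[7:10, 3:6] <- 2L
  m[4:8, 9:13] <- 3L
  m
}

toy_model <- function(spins = toy_spins(), temperature = 50, lambda_F = 0,
                      seed = 42, sampler = "edge_list", ...) {
  W <- nrow(spins); H <- ncol(spins)
  params <- cpm_params(model = "ce_one_type", n_cells = max(spins),
                       width = W, height = H, temperature = temperature,
                       lambda_F = lambda_F, seed = seed, ...)
  cpm_model(params, init = "spins", spins = spins, sampler = sampler)
}

# random multi-cell configuration grown briefly from single sites
fuzz_model <- function(n_cells = 4, W = 24, H = 24, seed = 1, grow = 30, ...) {
  set.seed(seed)
  m <- matrix(0L, W, H)
  pos <- cbind(sample(5:(W - 4), n_cells), sample(5:(H - 4), n_cells))
  for (i in seq_len(n_cells)) m[pos[i, 1], pos[i, 2]] <- i
  params <- cpm_params(model = "ce_one_type", n_cells = n_cells,
                       width = W, height = H, target_area = 25,
                       target_length = 6, lambda_F = 0, seed = seed, ...)
  mod <- cpm_model(params, init = "spins", spins = m)
  if (grow > 0) run_mcs(mod, grow)
  mod
}
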