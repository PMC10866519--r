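#' Run one gastruloid simulation
#'
#' Builds a [cpm_model()] from the parameter set, runs it for `params$mcs`
#' Monte Carlo steps and records the scaled LOCO-EFA coefficients of the
#' tissue outline every `record_every` MCS (and at the final step).
#' Optionally tracks a subset of cell centers and writes label-image
#' snapshots.
#'
#' @param params a [cpm_params()]; `params$seed` seeds the whole run.
#' @param record_every cadence (MCS) of shape measurements.
#' @param track_cells integer vector of cell IDs whose centers are recorded
#'   at every measurement between `track_from` and the final MCS, or `NULL`.
#' @param track_from first MCS of track recording (the elongation axis is
#'   ill-defined earlier).
#' @param snapshot_dir directory for PNG snapshots and per-snapshot cell
#'   CSVs every `params$snapshot_interval` MCS, or `NULL`.
#' @param keep_model return the live model object (holds the full lattice).
#' @return list with `trace` (data frame: mcs, L1, L2_L1, L3_L1), `cells`
#'   (final cell table), `mask` (final tissue mask), `tracks` (or `NULL`),
#'   `params`, and optionally `model`.
#' @export
simulate_gastruloid <- function(params = cpm_params(), record_every = 5000,
                                track_cells = NULL, track_from = 20000,
                                snapshot_dir = NULL, keep_model = FALSE) {
  model <- cpm_model(params)
  record_at <- sort(unique(c(seq(0, params$mcs, by = record_every), params$mcs)))
  snap_at <- if (!is.null(snapshot_dir))
    seq(0, params$mcs, by = params$snapshot_interval) else numeric(0)
  if (!is.null(snapshot_dir) && !dir.exists(snapshot_dir))
    dir.create(snapshot_dir, recursive = TRUE)
  stops <- sort(unique(c(record_at, snap_at)))
  trace <- list(); tracks <- list()
  warned_frame <- FALSE
  now <- 0
  for (s in stops) {
    if (s > now) {
      run_mcs(model, s - now)
      now <- s
    }
    if (s %in% record_at) {
      # tissues occasionally shed satellite cells; the outline of the main
      # body is what is scored, so multi-component warnings are muted here
      sp <- tryCatch(suppressWarnings(shape_spectrum(sim_mask(model))),
                     error = function(e) NULL)
      trace[[length(trace) + 1]] <- data.frame(
        mcs = s,
        L1 = if (is.null(sp)) NA_real_ else sp$L[1],
        L2_L1 = if (is.null(sp)) NA_real_ else sp$ratios[1],
        L3_L1 = if (is.null(sp)) NA_real_ else sp$ratios[2])
      if (!is.null(track_cells) && s >= track_from) {
        cells <- cpm_cells(model)
        sel <- cells[cells$id %in% track_cells, c("id", "x", "y")]
        tracks[[length(tracks) + 1]] <-
          data.frame(cell_id = sel$id, frame = s, x = sel$x, y = sel$y)
      }
      if (!warned_frame && tissue_touches_frame(model)) {
        warning("tissue touches the lattice frame at MCS ", s)
        warned_frame <- TRUE
      }
    }
    if (s %in% snap_at) write_snapshot(model, snapshot_dir, s)
  }
  out <- list(trace = do.call(rbind, trace), cells = cpm_cells(model),
              mask = sim_mask(model),
              tracks = if (length(tracks)) do.call(rbind, tracks) else NULL,
              params = params)
  if (keep_model) out$model <- model
  out
}

tissue_touches_frame <- function(model) {
  sp <- cpm_spins(model)
  W <- nrow(sp); H <- ncol(sp)
  any(sp[2, ] > 0) || any(sp[W - 1, ] > 0) ||
    any(sp[, 2] > 0) || any(sp[, H - 1] > 0)
}

#' Write a label-image snapshot
#'
#' One gray level per cell plus a type-colored variant, and a per-snapshot
#' CSV of the cell table (id, type, area, center, length, polarization).
#'
#' @param model a [cpm_model()].
#' @param dir output directory.
#' @param mcs Monte Carlo time used in the file names.
#' @export
write_snapshot <- function(model, dir, mcs = cpm_mcs(model)) {
  sp <- cpm_spins(model)
  n <- max(max(sp), 1)
  gray_img <- t(sp) / n
  png::writePNG(gray_img, file.path(dir, sprintf("labels_%07d.png", mcs)))
  cells <- cpm_cells(model)
  type_of <- c(0, cells$type)  # medium black, then type colors
  pal <- cbind(c(0, 0.85, 0.95, seq(0.2, 0.9, length.out = 8)),
               c(0, 0.25, 0.85, seq(0.9, 0.2, length.out = 8)),
               c(0, 0.25, 0.2, seq(0.5, 0.5, length.out = 8)))
  ti <- type_of[sp + 1] + 1
  rgb <- array(0, dim = c(ncol(sp), nrow(sp), 3))
  for (ch in 1:3) rgb[, , ch] <- t(matrix(pal[pmin(ti, nrow(pal)), ch],
                                          nrow(sp), ncol(sp)))
  png::writePNG(rgb, file.path(dir, sprintf("types_%07d.png", mcs)))
  utils::write.csv(cells, file.path(dir, sprintf("cells_%07d.csv", mcs)),
                   row.names = FALSE)
  invisible(NULL)
}

#' Run repeated simulations of one condition
#'
#' Runs `n_repeats` independent simulations (seed of repeat `i` is
#' `seed + i - 1`), collecting the LOCO-EFA trace of each, and summarizes
#' the final scaled coefficients as mean and SD over the population.
#'
#' @param params a [cpm_params()] (its `seed` is overridden per repeat).
#' @param n_repeats number of repeats.
#' @param seed base seed.
#' @param record_every measurement cadence, MCS.
#' @param out_dir if non-NULL, writes `population.csv`, `summary.csv` and a
#'   `manifest.txt` (config snapshot, seeds, package version) there.
#' @return list with `population` (one row per repeat and measurement),
#'   `final` (one row per repeat at the final MCS), and `summary`.
#' @export
run_experiment <- function(params = cpm_params(), n_repeats = 100,
                           seed = params$seed, record_every = 5000,
                           out_dir = NULL) {
  pop <- vector("list", n_repeats)
  for (i in seq_len(n_repeats)) {
    p <- params
    p$seed <- as.integer(seed + i - 1)
    res <- simulate_gastruloid(p, record_every = record_every)
    tr <- res$trace
    tr$run <- i
    tr$seed <- p$seed
    pop[[i]] <- tr
  }
  pop <- do.call(rbind, pop)
  final <- pop[pop$mcs == max(pop$mcs), ]
  summary <- data.frame(
    n_runs = n_repeats, mcs = max(pop$mcs),
    L2_L1_mean = mean(final$L2_L1, na.rm = TRUE),
    L2_L1_sd = stats::sd(final$L2_L1),
    L3_L1_mean = mean(final$L3_L1, na.rm = TRUE),
    L3_L1_sd = stats::sd(final$L3_L1))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(pop, file.path(out_dir, "population.csv"), row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
    writeLines(c(sprintf("gastruloidCPM %s", utils::packageVersion("gastruloidCPM")),
                 sprintf("base_seed: %d", as.integer(seed)),
                 sprintf("n_repeats: %d", n_repeats),
                 "config:", paste0("  ", format_config(params))),
               file.path(out_dir, "manifest.txt"))
  }
  list(population = pop, final = final, summary = summary)
}

#' Full-factorial parameter sweep
#'
#' Expands a grid of parameter values, runs `n_repeats` simulations per
#' combination and returns one tidy row per run with all parameters and the
#' final scaled coefficients.
#'
#' @param params base [cpm_params()].
#' @param grid named list of parameter values, e.g.
#'   `list(slope = c(1, 2.5, 4))`.
#' @param n_repeats repeats per grid point.
#' @param seed base seed (each run gets a distinct derived seed).
#' @param record_every measurement cadence.
#' @param max_runs refuse larger sweeps with a size estimate.
#' @return data frame: grid columns, `run`, `seed`, `L1`, `L2_L1`, `L3_L1`.
#' @export
sweep_grid <- function(params, grid, n_repeats = 20, seed = params$seed,
                       record_every = 5000, max_runs = 1000) {
  bad <- setdiff(names(grid), names(params))
  if (length(bad)) stop("unknown parameter(s) in grid: ", paste(bad, collapse = ", "))
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  n_total <- nrow(combos) * n_repeats
  if (n_total > max_runs)
    stop("sweep of ", nrow(combos), " combinations x ", n_repeats,
         " repeats = ", n_total, " runs exceeds max_runs = ", max_runs)
  out <- list()
  run_counter <- 0
  for (ci in seq_len(nrow(combos))) {
    p <- params
    for (nm in names(grid)) p[[nm]] <- combos[ci, nm]
    for (r in seq_len(n_repeats)) {
      run_counter <- run_counter + 1
      p$seed <- as.integer(seed + run_counter - 1)
      res <- simulate_gastruloid(p, record_every = record_every)
      fin <- res$trace[nrow(res$trace), ]
      out[[run_counter]] <- cbind(combos[ci, , drop = FALSE],
                                  data.frame(run = r, seed = p$seed,
                                             L1 = fin$L1, L2_L1 = fin$L2_L1,
                                             L3_L1 = fin$L3_L1))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ----------------------------------------------------------------- config IO

config_keys <- function() {
  c("model", "temperature", "target_area", "target_length", "lambda_area",
    "lambda_length", "mcs", "n_cells", "theta_max", "r_max", "n_max",
    "t_interval", "w", "lambda_F", "J_cell_medium", "J_cell_cell",
    "gamma_12", "offset", "slope", "type2_fraction", "repolarization_mode",
    "width", "height", "seed", "snapshot_interval", "burnin_mcs")
}

#' Read / write a flat key-value simulation config
#'
#' The config file is a flat `key = value` text file using exactly the
#' parameter names of [cpm_params()] (`temperature`, `target_area`,
#' `lambda_area`, `mcs`, `n_cells`, `theta_max`, `r_max`, `n_max`,
#' `t_interval`, `w`, `lambda_F`, `J_cell_medium`, `J_cell_cell`, `model`,
#' `seed`, `snapshot_interval`, ...). Lines starting with `#` are comments.
#' Unknown keys raise an error listing the valid names.
#'
#' @param file path.
#' @return `read_config()`: a [cpm_params()] object.
#' @export
read_config <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2)) stop("malformed config line(s): expected key = value")
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  bad <- setdiff(keys, config_keys())
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         "\nvalid keys: ", paste(config_keys(), collapse = ", "))
  args <- stats::setNames(as.list(vals), keys)
  num <- setdiff(keys, c("model", "repolarization_mode"))
  args[num] <- lapply(args[num], as.numeric)
  do.call(cpm_params, args)
}

#' @rdname read_config
#' @param params a [cpm_params()].
#' @export
write_config <- function(params, file) {
  writeLines(format_config(params), file)
  invisible(file)
}

format_config <- function(params) {
  vapply(config_keys(), function(k) paste(k, "=", format(params[[k]])), "")
}
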