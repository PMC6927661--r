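scenario_names <- c("static-shapes", "shrink-equilibrate", "signaling-cell",
                    "adhesion-pair", "signaling-pair", "sorting-separation",
                    "sorting-checkerboard", "sorting-engulfment")

scenario_defaults <- function(name) {
  switch(name,
    "static-shapes" = list(
      width = 50, height = 50, a = 300, p = 100, lambda_a = 10, lambda_p = 10,
      j_medium = 3000, temperature = 0, n_mcs = 0, record_every = 1,
      smooth_radius = 3
    ),
    "shrink-equilibrate" = list(
      width = 50, height = 50, diameter = 23, a = 200, p = 100, lambda_a = 8,
      lambda_p = 2000, j_medium = 3000, temperature = 10, n_mcs = 10,
      record_every = 1
    ),
    "signaling-cell" = list(
      width = 110, height = 110, diameter = 71.4, a = 4000, p = 0,
      lambda_a = 10, lambda_p = 0, j_medium = 5000, temperature = 50,
      beta = 40, r_active = 3, r_inactive = 75, n_mcs = 150, record_every = 25
    ),
    "adhesion-pair" = list(
      width = 80, height = 50, diameter = 20, gap = 19, a = 300, p = 0,
      lambda_a = 8, lambda_p = 0, j_medium = 1800, j_cell = 3600,
      temperature = 300, n_mcs = 200, record_every = 1
    ),
    "signaling-pair" = list(
      width = 190, height = 110, diameter = 56.4, gap = 55, a = 2500, p = 0,
      lambda_a = 2, lambda_p = 0, j_medium = 30000, j_cell = 30000,
      temperature = 200, beta = 80, r_active = 3, r_inactive = 75,
      n_mcs = 480, record_every = 40
    ),
    "sorting-separation" = list(
      width = 200, height = 200, n_side = 10, cell_side = 17, a = 300,
      p = 67, lambda_a = 1000, lambda_p = 20, j_medium = 1800, j_same = 900,
      j_diff = 9000, temperature = 600, n_mcs = 1000, record_every = 100
    ),
    "sorting-checkerboard" = list(
      width = 200, height = 200, n_side = 10, cell_side = 17, a = 300,
      p = 67, lambda_a = 1000, lambda_p = 20, j_medium = 1800, j_same = 7200,
      j_diff = 1800, temperature = 600, n_mcs = 1000, record_every = 100
    ),
    "sorting-engulfment" = list(
      width = 200, height = 200, n_side = 10, cell_side = 17, a = 300,
      p = 67, lambda_a = 1000, lambda_p = 20, j_medium = c(1800, 9000),
      j_same = 1800, j_diff = 3600, temperature = 600, n_mcs = 1000,
      record_every = 100
    ),
    abort(sprintf("unknown scenario '%s'; valid names: %s", name,
                  paste(scenario_names, collapse = ", ")))
  )
}

# two tangent/overlapping disks of two types on one lattice
two_cell_spin <- function(width, height, diameter, gap) {
  cy <- (height + 1) / 2
  cx1 <- (width + 1) / 2 - gap / 2
  cx2 <- cx1 + gap
  spin <- matrix(0L, height, width)
  xs <- matrix(rep(seq_len(width), each = height), height, width)
  ys <- matrix(rep(seq_len(height), times = width), height, width)
  r2 <- (diameter / 2)^2
  in1 <- (xs - cx1)^2 + (ys - cy)^2 <= r2
  in2 <- (xs - cx2)^2 + (ys - cy)^2 <= r2
  spin[in2] <- 2L
  spin[in1] <- 1L  # overlap resolves to cell 1
  spin
}

# n_side x n_side grid of square cells, 50/50 random types (uses current RNG)
sorting_spin <- function(width, height, n_side, cell_side) {
  span <- n_side * cell_side
  if (span + 2 * 10 > min(width, height))
    abort("sorting aggregate does not fit the lattice")
  off_r <- floor((height - span) / 2)
  off_c <- floor((width - span) / 2)
  spin <- matrix(0L, height, width)
  cid <- 0L
  for (br in seq_len(n_side)) for (bc in seq_len(n_side)) {
    cid <- cid + 1L
    rows <- off_r + ((br - 1) * cell_side + 1):(br * cell_side)
    cols <- off_c + ((bc - 1) * cell_side + 1):(bc * cell_side)
    spin[rows, cols] <- cid
  }
  n <- n_side^2
  types <- sample(rep(1:2, length.out = n))
  list(spin = spin, types = as.integer(types))
}

#' Total interface lengths by contact class
#'
#' @param state A [cpm_state()].
#' @return A one-row tibble with scaled `medium`, `homotypic` and
#'   `heterotypic` interface lengths (each unordered interface counted once).
#' @export
interface_totals <- function(state) {
  M <- state$cache$pairs
  ty <- state$cells$type
  n <- nrow(state$cells)
  med <- sum(M[seq_len(n) + 1, 1]) / state$xi
  hom <- het <- 0
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      len <- M[i + 1, j + 1] / state$xi
      if (ty[i] == ty[j]) hom <- hom + len else het <- het + len
    }
  }
  tibble(medium = med, homotypic = hom, heterotypic = het)
}

#' Run a packaged scenario
#'
#' Reproduces the package's benchmark simulations: static force maps for
#' disk/ellipse/blob shapes, a single shrinking-equilibrating cell, a
#' polarized motile cell, a two-cell adhesion pair, a signaling pair, and the
#' three classic cell-sorting regimes (separation, checkerboard, engulfment).
#' Defaults are the benchmark parameter sets; any entry can be overridden.
#'
#' @param name One of `r paste0('"', scenario_names, '"', collapse = ", ")`.
#' @param seed Integer seed controlling all randomness of the run.
#' @param n_mcs Number of Monte Carlo steps (default: scenario-specific).
#' @param record_every Snapshot/summary cadence in MCS.
#' @param params Named list of overrides of the scenario defaults.
#' @return A list of class `cpm_scenario`: `name`, `seed`, `params`,
#'   `summary` (per-cell series), `interfaces` (interface-length series),
#'   `snapshots` (spin matrices by MCS), `final_state`, and for force or
#'   signaling scenarios `forces` / `chem`.
#' @export
run_scenario <- function(name, seed = 1L, n_mcs = NULL, record_every = NULL,
                         params = list()) {
  if (!name %in% scenario_names)
    abort(sprintf("unknown scenario '%s'; valid names: %s", name,
                  paste(scenario_names, collapse = ", ")))
  cfg <- modifyList(scenario_defaults(name), params)
  if (!is.null(n_mcs)) cfg$n_mcs <- n_mcs
  if (!is.null(record_every)) cfg$record_every <- record_every
  set.seed(as.integer(seed))

  if (name == "static-shapes") return(run_static_shapes(cfg, seed))

  chem <- NULL
  coupling <- NULL
  if (name == "shrink-equilibrate") {
    state <- single_cell_state("disk", width = cfg$width, height = cfg$height,
                               diameter = cfg$diameter, a = cfg$a, p = cfg$p,
                               lambda_a = cfg$lambda_a, lambda_p = cfg$lambda_p,
                               j_medium = cfg$j_medium,
                               temperature = cfg$temperature)
  } else if (name == "signaling-cell") {
    state <- single_cell_state("disk", width = cfg$width, height = cfg$height,
                               diameter = cfg$diameter, a = cfg$a, p = cfg$p,
                               lambda_a = cfg$lambda_a, lambda_p = cfg$lambda_p,
                               j_medium = cfg$j_medium,
                               temperature = cfg$temperature)
    chem <- init_chem_polarized(state)
    coupling <- coupling_params(beta = cfg$beta, r_active = cfg$r_active,
                                r_inactive = cfg$r_inactive)
  } else if (name %in% c("adhesion-pair", "signaling-pair")) {
    spin <- two_cell_spin(cfg$width, cfg$height, cfg$diameter, cfg$gap)
    cells <- cpm_cells(id = 1:2, type = 1:2, a = cfg$a, p = cfg$p,
                       lambda_a = cfg$lambda_a, lambda_p = cfg$lambda_p)
    J <- adhesion_matrix(2, j_medium = cfg$j_medium, j_same = cfg$j_cell,
                         j_diff = cfg$j_cell)
    state <- cpm_state(spin, cells, J, temperature = cfg$temperature)
    if (name == "signaling-pair") {
      chem <- init_chem_polarized(state)
      coupling <- coupling_params(beta = cfg$beta, r_active = cfg$r_active,
                                  r_inactive = cfg$r_inactive)
    }
  } else {  # sorting
    agg <- sorting_spin(cfg$width, cfg$height, cfg$n_side, cfg$cell_side)
    cells <- cpm_cells(id = seq_along(agg$types), type = agg$types, a = cfg$a,
                       p = cfg$p, lambda_a = cfg$lambda_a,
                       lambda_p = cfg$lambda_p)
    jm <- rep_len(cfg$j_medium, 2)
    J <- adhesion_matrix(2, j_medium = jm, j_same = cfg$j_same,
                         j_diff = cfg$j_diff)
    state <- cpm_state(agg$spin, cells, J, temperature = cfg$temperature)
  }

  rd <- if (!is.null(chem)) rd_params() else NULL
  summary <- list(); interfaces <- list(); snaps <- list()
  record <- function(step) {
    summary[[length(summary) + 1]] <<- mutate(tidy(state), mcs = step)
    interfaces[[length(interfaces) + 1]] <<-
      mutate(interface_totals(state),
             pair_12 = if (nrow(state$cells) >= 2)
               state$cache$pairs[2, 3] / state$xi else NA_real_,
             mcs = step)
    snaps[[as.character(step)]] <<- state$spin
  }
  record(0L)
  step <- 0L
  while (step < cfg$n_mcs) {
    k <- min(cfg$record_every, cfg$n_mcs - step)
    if (is.null(chem)) {
      state <- mcs(state, k)
    } else {
      for (i in seq_len(k)) {
        chem <- rd_step(chem, state, rd, nsteps = rd$substeps)
        state <- mcs(state, 1, chem = chem, coupling = coupling)
        chem <- state$chem
      }
    }
    step <- step + k
    record(step)
  }
  structure(list(name = name, seed = seed, params = cfg,
                 summary = bind_rows(summary),
                 interfaces = bind_rows(interfaces), snapshots = snaps,
                 final_state = state, chem = chem),
            class = "cpm_scenario")
}

run_static_shapes <- function(cfg, seed) {
  shapes <- list(
    disk = make_shape("disk", cfg$width, cfg$height, diameter = 23),
    ellipse = make_shape("ellipse", cfg$width, cfg$height,
                         semi_x = 10.5, semi_y = 20.5),
    blob = make_shape("blob", cfg$width, cfg$height, diameter = 20, seed = seed)
  )
  forces <- list(); summary <- list(); snaps <- list()
  for (nm in names(shapes)) {
    st <- cpm_state(shapes[[nm]],
                    cells = cpm_cells(1L, a = cfg$a, p = cfg$p,
                                      lambda_a = cfg$lambda_a,
                                      lambda_p = cfg$lambda_p),
                    J = adhesion_matrix(1, j_medium = cfg$j_medium),
                    temperature = cfg$temperature)
    forces[[nm]] <- cell_forces(st, smooth_radius = cfg$smooth_radius)
    summary[[nm]] <- mutate(tidy(st), shape = nm, mcs = 0L)
    snaps[[nm]] <- st$spin
  }
  structure(list(name = "static-shapes", seed = seed, params = cfg,
                 summary = bind_rows(summary), interfaces = tibble(),
                 snapshots = snaps, forces = forces, final_state = NULL,
                 chem = NULL),
            class = "cpm_scenario")
}

#' Rebuild the CPM state at a recorded step
#'
#' @param scenario A [run_scenario()] result.
#' @param mcs_at Recorded MCS index (must be one of the snapshot steps).
#' @return A [cpm_state()].
#' @export
state_at <- function(scenario, mcs_at) {
  key <- as.character(mcs_at)
  if (!key %in% names(scenario$snapshots))
    abort(sprintf("no snapshot at MCS %s; recorded: %s", key,
                  paste(names(scenario$snapshots), collapse = ", ")))
  st <- scenario$final_state
  if (is.null(st)) abort("scenario holds no reconstructible state")
  st$spin <- scenario$snapshots[[key]]
  refresh_cache(st)
}

#' @export
print.cpm_scenario <- function(x, ...) {
  cat(sprintf("<cpm_scenario '%s'> seed %s, %d recorded step(s)\n",
              x$name, format(x$seed), length(x$snapshots)))
  invisible(x)
}

#' Long summary series of a scenario
#'
#' @param x A [run_scenario()] result.
#' @param ... Unused.
#' @return The per-cell summary tibble (one row per cell and recorded MCS).
#' @export
tidy.cpm_scenario <- function(x, ...) x$summary

#' One-row scenario summary
#'
#' @param x A [run_scenario()] result.
#' @param ... Unused.
#' @return A tibble with the scenario name, seed, cell count and final
#'   interface totals.
#' @export
glance.cpm_scenario <- function(x, ...) {
  last <- if (nrow(x$interfaces)) x$interfaces[nrow(x$interfaces), ] else
    tibble(medium = NA_real_, homotypic = NA_real_, heterotypic = NA_real_)
  tibble(name = x$name, seed = x$seed,
         n_mcs = max(c(0, x$summary$mcs)),
         n_cells = length(unique(x$summary$id)),
         medium = last$medium, homotypic = last$homotypic,
         heterotypic = last$heterotypic)
}
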