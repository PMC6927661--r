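#' Per-cell parameter table
#'
#' Builds the table of per-cell targets and energy weights used by the
#' Hamiltonian: rest area `a` (sites), rest perimeter `p` (neighborhood-scaled
#' length), and the quadratic weights `lambda_a`, `lambda_p`. Arguments are
#' recycled to the number of cells.
#'
#' @param id Positive integer cell indices (the spin values in the lattice).
#' @param type Small positive integer cell type; adhesion energies are looked
#'   up by type pair. Medium is always type 0.
#' @param a,p Rest area and rest perimeter.
#' @param lambda_a,lambda_p Energy weights (>= 0).
#' @return A tibble with one row per cell.
#' @export
#' @examples
#' cpm_cells(id = 1:2, type = c(1, 2), a = 300, p = 100,
#'           lambda_a = 10, lambda_p = 10)
cpm_cells <- function(id, type = 1L, a = 0, p = 0, lambda_a = 0, lambda_p = 0) {
  id <- as.integer(id)
  if (length(id) == 0 || any(id <= 0)) abort("cell ids must be positive integers")
  if (anyDuplicated(id)) abort("cell ids must be unique")
  out <- tibble(
    id = id,
    type = as.integer(rep_len(type, length(id))),
    a = as.numeric(rep_len(a, length(id))),
    p = as.numeric(rep_len(p, length(id))),
    lambda_a = as.numeric(rep_len(lambda_a, length(id))),
    lambda_p = as.numeric(rep_len(lambda_p, length(id)))
  )
  if (any(out$type <= 0)) abort("cell types must be positive (0 is the medium)")
  if (any(out$a < 0) || any(out$p < 0) || any(out$lambda_a < 0) || any(out$lambda_p < 0))
    abort("rest targets and energy weights must be non-negative")
  dplyr::arrange(out, .data$id)
}

#' Contact-energy matrix
#'
#' Builds a symmetric adhesion matrix `J` indexed by cell type, with row/column
#' 1 corresponding to the medium (type 0). `J[t1 + 1, t2 + 1]` is the contact
#' energy per unit interface length between types `t1` and `t2`.
#'
#' @param n_types Number of (non-medium) cell types.
#' @param j_medium Energy of a cell-medium interface; recycled over types.
#' @param j_same Energy of a homotypic cell-cell interface.
#' @param j_diff Energy of a heterotypic cell-cell interface.
#' @return A `(n_types + 1) x (n_types + 1)` numeric matrix.
#' @export
adhesion_matrix <- function(n_types = 1, j_medium = 0, j_same = 0, j_diff = j_same) {
  n <- as.integer(n_types)
  J <- matrix(0, n + 1, n + 1)
  jm <- rep_len(j_medium, n)
  js <- rep_len(j_same, n)
  for (t in seq_len(n)) {
    J[1, t + 1] <- J[t + 1, 1] <- jm[t]
    J[t + 1, t + 1] <- js[t]
  }
  if (n > 1) {
    for (t1 in seq_len(n - 1)) for (t2 in (t1 + 1):n) {
      J[t1 + 1, t2 + 1] <- J[t2 + 1, t1 + 1] <- j_diff
    }
  }
  dimnames(J) <- list(0:n, 0:n)
  J
}

#' Cellular Potts state
#'
#' Bundles a lattice spin configuration with per-cell parameters, the adhesion
#' matrix, and the Monte Carlo settings, and caches the per-cell areas and
#' neighborhood pair counts that the Hamiltonian needs.
#'
#' The spin matrix holds one non-negative integer per site, 0 denoting medium;
#' rows run down the lattice (y), columns run right (x). Sites beyond the
#' lattice edge are treated as medium. Every cell present must occupy a
#' 4-connected set of sites.
#'
#' @param spin Integer matrix of cell indices.
#' @param cells Per-cell parameter table from [cpm_cells()]. Defaults to a
#'   table covering the indices present in `spin` with zero weights.
#' @param J Contact-energy matrix from [adhesion_matrix()].
#' @param temperature Metropolis temperature `T >= 0`.
#' @param h0 Yield energy added to every energy change before the acceptance
#'   test (default 0).
#' @param radius Neighborhood radius for perimeter estimation (default 3).
#' @param xi Perimeter scale factor `xi(radius)`; 18 is the calibrated value
#'   for radius 3.
#' @param h Lattice spacing (length units per site, default 1).
#' @return An object of class `cpm_state`.
#' @export
cpm_state <- function(spin, cells = NULL, J = NULL, temperature = 0, h0 = 0,
                      radius = 3, xi = 18, h = 1) {
  spin <- as.matrix(spin)
  storage.mode(spin) <- "integer"
  if (nrow(spin) < 3 || ncol(spin) < 3) abort("lattice must be at least 3 x 3 sites")
  if (any(is.na(spin)) || any(spin < 0)) abort("spin values must be non-negative integers")
  if (h <= 0) abort("lattice spacing h must be positive")
  if (temperature < 0) abort("temperature must be non-negative")
  if (h0 < 0) abort("yield energy h0 must be non-negative")
  if (radius < 1) abort("neighborhood radius must be at least 1")
  if (xi <= 0) abort("perimeter scale xi must be positive")

  present <- sort(unique(spin[spin > 0]))
  if (is.null(cells)) {
    ids <- if (length(present)) seq_len(max(present)) else integer()
    cells <- cpm_cells(id = ids)
  }
  if (length(present) && !all(present %in% cells$id))
    abort("every nonzero spin index must have a row in `cells`")
  if (nrow(cells) && !identical(cells$id, seq_len(nrow(cells))))
    abort("cell ids must be the contiguous set 1..n")
  ntype <- max(1L, if (nrow(cells)) max(cells$type) else 1L)
  if (is.null(J)) J <- adhesion_matrix(ntype)
  J <- as.matrix(J)
  if (nrow(J) != ncol(J) || nrow(J) < ntype + 1)
    abort("adhesion matrix must be square and cover every cell type plus the medium")
  if (!isTRUE(all.equal(J, t(J)))) abort("adhesion matrix must be symmetric")

  state <- structure(
    list(spin = spin, cells = cells, J = J,
         temperature = as.numeric(temperature), h0 = as.numeric(h0),
         radius = as.numeric(radius), xi = as.numeric(xi), h = as.numeric(h),
         cache = NULL),
    class = "cpm_state"
  )
  refresh_cache(state)
}

refresh_cache <- function(state) {
  cc <- cpp_state_counts(state$spin, state$radius, state$cells$a, state$cells$p,
                         state$cells$lambda_a, state$cells$lambda_p,
                         state$cells$type, state$J, state$xi)
  state$cache <- list(area = cc$area, discordant = cc$discordant,
                      pairs = cc$pairs, hamiltonian = cc$hamiltonian)
  state
}

check_cell_id <- function(state, id) {
  id <- as.integer(id)
  if (length(id) != 1 || is.na(id) || !(id %in% state$cells$id))
    abort(sprintf("unknown cell id: %s", paste(id, collapse = ",")))
  id
}

# site = c(x, y), 1-based column/row
check_site <- function(state, site) {
  site <- as.integer(site)
  if (length(site) != 2 || any(is.na(site)) ||
      site[1] < 1 || site[1] > ncol(state$spin) ||
      site[2] < 1 || site[2] > nrow(state$spin))
    abort("site must be c(x, y) within the lattice")
  site
}

spin_at <- function(state, site) state$spin[site[2], site[1]]

#' @export
print.cpm_state <- function(x, ...) {
  cat(sprintf("<cpm_state> %d x %d lattice, %d cell(s), T = %g\n",
              ncol(x$spin), nrow(x$spin), nrow(x$cells), x$temperature))
  cat(sprintf("  H = %g, radius = %g, xi = %g, h = %g\n",
              x$cache$hamiltonian, x$radius, x$xi, x$h))
  invisible(x)
}

#' @export
dim.cpm_state <- function(x) dim(x$spin)

#' Per-cell summary of a CPM state
#'
#' @param x A [cpm_state()].
#' @param ... Unused.
#' @return A tibble with one row per cell: current area and scaled perimeter,
#'   their rest targets, the energy weights, and the cell centroid.
#' @export
tidy.cpm_state <- function(x, ...) {
  cents <- cell_centroids(x)
  dplyr::left_join(
    mutate(x$cells,
           area = x$cache$area[.data$id],
           perimeter = x$cache$discordant[.data$id] / x$xi),
    cents, by = "id"
  )
}

#' One-row summary of a CPM state
#'
#' @param x A [cpm_state()].
#' @param ... Unused.
#' @return A tibble with the cell count, total energy, and settings.
#' @export
glance.cpm_state <- function(x, ...) {
  tibble(n_cells = nrow(x$cells),
         width = ncol(x$spin), height = nrow(x$spin),
         hamiltonian = x$cache$hamiltonian,
         temperature = x$temperature, radius = x$radius, xi = x$xi)
}

#' Cell centroids
#'
#' @param state A [cpm_state()].
#' @return A tibble with columns `id`, `x`, `y` (site coordinates; NA for
#'   cells with no sites).
#' @export
cell_centroids <- function(state) {
  idx <- which(state$spin > 0, arr.ind = TRUE)
  if (!nrow(idx)) return(tibble(id = state$cells$id, x = NA_real_, y = NA_real_))
  d <- tibble(id = state$spin[idx], x = as.numeric(idx[, 2]), y = as.numeric(idx[, 1]))
  out <- summarise(group_by(d, .data$id), x = mean(.data$x), y = mean(.data$y),
                   .groups = "drop")
  dplyr::left_join(tibble(id = state$cells$id), out, by = "id")
}
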