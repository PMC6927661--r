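#' Cell area
#'
#' Number of lattice sites currently carrying a cell's index.
#'
#' @param state A [cpm_state()].
#' @param id Cell id.
#' @return Site count (integer-valued numeric).
#' @export
cell_area <- function(state, id) {
  id <- check_cell_id(state, id)
  state$cache$area[id]
}

#' Neighborhood-scaled cell perimeter
#'
#' Counts ordered site pairs `(x, y)` with `spin(x) = id`, `y` within Euclidean
#' distance `radius` of `x`, and `spin(y) != id`, and divides by the
#' calibration factor `xi(radius)` (18 for the default radius 3). This
#' neighborhood estimator suppresses the staircase bias of a naive edge count.
#'
#' @inheritParams cell_area
#' @return Scaled perimeter (lattice length units).
#' @export
cell_perimeter <- function(state, id) {
  id <- check_cell_id(state, id)
  state$cache$discordant[id] / state$xi
}

#' Interface length between two cells (or a cell and the medium)
#'
#' Scaled count of discordant pairs restricted to the two indices; `j = 0`
#' gives the cell-medium contact length.
#'
#' @inheritParams cell_area
#' @param j Second cell id, or 0 for the medium.
#' @return Scaled interface length.
#' @export
interface_length <- function(state, id, j = 0) {
  id <- check_cell_id(state, id)
  j <- as.integer(j)
  if (length(j) != 1 || is.na(j) || j < 0 || (j > 0 && !(j %in% state$cells$id)))
    abort("j must be 0 (medium) or a known cell id")
  state$cache$pairs[id + 1, j + 1] / state$xi
}

#' Total Hamiltonian
#'
#' Sum over cells of the quadratic area and perimeter penalties plus the
#' adhesion energy `J(0, tau_i) P_0i + (1/2) sum_j J(tau_i, tau_j) P_ij`;
#' the half corrects for double counting of each cell-cell interface.
#'
#' @param state A [cpm_state()].
#' @return Energy (scalar).
#' @export
hamiltonian <- function(state) {
  state$cache$hamiltonian
}

#' Per-cell Hamiltonian decomposition
#'
#' @param state A [cpm_state()].
#' @return A tibble with one row per cell and columns `h_area`, `h_perimeter`,
#'   `h_adhesion`, `h_total` (the cell's share `H^i`; shared interfaces count
#'   half toward each owner).
#' @export
hamiltonian_decomposition <- function(state) {
  cl <- state$cells
  n <- nrow(cl)
  A <- state$cache$area
  P <- state$cache$discordant / state$xi
  M <- state$cache$pairs
  h_adh <- vapply(seq_len(n), function(i) {
    ti <- cl$type[i]
    val <- state$J[1, ti + 1] * M[i + 1, 1] / state$xi
    if (n > 1) {
      for (j in seq_len(n)) {
        if (j == i) next
        val <- val + 0.5 * state$J[cl$type[i] + 1, cl$type[j] + 1] *
          M[i + 1, j + 1] / state$xi
      }
    }
    val
  }, numeric(1))
  out <- tibble(
    id = cl$id,
    h_area = cl$lambda_a * (A - cl$a)^2,
    h_perimeter = cl$lambda_p * (P - cl$p)^2,
    h_adhesion = h_adh
  )
  mutate(out, h_total = .data$h_area + .data$h_perimeter + .data$h_adhesion)
}

#' Energy change of a spin copy
#'
#' Energy difference produced by copying the spin of `source` onto `target`
#' (a protrusion of the source cell and/or retraction of the target cell).
#' Computed incrementally from local neighborhood counts; equals the full
#' recomputation difference exactly.
#'
#' @param state A [cpm_state()].
#' @param source,target Sites `c(x, y)`; `target` must be a Moore neighbor of
#'   `source` and carry a different spin.
#' @return Energy change (scalar).
#' @export
delta_h_flip <- function(state, source, target) {
  source <- check_site(state, source)
  target <- check_site(state, target)
  if (max(abs(source - target)) != 1)
    abort("target must be one of the eight Moore neighbors of source")
  s_new <- spin_at(state, source)
  s_old <- spin_at(state, target)
  if (s_new == s_old) abort("source and target already share a spin; not a valid flip")
  cpp_delta_h(state$spin, state$radius, state$cells$a, state$cells$p,
              state$cells$lambda_a, state$cells$lambda_p, state$cells$type,
              state$J, state$xi, target[2], target[1], s_new, 0L)
}

#' Metropolis acceptance probability
#'
#' Probability of accepting a move with energy change `dh` under temperature
#' `temperature` and yield energy `h0`: 1 when `dh + h0 < 0`, otherwise
#' `exp(-(dh + h0) / T)`. At `T = 0` an exactly neutral move is accepted
#' (the continuous limit of `exp(0)`), any uphill move is rejected.
#'
#' @param dh Energy change(s).
#' @param temperature Temperature `T >= 0`.
#' @param h0 Yield energy (default 0).
#' @return Probabilities in `[0, 1]`, vectorized over `dh`.
#' @export
accept_probability <- function(dh, temperature, h0 = 0) {
  if (temperature < 0) abort("temperature must be non-negative")
  x <- dh + h0
  ifelse(x <= 0, 1,
         ifelse(rep(temperature > 0, length(x)), exp(-x / max(temperature, .Machine$double.xmin)), 0))
}

#' Metropolis acceptance draw
#'
#' Draws accept/reject decisions with probability [accept_probability()],
#' using R's random number stream (seed with [set.seed()]).
#'
#' @inheritParams accept_probability
#' @return Logical vector.
#' @export
metropolis_accept <- function(dh, temperature, h0 = 0) {
  pr <- accept_probability(dh, temperature, h0)
  runif(length(pr)) < pr
}

#' Would removing a site fragment its cell?
#'
#' Tests the connectivity constraint: `TRUE` iff removing `site` from the cell
#' that owns it leaves the cell's remaining sites 4-connected (vacuously
#' `TRUE` for a single-site cell). A local 3x3 ring test answers most cases;
#' an exact flood fill is the fallback.
#'
#' @param state A [cpm_state()] (or a bare spin matrix).
#' @param site Site `c(x, y)` currently owned by a cell.
#' @return Logical.
#' @export
connectivity_preserved <- function(state, site) {
  spin <- if (inherits(state, "cpm_state")) state$spin else {
    m <- as.matrix(state); storage.mode(m) <- "integer"; m
  }
  site <- as.integer(site)
  if (length(site) != 2 || site[1] < 1 || site[1] > ncol(spin) ||
      site[2] < 1 || site[2] > nrow(spin))
    abort("site must be c(x, y) within the lattice")
  if (spin[site[2], site[1]] == 0) abort("site is medium; only cell sites can be removed")
  cpp_connectivity_preserved(spin, site[2], site[1])
}
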