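#' Wave-pinning reaction-diffusion parameters
#'
#' Kinetics for a single GTPase in active (`u`, slow-diffusing,
#' membrane-bound) and inactive (`v`, fast-diffusing, cytosolic) forms:
#' `f(u, v) = v (k0 + gamma_fb u^2 / (K^2 + u^2)) - eta u`, with
#' `du/dt = Du lap(u) + f` and `dv/dt = Dv lap(v) - f`. The defaults sit in
#' the bistable wave-pinning regime of the canonical model; `Du < Dv` is
#' required for pinning. The explicit scheme requires
#' `dt <= h^2 / (4 max(Du, Dv))`.
#'
#' @param Du,Dv Diffusion coefficients (length^2/time).
#' @param k0 Basal activation rate.
#' @param gamma_fb Feedback activation strength.
#' @param K Saturation constant of the positive feedback.
#' @param eta Inactivation rate.
#' @param dt Time step of the explicit update.
#' @param substeps Reaction-diffusion substeps per Monte Carlo step in coupled
#'   runs.
#' @return A list of class `rd_params`.
#' @export
rd_params <- function(Du = 0.1, Dv = 10, k0 = 0.067, gamma_fb = 1, K = 1,
                      eta = 1, dt = 0.02, substeps = 20) {
  if (Du >= Dv) abort("wave pinning requires Du < Dv")
  if (dt <= 0) abort("dt must be positive")
  structure(list(Du = Du, Dv = Dv, k0 = k0, gamma_fb = gamma_fb, K = K,
                 eta = eta, dt = dt, substeps = as.integer(substeps)),
            class = "rd_params")
}

#' Signaling-to-lattice coupling parameters
#'
#' The active signal augments the energy change of a boundary move by
#' `+beta u` for protrusions and `-beta u` for retractions, so high activity
#' promotes local contraction. After an accepted retraction the lost site's
#' chemical mass is redistributed within the losing cell: the active form
#' within `r_active` (membrane-local), the inactive form within `r_inactive`
#' (effectively cell-wide, reflecting fast cytosolic diffusion).
#'
#' @param beta Coupling strength (energy per unit concentration).
#' @param r_active,r_inactive Redistribution radii (lattice units, >= 1).
#' @return A list of class `coupling_params`.
#' @export
coupling_params <- function(beta = 40, r_active = 3, r_inactive = 75) {
  if (beta < 0) abort("beta must be non-negative")
  if (r_active < 1 || r_inactive < 1) abort("redistribution radii must be >= 1")
  structure(list(beta = beta, r_active = r_active, r_inactive = r_inactive),
            class = "coupling_params")
}

#' Chemical field on cell interiors
#'
#' Active/inactive concentrations per cell-owned site, stored as full-lattice
#' matrices that are zero on medium sites.
#'
#' @param state A [cpm_state()].
#' @param u,v Numeric matrices matching the lattice, or scalars recycled over
#'   all cell sites.
#' @return A list of class `chem_field` with matrices `u` and `v`.
#' @export
chem_field <- function(state, u = 0, v = 0) {
  mask <- state$spin > 0
  expand <- function(q) {
    if (is.matrix(q)) {
      if (!all(dim(q) == dim(state$spin))) abort("chem matrix must match the lattice")
      q <- q * mask
    } else {
      q <- matrix(as.numeric(q), nrow(state$spin), ncol(state$spin)) * mask
    }
    if (any(q < 0)) abort("concentrations must be non-negative")
    q
  }
  structure(list(u = expand(u), v = expand(v)), class = "chem_field")
}

#' Polarized initial chemical field
#'
#' Uniform inactive concentration plus an active strip along one edge of the
#' cell footprint: the leftmost `frac` of each cell's x-extent starts at
#' `u_high`, the remainder at `u_low`.
#'
#' @param state A [cpm_state()].
#' @param frac Fraction of the cell's x-extent that starts active.
#' @param u_high,u_low Active concentration inside/outside the strip.
#' @param v0 Uniform inactive concentration.
#' @return A [chem_field()].
#' @export
init_chem_polarized <- function(state, frac = 0.3, u_high = 2, u_low = 0.05, v0 = 2) {
  u <- matrix(0, nrow(state$spin), ncol(state$spin))
  for (cid in state$cells$id) {
    idx <- which(state$spin == cid, arr.ind = TRUE)
    if (!nrow(idx)) next
    xs <- idx[, 2]
    cut <- min(xs) + frac * (max(xs) - min(xs))
    u[idx] <- ifelse(xs <= cut, u_high, u_low)
  }
  chem_field(state, u = u, v = v0)
}

#' Total chemical mass per cell
#'
#' @param chem A [chem_field()].
#' @param state The matching [cpm_state()].
#' @return A tibble with per-cell `mass_u`, `mass_v` (concentration times
#'   site area `h^2`).
#' @export
chem_mass <- function(chem, state) {
  out <- lapply(state$cells$id, function(cid) {
    sel <- state$spin == cid
    tibble(id = cid,
           mass_u = sum(chem$u[sel]) * state$h^2,
           mass_v = sum(chem$v[sel]) * state$h^2)
  })
  bind_rows(out)
}

#' One (or more) explicit reaction-diffusion updates
#'
#' Advances the wave-pinning system on the current cell footprint with
#' zero-flux boundaries at every cell edge (no diffusion across cell-cell or
#' cell-medium interfaces). The conservative flux form keeps the total mass
#' `sum(u + v)` unchanged to rounding error.
#'
#' @param chem A [chem_field()].
#' @param state The matching [cpm_state()].
#' @param params [rd_params()].
#' @param nsteps Number of `dt` updates.
#' @return The updated [chem_field()].
#' @export
rd_step <- function(chem, state, params = rd_params(), nsteps = 1) {
  stability <- state$h^2 / (4 * max(params$Du, params$Dv))
  if (params$dt > stability + 1e-12)
    abort(sprintf("dt = %g exceeds the explicit stability bound h^2/(4 max(D)) = %g",
                  params$dt, stability))
  res <- cpp_rd_steps(chem$u, chem$v, state$spin, params$Du, params$Dv,
                      params$k0, params$gamma_fb, params$K, params$eta,
                      params$dt, state$h, as.integer(nsteps))
  structure(list(u = res$u, v = res$v), class = "chem_field")
}

#' Coupled energy increment of a boundary move
#'
#' `+beta u` for a protrusion, `-beta u` for a retraction, where `u` is the
#' local active concentration (at the copied source site for protrusions, at
#' the lost site for retractions).
#'
#' @param u_local Local active concentration (>= 0).
#' @param move `"protrusion"` or `"retraction"`.
#' @param params [coupling_params()].
#' @return Energy increment.
#' @export
coupling_delta_h <- function(u_local, move = c("protrusion", "retraction"),
                             params = coupling_params()) {
  move <- match.arg(move)
  if (any(u_local < 0)) abort("u_local must be non-negative")
  if (move == "protrusion") params$beta * u_local else -params$beta * u_local
}

#' Redistribute chemical mass after a lost site
#'
#' Moves the mass held at `site` (just vacated by cell `id`) onto same-cell
#' sites within the redistribution radii, proportionally to their current
#' content (uniformly if the neighborhood holds none), expanding the radius
#' until a recipient exists. Per-cell mass of `u` and of `v` is conserved
#' exactly; gained sites always start at zero concentration.
#'
#' @param chem A [chem_field()] in which `site` still carries the lost mass.
#' @param state The [cpm_state()] after the flip.
#' @param site Site `c(x, y)` that left cell `id`.
#' @param id The losing cell.
#' @param params [coupling_params()].
#' @return The updated [chem_field()].
#' @export
redistribute_after_flip <- function(chem, state, site, id, params = coupling_params()) {
  site <- as.integer(site)
  u <- cpp_redistribute(chem$u, state$spin, site[2], site[1], as.integer(id),
                        params$r_active)
  v <- cpp_redistribute(chem$v, state$spin, site[2], site[1], as.integer(id),
                        params$r_inactive)
  structure(list(u = u, v = v), class = "chem_field")
}

#' Active-force component of the signaling coupling
#'
#' The centered-difference force contributed by the coupling term alone: at a
#' boundary site with active concentration `u`, both the protrusion and the
#' retraction variant shift the energy by `beta u`, so the active force has
#' magnitude `beta u / h` per open axis, directed into the cell.
#'
#' @param state A [cpm_state()].
#' @param chem A [chem_field()].
#' @param params [coupling_params()].
#' @return A force table over boundary sites with the active (contractile)
#'   component only.
#' @export
active_forces <- function(state, chem, params = coupling_params()) {
  f <- boundary_forces(state)
  h <- state$h
  for (k in seq_len(nrow(f))) {
    x <- f$x[k]; y <- f$y[k]; i <- f$cell_id[k]
    uloc <- chem$u[y, x]
    sp <- function(xx, yy) {
      if (xx < 1 || xx > ncol(state$spin) || yy < 1 || yy > nrow(state$spin)) 0L
      else state$spin[yy, xx]
    }
    fx <- 0; fy <- 0
    l <- sp(x - 1, y); r <- sp(x + 1, y)
    if (l == i && r != i) fx <- -params$beta * uloc / h       # right boundary: inward = -x
    else if (r == i && l != i) fx <- +params$beta * uloc / h  # left boundary: inward = +x
    up <- sp(x, y - 1); dn <- sp(x, y + 1)
    if (up == i && dn != i) fy <- -params$beta * uloc / h
    else if (dn == i && up != i) fy <- +params$beta * uloc / h
    f$fx[k] <- fx; f$fy[k] <- fy
  }
  f
}

#' Coupled signaling-motility run
#'
#' Alternates `substeps` reaction-diffusion updates with one coupled Monte
#' Carlo step, recording the lattice, the chemical field, and summary series.
#'
#' @param state A [cpm_state()].
#' @param chem Initial [chem_field()]; default is a left-polarized field.
#' @param rd [rd_params()].
#' @param coupling [coupling_params()].
#' @param n_mcs Number of Monte Carlo steps.
#' @param record_every Snapshot cadence (MCS); `NULL` records only the final
#'   state.
#' @return A list of class `cpm_trajectory`: `state`, `chem`, `summary`
#'   (tibble of per-cell area, perimeter, centroid and chemical mass per
#'   recorded MCS), and `snapshots` (named list of `list(spin, u, v)`).
#' @export
run_signaling_cell <- function(state, chem = NULL, rd = rd_params(),
                               coupling = coupling_params(), n_mcs = 150,
                               record_every = NULL) {
  if (is.null(chem)) chem <- init_chem_polarized(state)
  cadence <- if (is.null(record_every)) n_mcs else as.integer(record_every)
  summary <- list()
  snaps <- list()
  record <- function(step) {
    td <- mutate(tidy(state), mcs = step)
    cm <- chem_mass(chem, state)
    summary[[length(summary) + 1]] <<- dplyr::left_join(td, cm, by = "id")
    snaps[[as.character(step)]] <<- list(spin = state$spin, u = chem$u, v = chem$v)
  }
  record(0L)
  step <- 0L
  while (step < n_mcs) {
    k <- min(cadence, n_mcs - step)
    for (i in seq_len(k)) {
      chem <- rd_step(chem, state, rd, nsteps = rd$substeps)
      state <- mcs(state, 1, chem = chem, coupling = coupling)
      chem <- state$chem
    }
    step <- step + k
    record(step)
  }
  structure(list(state = state, chem = chem,
                 summary = bind_rows(summary), snapshots = snaps),
            class = "cpm_trajectory")
}
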