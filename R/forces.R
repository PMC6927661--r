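new_cpm_forces <- function(x) {
  class(x) <- c("cpm_forces", class(tibble()))
  x
}

#' Boundary forces from the Hamiltonian gradient
#'
#' Computes the force `F = -grad H` at every boundary site of a cell (a site
#' with at least one Moore neighbor of different spin) by a centered
#' difference: for each axis, the two variant configurations advance the
#' cell's boundary one site in the positive and negative direction (a
#' protrusion and a retraction spin copy), and the force component is minus
#' their energy difference over `2h`. The energy used is the cell's own share
#' `H^i` of the total Hamiltonian, so at cell-cell interfaces the variants
#' shift the interface and the cell feels half of the shared contact energy.
#' At sites where both neighbors along an axis lie inside (or both outside)
#' the cell, that component is 0 and is recovered by smoothing.
#'
#' Vectors are forces exerted by the cell boundary: they point inward where
#' the configuration is over target (e.g. area above rest area).
#'
#' @param state A [cpm_state()].
#' @param id A cell id, or `NULL` for all cells.
#' @return A force table: tibble with columns `x`, `y`, `cell_id`, `fx`, `fy`,
#'   and `weight` (the site's local perimeter contribution in raw discordant
#'   pairs, used as the smoothing weight).
#' @export
boundary_forces <- function(state, id = NULL) {
  stopifnot(inherits(state, "cpm_state"))
  idn <- if (is.null(id)) 0L else check_cell_id(state, id)
  res <- cpp_boundary_forces(state$spin, state$radius, state$cells$a,
                             state$cells$p, state$cells$lambda_a,
                             state$cells$lambda_p, state$cells$type, state$J,
                             state$xi, state$h, idn)
  new_cpm_forces(tibble(x = res$x, y = res$y, cell_id = res$cell_id,
                        fx = res$fx, fy = res$fy, weight = res$weight))
}

#' Force at one boundary site
#'
#' @inheritParams boundary_forces
#' @param site Site `c(x, y)` on the boundary of cell `id`.
#' @param id Owning cell id.
#' @return A one-row force table.
#' @export
boundary_force <- function(state, site, id) {
  id <- check_cell_id(state, id)
  site <- check_site(state, site)
  if (spin_at(state, site) != id) abort("site is not owned by cell `id`")
  all <- boundary_forces(state, id)
  row <- filter(all, .data$x == site[1], .data$y == site[2])
  if (!nrow(row)) abort("site is not on the boundary of cell `id`")
  row
}

#' Perimeter-weighted smoothing of boundary forces
#'
#' Replaces each boundary vector by the weighted mean of the vectors at
#' boundary sites of the same cell within Euclidean distance `radius`
#' (including the site itself), with weights given by each site's local
#' perimeter contribution. This suppresses the lattice staircase artifact and
#' aligns the field with the boundary normal.
#'
#' @param forces A force table from [boundary_forces()].
#' @param radius Smoothing radius in lattice units (>= 1).
#' @return A force table of the same sites with smoothed `fx`, `fy`.
#' @export
smooth_forces <- function(forces, radius = 3) {
  if (radius < 1) abort("smoothing radius must be at least 1")
  out <- forces
  for (cid in unique(forces$cell_id)) {
    sel <- which(forces$cell_id == cid)
    fx <- forces$fx[sel]; fy <- forces$fy[sel]; w <- forces$weight[sel]
    px <- forces$x[sel]; py <- forces$y[sel]
    d2 <- outer(px, px, "-")^2 + outer(py, py, "-")^2
    inball <- d2 <= radius^2 + 1e-9
    wmat <- inball * rep(w, each = length(w))  # row i: weights of sites near i
    denom <- rowSums(wmat)
    denom[denom == 0] <- 1
    out$fx[sel] <- as.numeric(wmat %*% fx) / denom
    out$fy[sel] <- as.numeric(wmat %*% fy) / denom
  }
  out
}

#' Interpolate boundary forces into the cell interior
#'
#' Extends a boundary force field over the full cell footprint. For each
#' interior site, the boundary site whose ray from the interpolation center
#' has the smallest angular deviation from the site's own ray is selected
#' (ties broken by the nearer boundary site, then by site order), and the
#' boundary vector is scaled by a function of the relative radial position
#' `t = |x - x_C| / |x_M - x_C|`: `t` (linear), `t^2` (quadratic), or
#' `(exp(t) - 1)/(e - 1)` (exponential); all modes give zero force at the
#' center and the full boundary vector at the boundary.
#'
#' @param forces A (typically smoothed) force table from [boundary_forces()].
#' @param state The [cpm_state()] the forces were computed on.
#' @param mode One of `"linear"`, `"quadratic"`, `"exponential"`.
#' @param center Optional named list/matrix of per-cell centers; defaults to
#'   each cell's area centroid.
#' @return A force table covering boundary and interior sites.
#' @export
interpolate_forces <- function(forces, state, mode = c("linear", "quadratic", "exponential"),
                               center = NULL) {
  mode <- match.arg(mode)
  scale_fun <- switch(mode,
                      linear = function(t) t,
                      quadratic = function(t) t^2,
                      exponential = function(t) (exp(t) - 1) / (exp(1) - 1))
  cents <- cell_centroids(state)
  out <- list()
  for (cid in unique(forces$cell_id)) {
    bsel <- forces[forces$cell_id == cid, ]
    ctr <- if (!is.null(center) && !is.null(center[[as.character(cid)]])) {
      as.numeric(center[[as.character(cid)]])
    } else {
      as.numeric(cents[cents$id == cid, c("x", "y")])
    }
    idx <- which(state$spin == cid, arr.ind = TRUE)
    sites <- tibble(x = as.numeric(idx[, 2]), y = as.numeric(idx[, 1]))
    interior <- dplyr::anti_join(sites, bsel[, c("x", "y")], by = c("x", "y"))
    res <- bsel
    if (nrow(interior)) {
      bx <- bsel$x - ctr[1]; by <- bsel$y - ctr[2]
      bang <- atan2(by, bx)
      bdist <- sqrt(bx^2 + by^2)
      ix <- interior$x - ctr[1]; iy <- interior$y - ctr[2]
      iang <- atan2(iy, ix)
      idist <- sqrt(ix^2 + iy^2)
      dang <- abs(outer(iang, bang, "-"))
      dang <- pmin(dang, 2 * pi - dang)
      # ties: nearest boundary site, then site order (rows of bsel)
      tie <- matrix(bdist * 1e-9, nrow(interior), length(bdist), byrow = TRUE)
      pick <- apply(dang + tie, 1, which.min)
      tt <- ifelse(bdist[pick] > 0, idist / bdist[pick], 0)
      s <- scale_fun(pmin(tt, 1))
      res <- bind_rows(res, tibble(
        x = interior$x, y = interior$y, cell_id = cid,
        fx = s * bsel$fx[pick], fy = s * bsel$fy[pick],
        weight = 0
      ))
    }
    out[[length(out) + 1]] <- res
  }
  new_cpm_forces(dplyr::arrange(bind_rows(out), .data$cell_id, .data$y, .data$x))
}

#' Full force-field pipeline for a state
#'
#' Convenience wrapper: boundary forces, perimeter-weighted smoothing, then
#' interior interpolation.
#'
#' @inheritParams boundary_forces
#' @param smooth_radius Smoothing radius; `NULL` or 0 skips smoothing.
#' @param mode Interior interpolation mode (see [interpolate_forces()]);
#'   `NULL` skips interpolation and returns the boundary field.
#' @return A force table.
#' @export
cell_forces <- function(state, id = NULL, smooth_radius = 3, mode = "linear") {
  f <- boundary_forces(state, id)
  if (!is.null(smooth_radius) && smooth_radius >= 1)
    f <- smooth_forces(f, smooth_radius)
  if (!is.null(mode)) f <- interpolate_forces(f, state, mode)
  f
}

#' Closed-form boundary force
#'
#' The analytic force for the area-perimeter-adhesion Hamiltonian at a
#' boundary point with local curvature `kappa` and outward unit normal
#' `normal`:
#' `F = -(2 lambda_a (A - a) + 2 lambda_p (P - p) kappa + j_eff kappa) * normal`,
#' i.e. inward when the bracket is positive. `j_eff` is the cell-medium
#' contact energy, or half the cell-cell contact energy at a shared interface.
#'
#' @param area,a Current and rest area.
#' @param perimeter,p Current and rest (scaled) perimeter.
#' @param lambda_a,lambda_p Energy weights.
#' @param kappa Local curvature (1/length; `1/R` on a disk of radius `R`).
#' @param normal Outward unit normal, `c(nx, ny)`.
#' @param j_eff Effective contact energy per unit length.
#' @return Named numeric `c(fx, fy)`.
#' @export
analytic_force <- function(area, a, perimeter, p, lambda_a, lambda_p, kappa,
                           normal, j_eff = 0) {
  nrm <- sqrt(sum(normal^2))
  if (abs(nrm - 1) > 1e-6) abort("`normal` must be a unit vector")
  mag <- 2 * lambda_a * (area - a) + 2 * lambda_p * (perimeter - p) * kappa +
    j_eff * kappa
  c(fx = -mag * normal[1], fy = -mag * normal[2])
}

#' Line tension and pressure of a cell
#'
#' The continuum decomposition of the CPM force: tension
#' `gamma = dH/dP = 2 lambda_p (P - p) + j_eff` and pressure
#' `Pi = -dH/dA = -2 lambda_a (A - a)`.
#'
#' @inheritParams analytic_force
#' @return A tibble with columns `gamma` and `pi`.
#' @export
tension_pressure <- function(area, a, perimeter, p, lambda_a, lambda_p, j_eff = 0) {
  tibble(gamma = 2 * lambda_p * (perimeter - p) + j_eff,
         pi = -2 * lambda_a * (area - a))
}

#' Net force of a field
#'
#' Component-wise sum of all vectors; a diagnostic for the approximate force
#' balance of isolated cells (the residual is a lattice-discretization
#' artifact).
#'
#' @param forces A force table.
#' @param by_cell Summarise per cell instead of overall.
#' @return A tibble with `fx`, `fy` (and `cell_id` when `by_cell`).
#' @export
net_force <- function(forces, by_cell = FALSE) {
  if (!nrow(forces)) return(tibble(fx = 0, fy = 0))
  if (by_cell) {
    summarise(group_by(forces, .data$cell_id),
              fx = sum(.data$fx), fy = sum(.data$fy), .groups = "drop")
  } else {
    summarise(forces, fx = sum(.data$fx), fy = sum(.data$fy))
  }
}
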