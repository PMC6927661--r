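join_fields <- function(fa, fb) {
  j <- inner_join(fa, fb, by = c("x", "y"), suffix = c("_a", "_b"))
  if (!nrow(j)) abort("the two force fields share no sites")
  j
}

#' Directional deviation between two force fields
#'
#' Per-site angle (degrees, in `[0, 180]`) between the vectors of two fields
#' on their common sites; `NA` where either vector vanishes.
#'
#' @param fa,fb Force tables with columns `x`, `y`, `fx`, `fy`.
#' @return A tibble `x`, `y`, `angle_deg`.
#' @export
directional_deviation <- function(fa, fb) {
  j <- join_fields(fa, fb)
  ma <- sqrt(j$fx_a^2 + j$fy_a^2)
  mb <- sqrt(j$fx_b^2 + j$fy_b^2)
  cosang <- (j$fx_a * j$fx_b + j$fy_a * j$fy_b) / (ma * mb)
  cosang <- pmin(1, pmax(-1, cosang))
  ang <- acos(cosang) * 180 / pi
  ang[ma == 0 | mb == 0] <- NA_real_
  tibble(x = j$x, y = j$y, angle_deg = ang)
}

#' Relative force magnitudes
#'
#' Per-site ratio `|Fa| / |Fb|` on common sites; `NA` where `|Fb| = 0`.
#'
#' @inheritParams directional_deviation
#' @return A tibble `x`, `y`, `ratio`.
#' @export
relative_magnitude <- function(fa, fb) {
  j <- join_fields(fa, fb)
  ma <- sqrt(j$fx_a^2 + j$fy_a^2)
  mb <- sqrt(j$fx_b^2 + j$fy_b^2)
  ratio <- ifelse(mb > 0, ma / mb, NA_real_)
  tibble(x = j$x, y = j$y, ratio = ratio)
}

#' Per-site field difference
#'
#' `Fb - Fa` on common sites.
#'
#' @inheritParams directional_deviation
#' @return A tibble `x`, `y`, `dfx`, `dfy`.
#' @export
field_difference <- function(fa, fb) {
  j <- join_fields(fa, fb)
  tibble(x = j$x, y = j$y, dfx = j$fx_b - j$fx_a, dfy = j$fy_b - j$fy_a)
}

#' Sum of squared differences between two fields
#'
#' @inheritParams directional_deviation
#' @return Scalar `sum(|Fa - Fb|^2)` over common sites.
#' @export
field_sse <- function(fa, fb) {
  j <- join_fields(fa, fb)
  sum((j$fx_a - j$fx_b)^2 + (j$fy_a - j$fy_b)^2)
}

#' Full comparison report between two fields
#'
#' @inheritParams directional_deviation
#' @return A list with the per-site `deviation`, `magnitude` and `difference`
#'   tables plus the scalar `sse`.
#' @export
compare_fields <- function(fa, fb) {
  list(deviation = directional_deviation(fa, fb),
       magnitude = relative_magnitude(fa, fb),
       difference = field_difference(fa, fb),
       sse = field_sse(fa, fb))
}

# SSE between unit force directions and analytic inward ellipse normals
# (-b cos t, -a sin t), evaluated at each boundary site's parameter angle.
ellipse_normal_sse <- function(forces, center, semi_x, semi_y) {
  dx <- forces$x - center[1]
  dy <- forces$y - center[2]
  theta <- atan2(dy / semi_y, dx / semi_x)
  nx <- -semi_y * cos(theta)
  ny <- -semi_x * sin(theta)
  nn <- sqrt(nx^2 + ny^2)
  nx <- nx / nn; ny <- ny / nn
  fm <- sqrt(forces$fx^2 + forces$fy^2)
  keep <- fm > 0
  fx <- forces$fx[keep] / fm[keep]
  fy <- forces$fy[keep] / fm[keep]
  sum((fx - nx[keep])^2 + (fy - ny[keep])^2)
}

#' Smoothing radius minimizing the normal-direction error on an ellipse
#'
#' Computes unsmoothed boundary forces for an elliptical cell, smooths them at
#' each radius of the sweep, and returns the radius whose normalized vectors
#' have the smallest sum of squared errors against the analytic inward unit
#' normals of the ellipse (ties go to the smaller radius).
#'
#' @param state A [cpm_state()] holding one elliptical cell.
#' @param semi_x,semi_y The ellipse semi-axes used for the analytic normals.
#' @param radii Integer sweep of smoothing radii.
#' @param center Ellipse center `c(x, y)`; defaults to the cell centroid.
#' @param id Cell id.
#' @return A list: `radius` (the argmin), and `sse` (tibble of the sweep).
#' @export
optimal_smoothing_radius <- function(state, semi_x, semi_y, radii = 1:20,
                                     center = NULL, id = 1L) {
  if (!length(radii)) abort("the radius sweep is empty")
  if (is.null(center)) {
    cents <- cell_centroids(state)
    center <- as.numeric(cents[cents$id == id, c("x", "y")])
  }
  raw <- boundary_forces(state, id)
  sse <- vapply(radii, function(r) {
    ellipse_normal_sse(smooth_forces(raw, r), center, semi_x, semi_y)
  }, numeric(1))
  tab <- tibble(radius = radii, sse = sse)
  list(radius = radii[which.min(sse)], sse = tab)
}

#' Latin hypercube parameter search
#'
#' Draws `n_samples` maximin-free Latin hypercube points over a box of
#' parameter bounds, evaluates a scalar objective at each, and returns the
#' samples ranked by objective (ascending). Sampling uses R's random stream.
#'
#' @param objective Function taking a named list (one draw) and returning a
#'   scalar; smaller is better (e.g. the SSE between a predicted and a
#'   reference force field).
#' @param bounds Named list of `c(min, max)` per parameter.
#' @param n_samples Number of hypercube points (>= 1).
#' @param seed Optional integer; when given, seeds the stream so the sample
#'   set is reproducible.
#' @return A tibble of the sampled parameters plus `objective`, sorted
#'   ascending.
#' @export
lhs_parameter_search <- function(objective, bounds, n_samples = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (n_samples < 1) abort("n_samples must be at least 1")
  k <- length(bounds)
  if (!k || is.null(names(bounds))) abort("bounds must be a named list of c(min, max)")
  rng <- do.call(rbind, bounds)
  if (any(!is.finite(rng))) abort("bounds must be finite")
  unit <- lhs::randomLHS(n_samples, k)
  pts <- sweep(sweep(unit, 2, rng[, 2] - rng[, 1], "*"), 2, rng[, 1], "+")
  colnames(pts) <- names(bounds)
  vals <- vapply(seq_len(n_samples), function(i) {
    objective(as.list(pts[i, ]))
  }, numeric(1))
  out <- as_tibble(as.data.frame(pts))
  out$objective <- vals
  dplyr::arrange(out, .data$objective)
}

#' Synthetic reference force field
#'
#' Stands in for an externally measured traction field: the analytic
#' closed-form boundary force of the cell (curvature-based), interpolated to
#' the interior, with isotropic Gaussian noise and optional localized
#' "hot spots" of elevated magnitude. Clearly synthetic; intended for
#' exercising the comparison metrics and parameter search.
#'
#' @param state A [cpm_state()] with a single cell.
#' @param noise_sd Standard deviation of the added component noise (as a
#'   fraction of the median boundary magnitude).
#' @param hotspots Optional tibble `x`, `y`, `radius`, `factor`: sites within
#'   `radius` of a hotspot get magnitudes multiplied by `factor`.
#' @param id Cell id.
#' @param mode Interior interpolation mode.
#' @return A force table over the cell footprint.
#' @export
make_synthetic_reference_field <- function(state, noise_sd = 0, hotspots = NULL,
                                           id = 1L, mode = "linear") {
  id <- check_cell_id(state, id)
  cents <- cell_centroids(state)
  ctr <- as.numeric(cents[cents$id == id, c("x", "y")])
  raw <- boundary_forces(state, id)
  A <- cell_area(state, id)
  P <- cell_perimeter(state, id)
  cl <- state$cells[state$cells$id == id, ]
  R_eff <- sqrt(A / pi)
  dx <- raw$x - ctr[1]; dy <- raw$y - ctr[2]
  dn <- sqrt(dx^2 + dy^2); dn[dn == 0] <- 1
  mag <- 2 * cl$lambda_a * (A - cl$a) +
    2 * cl$lambda_p * (P - cl$p) / R_eff +
    state$J[1, cl$type + 1] / R_eff
  f <- raw
  f$fx <- -mag * dx / dn
  f$fy <- -mag * dy / dn
  f <- interpolate_forces(f, state, mode)
  if (!is.null(hotspots) && nrow(hotspots)) {
    for (k in seq_len(nrow(hotspots))) {
      sel <- (f$x - hotspots$x[k])^2 + (f$y - hotspots$y[k])^2 <=
        hotspots$radius[k]^2
      f$fx[sel] <- f$fx[sel] * hotspots$factor[k]
      f$fy[sel] <- f$fy[sel] * hotspots$factor[k]
    }
  }
  if (noise_sd > 0) {
    scale <- median(sqrt(raw$fx^2 + raw$fy^2)) * noise_sd
    f$fx <- f$fx + rnorm(nrow(f), 0, scale)
    f$fy <- f$fy + rnorm(nrow(f), 0, scale)
  }
  f
}
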