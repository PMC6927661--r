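#' Run Monte Carlo steps
#'
#' Performs `n` Monte Carlo steps (MCS). One MCS makes `width * height` flip
#' attempts: a uniformly random source site, a uniformly random Moore-neighbor
#' target; attempts whose source and target already agree, or whose target
#' falls off the lattice, count but do nothing. Moves that would fragment the
#' losing cell are rejected; admissible moves are accepted by the Metropolis
#' rule on the incremental energy change. Randomness comes from R's stream,
#' so [set.seed()] makes trajectories bit-reproducible.
#'
#' When `chem` is supplied, the coupled energy increment `+beta * u(source)`
#' for protrusions and `-beta * u(target)` for retractions is added before the
#' acceptance test, and the chemical mass of a lost site is redistributed
#' within the losing cell (see [coupling_params()]).
#'
#' @param state A [cpm_state()].
#' @param n Number of Monte Carlo steps.
#' @param chem Optional [chem_field()] for signaling-coupled dynamics.
#' @param coupling [coupling_params()] used when `chem` is supplied.
#' @return The updated state. The step statistics (attempts, accepted moves,
#'   summed accepted energy change) are in `$last_stats`; when coupled, the
#'   updated chemical field is in `$chem`.
#' @export
mcs <- function(state, n = 1, chem = NULL, coupling = coupling_params()) {
  stopifnot(inherits(state, "cpm_state"))
  n <- as.integer(n)
  if (n < 0) abort("n must be non-negative")
  coupled <- !is.null(chem)
  u <- if (coupled) chem$u else matrix(0, 1, 1)
  v <- if (coupled) chem$v else matrix(0, 1, 1)
  res <- cpp_run_mcs(state$spin, n, state$cells$a, state$cells$p,
                     state$cells$lambda_a, state$cells$lambda_p,
                     state$cells$type, state$J, state$radius, state$xi,
                     state$temperature, state$h0, coupled, u, v,
                     if (coupled) coupling$beta else 0,
                     if (coupled) coupling$r_active else 1,
                     if (coupled) coupling$r_inactive else 1)
  state$spin <- res$spin
  state <- refresh_cache(state)
  state$last_stats <- tibble(
    n_mcs = n, attempts = res$attempts, accepted = res$accepted,
    dh_sum = res$dh_sum, dhu_sum = res$dhu_sum
  )
  if (coupled) state$chem <- chem_field(state, u = res$u, v = res$v)
  state
}
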