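#' Rasterized test shapes
#'
#' Builds a spin matrix containing one cell of the requested shape. Disks and
#' ellipses are rasterized by site centers (`(x - cx)^2/sa^2 +
#' (y - cy)^2/sb^2 <= 1`); irregular blobs are produced by seeding a disk and
#' running a high-temperature Monte Carlo burn-in under a fixed seed, which
#' yields a reproducible 4-connected irregular footprint.
#'
#' @param kind `"disk"`, `"ellipse"` or `"blob"`.
#' @param width,height Lattice size in sites.
#' @param center Shape center `c(x, y)`; defaults to the lattice center.
#' @param diameter Disk diameter (sites); also the seed disk of a blob.
#' @param semi_x,semi_y Ellipse semi-axes (sites).
#' @param id Cell index to write.
#' @param burnin_mcs,burnin_temperature,seed Blob burn-in settings.
#' @return An integer spin matrix.
#' @export
make_shape <- function(kind = c("disk", "ellipse", "blob"), width = 50, height = 50,
                       center = NULL, diameter = 23, semi_x = 10, semi_y = 20,
                       id = 1L, burnin_mcs = 10, burnin_temperature = 1000,
                       seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(center)) center <- c((width + 1) / 2, (height + 1) / 2)
  spin <- matrix(0L, height, width)
  xs <- matrix(rep(seq_len(width), each = height), height, width)
  ys <- matrix(rep(seq_len(height), times = width), height, width)
  if (kind == "disk" || kind == "blob") {
    sa <- sb <- diameter / 2
  } else {
    sa <- semi_x; sb <- semi_y
  }
  inside <- ((xs - center[1]) / sa)^2 + ((ys - center[2]) / sb)^2 <= 1
  if (!any(inside)) abort("shape contains no lattice sites")
  if (any(inside[c(1, height), ]) || any(inside[, c(1, width)]))
    abort("shape overflows the lattice; enlarge the grid or shrink the shape")
  spin[inside] <- as.integer(id)
  if (kind == "blob") {
    a0 <- sum(inside)
    st <- cpm_state(spin,
                    cells = cpm_cells(id = seq_len(id), a = a0, p = 0,
                                      lambda_a = 5, lambda_p = 0),
                    J = adhesion_matrix(1, j_medium = 50),
                    temperature = burnin_temperature)
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    st <- mcs(st, burnin_mcs)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    spin <- st$spin
  }
  spin
}

#' Single-cell state from a shape
#'
#' @inheritParams make_shape
#' @param ... Passed to [make_shape()].
#' @param a,p,lambda_a,lambda_p,j_medium,temperature,h0 Hamiltonian and
#'   Monte Carlo settings for the single cell.
#' @param radius,xi,h Neighborhood settings (see [cpm_state()]).
#' @return A [cpm_state()] holding one cell.
#' @export
single_cell_state <- function(kind = "disk", ..., a = 300, p = 100,
                              lambda_a = 10, lambda_p = 10, j_medium = 3000,
                              temperature = 0, h0 = 0, radius = 3, xi = 18, h = 1) {
  spin <- make_shape(kind, ...)
  cpm_state(spin,
            cells = cpm_cells(id = 1L, a = a, p = p, lambda_a = lambda_a,
                              lambda_p = lambda_p),
            J = adhesion_matrix(1, j_medium = j_medium),
            temperature = temperature, h0 = h0, radius = radius, xi = xi, h = h)
}
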