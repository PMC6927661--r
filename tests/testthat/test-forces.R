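# Boundary forces, smoothing, interpolation, and the closed-form oracle.

fig2_disk <- function(diameter = 23, width = 50) {
  single_cell_state("disk", width = width, height = width, diameter = diameter,
                    a = 300, p = 100, lambda_a = 10, lambda_p = 10,
                    j_medium = 3000)
}

test_that("straight-boundary force reduces to the area-term algebra", {
  # large rectangle, area term only: Fx = -2 lambda_a (A - a), inward for A > a
  sp <- matrix(0L, 20, 20); sp[5:15, 5:15] <- 1L
  st <- cpm_state(sp, cpm_cells(1, a = 100, lambda_a = 2))
  A <- cell_area(st, 1)
  f <- boundary_force(st, site = c(15, 10), id = 1)  # right-hand boundary, mid-edge
  expect_equal(f$fx, -2 * 2 * (A - 100))
  expect_equal(f$fy, 0)
  f2 <- boundary_force(st, site = c(5, 10), id = 1)  # left-hand boundary
  expect_equal(f2$fx, +2 * 2 * (A - 100))
})

test_that("boundary sets cover exactly the Moore-edge sites", {
  sp <- matrix(0L, 9, 9); sp[4:6, 4:6] <- 1L
  st <- cpm_state(sp)
  f <- boundary_forces(st, 1)
  expect_equal(nrow(f), 8)  # all but the center of a 3 x 3 block
  expect_false(any(f$x == 5 & f$y == 5))

  st2 <- fig2_disk()
  f2 <- boundary_forces(st2, 1)
  # independent edge scan
  sp2 <- st2$spin
  edge <- 0
  for (r in 1:50) for (c in 1:50) {
    if (sp2[r, c] != 1) next
    nb <- sp2[max(1, r - 1):min(50, r + 1), max(1, c - 1):min(50, c + 1)]
    if (any(nb != 1)) edge <- edge + 1
  }
  expect_equal(nrow(f2), edge)
  expect_error(boundary_force(st2, site = c(25, 25), id = 1), "not on the boundary")
})

test_that("a cell at rest with no contact energy exerts (almost) no force", {
  sp <- matrix(0L, 21, 21); sp[5:17, 5:17] <- 1L  # edges long enough that the
  P <- sum(oracle_pair_counts(sp, 1)[2, ]) / 18   # r = 3 ball misses corners
  st <- cpm_state(sp, cpm_cells(1, a = 169, p = P, lambda_a = 3, lambda_p = 4))
  f <- boundary_forces(st, 1)
  # flat mid-edge sites: protrusion and retraction are mirror images, force 0
  mid <- f[(f$x == 11 & f$y %in% c(5, 17)) | (f$y == 11 & f$x %in% c(5, 17)), ]
  expect_equal(mid$fx, rep(0, 4))
  expect_equal(mid$fy, rep(0, 4))
  # corner residuals are second order in the perimeter quantum (1/xi)
  resid <- max(sqrt(f$fx^2 + f$fy^2))
  expect_lt(resid, 2)
  # ... and tiny relative to the same cell pushed off its rest targets
  st2 <- cpm_state(sp, cpm_cells(1, a = 144, p = P + 5, lambda_a = 3, lambda_p = 4))
  f2 <- boundary_forces(st2, 1)
  expect_gt(min(sqrt(f2$fx^2 + f2$fy^2)[f2$fx != 0 | f2$fy != 0]), 10 * resid)
})

test_that("forces inherit the mirror symmetry of the Hamiltonian", {
  st <- single_cell_state("ellipse", width = 41, height = 41, semi_x = 8,
                          semi_y = 13, a = 300, p = 100, lambda_a = 10,
                          lambda_p = 10, j_medium = 3000)
  f <- boundary_forces(st, 1)
  mirrored <- merge(as.data.frame(f),
                    transform(as.data.frame(f), x = 42 - x),
                    by = c("x", "y"))
  expect_gt(nrow(mirrored), 0)
  expect_equal(mirrored$fx.x, -mirrored$fx.y, tolerance = 1e-9)
  expect_equal(mirrored$fy.x, mirrored$fy.y, tolerance = 1e-9)
})

test_that("boundary forces equal the per-cell full-recompute gradient", {
  st <- random_two_cell_state(23)
  f <- boundary_forces(st)
  sp <- st$spin
  at <- function(x, y) {
    if (x < 1 || x > ncol(sp) || y < 1 || y > nrow(sp)) 0L else sp[y, x]
  }
  hi <- function(spin, i) oracle_hamiltonian(spin, st$cells, st$J, scope = i)
  flip <- function(x, y, s) { m <- sp; m[y, x] <- s; m }
  for (k in seq_len(nrow(f))) {
    x <- f$x[k]; y <- f$y[k]; i <- f$cell_id[k]
    l <- at(x - 1, y); r <- at(x + 1, y)
    fx <- 0
    if (l == i && r != i) fx <- -(hi(flip(x + 1, y, i), i) - hi(flip(x, y, r), i)) / 2
    if (r == i && l != i) fx <- -(hi(flip(x, y, l), i) - hi(flip(x - 1, y, i), i)) / 2
    up <- at(x, y - 1); dn <- at(x, y + 1)
    fy <- 0
    if (up == i && dn != i) fy <- -(hi(flip(x, y + 1, i), i) - hi(flip(x, y, dn), i)) / 2
    if (dn == i && up != i) fy <- -(hi(flip(x, y, up), i) - hi(flip(x, y - 1, i), i)) / 2
    expect_equal(f$fx[k], fx, tolerance = 1e-9)
    expect_equal(f$fy[k], fy, tolerance = 1e-9)
  }
})

test_that("perimeter-weighted smoothing fixes lattice artifacts without inventing structure", {
  # constant field on a straight boundary stays unchanged
  sp <- matrix(0L, 20, 20); sp[5:15, 5:15] <- 1L
  st <- cpm_state(sp, cpm_cells(1, a = 50, lambda_a = 1))
  f <- boundary_forces(st, 1)
  con <- f
  con$fx <- 2.5; con$fy <- -1
  sm <- smooth_forces(con, 3)
  expect_equal(sm$fx, rep(2.5, nrow(sm)))
  expect_equal(sm$fy, rep(-1, nrow(sm)))

  # smoothing strictly reduces the normal-direction error on a disk
  std <- single_cell_state("disk", width = 44, height = 44, diameter = 20,
                           a = 300, p = 100, lambda_a = 10, lambda_p = 10,
                           j_medium = 3000)
  raw <- boundary_forces(std, 1)
  ctr <- as.numeric(cell_centroids(std)[1, c("x", "y")])
  sse_radial <- function(fld) {
    dx <- fld$x - ctr[1]; dy <- fld$y - ctr[2]
    dn <- sqrt(dx^2 + dy^2)
    fm <- sqrt(fld$fx^2 + fld$fy^2)
    k <- fm > 0
    # inward radial target (disk over target area)
    sum((fld$fx[k] / fm[k] + dx[k] / dn[k])^2 +
          (fld$fy[k] / fm[k] + dy[k] / dn[k])^2)
  }
  expect_lt(sse_radial(smooth_forces(raw, 3)), sse_radial(raw))
  expect_error(smooth_forces(raw, 0.5), "at least 1")
})

test_that("interior interpolation is zero at the center and scales along rays", {
  sp <- matrix(0L, 15, 15); sp[4:12, 4:12] <- 1L
  st <- cpm_state(sp, cpm_cells(1, a = 40, lambda_a = 1))
  f <- interpolate_forces(boundary_forces(st, 1), st, "linear")
  ctr <- f[f$x == 8 & f$y == 8, ]
  expect_equal(c(ctr$fx, ctr$fy), c(0, 0))
  # midpoint of the center-to-boundary ray: half the boundary magnitude
  edge <- f[f$x == 12 & f$y == 8, ]
  mid <- f[f$x == 10 & f$y == 8, ]
  expect_equal(c(mid$fx, mid$fy), c(edge$fx, edge$fy) / 2, tolerance = 1e-9)

  # disk with integer center: magnitude non-decreasing outward along the
  # exact axis rays through the centroid
  std <- single_cell_state("disk", width = 45, height = 45, center = c(23, 23),
                           diameter = 23, a = 300, p = 100, lambda_a = 10,
                           lambda_p = 10, j_medium = 3000)
  fd <- cell_forces(std, smooth_radius = 3, mode = "linear")
  fd$mag <- sqrt(fd$fx^2 + fd$fy^2)
  for (half in list(fd[fd$y == 23 & fd$x >= 23, ], fd[fd$y == 23 & fd$x <= 23, ],
                    fd[fd$x == 23 & fd$y >= 23, ], fd[fd$x == 23 & fd$y <= 23, ])) {
    half$r <- sqrt((half$x - 23)^2 + (half$y - 23)^2)
    half <- half[order(half$r), ]
    expect_true(all(diff(half$mag) > -1e-9),
                label = "monotone magnitude along an axis ray")
  }
  # quadratic mode shrinks interior magnitudes relative to linear (t^2 <= t)
  fq <- cell_forces(std, smooth_radius = 3, mode = "quadratic")
  j <- merge(as.data.frame(fd), as.data.frame(fq), by = c("x", "y"))
  expect_true(all(sqrt(j$fx.y^2 + j$fy.y^2) <= sqrt(j$fx.x^2 + j$fy.x^2) + 1e-9))
})

test_that("degenerate cells fall back to the boundary field", {
  sp <- matrix(0L, 8, 8); sp[4, 3:6] <- 1L  # 1 x 4 strip: all boundary
  st <- cpm_state(sp, cpm_cells(1, a = 4, lambda_a = 1))
  b <- boundary_forces(st, 1)
  f <- interpolate_forces(b, st, "linear")
  expect_equal(nrow(f), nrow(b))
})

test_that("closed-form force and tension/pressure follow the energy derivatives", {
  expect_equal(analytic_force(10, 10, 20, 20, 1, 1, 0.1, c(1, 0), 0),
               c(fx = 0, fy = 0))
  expect_equal(analytic_force(12, 10, 0, 0, 3, 0, 0.2, c(0, 1), 0),
               c(fx = 0, fy = -2 * 3 * 2))
  # disk: same magnitude at every boundary angle
  th <- seq(0, 2 * pi, length.out = 9)
  mags <- vapply(th, function(t) {
    sqrt(sum(analytic_force(401, 300, 74, 100, 10, 10, 1 / 11.5,
                            c(cos(t), sin(t)), 3000)^2))
  }, numeric(1))
  expect_equal(max(mags) - min(mags), 0, tolerance = 1e-9)
  expect_error(analytic_force(1, 1, 1, 1, 1, 1, 1, c(2, 0)), "unit vector")

  tp <- tension_pressure(area = 100, a = 100, perimeter = 40, p = 40, 2, 3, j_eff = 7)
  expect_equal(tp$pi, 0)
  expect_equal(tp$gamma, 7)
  # finite-difference check on a rectangle: gamma and Pi vs H under one-site
  # area change and one-pair perimeter change
  sp <- matrix(0L, 24, 24); sp[6:17, 6:17] <- 1L
  cells <- cpm_cells(1, a = 100, p = 30, lambda_a = 2, lambda_p = 3)
  st <- cpm_state(sp, cells)
  A <- cell_area(st, 1); P <- cell_perimeter(st, 1)
  tp2 <- tension_pressure(A, 100, P, 30, 2, 3)
  hfun <- function(a_, p_) 2 * (a_ - 100)^2 + 3 * (p_ - 30)^2
  expect_equal(tp2$pi, -(hfun(A + 1, P) - hfun(A - 1, P)) / 2)
  expect_equal(tp2$gamma, (hfun(A, P + 1) - hfun(A, P - 1)) / 2)
})

test_that("net force sums vectors and balances on equilibrated cells", {
  empty <- tibble::tibble(x = numeric(), y = numeric(), cell_id = integer(),
                          fx = numeric(), fy = numeric())
  expect_equal(as.numeric(net_force(empty)), c(0, 0))
  pair <- tibble::tibble(x = 1:2, y = 1, cell_id = 1L, fx = c(1, -1), fy = 0)
  expect_equal(as.numeric(net_force(pair)), c(0, 0))

  for (shape in c("disk", "ellipse", "blob")) {
    st <- single_cell_state(shape, width = 50, height = 50, diameter = 23,
                            semi_x = 10, semi_y = 20, a = 300, p = 100,
                            lambda_a = 10, lambda_p = 10, j_medium = 3000)
    f <- smooth_forces(boundary_forces(st, 1), 3)
    nf <- net_force(f)
    expect_lt(sqrt(nf$fx^2 + nf$fy^2), 0.05 * sum(sqrt(f$fx^2 + f$fy^2)),
              label = sprintf("%s net force below 5%% of summed magnitude", shape))
  }
})

test_that("interface forces grow with the cell-cell contact energy", {
  mags <- vapply(c(1800, 3600, 7200), function(J12) {
    res <- run_scenario("adhesion-pair", seed = 2, n_mcs = 1,
                        params = list(j_cell = J12))
    st <- res$final_state
    f <- smooth_forces(boundary_forces(st), 3)
    sp <- st$spin
    hetero <- vapply(seq_len(nrow(f)), function(k) {
      x <- f$x[k]; y <- f$y[k]
      nb <- sp[max(1, y - 1):min(nrow(sp), y + 1),
               max(1, x - 1):min(ncol(sp), x + 1)]
      any(nb > 0 & nb != f$cell_id[k])
    }, logical(1))
    mean(sqrt(f$fx^2 + f$fy^2)[hetero])
  }, numeric(1))
  expect_true(all(diff(mags) > 0))
})
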