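static_cell <- function(rows = 4:17, cols = 4:43, H = 20, W = 46) {
  sp <- matrix(0L, H, W); sp[rows, cols] <- 1L
  cpm_state(sp, cpm_cells(1, a = sum(sp == 1), lambda_a = 1))
}

test_that("rd_step conserves mass, fixes homogeneous steady states, and guards dt", {
  st <- static_cell()
  rp <- rd_params()
  # homogeneous steady state: f(u*, v*) = 0 with u* solving v* kinetics
  ustar <- 0.2
  vstar <- ustar / (rp$k0 + rp$gamma_fb * ustar^2 / (rp$K^2 + ustar^2))
  ch <- chem_field(st, u = ustar, v = vstar)
  ch2 <- rd_step(ch, st, rp, nsteps = 50)
  expect_equal(ch2$u, ch$u, tolerance = 1e-8)
  expect_equal(ch2$v, ch$v, tolerance = 1e-8)

  set.seed(8)
  umat <- matrix(runif(20 * 46), 20, 46)
  ch3 <- chem_field(st, u = umat, v = 2)
  m0 <- chem_mass(ch3, st)
  ch4 <- rd_step(ch3, st, rp, nsteps = 200)
  m1 <- chem_mass(ch4, st)
  expect_equal(m1$mass_u + m1$mass_v, m0$mass_u + m0$mass_v,
               tolerance = 1e-10)
  expect_error(rd_step(ch3, st, rd_params(dt = 1)), "stability")
})

test_that("a 2D strip initial condition reproduces an independent 1D explicit solve", {
  # y-uniform field on a rectangle: the 2D solver must match a 1D scheme
  st <- static_cell(rows = 4:9, cols = 4:43, H = 12, W = 46)
  rp <- rd_params()
  u0 <- ifelse(seq_len(40) <= 12, 2, 0.05)
  um <- matrix(0, 12, 46); um[4:9, 4:43] <- matrix(u0, 6, 40, byrow = TRUE)
  ch <- chem_field(st, u = um, v = 2)
  nst <- 400
  ch2 <- rd_step(ch, st, rp, nsteps = nst)
  # independent 1D explicit reference
  u <- u0; v <- rep(2, 40)
  for (s in seq_len(nst)) {
    lap <- function(q) {
      c(q[2] - q[1], diff(q, lag = 1)[-1] - diff(q, lag = 1)[-39],
        q[39] - q[40])
    }
    f <- v * (rp$k0 + rp$gamma_fb * u^2 / (rp$K^2 + u^2)) - rp$eta * u
    u2 <- u + rp$dt * (rp$Du * lap(u) + f)
    v2 <- v + rp$dt * (rp$Dv * lap(v) - f)
    u <- u2; v <- v2
  }
  expect_equal(ch2$u[6, 4:43], u, tolerance = 1e-10)
  expect_equal(ch2$v[6, 4:43], v, tolerance = 1e-10)
  # y-symmetry of the y-uniform condition is preserved exactly
  expect_equal(ch2$u[4, ], ch2$u[9, ], tolerance = 1e-12)
})

test_that("the activity front decelerates and leaves a mid-range plateau", {
  st <- static_cell()
  ch <- init_chem_polarized(st, frac = 0.3, u_high = 2, u_low = 0.05, v0 = 2)
  rp <- rd_params()
  front <- function(ch) sum(colMeans(ch$u[4:17, 4:43]) > 0.6)
  pos <- front(ch)
  for (k in 1:4) {
    ch <- rd_step(ch, st, rp, nsteps = 2500)
    pos <- c(pos, front(ch))
  }
  early <- pos[2] - pos[1]
  late <- pos[5] - pos[4]
  expect_lt(late, max(1.5, 0.35 * early))  # front decelerating toward pinning
  frac <- pos[5] / 40
  expect_gt(frac, 0.2)
  expect_lt(frac, 0.8)
  # the high and low states both persist
  expect_gt(max(ch$u), 1)
  expect_lt(min(ch$u[st$spin == 1]), 0.4)
})

test_that("coupling increments follow +/- beta u and redistribution conserves mass", {
  cp <- coupling_params(beta = 40)
  expect_equal(coupling_delta_h(0, "protrusion", cp), 0)
  expect_equal(coupling_delta_h(1, "retraction", cp), -40)
  expect_equal(coupling_delta_h(1, "protrusion", cp), +40)

  st <- static_cell()
  set.seed(2)
  um <- matrix(0, 20, 46); um[st$spin == 1] <- runif(sum(st$spin == 1))
  ch <- chem_field(st, u = um, v = 1.5)
  # pretend site (10, 6) was just lost by cell 1: flip it to medium first
  st2 <- st; st2$spin[6, 10] <- 0L
  st2 <- cpmforce:::refresh_cache(st2)
  m0u <- sum(ch$u); m0v <- sum(ch$v)
  ch2 <- redistribute_after_flip(ch, st2, site = c(10, 6), id = 1,
                                 params = coupling_params(r_active = 3, r_inactive = 75))
  expect_equal(ch2$u[6, 10], 0)
  expect_equal(ch2$v[6, 10], 0)
  expect_equal(sum(ch2$u), m0u, tolerance = 1e-10)
  expect_equal(sum(ch2$v), m0v, tolerance = 1e-10)
  # nothing lands outside the owning cell
  expect_true(all(ch2$u[st2$spin != 1] == 0))
  expect_true(all(ch2$v[st2$spin != 1] == 0))
  # zero-mass site: no change at all
  ch$u[6, 10] <- 0; ch$v[6, 10] <- 0
  ch3 <- redistribute_after_flip(ch, st2, site = c(10, 6), id = 1)
  expect_equal(ch3$u, ch$u)
  expect_equal(ch3$v, ch$v)
})

test_that("beta = 0 coupling reproduces the uncoupled trajectory exactly", {
  st <- single_cell_state("disk", width = 36, height = 36, diameter = 17,
                          a = 220, p = 0, lambda_a = 5, lambda_p = 0,
                          j_medium = 300, temperature = 40)
  ch <- init_chem_polarized(st)
  set.seed(77); plain <- mcs(st, 5)
  set.seed(77); coupled <- mcs(st, 5, chem = ch,
                               coupling = coupling_params(beta = 0))
  expect_identical(plain$spin, coupled$spin)
})

test_that("chemical mass is conserved through a coupled moving-boundary run", {
  set.seed(12)
  st <- single_cell_state("disk", width = 50, height = 50, diameter = 30,
                          a = 700, p = 0, lambda_a = 4, lambda_p = 0,
                          j_medium = 500, temperature = 100)
  ch <- init_chem_polarized(st)
  rp <- rd_params()
  m0 <- chem_mass(ch, st)
  tot0 <- m0$mass_u + m0$mass_v
  accepted <- 0
  for (i in 1:30) {
    ch <- rd_step(ch, st, rp, nsteps = rp$substeps)
    st <- mcs(st, 1, chem = ch, coupling = coupling_params(beta = 20))
    ch <- st$chem
    accepted <- accepted + st$last_stats$accepted
  }
  expect_gt(accepted, 50)  # the boundary really moved
  m1 <- chem_mass(ch, st)
  expect_equal(m1$mass_u + m1$mass_v, tot0, tolerance = 1e-8)
  expect_connected_cells(st)
})
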