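test_that("cell areas count sites, and unknown ids signal errors", {
  sp <- matrix(0L, 9, 9)
  sp[5, 5] <- 1L
  st <- cpm_state(sp)
  expect_equal(cell_area(st, 1), 1)

  sp2 <- matrix(0L, 9, 9); sp2[3:5, 3:5] <- 1L
  st2 <- cpm_state(sp2)
  expect_equal(cell_area(st2, 1), 9)
  expect_error(cell_area(st2, 7), "unknown cell id")

  # registered but empty cell has area 0
  st3 <- cpm_state(sp2, cells = cpm_cells(1:5))
  expect_equal(cell_area(st3, 5), 0)
})

test_that("neighborhood-scaled perimeter matches brute-force pair enumeration", {
  sp <- matrix(0L, 11, 11); sp[6, 6] <- 1L
  st <- cpm_state(sp)  # radius 3, xi 18
  expect_equal(cell_perimeter(st, 1), 28 / 18)

  sp2 <- matrix(0L, 20, 20); sp2[6:15, 6:15] <- 1L
  st2 <- cpm_state(sp2)
  M <- oracle_pair_counts(sp2, 1, radius = 3)
  expect_identical(cell_perimeter(st2, 1), sum(M[2, ]) / 18)
  expect_error(cell_perimeter(st2, 3), "unknown cell id")
})

test_that("scaled perimeter of digitized disks tracks the circumference", {
  for (D in c(15, 23, 31)) {
    sp <- make_shape("disk", width = D + 10, height = D + 10, diameter = D)
    st <- cpm_state(sp)
    expect_lt(abs(cell_perimeter(st, 1) - pi * D) / (pi * D), 0.06,
              label = sprintf("disk D=%d perimeter within 6%% of pi*D", D))
  }
})

test_that("total Hamiltonian reduces correctly and matches a full recount", {
  # quadratic terms vanish at the rest configuration: H = J(0,1) * P
  sp <- matrix(0L, 12, 12); sp[4:8, 4:8] <- 1L
  P <- sum(oracle_pair_counts(sp, 1)[2, ]) / 18
  st <- cpm_state(sp, cpm_cells(1, a = 25, p = P, lambda_a = 7, lambda_p = 9),
                  adhesion_matrix(1, j_medium = 11))
  expect_equal(hamiltonian(st), 11 * P)

  # two cells, no quadratic terms, no medium contact on a shared interface:
  # the 1/2 and the double-count cancel to J * L
  sp2 <- matrix(0L, 12, 12); sp2[4:8, 4:6] <- 1L; sp2[4:8, 7:9] <- 2L
  cells <- cpm_cells(1:2, type = 1:2)
  J <- adhesion_matrix(2, j_medium = 0, j_same = 0, j_diff = 13)
  st2 <- cpm_state(sp2, cells, J)
  L <- interface_length(st2, 1, 2)
  expect_gt(L, 0)
  expect_equal(hamiltonian(st2), 13 * L)

  # arbitrary state equals the from-scratch oracle
  st3 <- random_two_cell_state(11)
  expect_equal(hamiltonian(st3),
               oracle_hamiltonian(st3$spin, st3$cells, st3$J), tolerance = 1e-12)
  dec <- hamiltonian_decomposition(st3)
  expect_equal(sum(dec$h_total), hamiltonian(st3), tolerance = 1e-12)
})

test_that("incremental delta-H equals the full-recompute difference", {
  # closed-form area-only growth: dH = lambda_a (2 (A - a) + 1)
  sp <- matrix(0L, 10, 10); sp[3:6, 3:6] <- 1L
  st <- cpm_state(sp, cpm_cells(1, a = 10, lambda_a = 5))
  dh <- delta_h_flip(st, source = c(3, 3), target = c(2, 3))
  expect_equal(dh, 5 * (2 * (16 - 10) + 1))

  st2 <- random_two_cell_state(7)
  set.seed(99)
  for (k in 1:300) {
    pr <- random_proposal(st2)
    expect_equal(delta_h_flip(st2, pr$source, pr$target),
                 oracle_delta_h(st2, pr$source, pr$target), tolerance = 1e-9)
  }

  expect_error(delta_h_flip(st2, c(5, 5), c(8, 5)), "Moore")
  expect_error(delta_h_flip(st2, c(1, 1), c(1, 2)), "share a spin")
})

test_that("Metropolis rule follows the acceptance law including T = 0 limits", {
  expect_equal(accept_probability(-1, temperature = 10), 1)
  expect_equal(accept_probability(0, temperature = 10), 1)
  expect_equal(accept_probability(5, temperature = 5), exp(-1))
  expect_equal(accept_probability(3, temperature = 5, h0 = 2), exp(-1))
  # T = 0: neutral move accepted, uphill rejected
  expect_equal(accept_probability(0, temperature = 0), 1)
  expect_equal(accept_probability(1e-9, temperature = 0), 0)
  expect_error(accept_probability(1, temperature = -2), "non-negative")
  expect_error(metropolis_accept(1, temperature = -2), "non-negative")

  set.seed(123)
  expect_true(all(metropolis_accept(rep(-0.5, 100), temperature = 3)))
  acc <- mean(metropolis_accept(rep(2, 2e4), temperature = 2))
  se <- sqrt(exp(-1) * (1 - exp(-1)) / 2e4)
  expect_lt(abs(acc - exp(-1)), 3 * se)
})

test_that("connectivity test matches flood-fill intuition on canonical cases", {
  strip <- matrix(0L, 3, 5); strip[2, 2:4] <- 1L
  expect_false(connectivity_preserved(strip, c(3, 2)))  # middle of a 1x3 strip
  expect_true(connectivity_preserved(strip, c(2, 2)))   # end of the strip
  expect_true(connectivity_preserved(strip, c(4, 2)))

  block <- matrix(0L, 4, 4); block[2:3, 2:3] <- 1L
  for (x in 2:3) for (y in 2:3)
    expect_true(connectivity_preserved(block, c(x, y)))

  # diagonal-only touching halves: the bridging site is critical
  dg <- matrix(0L, 5, 5)
  dg[2, 2] <- 1L; dg[3, 2] <- 1L; dg[3, 3] <- 1L; dg[4, 3] <- 1L; dg[4, 4] <- 1L
  expect_false(connectivity_preserved(dg, c(3, 3)))
  expect_error(connectivity_preserved(dg, c(1, 1)), "medium")
})
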