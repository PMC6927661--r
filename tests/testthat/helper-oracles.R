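# Independent brute-force oracles (pure R, no use of the package's cached or
# incremental paths) plus small fixture builders shared across tests.

ball_offsets_r <- function(radius) {
  R <- floor(radius)
  offs <- expand.grid(dx = -R:R, dy = -R:R)
  offs[offs$dx^2 + offs$dy^2 > 0 & offs$dx^2 + offs$dy^2 <= radius^2 + 1e-9, ]
}

# ordered discordant pair counts between all indices (rows/cols = index + 1)
oracle_pair_counts <- function(spin, n, radius = 3) {
  offs <- ball_offsets_r(radius)
  H <- nrow(spin); W <- ncol(spin)
  M <- matrix(0, n + 1, n + 1)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    s <- spin[r, c]
    for (k in seq_len(nrow(offs))) {
      rr <- r + offs$dy[k]; cc <- c + offs$dx[k]
      s2 <- if (rr < 1 || rr > H || cc < 1 || cc > W) 0L else spin[rr, cc]
      if (s2 != s) M[s + 1, s2 + 1] <- M[s + 1, s2 + 1] + 1
    }
  }
  M
}

# per-cell Hamiltonian share H^i recomputed from scratch; i = 0 gives the total
oracle_hamiltonian <- function(spin, cells, J, radius = 3, xi = 18, scope = 0) {
  n <- nrow(cells)
  M <- oracle_pair_counts(spin, n, radius)
  A <- vapply(cells$id, function(i) sum(spin == i), numeric(1))
  P <- vapply(cells$id, function(i) sum(M[i + 1, ]) / xi, numeric(1))
  share <- function(i) {
    v <- cells$lambda_a[i] * (A[i] - cells$a[i])^2 +
      cells$lambda_p[i] * (P[i] - cells$p[i])^2 +
      J[1, cells$type[i] + 1] * M[i + 1, 1] / xi
    for (j in seq_len(n)) {
      if (j != i)
        v <- v + 0.5 * J[cells$type[i] + 1, cells$type[j] + 1] * M[i + 1, j + 1] / xi
    }
    v
  }
  if (scope > 0) share(scope) else sum(vapply(seq_len(n), share, numeric(1)))
}

oracle_delta_h <- function(state, source, target) {
  sp2 <- state$spin
  sp2[target[2], target[1]] <- state$spin[source[2], source[1]]
  oracle_hamiltonian(sp2, state$cells, state$J, state$radius, state$xi) -
    oracle_hamiltonian(state$spin, state$cells, state$J, state$radius, state$xi)
}

# random 4-connected two-cell configuration on a 30 x 30 lattice
random_two_cell_state <- function(seed, temperature = 100) {
  set.seed(seed)
  spin <- matrix(0L, 30, 30)
  spin[6:14, 5:15] <- 1L
  spin[15:24, 12:24] <- 2L
  cells <- cpm_cells(1:2, type = 1:2, a = c(90, 120), p = c(35, 45),
                     lambda_a = c(4, 6), lambda_p = c(3, 2))
  J <- adhesion_matrix(2, j_medium = 50, j_same = 15, j_diff = 30)
  st <- cpm_state(spin, cells, J, temperature = temperature)
  mcs(st, 3)  # roughen the shapes
}

# draw a random admissible flip proposal (Moore-adjacent, unequal spins)
random_proposal <- function(state) {
  H <- nrow(state$spin); W <- ncol(state$spin)
  repeat {
    x <- sample.int(W, 1); y <- sample.int(H, 1)
    d <- sample(c(-1L, 0L, 1L), 2, replace = TRUE)
    if (all(d == 0)) next
    tx <- x + d[1]; ty <- y + d[2]
    if (tx < 1 || tx > W || ty < 1 || ty > H) next
    if (state$spin[y, x] != state$spin[ty, tx])
      return(list(source = c(x, y), target = c(tx, ty)))
  }
}

expect_connected_cells <- function(state) {
  for (cid in state$cells$id) {
    idx <- which(state$spin == cid, arr.ind = TRUE)
    if (!nrow(idx)) next
    # flood fill in R over 4-adjacency
    key <- paste(idx[, 1], idx[, 2])
    seen <- setNames(rep(FALSE, nrow(idx)), key)
    queue <- key[1]; seen[queue] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      rc <- as.integer(strsplit(cur, " ")[[1]])
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        nk <- paste(rc[1] + d[1], rc[2] + d[2])
        if (!is.na(seen[nk]) && !seen[nk]) {
          seen[nk] <- TRUE
          queue <- c(queue, nk)
        }
      }
    }
    expect_true(all(seen),
                label = sprintf("cell %d is 4-connected (%d of %d reached)",
                                cid, sum(seen), length(seen)))
  }
  invisible(state)
}
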