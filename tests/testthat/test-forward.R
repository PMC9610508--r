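test_that("the nodal system is a symmetric Laplacian with EMF sources", {
  fix <- random_system(c(3, 3, 3), seed = 1)
  p <- physics_params()
  sys <- assemble_network(fix$cgrid, fix$A, p, fix$edges)
  expect_lt(max(abs(sys$L - Matrix::t(sys$L))), 1e-12)
  expect_lt(max(abs(Matrix::rowSums(sys$L))), 1e-9 * max(abs(sys$L)))
  # zero excitation -> zero source vector -> zero potential
  sys0 <- assemble_network(fix$cgrid, fix$A * 0, p, fix$edges)
  expect_equal(max(abs(sys0$b)), 0)
  expect_equal(max(abs(solve_potential(sys0)$psi)), 0)
})

test_that("a two-voxel network reproduces the hand-solved potential step", {
  g <- make_body_grid(c(2, 1, 1), 1)
  cg <- conductivity_grid(g, array(0.8, dim = g$shape))
  edges <- mitnet:::grid_edges(g)
  p <- physics_params()
  A <- matrix(c(1, 0, 0), 1, 3)  # A along x on the single edge
  sys <- assemble_network(cg, A, p, edges)
  sol <- solve_potential(sys)
  # single edge, conductance g = sigma*h, EMF s = sigma*h^2*omega*A_x:
  # psi_2 - psi_1 = s / g = h * omega * A_x
  expect_equal(diff(sol$psi), 1 * p$omega * 1, tolerance = 1e-12)
})

test_that("edge conductance uses the harmonic mean (zero blocks the edge)", {
  g <- make_body_grid(c(2, 1, 1), 1)
  sig <- array(c(0, 1), dim = g$shape)
  edges <- mitnet:::grid_edges(g)
  sys <- assemble_network(conductivity_grid(g, sig),
                          matrix(1, 1, 3), physics_params(), edges)
  expect_equal(sys$g, 0)
  sig2 <- array(c(0.5, 1), dim = g$shape)
  sys2 <- assemble_network(conductivity_grid(g, sig2),
                           matrix(1, 1, 3), physics_params(), edges)
  expect_equal(sys2$g, 2 * 0.5 * 1 / 1.5)  # harmonic mean * h
})

test_that("sparse solve matches a dense direct solve on small random grids", {
  p <- physics_params()
  for (shape in list(c(3, 3, 3), c(4, 3, 2), c(5, 5, 5))) {
    fix <- random_system(shape, seed = sum(shape))
    sys <- assemble_network(fix$cgrid, fix$A, p, fix$edges)
    sol <- solve_potential(sys)
    L <- as.matrix(sys$L)
    keep <- setdiff(seq_len(fix$grid$n), sol$grounds)
    psi_dense <- numeric(fix$grid$n)
    psi_dense[keep] <- solve(L[keep, keep], sys$b[keep])
    expect_lt(max(abs(psi_dense - sol$psi)) / max(abs(psi_dense)), 1e-9)
  }
})

test_that("the potential is linear in the sources", {
  fix <- random_system(c(3, 3, 3), seed = 4)
  p <- physics_params()
  sys <- assemble_network(fix$cgrid, fix$A, p, fix$edges)
  sys3 <- sys; sys3$b <- 3 * sys$b
  expect_equal(solve_potential(sys3)$psi, 3 * solve_potential(sys)$psi,
               tolerance = 1e-12)
})

test_that("solutions are reference-node independent up to a constant", {
  fix <- random_system(c(3, 3, 3), seed = 8)
  p <- physics_params()
  sys <- assemble_network(fix$cgrid, fix$A, p, fix$edges)
  sol <- solve_potential(sys)
  L <- as.matrix(sys$L)
  keep <- setdiff(seq_len(fix$grid$n), 14L)  # ground a different node
  psi2 <- numeric(fix$grid$n); psi2[keep] <- solve(L[keep, keep], sys$b[keep])
  d <- sol$psi - psi2
  expect_lt(diff(range(d)), 1e-9 * max(abs(sol$psi)))
})

test_that("isolated conducting clusters are grounded per component", {
  g <- make_body_grid(c(5, 1, 1), 1)
  sig <- array(c(1, 1, 0, 1, 1), dim = g$shape)  # two 2-voxel components
  edges <- mitnet:::grid_edges(g)
  set.seed(2)
  sys <- assemble_network(conductivity_grid(g, sig),
                          matrix(rnorm(12), 4, 3), physics_params(), edges)
  sol <- solve_potential(sys)
  expect_true(all(is.finite(sol$psi)))
  expect_length(sol$grounds, 2)       # one reference node per component
  expect_lt(sol$residual, 1e-10)
})

test_that("Kirchhoff currents balance at every non-reference node", {
  fix <- random_system(c(4, 4, 4), seed = 10)
  p <- physics_params()
  sys <- assemble_network(fix$cgrid, fix$A, p, fix$edges)
  sol <- solve_potential(sys)
  expect_lt(sol$residual, 1e-10)
})

test_that("eddy currents vanish with conductivity and follow sigma*omega*A", {
  g <- make_body_grid(c(3, 3, 3), 1)
  p <- physics_params()
  edges <- mitnet:::grid_edges(g)
  # sigma = 0 everywhere -> empty network, J = 0
  cg0 <- conductivity_grid(g, 0)
  sys0 <- assemble_network(cg0, matrix(1, length(edges$axis), 3), p, edges)
  expect_true(sys0$empty)
  sol0 <- solve_potential(sys0)
  J0 <- eddy_currents(sol0, matrix(1, g$n, 3), cg0, p)
  expect_equal(max(abs(J0)), 0)
  # gradient-free case: with psi = 0 the current is sigma * omega * A
  cg <- conductivity_grid(g, 0.5)
  sol_flat <- structure(list(psi = rep(0, g$n), grounds = 1L, residual = 0),
                        class = "potential_solution")
  J <- eddy_currents(sol_flat, matrix(rep(c(1, 2, 3), each = g$n), ncol = 3),
                     cg, p)
  expect_equal(J[, 1], rep(0.5 * p$omega * 1, g$n), tolerance = 1e-9)
  expect_equal(J[, 3], rep(0.5 * p$omega * 3, g$n), tolerance = 1e-9)
})

test_that("eddy currents match a dense oracle with explicit stencils", {
  fix <- random_system(c(3, 3, 3), seed = 12)
  p <- physics_params()
  sys <- assemble_network(fix$cgrid, fix$A, p, fix$edges)
  sol <- solve_potential(sys)
  Ac <- matrix(rnorm(fix$grid$n * 3), ncol = 3)
  J <- eddy_currents(sol, Ac, fix$cgrid, p)
  # oracle: loop voxel by voxel with literal central/one-sided differences
  psi <- array(sol$psi, dim = fix$grid$shape)
  sig <- fix$cgrid$sigma
  idx <- function(i, j, k) (k - 1) * 9 + (j - 1) * 3 + i
  for (v in c(1, 5, 14, 27)) {
    k <- (v - 1) %/% 9 + 1; j <- ((v - 1) %% 9) %/% 3 + 1; i <- (v - 1) %% 3 + 1
    grad <- numeric(3)
    pos <- c(i, j, k)
    for (a in 1:3) {
      lo <- pos; lo[a] <- lo[a] - 1
      hi <- pos; hi[a] <- hi[a] + 1
      ok_lo <- lo[a] >= 1; ok_hi <- hi[a] <= 3
      if (ok_lo && ok_hi) {
        grad[a] <- (psi[hi[1], hi[2], hi[3]] - psi[lo[1], lo[2], lo[3]]) / 2
      } else if (ok_hi) {
        grad[a] <- psi[hi[1], hi[2], hi[3]] - psi[i, j, k]
      } else {
        grad[a] <- psi[i, j, k] - psi[lo[1], lo[2], lo[3]]
      }
    }
    expect_equal(J[v, ], sig[i, j, k] * (p$omega * Ac[v, ] - grad),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("receiver projection is the volume-weighted dot product", {
  g <- make_body_grid(c(1, 1, 1), 1)
  p <- physics_params(signal_gain = 1)
  val <- receiver_projection(matrix(c(1, 0, 0), 1), matrix(c(2, 0, 0), 1), g, p)
  expect_equal(val, 2)
  expect_equal(receiver_projection(matrix(0, 1, 3), matrix(c(2, 1, 1), 1), g, p), 0)
  expect_equal(receiver_projection(matrix(c(1, 2, 3), 1), matrix(0, 1, 3), g, p), 0)
  # gain and voxel volume scale linearly
  g2 <- make_body_grid(c(2, 2, 2), 2)
  p2 <- physics_params(signal_gain = 10)
  expect_equal(receiver_projection(matrix(c(1, 0, 0), 1), matrix(c(2, 0, 0), 1), g2, p2),
               2 * 8 * 10)
  expect_error(receiver_projection(matrix(0, 2, 3), matrix(0, 1, 3), g, p),
               "same voxel centers")
})

test_that("scan configuration validates trimming", {
  sc <- scan_config(256, 25)
  expect_equal(sc$kept, 206L)
  expect_error(scan_config(10, 5), "trim")
  # offsets are symmetric about the coil centre
  off <- mitnet:::scan_offsets(scan_config(8, 1))
  expect_equal(off, -off[8:1])
})

test_that("a zero-conductivity body yields an all-zero scan signal", {
  fix <- desk_caches()
  cg0 <- conductivity_grid(fix$caches$grid, 0)
  S <- scan_body(cg0, fix$caches, fix$config$physics)
  expect_equal(max(abs(S$values)), 0)
  expect_equal(dim(S$values), c(6L, fix$config$scan$kept))
})

test_that("the desk forward operator returns the documented signal length", {
  fix <- desk_caches()
  v <- forward_operator(rep(0.5, fix$caches$grid$n), fix$caches,
                        fix$config$physics)
  expect_length(v, 6 * fix$config$scan$kept)
  expect_error(forward_operator(rep(1.5, fix$caches$grid$n), fix$caches),
               "\\[0, 1\\]")
})

test_that("scan signals double when the excitation frequency doubles", {
  fix <- desk_caches()
  set.seed(21)
  res <- place_perturbations(fix$caches$grid, 1, c(4, 6), sigmas = 0)
  S1 <- scan_body(res$cgrid, fix$caches, physics_params(1.5e6))
  S2 <- scan_body(res$cgrid, fix$caches, physics_params(3.0e6))
  expect_equal(S2$values, 2 * S1$values, tolerance = 1e-9)
})

test_that("mirroring the body about the scan midline time-reverses the signal", {
  fix <- desk_caches()
  g <- fix$caches$grid
  set.seed(31)
  res <- place_perturbations(g, 1, c(4, 6), sigmas = 0)
  sig <- res$cgrid$sigma
  mir <- sig[g$shape[1]:1, , ]
  S <- scan_body(res$cgrid, fix$caches, fix$config$physics)
  Sm <- scan_body(conductivity_grid(g, mir), fix$caches, fix$config$physics)
  P <- ncol(S$values)
  expect_equal(Sm$values, S$values[, P:1], tolerance = 1e-7)
})

test_that("assembly is independent of voxel traversal order", {
  # permuting the edge list must not change the signal
  fix <- random_system(c(3, 3, 3), seed = 17)
  p <- physics_params()
  sys1 <- assemble_network(fix$cgrid, fix$A, p, fix$edges)
  set.seed(1)
  perm <- sample(length(fix$edges$axis))
  edges2 <- fix$edges
  edges2$i <- edges2$i[perm]; edges2$j <- edges2$j[perm]
  edges2$axis <- edges2$axis[perm]
  edges2$midpoints_cm <- edges2$midpoints_cm[perm, ]
  edges2$B <- edges2$B[, perm]
  sys2 <- assemble_network(fix$cgrid, fix$A[perm, ], p, edges2)
  expect_equal(as.matrix(sys1$L), as.matrix(sys2$L))
  expect_equal(sys1$b, sys2$b)
})

test_that("noise injection hits the requested SNR and is reproducible", {
  set.seed(1)
  base <- scan_signal(matrix(rnorm(6 * 40), 6, 40))
  expect_identical(add_noise(base, Inf), base)
  set.seed(5); n1 <- add_noise(base, 60)
  set.seed(5); n2 <- add_noise(base, 60)
  expect_identical(n1$values, n2$values)
  # Monte-Carlo SNR over many draws
  set.seed(7)
  psig <- mean(base$values^2)
  pnoise <- mean(vapply(1:2000, function(i)
    mean((add_noise(base, 60)$values - base$values)^2), 0))
  snr <- 10 * log10(psig / pnoise)
  expect_equal(snr, 60, tolerance = 0.1)
})

test_that("differential signals subtract after independent noise injection", {
  a <- scan_signal(matrix(c(3, 5), 1, 2), kind = "S_E")
  b <- scan_signal(matrix(c(1, 2), 1, 2), kind = "S_norm")
  d <- differential_signal(a, b, snr_db = Inf)
  expect_equal(d$values, matrix(c(2, 3), 1, 2))
  expect_equal(d$kind, "S_Diff")
  # identical signals cancel exactly when noise-free
  z <- differential_signal(a, a, snr_db = Inf)
  expect_equal(max(abs(z$values)), 0)
  expect_error(differential_signal(a, scan_signal(matrix(0, 2, 2))), "mismatch")
  # noise variance doubles relative to a single injection
  set.seed(9)
  base <- scan_signal(matrix(rnorm(6 * 40), 6, 40))
  v2 <- mean(vapply(1:1500, function(i) {
    d <- differential_signal(base, base, snr_db = 40)
    mean(d$values^2)
  }, 0))
  v1 <- mean(base$values^2) / 10^(40 / 10)
  expect_equal(v2 / v1, 2, tolerance = 0.1)
})

test_that("insulating perturbations perturb the signal more than conductive ones", {
  fix <- desk_caches()
  g <- fix$caches$grid
  bg <- conductivity_grid(g, 0.5)
  Sn <- scan_body(bg, fix$caches, fix$config$physics)
  set.seed(41)
  for (i in 1:3) {
    res <- place_perturbations(g, 1, c(4, 8), sigmas = 0)
    pert <- res$perturbations[[1]]
    S0 <- scan_body(res$cgrid, fix$caches, fix$config$physics)
    pert1 <- pert; pert1$sigma <- 1
    sig1 <- mitnet:::paint_cuboid(array(0.5, g$shape), g, pert1)
    S1 <- scan_body(conductivity_grid(g, sig1), fix$caches, fix$config$physics)
    expect_gt(max(abs(S0$values - Sn$values)), max(abs(S1$values - Sn$values)))
  }
})
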