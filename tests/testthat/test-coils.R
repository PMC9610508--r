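test_that("segment potential matches an adaptive quadrature oracle", {
  # A . u = integral of 1/r along the segment (unit current, mu0 I/4pi units)
  seg <- wire_segment(c(0, -3, 0), c(0, 3, 0))
  pts <- rbind(c(2, 0, 0), c(0.5, 1.7, 0.3), c(-4, 2, 5), c(0.3, 5, 0))
  A <- segment_vector_potential(seg, pts)
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    oracle <- stats::integrate(function(t) {
      1 / sqrt(p[1]^2 + (p[2] - t)^2 + p[3]^2)
    }, -3, 3, rel.tol = 1e-12)$value
    expect_equal(A[i, 2], oracle, tolerance = 1e-8)
    expect_equal(A[i, c(1, 3)], c(0, 0))  # parallel to the wire
  }
})

test_that("segment potential is symmetric and linear in current", {
  seg <- wire_segment(c(0, 0, -1), c(0, 0, 1))
  d <- 1.3
  A <- segment_vector_potential(seg, rbind(c(d, 0, 0), c(-d, 0, 0)))
  expect_equal(A[1, ], A[2, ])
  seg2 <- wire_segment(c(0, 0, -1), c(0, 0, 1), weight = -2)
  A2 <- segment_vector_potential(seg2, rbind(c(d, 0, 0)))
  expect_equal(A2[1, ], -2 * A[1, ])
  seg0 <- wire_segment(c(0, 0, -1), c(0, 0, 1), weight = 0)
  expect_equal(segment_vector_potential(seg0, rbind(c(d, 0, 0)))[1, ],
               c(0, 0, 0))
})

test_that("points near the wire axis are clamped and counted", {
  seg <- wire_segment(c(0, -1, 0), c(0, 1, 0))
  A <- segment_vector_potential(seg, rbind(c(1e-4, 0, 0)), excl_cm = 0.1)
  expect_true(all(is.finite(A)))
  expect_equal(attr(A, "n_clamped"), 1L)
  expect_error(wire_segment(c(1, 1, 1), c(1, 1, 1)), "zero length")
})

test_that("coil potential sums segments; single wire equals the segment", {
  seg <- wire_segment(c(0, -2, 0), c(0, 2, 0))
  coil <- coil_spec("exciter", list(seg), "one")
  pts <- rbind(c(1, 0.5, 2), c(3, -1, 0))
  expect_equal(coil_potential(coil, pts), segment_vector_potential(seg, pts),
               ignore_attr = TRUE)
  expect_error(coil_spec("exciter", list()), "at least one")
})

test_that("undulator wires alternate and sum like direct pairwise evaluation", {
  und <- undulator_coil(n_wires = 5, pitch_cm = 4, length_cm = 20,
                        y_center_cm = 0, z_cm = -5)
  w <- vapply(und$segments, function(s) s$weight, 0)
  expect_equal(w, c(1, -1, 1, -1, 1))
  pts <- rbind(c(2, 0, 3), c(0, 1, 8))  # first point midway between 2 wires
  direct <- Reduce(`+`, lapply(und$segments, function(s)
    segment_vector_potential(s, pts)))
  expect_equal(coil_potential(und, pts), direct, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("translating the body equals translating the coil oppositely", {
  und <- undulator_coil(n_wires = 3, pitch_cm = 5, length_cm = 10,
                        y_center_cm = 0, z_cm = -4)
  pts <- rbind(c(1, 2, 3), c(-2, 0, 6))
  dx <- 2.5
  shifted_pts <- pts; shifted_pts[, 1] <- shifted_pts[, 1] + dx
  und_m <- undulator_coil(n_wires = 3, pitch_cm = 5, length_cm = 10,
                          y_center_cm = 0, z_cm = -4)
  und_m$segments <- lapply(und_m$segments, function(s) {
    s$start_cm[1] <- s$start_cm[1] - dx; s$end_cm[1] <- s$end_cm[1] - dx; s
  })
  expect_equal(coil_potential(und, shifted_pts), coil_potential(und_m, pts),
               ignore_attr = TRUE)
})

test_that("potential caches reproduce direct evaluation for every offset", {
  fix <- desk_caches()
  grid <- fix$caches$grid
  coils <- config_coils(fix$config)
  pts <- voxel_centers(grid)[seq(1, grid$n, by = 97), , drop = FALSE]
  shifts <- c(-10, 0, 7.5)
  cache <- precompute_coil_maps(coils$receivers[[2]], pts, shifts)
  expect_equal(cache$n_offsets, 3L)
  for (j in 1:3) {
    moved <- pts; moved[, 1] <- moved[, 1] + shifts[j]
    expect_equal(cache_slice(cache, j),
                 coil_potential(coils$receivers[[2]], moved),
                 ignore_attr = TRUE)
  }
  expect_error(cache_slice(cache, 4))
})

test_that("offsets one lattice step apart are index-shifted copies", {
  # moving the body +1 cm equals sampling the previous map one voxel over
  g <- make_body_grid(c(6, 4, 4), 1)
  und <- undulator_coil(n_wires = 3, pitch_cm = 4, length_cm = 10,
                        y_center_cm = 2, z_cm = -3)
  ctr <- voxel_centers(g)
  c0 <- precompute_coil_maps(und, ctr, c(0, 1))
  A0 <- cache_slice(c0, 1); A1 <- cache_slice(c0, 2)
  arr0 <- array(A0, dim = c(g$shape, 3)); arr1 <- array(A1, dim = c(g$shape, 3))
  # interior x slices: A1[x, ...] == A0[x+1, ...]
  expect_equal(arr1[1:5, , , ], arr0[2:6, , , ], tolerance = 1e-12)
})

test_that("receiver array has three wide and three narrow butterflies", {
  rx <- receiver_array(28, 30, 12, 4)
  expect_length(rx, 6)
  labs <- vapply(rx, function(r) r$label, "")
  expect_equal(sum(grepl("wide", labs)), 3)
  expect_equal(sum(grepl("narrow", labs)), 3)
  # each butterfly is two counter-wound rectangles = 8 segments
  expect_true(all(vapply(rx, function(r) length(r$segments), 0L) == 8))
})

test_that("butterfly receivers reject the primary field by at least 20 dB", {
  cfg <- desk_caches()$config
  coils <- config_coils(cfg)
  grid <- desk_caches()$caches$grid
  pts <- voxel_centers(grid)
  rx <- cfg$receivers
  for (r in coils$receivers[c(1, 2)]) {
    lobe <- if (grepl("wide", r$label)) rx$wide_lobe_cm else rx$narrow_lobe_cm
    ys <- range(vapply(r$segments, function(s) s$start_cm[2], 0))
    ref <- single_lobe_receiver(lobe, ys[1], ys[2], rx$z_cm)
    rej <- primary_rejection_db(coils$exciter, r, ref, pts)
    expect_lt(rej, -20)
  }
})

test_that("the field decays monotonically far from the coil", {
  und <- undulator_coil(n_wires = 11, pitch_cm = 6, length_cm = 60,
                        y_center_cm = 0, z_cm = 0)
  # coil extent ~60 cm; probe along z beyond 5x that
  z <- seq(300, 900, by = 50)
  A <- coil_potential(und, cbind(0, 0, z))
  mag <- sqrt(rowSums(A^2))
  expect_true(all(diff(mag) < 0))
})
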