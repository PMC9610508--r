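#' Physical parameters of the forward model
#'
#' The forward model works in a real auxiliary formulation: under weak
#' coupling (the secondary field does not react on the excitation) with real
#' excitation potential `A` and real conductivity, the complex scalar
#' potential is `phi = -i * omega * psi` with `psi` solving a purely real
#' nodal system, the eddy currents are purely quadrature, and the Geselowitz
#' signal purely imaginary. Only the real quadrature amplitudes are stored;
#' this halves memory and time with no information loss.
#'
#' @param frequency_hz excitation frequency, default 1.5 MHz.
#' @param signal_gain overall output scale constant. Absolute signal units are
#'   not reproducible from geometry alone (they fold in coil turns, amplifier
#'   gain, ...); the gain is calibrated once per geometry profile so that
#'   differential signals are order 1 (see [calibrate_signal_gain()]).
#' @param emf_rule how the exciter potential is turned into an edge EMF:
#'   `"midpoint"` evaluates `A` at the edge midpoint, `"trapezoid"` averages
#'   the two voxel-centre values.
#' @param excl_cm wire singularity exclusion radius (cm).
#' @return a `physics_params` list with `omega = 2 * pi * frequency_hz`.
#' @export
physics_params <- function(frequency_hz = 1.5e6, signal_gain = 1,
                           emf_rule = c("midpoint", "trapezoid"),
                           excl_cm = 0.1) {
  if (frequency_hz <= 0) stop("frequency must be positive")
  structure(list(frequency_hz = frequency_hz,
                 omega = 2 * pi * frequency_hz,
                 signal_gain = signal_gain,
                 emf_rule = match.arg(emf_rule),
                 excl_cm = excl_cm),
            class = "physics_params")
}

#' Face-adjacency edge list of a voxel grid
#'
#' Enumerates all pairs of face-adjacent voxels. Each edge carries the linear
#' (Fortran-order) indices of its two endpoints, its axis, and its midpoint
#' (= shared face centre) in body-frame cm. Computed once per grid and reused
#' across samples and scan offsets.
#'
#' @param grid a `voxel_grid`.
#' @return list with integer vectors `i`, `j`, `axis` (1 = x, 2 = y, 3 = z)
#'   and the `ne x 3` matrix `midpoints_cm`.
#' @export
grid_edges <- function(grid) {
  sh <- grid$shape
  h <- grid$voxel_cm
  lin <- array(seq_len(grid$n), dim = sh)
  centers <- voxel_centers(grid)
  ii <- integer(0); jj <- integer(0); ax <- integer(0)
  for (a in 1:3) {
    if (sh[a] < 2) next
    idx_lo <- switch(a,
                     lin[-sh[1], , , drop = FALSE],
                     lin[, -sh[2], , drop = FALSE],
                     lin[, , -sh[3], drop = FALSE])
    idx_hi <- switch(a,
                     lin[-1, , , drop = FALSE],
                     lin[, -1, , drop = FALSE],
                     lin[, , -1, drop = FALSE])
    ii <- c(ii, as.integer(idx_lo))
    jj <- c(jj, as.integer(idx_hi))
    ax <- c(ax, rep.int(a, length(idx_lo)))
  }
  mids <- (centers[ii, , drop = FALSE] + centers[jj, , drop = FALSE]) / 2
  ne <- length(ii)
  # signed incidence matrix (n x ne): b = B %*% s accumulates edge sources
  B <- Matrix::sparseMatrix(i = c(jj, ii), j = c(seq_len(ne), seq_len(ne)),
                            x = c(rep(1, ne), rep(-1, ne)),
                            dims = c(grid$n, ne))
  list(i = ii, j = jj, axis = ax, midpoints_cm = mids, h = h, n = grid$n,
       B = B)
}

harmonic_mean_sigma <- function(si, sj) {
  s <- si + sj
  ifelse(s > 0, 2 * si * sj / pmax(s, .Machine$double.xmin), 0)
}

#' Assemble the resistor-network nodal system
#'
#' The body is interpreted as an electrical network with one node per voxel.
#' The conductance of the edge between two face-adjacent voxels is the
#' harmonic mean of their conductivities (series resistors) times face area
#' over centre distance; the exciter vector potential acts as an EMF source
#' on each edge (`omega * A . edge vector` in the real auxiliary form).
#' Kirchhoff's current law at every node yields a symmetric weighted graph
#' Laplacian `L` with zero row sums before grounding, and a source vector `b`
#' that vanishes when `A == 0`.
#'
#' @param cgrid a `conductivity_grid`.
#' @param A_ex_edges exciter vector potential at the edge midpoints: an
#'   `ne x 3` matrix (one scan offset) or a `potential_cache` over the edge
#'   midpoints (all offsets; `b` becomes an `n x n_offsets` matrix).
#' @param params a `physics_params`.
#' @param edges precomputed [grid_edges()]; computed if `NULL`.
#' @return a `network_system`: sparse `L`, source `b`, conductances `g`,
#'   conducting-node mask and edge bookkeeping. An all-zero conductivity
#'   yields an empty conducting set, flagged via `empty = TRUE` (the signal
#'   is identically zero).
#' @export
assemble_network <- function(cgrid, A_ex_edges, params, edges = NULL) {
  stopifnot(inherits(cgrid, "conductivity_grid"),
            inherits(params, "physics_params"))
  grid <- cgrid$grid
  if (is.null(edges)) edges <- grid_edges(grid)
  h <- grid$voxel_cm
  sig <- as.vector(cgrid$sigma)
  si <- sig[edges$i]; sj <- sig[edges$j]
  sh_edge <- harmonic_mean_sigma(si, sj)
  g <- sh_edge * h            # sigma_h * area (h^2) / distance (h)
  # edge EMF coefficient: sigma_h * area * omega, times A component along edge
  coef <- sh_edge * h^2 * params$omega
  A_axis <- edge_A_component(A_ex_edges, edges, params)
  n <- grid$n
  L <- Matrix::sparseMatrix(
    i = c(edges$i, edges$j, edges$i, edges$j),
    j = c(edges$j, edges$i, edges$i, edges$j),
    x = c(-g, -g, g, g),
    dims = c(n, n))
  s <- coef * A_axis                    # per-edge source, ne (x n_offsets)
  if (is.matrix(s)) {
    b <- as.matrix(edges$B %*% s)
  } else {
    b <- as.vector(edges$B %*% s)
  }
  conducting <- sig > 0
  structure(list(L = L, b = b, g = g, edges = edges,
                 conducting = conducting, n = n,
                 empty = !any(conducting)),
            class = "network_system")
}

# A component along each edge's axis; supports a plain ne x 3 matrix
# (midpoint values), a potential_cache over midpoints (all offsets), or
# voxel-centre values under the trapezoid rule
edge_A_component <- function(A_ex_edges, edges, params) {
  pick <- function(M) M[cbind(seq_along(edges$axis), edges$axis)]
  if (inherits(A_ex_edges, "potential_cache")) {
    ne <- length(edges$axis)
    stopifnot(A_ex_edges$n_points == ne)
    m <- A_ex_edges$n_offsets
    comp <- A_ex_edges$A[cbind(seq_len(ne * m), rep(edges$axis, m))]
    matrix(comp, ne, m)
  } else {
    A_ex_edges <- as_points(A_ex_edges)
    if (nrow(A_ex_edges) == length(edges$axis)) {
      pick(A_ex_edges)
    } else if (nrow(A_ex_edges) == edges$n && params$emf_rule == "trapezoid") {
      pick((A_ex_edges[edges$i, , drop = FALSE] +
              A_ex_edges[edges$j, , drop = FALSE]) / 2)
    } else {
      stop("A_ex_edges must be sampled at edge midpoints (or voxel centers under the trapezoid rule)")
    }
  }
}

#' Solve the nodal system for the auxiliary scalar potential
#'
#' Grounds one reference node per connected conducting component and solves
#' the reduced symmetric positive-definite system with a sparse Cholesky
#' factorisation (multiple right-hand sides are solved against one
#' factorisation). The common case of a single conducting component is tried
#' first with one ground node; if the reduced matrix turns out singular
#' (isolated conducting clusters), the components are identified and each is
#' grounded separately. The solution is extended by zero on grounded and
#' non-conducting nodes; the Kirchhoff current residual at every
#' non-reference node is checked against `tol`.
#'
#' @param system a `network_system` from [assemble_network()].
#' @param tol relative residual tolerance, default 1e-10.
#' @return a `potential_solution` with `psi` (vector, or `n x n_offsets`
#'   matrix), the grounded node indices and the worst relative residual.
#' @export
solve_potential <- function(system, tol = 1e-10) {
  stopifnot(inherits(system, "network_system"))
  b <- system$b
  bmat <- if (is.matrix(b)) b else matrix(b, ncol = 1)
  psi <- matrix(0, system$n, ncol(bmat))
  if (system$empty || all(bmat == 0)) {
    return(finish_solution(system, psi, b, grounds = integer(0), tol))
  }
  reduced_solve <- function(grounds) {
    keep <- setdiff(which(system$conducting), grounds)
    if (length(keep) > 0) {
      Lk <- system$L[keep, keep, drop = FALSE]
      ch <- Matrix::Cholesky(Matrix::forceSymmetric(Lk), LDL = FALSE, perm = TRUE)
      sol <- Matrix::solve(ch, bmat[keep, , drop = FALSE], system = "A")
      psi[keep, ] <- as.matrix(sol)
    }
    psi
  }
  grounds <- which(system$conducting)[1]
  # speculative single-component attempt: CHOLMOD's not-positive-definite
  # warning is expected when the guess is wrong, the fallback handles it
  psi <- tryCatch(suppressWarnings(reduced_solve(grounds)),
                  error = function(e) NULL)
  if (is.null(psi)) {
    # singular with one ground: ground every conducting component separately
    comps <- conducting_components(system)
    grounds <- vapply(comps, function(cc) cc[1], integer(1))
    psi <- matrix(0, system$n, ncol(bmat))
    psi <- reduced_solve(grounds)
  }
  finish_solution(system, psi, b, grounds, tol)
}

finish_solution <- function(system, psi, b, grounds, tol) {
  bmat <- if (is.matrix(b)) b else matrix(b, ncol = 1)
  res <- system$L %*% psi - bmat
  check <- setdiff(which(system$conducting), grounds)
  rel <- if (length(check) == 0 || all(bmat == 0)) 0 else {
    denom <- max(abs(bmat[check, ]), na.rm = TRUE)
    if (denom == 0) 0 else max(abs(res[check, ])) / denom
  }
  if (rel > tol)
    warning(sprintf("Kirchhoff residual %.3g exceeds tolerance %.3g", rel, tol))
  if (!is.matrix(b)) psi <- psi[, 1]
  structure(list(psi = psi, grounds = grounds, residual = rel),
            class = "potential_solution")
}

# connected components of the conducting voxel graph (edges with g > 0);
# breadth-first search on the sparse adjacency. The generator's bodies are
# almost always one component; this path is cheap relative to the solve.
conducting_components <- function(system) {
  cond <- which(system$conducting)
  if (length(cond) == 0) return(list())
  pos <- system$g > 0
  adj <- Matrix::sparseMatrix(
    i = c(system$edges$i[pos], system$edges$j[pos]),
    j = c(system$edges$j[pos], system$edges$i[pos]),
    x = 1, dims = c(system$n, system$n))
  labels <- integer(system$n)            # 0 = unvisited
  comps <- list()
  for (v in cond) {
    if (labels[v] != 0L) next
    id <- length(comps) + 1L
    frontier <- v
    labels[v] <- id
    members <- v
    while (length(frontier) > 0) {
      nb <- unique(adj@i[unlist(lapply(frontier, function(f)
        seq.int(adj@p[f] + 1L, length.out = adj@p[f + 1L] - adj@p[f])))] + 1L)
      nb <- nb[labels[nb] == 0L & system$conducting[nb]]
      labels[nb] <- id
      members <- c(members, nb)
      frontier <- nb
    }
    comps[[id]] <- sort(members)
  }
  comps
}

# neighbor linear index along axis (dir = +1/-1), NA outside the grid
shift_index <- function(shape, axis, dir) {
  n <- prod(shape)
  lin <- array(seq_len(n), dim = shape)
  pad <- function(a, along) {
    # shift array values by -dir along `along`, NA-filling
    idx <- seq_len(shape[along]) + dir
    idx[idx < 1 | idx > shape[along]] <- NA
    switch(along, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
           a[, , idx, drop = FALSE])
  }
  as.integer(pad(lin, axis))
}

#' Eddy-current density from the potential solution
#'
#' In the real auxiliary form the quadrature current density is
#' `J = sigma * (omega * A - grad(psi))` (with `psi` already carrying the
#' `omega` scale from the edge EMFs). The gradient uses central differences
#' on interior conducting voxels and one-sided differences where a neighbour
#' is outside the grid or non-conducting; `J = 0` wherever `sigma = 0`.
#'
#' @param sol a `potential_solution` (single offset: `psi` a vector).
#' @param A_ex_centers exciter potential at voxel centres, `n x 3`.
#' @param cgrid the `conductivity_grid` the system was assembled from.
#' @param params `physics_params`.
#' @return an `n x 3` matrix of quadrature current-density amplitudes.
#' @export
eddy_currents <- function(sol, A_ex_centers, cgrid, params) {
  psi <- if (is.matrix(sol$psi)) sol$psi else matrix(sol$psi, ncol = 1)
  G <- psi_gradient(psi, cgrid)
  sig <- as.vector(cgrid$sigma)
  A <- as_points(A_ex_centers)
  J <- cbind(sig * (params$omega * A[, 1] - G$gx[, 1]),
             sig * (params$omega * A[, 2] - G$gy[, 1]),
             sig * (params$omega * A[, 3] - G$gz[, 1]))
  J[sig == 0, ] <- 0
  J
}

# precomputed +/- shift index pairs for the three axes
grid_shifts <- function(shape) {
  lapply(1:3, function(a) list(ip = shift_index(shape, a, +1L),
                               im = shift_index(shape, a, -1L)))
}

# gradient of psi (n x m matrix over offsets) with conducting-aware stencils
psi_gradient <- function(psi, cgrid, shifts = NULL) {
  grid <- cgrid$grid
  h <- grid$voxel_cm
  cond <- as.vector(cgrid$sigma) > 0
  if (is.null(shifts)) shifts <- grid_shifts(grid$shape)
  out <- list()
  for (a in 1:3) {
    ip <- shifts[[a]]$ip
    im <- shifts[[a]]$im
    vp <- !is.na(ip); vp[vp] <- cond[ip[vp]]
    vm <- !is.na(im); vm[vm] <- cond[im[vm]]
    ip[is.na(ip)] <- 1L; im[is.na(im)] <- 1L
    pp <- psi[ip, , drop = FALSE]
    pm <- psi[im, , drop = FALSE]
    gboth <- (pp - pm) / (2 * h)
    gfwd <- (pp - psi) / h
    gbwd <- (psi - pm) / h
    w_both <- vp & vm; w_f <- vp & !vm; w_b <- !vp & vm
    g <- gboth * w_both + gfwd * w_f + gbwd * w_b
    out[[c("gx", "gy", "gz")[a]]] <- g
  }
  out
}

#' Geselowitz receiver projection
#'
#' The receiver signal is the reciprocity volume integral of the eddy-current
#' density dotted with the receiver coil's unit-current vector potential,
#' evaluated by the midpoint rule over voxels:
#' `S = gain * sum(J . A_R) * voxel volume`.
#'
#' @param J `n x 3` eddy-current matrix.
#' @param A_R `n x 3` receiver vector potential at the same voxel centres.
#' @param grid the `voxel_grid` (for the voxel volume).
#' @param params `physics_params` (for `signal_gain`).
#' @return scalar signal value.
#' @export
receiver_projection <- function(J, A_R, grid, params = physics_params()) {
  J <- as_points(J); A_R <- as_points(A_R)
  if (nrow(J) != nrow(A_R) || nrow(J) != grid$n)
    stop("J and A_R must be sampled at the same voxel centers as the grid")
  sum(J * A_R) * grid$voxel_cm^3 * params$signal_gain
}

#' Scan-range configuration
#'
#' @param positions total scan positions (default 256: the body travels
#'   through a 256 cm measuring range, one signal value per cm).
#' @param trim positions discarded from each end (default 25, leaving 206 —
#'   the edge values carry no further information).
#' @param step_cm scan step, default 1 cm.
#' @return a `scan_config`.
#' @export
scan_config <- function(positions = 256, trim = 25, step_cm = 1) {
  if (trim < 0 || 2 * trim >= positions)
    stop("trim must satisfy 0 <= 2*trim < positions")
  structure(list(positions = as.integer(positions), trim = as.integer(trim),
                 step_cm = step_cm, kept = as.integer(positions - 2 * trim)),
            class = "scan_config")
}

# body-center scan offsets (coil frame), symmetric about x = 0
scan_offsets <- function(scan) {
  (seq_len(scan$positions) - (scan$positions + 1) / 2) * scan$step_cm
}

# offsets of the kept (untrimmed) positions only; the trimmed edge positions
# are never part of the output, so they are never simulated
scan_kept_offsets <- function(scan) {
  scan_offsets(scan)[(scan$trim + 1L):(scan$positions - scan$trim)]
}


#' Precompute all coil potential maps for a scan
#'
#' Evaluates the exciter potential at voxel centres and edge midpoints and
#' every receiver potential at voxel centres, for every scan offset. This is
#' the expensive geometric part of the forward model; it depends only on the
#' grid and coils, never on the conductivity, so one cache serves a whole
#' dataset.
#'
#' @param grid the simulation `voxel_grid`.
#' @param coils list with `exciter` (a `coil_spec`) and `receivers` (list of
#'   `coil_spec`).
#' @param scan a `scan_config`.
#' @param params `physics_params`.
#' @return a `scan_cache`.
#' @export
scan_caches <- function(grid, coils, scan, params = physics_params()) {
  edges <- grid_edges(grid)
  shifts <- scan_kept_offsets(scan) - grid$extent_cm[1] / 2
  centers <- voxel_centers(grid)
  ex_centers <- precompute_coil_maps(coils$exciter, centers, shifts, params$excl_cm)
  ex_edges <- precompute_coil_maps(coils$exciter, edges$midpoints_cm, shifts,
                                   params$excl_cm)
  rx <- lapply(coils$receivers, function(r)
    precompute_coil_maps(r, centers, shifts, params$excl_cm))
  structure(list(grid = grid, edges = edges, scan = scan,
                 ex_centers = ex_centers, ex_edges = ex_edges, rx = rx,
                 shifts = grid_shifts(grid$shape)),
            class = "scan_cache")
}

#' Simulate a full scan of a body
#'
#' For every scan position: the exciter potential (from the cache) drives the
#' nodal system assembled from the conductivity grid, the system is solved
#' for the auxiliary potential (one Cholesky factorisation, all positions as
#' right-hand sides), eddy currents are formed, and each receiver signal is
#' obtained by Geselowitz projection. The leading and trailing `trim`
#' positions are then discarded.
#'
#' @param cgrid the `conductivity_grid` to scan (on the cache's grid).
#' @param caches a `scan_cache` from [scan_caches()].
#' @param params `physics_params`.
#' @return a `scan_signal`: `values` is a `6 x P` matrix (receivers x kept
#'   positions), `kind = "S"`, `noise_db = NA`.
#' @export
scan_body <- function(cgrid, caches, params = physics_params()) {
  stopifnot(inherits(caches, "scan_cache"),
            identical(cgrid$grid$shape, caches$grid$shape))
  scan <- caches$scan
  sys <- assemble_network(cgrid, caches$ex_edges, params, edges = caches$edges)
  sol <- solve_potential(sys)
  psi <- if (is.matrix(sol$psi)) sol$psi else matrix(sol$psi, ncol = 1)
  G <- psi_gradient(psi, cgrid, caches$shifts)
  n <- caches$grid$n
  m <- scan$kept
  sig_rep <- rep.int(as.vector(cgrid$sigma), m)
  # stacked quadrature current density over all offsets ((n*m) x 3);
  # the (n x m) gradient matrices flatten in the same block order as the
  # potential caches (offset blocks of n points)
  Aex <- caches$ex_centers$A
  Jx <- sig_rep * (params$omega * Aex[, 1] - as.vector(G$gx))
  Jy <- sig_rep * (params$omega * Aex[, 2] - as.vector(G$gy))
  Jz <- sig_rep * (params$omega * Aex[, 3] - as.vector(G$gz))
  nr <- length(caches$rx)
  volgain <- caches$grid$voxel_cm^3 * params$signal_gain
  S <- matrix(0, nr, m)
  for (r in seq_len(nr)) {
    AR <- caches$rx[[r]]$A
    prods <- Jx * AR[, 1] + Jy * AR[, 2] + Jz * AR[, 3]
    S[r, ] <- colSums(matrix(prods, n, m)) * volgain
  }
  scan_signal(S, kind = "S", noise_db = NA_real_)
}

#' Construct a scan-signal object
#'
#' @param values `n_receivers x P` matrix of real signal values.
#' @param kind one of `"S"`, `"S_norm"`, `"S_E"`, `"S_Diff"`.
#' @param noise_db applied SNR in dB, or `NA` for noise-free.
#' @return a `scan_signal`.
#' @export
scan_signal <- function(values, kind = "S", noise_db = NA_real_) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("scan signal contains non-finite values")
  structure(list(values = values, kind = kind, noise_db = noise_db),
            class = "scan_signal")
}

#' @export
print.scan_signal <- function(x, ...) {
  cat(sprintf("<scan_signal> %s: %d receivers x %d positions%s\n",
              x$kind, nrow(x$values), ncol(x$values),
              if (is.na(x$noise_db)) "" else sprintf(", %g dB noise", x$noise_db)))
  invisible(x)
}

#' Flatten a scan signal to the network's input vector
#'
#' Receiver traces are concatenated: the flat vector is
#' `c(receiver 1 trace, receiver 2 trace, ...)`, length `6 * P` (1236 for the
#' default torso scan).
#'
#' @param signal a `scan_signal` or `6 x P` matrix.
#' @return numeric vector.
#' @export
flatten_signal <- function(signal) {
  v <- if (inherits(signal, "scan_signal")) signal$values else as.matrix(signal)
  as.vector(t(v))
}

#' The deterministic forward operator sigma -> S
#'
#' Composes placement-free simulation: wraps a conductivity vector into a
#' grid, scans it, and flattens the noise-free result. The map is
#' deterministic; noise and differential signalling are applied downstream.
#'
#' @param sigma_vector per-voxel conductivities in `[0, 1]`, Fortran order,
#'   on the cache's grid.
#' @param caches a `scan_cache`.
#' @param params `physics_params`.
#' @return flattened signal vector of length `n_receivers * P`.
#' @export
forward_operator <- function(sigma_vector, caches, params = physics_params()) {
  if (any(sigma_vector < 0 | sigma_vector > 1))
    stop("conductivities must lie in [0, 1]")
  cg <- unflatten_fortran(sigma_vector, caches$grid)
  flatten_signal(scan_body(cg, caches, params))
}

#' Add white Gaussian measurement noise at a target SNR
#'
#' The noise RMS is `rms(reference) / 10^(snr_db / 20)` with the signal
#' itself as reference (or `rms_ref` when the signal is all-zero, e.g. a
#' degenerate differential trace). Draws come from R's global RNG stream.
#'
#' @param signal a `scan_signal`.
#' @param snr_db target signal-to-noise ratio in dB; `Inf` returns the signal
#'   unchanged.
#' @param rms_ref optional externally supplied reference RMS.
#' @return a `scan_signal` with `noise_db` recorded.
#' @export
add_noise <- function(signal, snr_db = 60, rms_ref = NULL) {
  stopifnot(inherits(signal, "scan_signal"))
  if (is.infinite(snr_db)) return(signal)
  v <- signal$values
  ref <- if (!is.null(rms_ref)) rms_ref else sqrt(mean(v^2))
  if (ref == 0) stop("all-zero signal: supply rms_ref (e.g. the paired S_norm RMS)")
  noise_rms <- ref / 10^(snr_db / 20)
  out <- v + matrix(stats::rnorm(length(v), sd = noise_rms), nrow(v), ncol(v))
  scan_signal(out, kind = signal$kind, noise_db = snr_db)
}

#' Differential signal: perturbed minus background measurement
#'
#' `S_Diff = S_E - S_norm`, with measurement noise added independently to
#' both signals first (each referenced to its own RMS). This mimics two
#' separate physical measurements, one with and one without perturbation.
#'
#' @param S_E `scan_signal` of the perturbed body.
#' @param S_norm `scan_signal` of the background body.
#' @param snr_db SNR of the two independent noise injections; `Inf` for
#'   noise-free.
#' @return a `scan_signal` with `kind = "S_Diff"`.
#' @export
differential_signal <- function(S_E, S_norm, snr_db = 60) {
  stopifnot(inherits(S_E, "scan_signal"), inherits(S_norm, "scan_signal"))
  if (!all(dim(S_E$values) == dim(S_norm$values)))
    stop("S_E and S_norm have mismatched shapes")
  ref <- sqrt(mean(S_norm$values^2))
  nE <- add_noise(S_E, snr_db, rms_ref = if (all(S_E$values == 0)) ref else NULL)
  nN <- add_noise(S_norm, snr_db)
  scan_signal(nE$values - nN$values, kind = "S_Diff", noise_db = snr_db)
}

#' Calibrate the overall signal gain for a geometry profile
#'
#' Runs one noise-free differential simulation of a centred reference cuboid
#' (sigma = 0, mid-range edge length) and returns the gain that maps the
#' maximum absolute differential signal to 1. Called once per geometry
#' profile; the resulting constant is stored in the profile.
#'
#' @param caches a `scan_cache`.
#' @param params `physics_params` (its `signal_gain` is ignored).
#' @param edge_cm reference cuboid edge length; default mid-range 8 cm.
#' @return the calibrated gain (numeric scalar).
#' @export
calibrate_signal_gain <- function(caches, params = physics_params(),
                                  edge_cm = 8) {
  grid <- caches$grid
  p0 <- physics_params(params$frequency_hz, signal_gain = 1,
                       emf_rule = params$emf_rule, excl_cm = params$excl_cm)
  bg <- conductivity_grid(grid, 0.5)
  org <- round((grid$extent_cm - edge_cm) / 2)
  pert <- cuboid_perturbation(org, rep(edge_cm, 3), 0.0)
  sig <- paint_cuboid(array(0.5, grid$shape), grid, pert)
  Sn <- scan_body(bg, caches, p0)
  Se <- scan_body(conductivity_grid(grid, sig), caches, p0)
  dmax <- max(abs(Se$values - Sn$values))
  if (dmax == 0) stop("degenerate geometry: zero differential signal")
  1 / dmax
}
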