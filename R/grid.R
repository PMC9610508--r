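#' Voxel lattice for a cuboid body
#'
#' A regular voxel grid covering a cuboid body. The coordinate frame follows
#' the scanner: x is the travel direction, y is vertical, z is depth towards
#' the receiver array. Voxel indices are 1-based in R; physical positions are
#' measured at voxel centres (`origin + (index - 0.5) * voxel_cm`).
#'
#' @param extent_cm numeric length-3, body dimensions (x, y, z) in cm.
#' @param voxel_cm voxel edge length in cm (typically 1 for the simulation
#'   grid, 2 for the reconstruction grid).
#' @return an object of class `voxel_grid` with fields `extent_cm`,
#'   `voxel_cm`, `shape` (voxel counts per axis) and `n` (total voxel count).
#' @examples
#' g <- make_body_grid(c(50, 28, 24), 1)
#' g$n  # 33600
#' @export
make_body_grid <- function(extent_cm, voxel_cm = 1) {
  stopifnot(length(extent_cm) == 3, length(voxel_cm) == 1)
  if (any(extent_cm <= 0) || voxel_cm <= 0)
    stop("extents and voxel size must be positive")
  rem <- extent_cm %% voxel_cm
  if (any(abs(rem) > 1e-9 & abs(rem - voxel_cm) > 1e-9)) {
    ax <- c("x", "y", "z")[which(abs(rem) > 1e-9 & abs(rem - voxel_cm) > 1e-9)[1]]
    stop(sprintf("extent along %s axis (%g cm) is not divisible by voxel size %g cm",
                 ax, extent_cm[match(ax, c("x", "y", "z"))], voxel_cm))
  }
  shape <- as.integer(round(extent_cm / voxel_cm))
  structure(list(extent_cm = as.numeric(extent_cm),
                 voxel_cm = as.numeric(voxel_cm),
                 shape = shape,
                 n = prod(shape)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %g x %g x %g cm at %g cm (%d x %d x %d = %d voxels)\n",
              x$extent_cm[1], x$extent_cm[2], x$extent_cm[3], x$voxel_cm,
              x$shape[1], x$shape[2], x$shape[3], x$n))
  invisible(x)
}

#' Voxel centre coordinates
#'
#' @param grid a `voxel_grid`.
#' @return an `n x 3` matrix of voxel centre coordinates in cm, in Fortran
#'   (column-major, x fastest) order — the same order used by
#'   [flatten_fortran()].
#' @export
voxel_centers <- function(grid) {
  h <- grid$voxel_cm
  ax <- lapply(grid$shape, function(k) (seq_len(k) - 0.5) * h)
  cbind(x = rep(ax[[1]], times = grid$shape[2] * grid$shape[3]),
        y = rep(rep(ax[[2]], each = grid$shape[1]), times = grid$shape[3]),
        z = rep(ax[[3]], each = grid$shape[1] * grid$shape[2]))
}

#' Conductivity distribution on a voxel grid
#'
#' @param grid a `voxel_grid`.
#' @param sigma a 3D array matching `grid$shape`, or a scalar, conductivity in
#'   S/m. Values must lie in `[0, 1]`.
#' @return an object of class `conductivity_grid`.
#' @export
conductivity_grid <- function(grid, sigma = 0.5) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (length(sigma) == 1) sigma <- array(sigma, dim = grid$shape)
  sigma <- as.array(sigma)
  if (!identical(as.integer(dim(sigma)), grid$shape))
    stop("sigma dimensions do not match grid shape")
  if (any(sigma < 0 | sigma > 1))
    stop("conductivities must lie in [0, 1] S/m")
  structure(list(grid = grid, sigma = sigma), class = "conductivity_grid")
}

#' @export
print.conductivity_grid <- function(x, ...) {
  cat(sprintf("<conductivity_grid> %d x %d x %d voxels, sigma in [%.3g, %.3g] S/m\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              min(x$sigma), max(x$sigma)))
  invisible(x)
}

#' Cuboid conductivity perturbation
#'
#' @param origin_cm lower corner (x, y, z) in cm.
#' @param lengths_cm edge lengths per axis in cm.
#' @param sigma conductivity inside the cuboid, S/m.
#' @return an object of class `cuboid_perturbation`.
#' @export
cuboid_perturbation <- function(origin_cm, lengths_cm, sigma) {
  stopifnot(length(origin_cm) == 3, length(lengths_cm) == 3, length(sigma) == 1)
  if (any(lengths_cm <= 0)) stop("cuboid edge lengths must be positive")
  structure(list(origin_cm = as.numeric(origin_cm),
                 lengths_cm = as.numeric(lengths_cm),
                 sigma = as.numeric(sigma)),
            class = "cuboid_perturbation")
}

# voxel index ranges (per axis) covered by a cuboid on a grid; cuboids are
# expected to be lattice-aligned (integer-cm corners on a 1 cm grid)
cuboid_index_ranges <- function(grid, pert) {
  h <- grid$voxel_cm
  lo <- pert$origin_cm
  hi <- pert$origin_cm + pert$lengths_cm
  lapply(1:3, function(a) {
    i0 <- floor(lo[a] / h + 1e-9) + 1
    i1 <- ceiling(hi[a] / h - 1e-9)
    as.integer(i0):as.integer(i1)
  })
}

# paint a cuboid into a sigma array (lattice-aligned)
paint_cuboid <- function(sigma, grid, pert) {
  r <- cuboid_index_ranges(grid, pert)
  sigma[r[[1]], r[[2]], r[[3]]] <- pert$sigma
  sigma
}

#' Randomly place cuboid perturbations into a background body
#'
#' Places `n_objects` non-overlapping cuboids fully inside the body, with edge
#' lengths drawn uniformly from the integer centimetres in `length_range_cm`
#' (so cuboids align to the fine lattice) and lattice-aligned origins.
#' Placement uses rejection sampling; overlap between objects is rejected.
#' Uses R's global RNG stream — call [set.seed()] beforehand for
#' reproducibility.
#'
#' @param grid a fine `voxel_grid` (1 cm).
#' @param n_objects 1 or 2 cuboids.
#' @param length_range_cm integer range of edge lengths, default `c(6, 10)`.
#' @param sigmas conductivity per object, S/m (recycled); default 0.
#' @param background background conductivity, default 0.5 S/m.
#' @param margin_cm minimum distance from cuboid to body boundary, default 0.
#' @param max_attempts rejection-sampling cap per object.
#' @return list with `cgrid` (a `conductivity_grid`) and `perturbations`
#'   (list of `cuboid_perturbation`).
#' @export
place_perturbations <- function(grid, n_objects = 1,
                                length_range_cm = c(6, 10),
                                sigmas = 0.0, background = 0.5,
                                margin_cm = 0, max_attempts = 1000) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!n_objects %in% c(1L, 2L)) stop("n_objects must be 1 or 2")
  sigmas <- rep_len(sigmas, n_objects)
  h <- grid$voxel_cm
  perts <- list()
  occ <- array(FALSE, dim = grid$shape)
  for (k in seq_len(n_objects)) {
    placed <- FALSE
    lens <- seq(length_range_cm[1], length_range_cm[2])
    for (att in seq_len(max_attempts)) {
      # index-based draws: sample(x, ...) with a length-1 x would resample 1:x
      len <- lens[sample.int(length(lens), 3, replace = TRUE)]
      room <- grid$extent_cm - len - 2 * margin_cm
      if (any(room < 0)) next
      org <- margin_cm + vapply(room, function(r) {
        pos <- 0:as.integer(r)
        pos[sample.int(length(pos), 1)]
      }, 0L)
      cand <- cuboid_perturbation(org, len, sigmas[k])
      r <- cuboid_index_ranges(grid, cand)
      if (any(occ[r[[1]], r[[2]], r[[3]]])) next
      occ[r[[1]], r[[2]], r[[3]]] <- TRUE
      perts[[k]] <- cand
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf("failed to place object %d within %d attempts (seed-dependent); enlarge the body or shrink length_range_cm",
                   k, max_attempts))
  }
  sig <- array(background, dim = grid$shape)
  for (p in perts) sig <- paint_cuboid(sig, grid, p)
  list(cgrid = conductivity_grid(grid, sig), perturbations = perts)
}

#' Coarsen a fine conductivity grid by 2x2x2 averaging
#'
#' Each 2 cm voxel takes the arithmetic mean of its eight 1 cm children; the
#' volume-weighted mean conductivity is conserved exactly. This is the
#' fine-to-coarse map that separates the simulation discretisation from the
#' reconstruction discretisation (inverse-crime avoidance): partially covered
#' coarse voxels take intermediate values such as 0.25 or 0.75 S/m.
#'
#' @param fine a `conductivity_grid` on a fine grid with even voxel counts.
#' @param factor integer coarsening factor per axis, default 2.
#' @return a `conductivity_grid` on the coarse grid.
#' @export
coarsen <- function(fine, factor = 2L) {
  stopifnot(inherits(fine, "conductivity_grid"))
  sh <- fine$grid$shape
  if (any(sh %% factor != 0))
    stop("fine grid shape must be divisible by the coarsening factor on every axis")
  cs <- sh %/% factor
  # average factor^3 children: reshape to 6D and reduce
  a <- array(fine$sigma, dim = c(factor, cs[1], factor, cs[2], factor, cs[3]))
  csig <- apply(a, c(2, 4, 6), mean)
  cgrid <- make_body_grid(fine$grid$extent_cm, fine$grid$voxel_cm * factor)
  conductivity_grid(cgrid, csig)
}

#' Flatten a conductivity grid to a vector in Fortran order
#'
#' Fortran (column-major) order: the x index varies fastest, then y, then z —
#' R's native array order, so the round trip with [unflatten_fortran()] is
#' exact. The default coarse torso grid flattens to length 4200.
#'
#' @param cgrid a `conductivity_grid` (or a 3D array).
#' @return numeric vector of per-voxel conductivities.
#' @export
flatten_fortran <- function(cgrid) {
  sigma <- if (inherits(cgrid, "conductivity_grid")) cgrid$sigma else cgrid
  as.vector(sigma)
}

#' Restore a flattened conductivity vector to its 3D grid
#'
#' @param v numeric vector of length `prod(grid$shape)`.
#' @param grid the `voxel_grid` the vector was flattened from.
#' @return a `conductivity_grid`.
#' @export
unflatten_fortran <- function(v, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (length(v) != grid$n)
    stop(sprintf("vector length %d does not match grid voxel count %d",
                 length(v), grid$n))
  conductivity_grid(grid, array(v, dim = grid$shape))
}
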