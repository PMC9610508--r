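#' @useDynLib mitnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Straight wire segment carrying unit current
#'
#' @param start_cm,end_cm 3D endpoints in cm.
#' @param weight signed current weight (+1 / -1 for antiparallel wires).
#' @return a `wire_segment`.
#' @export
wire_segment <- function(start_cm, end_cm, weight = 1) {
  stopifnot(length(start_cm) == 3, length(end_cm) == 3)
  if (sum((end_cm - start_cm)^2) == 0) stop("wire segment has zero length")
  structure(list(start_cm = as.numeric(start_cm), end_cm = as.numeric(end_cm),
                 weight = as.numeric(weight)),
            class = "wire_segment")
}

#' Vector potential of a straight segment at field points
#'
#' Closed-form Biot-Savart solution for a finite straight wire with unit
#' current: `A = w * ln((r1 + r2 + L)/(r1 + r2 - L)) * u`, in units of
#' `mu0 * I / (4 * pi)`, where `r1`, `r2` are the distances from the field
#' point to the endpoints, `L` the segment length and `u` the segment
#' direction. Field points within `excl_cm` of the wire axis are clamped to
#' that radius (counted in the `"n_clamped"` attribute); voxel centres never
#' coincide with wires in the default geometries.
#'
#' @param seg a `wire_segment`.
#' @param points an `N x 3` matrix of field points (cm).
#' @param excl_cm singularity exclusion radius, default 0.1 cm.
#' @return `N x 3` matrix of vector-potential samples.
#' @export
segment_vector_potential <- function(seg, points, excl_cm = 0.1) {
  stopifnot(inherits(seg, "wire_segment"))
  points <- as_points(points)
  acc <- matrix(0, nrow(points), 3)
  nc <- .segment_potential_accum(points, seg$start_cm, seg$end_cm,
                                 seg$weight, excl_cm, acc)
  attr(acc, "n_clamped") <- nc
  acc
}

as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  storage.mode(points) <- "double"
  if (ncol(points) != 3) stop("points must be an N x 3 matrix")
  points
}

#' Coil built from straight wire segments
#'
#' @param role `"exciter"` or `"receiver"`.
#' @param segments list of `wire_segment`s.
#' @param label free-form label (receiver index / width class).
#' @return a `coil_spec`.
#' @export
coil_spec <- function(role = c("exciter", "receiver"), segments, label = "") {
  role <- match.arg(role)
  if (length(segments) == 0) stop("coil must contain at least one segment")
  stopifnot(all(vapply(segments, inherits, TRUE, "wire_segment")))
  structure(list(role = role, segments = segments, label = label),
            class = "coil_spec")
}

#' @export
print.coil_spec <- function(x, ...) {
  cat(sprintf("<coil_spec> %s '%s' with %d segments\n",
              x$role, x$label, length(x$segments)))
  invisible(x)
}

#' Undulator exciter: parallel vertical wires with antiparallel currents
#'
#' The exciter is an array of `n_wires` vertical (y-aligned) wires with
#' alternating current direction, centred on x = 0 in the coil frame. The
#' alternating currents produce a primary field whose sign alternates along
#' the travel direction with spatial period `2 * pitch_cm`.
#'
#' @param n_wires number of wires (odd; default 11).
#' @param pitch_cm wire-to-wire spacing in cm.
#' @param length_cm wire length in cm.
#' @param y_center_cm vertical centre of the wires.
#' @param z_cm plane of the exciter (negative: in front of the body).
#' @return a `coil_spec` with `role = "exciter"`.
#' @export
undulator_coil <- function(n_wires = 11, pitch_cm = 6, length_cm = 60,
                           y_center_cm = 14, z_cm = -6) {
  stopifnot(n_wires >= 1)
  xs <- (seq_len(n_wires) - (n_wires + 1) / 2) * pitch_cm
  y0 <- y_center_cm - length_cm / 2
  y1 <- y_center_cm + length_cm / 2
  segs <- lapply(seq_len(n_wires), function(i)
    wire_segment(c(xs[i], y0, z_cm), c(xs[i], y1, z_cm),
                 weight = (-1)^(i - 1)))
  coil_spec("exciter", segs, label = sprintf("undulator-%d", n_wires))
}

# rectangular loop in a z = const plane; winding +1 traverses counterclockwise
# when viewed from +z
rect_loop_segments <- function(x0, x1, y0, y1, z, winding = 1) {
  corners <- list(c(x0, y0, z), c(x1, y0, z), c(x1, y1, z), c(x0, y1, z))
  if (winding < 0) corners <- rev(corners)
  lapply(1:4, function(i)
    wire_segment(corners[[i]], corners[[i %% 4 + 1]], weight = 1))
}

#' Butterfly (figure-eight) receiver coil
#'
#' Two counter-wound rectangular loops sharing the vertical edge at x = 0.
#' The opposite windings place the receiver in a gradiometric position: a
#' field symmetric about x = 0 couples equally but with opposite sign into
#' the two lobes, cancelling the exciter's primary field.
#'
#' @param lobe_width_cm width of each lobe in cm (total coil width is twice
#'   this).
#' @param y0_cm,y1_cm vertical extent of the loops.
#' @param z_cm receiver plane (beyond the body's back face).
#' @param label receiver label.
#' @return a `coil_spec` with `role = "receiver"`.
#' @export
butterfly_receiver <- function(lobe_width_cm, y0_cm, y1_cm, z_cm, label = "") {
  segs <- c(rect_loop_segments(-lobe_width_cm, 0, y0_cm, y1_cm, z_cm, +1),
            rect_loop_segments(0, lobe_width_cm, y0_cm, y1_cm, z_cm, -1))
  coil_spec("receiver", segs, label = label)
}

#' Single-lobe rectangular reference receiver
#'
#' A plain rectangular loop with the same outer dimensions as a butterfly
#' receiver, used as the non-gradiometric reference when quantifying primary
#' field rejection.
#'
#' @inheritParams butterfly_receiver
#' @export
single_lobe_receiver <- function(lobe_width_cm, y0_cm, y1_cm, z_cm,
                                 label = "single") {
  segs <- rect_loop_segments(-lobe_width_cm, lobe_width_cm, y0_cm, y1_cm,
                             z_cm, +1)
  coil_spec("receiver", segs, label = label)
}

#' Receiver array: three wide and three narrow butterfly coils
#'
#' Six butterfly receivers vertically stacked over the body height,
#' alternating wide and narrow lobes from bottom to top. Wide lobes improve
#' coverage, narrow lobes sharpen depth (z) discrimination; the vertical
#' stacking resolves the y direction.
#'
#' @param body_height_cm vertical body extent the array spans.
#' @param z_cm receiver plane.
#' @param wide_lobe_cm,narrow_lobe_cm lobe widths of the two receiver classes.
#' @return list of six `coil_spec`s, labels `"r1.wide" ... "r6.narrow"`.
#' @export
receiver_array <- function(body_height_cm = 28, z_cm = 30,
                           wide_lobe_cm = 12, narrow_lobe_cm = 4) {
  band <- body_height_cm / 6
  lapply(1:6, function(i) {
    wide <- i %% 2 == 1
    butterfly_receiver(if (wide) wide_lobe_cm else narrow_lobe_cm,
                       y0_cm = (i - 1) * band, y1_cm = i * band, z_cm = z_cm,
                       label = sprintf("r%d.%s", i, if (wide) "wide" else "narrow"))
  })
}

#' Vector potential of a coil at field points
#'
#' Sums the closed-form straight-segment contributions of every segment in
#' the coil. Linear in current by construction.
#'
#' @param coil a `coil_spec`.
#' @param points `N x 3` matrix of field points (cm) in the coil frame.
#' @param excl_cm singularity exclusion radius.
#' @return `N x 3` matrix of vector-potential samples (units `mu0*I/(4*pi)`).
#' @export
coil_potential <- function(coil, points, excl_cm = 0.1) {
  stopifnot(inherits(coil, "coil_spec"))
  points <- as_points(points)
  acc <- matrix(0, nrow(points), 3)
  nc <- 0L
  for (s in coil$segments)
    nc <- nc + .segment_potential_accum(points, s$start_cm, s$end_cm,
                                        s$weight, excl_cm, acc)
  attr(acc, "n_clamped") <- nc
  acc
}

#' Precompute coil potentials over all scan offsets
#'
#' The body moves through the fixed coil frame; translating the body by an
#' offset along x is implemented by shifting the sample points. The cache
#' stacks the per-offset `N x 3` potential maps into one
#' `(N * n_offsets) x 3` matrix; [cache_slice()] extracts one offset block.
#' Evaluation happens exactly once per (coil, offset).
#'
#' @param coil a `coil_spec`.
#' @param points `N x 3` body-frame sample points (cm).
#' @param x_shifts numeric vector: x translation of the body frame into the
#'   coil frame, one per scan offset.
#' @param excl_cm singularity exclusion radius.
#' @return a `potential_cache` (fields `A`, `n_points`, `n_offsets`).
#' @export
precompute_coil_maps <- function(coil, points, x_shifts, excl_cm = 0.1) {
  points <- as_points(points)
  n <- nrow(points)
  m <- length(x_shifts)
  all_pts <- points[rep.int(seq_len(n), m), , drop = FALSE]
  all_pts[, 1] <- all_pts[, 1] + rep(x_shifts, each = n)
  A <- coil_potential(coil, all_pts, excl_cm)
  structure(list(A = A, n_points = n, n_offsets = m, x_shifts = x_shifts),
            class = "potential_cache")
}

#' Extract one offset block from a potential cache
#'
#' @param cache a `potential_cache`.
#' @param j offset index (1-based).
#' @return `N x 3` matrix, identical to direct evaluation at that offset.
#' @export
cache_slice <- function(cache, j) {
  stopifnot(inherits(cache, "potential_cache"), j >= 1, j <= cache$n_offsets)
  idx <- (j - 1L) * cache$n_points + seq_len(cache$n_points)
  cache$A[idx, , drop = FALSE]
}

#' Primary-field rejection of a receiver geometry
#'
#' Quantifies the gradiometric design: the direct (conductivity-free)
#' coupling surrogate `sum(A_ex . A_R) * voxel volume` over the body volume,
#' for a candidate receiver versus a single-lobe rectangular loop of the same
#' outer dimensions. Returns the rejection in dB
#' (`20 * log10(|butterfly| / |single|)`, negative = suppressed).
#'
#' @param exciter exciter `coil_spec`.
#' @param receiver butterfly `coil_spec`.
#' @param reference single-lobe reference `coil_spec`.
#' @param points body voxel centres in the coil frame.
#' @param voxel_volume_cm3 voxel volume.
#' @return rejection in dB (negative values mean the butterfly suppresses the
#'   primary coupling relative to the reference).
#' @export
primary_rejection_db <- function(exciter, receiver, reference, points,
                                 voxel_volume_cm3 = 1) {
  A_ex <- coil_potential(exciter, points)
  s_fly <- sum(A_ex * coil_potential(receiver, points)) * voxel_volume_cm3
  s_ref <- sum(A_ex * coil_potential(reference, points)) * voxel_volume_cm3
  20 * log10(abs(s_fly) / abs(s_ref))
}
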