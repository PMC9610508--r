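#' Enumerate conductivity combinations for the perturbation objects
#'
#' Each geometric case is simulated under every possible assignment of the
#' perturbation conductivities: one object gives the two combinations
#' `(0)` and `(1)` S/m, two objects give all four of `{0, 1}^2`. Weak-signal
#' combinations (1.0 S/m objects) are therefore represented as often as
#' strong ones.
#'
#' @param n_objects 1 or 2.
#' @param sigmas the admissible object conductivities, default `c(0, 1)` S/m.
#' @return list of numeric vectors, one conductivity per object.
#' @export
enumerate_combos <- function(n_objects, sigmas = c(0, 1)) {
  if (!n_objects %in% c(1L, 2L)) stop("n_objects must be 1 or 2")
  g <- do.call(expand.grid, rep(list(sigmas), n_objects))
  lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ]))
}

#' Dataset generation configuration
#'
#' @param cases_1obj geometric cases with one perturbation object (each
#'   yields 2 samples).
#' @param cases_2obj geometric cases with two objects (each yields 4
#'   samples). Paper-scale corpus: 3000 and 15000, i.e. 66,000 samples.
#' @param length_range_cm cuboid edge-length range (integer cm).
#' @param sigmas admissible object conductivities.
#' @param background background conductivity, S/m.
#' @param snr_db measurement noise level, default 60 dB.
#' @param margin_cm minimum object distance from the body boundary.
#' @param coarsen_factor fine-to-coarse factor for the targets, default 2.
#' @return a `dataset_config`.
#' @export
dataset_config <- function(cases_1obj = 3000, cases_2obj = 15000,
                           length_range_cm = c(6, 10), sigmas = c(0, 1),
                           background = 0.5, snr_db = 60, margin_cm = 0,
                           coarsen_factor = 2L) {
  structure(list(cases_1obj = as.integer(cases_1obj),
                 cases_2obj = as.integer(cases_2obj),
                 length_range_cm = length_range_cm, sigmas = sigmas,
                 background = background, snr_db = snr_db,
                 margin_cm = margin_cm,
                 coarsen_factor = as.integer(coarsen_factor)),
            class = "dataset_config")
}

#' Expected sample count of a dataset configuration
#'
#' `cases_1obj * 2 + cases_2obj * 4` (66,000 at paper scale).
#'
#' @param dconfig a `dataset_config`.
#' @return integer sample count.
#' @export
dataset_sample_count <- function(dconfig) {
  n1 <- length(enumerate_combos(1, dconfig$sigmas))
  n2 <- length(enumerate_combos(2, dconfig$sigmas))
  dconfig$cases_1obj * n1 + dconfig$cases_2obj * n2
}

#' Enumerate the dataset manifest without simulating
#'
#' Draws all geometric cases (cuboid placements) and expands them into the
#' per-sample manifest with every conductivity combination, but runs no
#' forward simulation. [generate_dataset()] consumes this to produce signals;
#' structural checks (sample counts, split bookkeeping) can use the manifest
#' alone.
#'
#' @param grid the fine simulation `voxel_grid`.
#' @param dconfig a `dataset_config`.
#' @param seed placement RNG seed.
#' @return a `dataset_manifest`: data frame with columns `sample_id`,
#'   `case_id`, `n_objects`, `combo_id`, `sigma1`, `sigma2`, plus the list of
#'   per-case perturbation geometries in `attr(, "cases")`.
#' @export
enumerate_manifest <- function(grid, dconfig, seed = 1) {
  set.seed(seed)
  cases <- list()
  rows <- list()
  case_id <- 0L
  sample_id <- 0L
  for (nobj in c(1L, 2L)) {
    ncase <- if (nobj == 1L) dconfig$cases_1obj else dconfig$cases_2obj
    combos <- enumerate_combos(nobj, dconfig$sigmas)
    for (ci in seq_len(ncase)) {
      case_id <- case_id + 1L
      placed <- place_perturbations(grid, nobj,
                                    length_range_cm = dconfig$length_range_cm,
                                    sigmas = rep(0, nobj),
                                    background = dconfig$background,
                                    margin_cm = dconfig$margin_cm)
      cases[[case_id]] <- placed$perturbations
      for (k in seq_along(combos)) {
        sample_id <- sample_id + 1L
        cmb <- combos[[k]]
        rows[[sample_id]] <- data.frame(
          sample_id = sample_id, case_id = case_id, n_objects = nobj,
          combo_id = k, sigma1 = cmb[1],
          sigma2 = if (nobj == 2L) cmb[2] else NA_real_)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  attr(manifest, "cases") <- cases
  attr(manifest, "seed") <- seed
  class(manifest) <- c("dataset_manifest", class(manifest))
  manifest
}

# realize one sample's fine conductivity grid from its manifest row
manifest_fine_grid <- function(grid, manifest, row, background = 0.5) {
  cases <- attr(manifest, "cases")
  perts <- cases[[manifest$case_id[row]]]
  sig <- array(background, dim = grid$shape)
  combo <- c(manifest$sigma1[row], manifest$sigma2[row])
  for (k in seq_along(perts)) {
    p <- perts[[k]]
    p$sigma <- combo[k]
    sig <- paint_cuboid(sig, grid, p)
  }
  conductivity_grid(grid, sig)
}

#' Generate a simulated MIT dataset
#'
#' Runs the full corpus recipe: cuboid perturbations are placed on the fine
#' (1 cm) grid; each conductivity combination is pushed through the forward
#' scan; measurement noise is injected independently into the perturbed and
#' background signals before the differential signal is formed; the target
#' is the fine grid coarsened to the reconstruction (2 cm) grid and
#' flattened in Fortran order. The fine/coarse split plus noise is what
#' avoids the inverse crime.
#'
#' @param caches a `scan_cache` on the fine grid.
#' @param dconfig a `dataset_config`.
#' @param params `physics_params`.
#' @param seed master seed; placement and noise use distinct derived streams.
#' @param manifest optionally a pre-enumerated `dataset_manifest` (its
#'   placement seed then governs geometry).
#' @param progress print a progress line every 500 samples.
#' @return a `mit_dataset`: `signals` (`N x (6 P)` matrix of differential
#'   signals), `targets` (`N x n_coarse` matrix, values in `[0, 1]`),
#'   `manifest`, `coarse_grid`, `snr_db`.
#' @export
generate_dataset <- function(caches, dconfig, params = physics_params(),
                             seed = 1, manifest = NULL, progress = FALSE) {
  grid <- caches$grid
  if (is.null(manifest))
    manifest <- enumerate_manifest(grid, dconfig, seed = derive_seed(seed, "placement"))
  n <- nrow(manifest)
  bg <- conductivity_grid(grid, dconfig$background)
  S_norm <- scan_body(bg, caches, params)
  p <- length(flatten_signal(S_norm))
  cgrid_coarse <- make_body_grid(grid$extent_cm,
                                 grid$voxel_cm * dconfig$coarsen_factor)
  signals <- matrix(NA_real_, n, p)
  targets <- matrix(NA_real_, n, cgrid_coarse$n)
  set.seed(derive_seed(seed, "noise"))
  last_case <- -1L
  for (s in seq_len(n)) {
    fine <- manifest_fine_grid(grid, manifest, s, dconfig$background)
    S_E <- scan_body(fine, caches, params)
    S_D <- differential_signal(S_E, S_norm, snr_db = dconfig$snr_db)
    signals[s, ] <- flatten_signal(S_D)
    targets[s, ] <- flatten_fortran(coarsen(fine, dconfig$coarsen_factor))
    if (progress && s %% 500 == 0)
      message(sprintf("  sample %d / %d", s, n))
    last_case <- manifest$case_id[s]
  }
  structure(list(signals = signals, targets = targets, manifest = manifest,
                 fine_grid = grid, coarse_grid = cgrid_coarse,
                 snr_db = dconfig$snr_db, seed = seed),
            class = "mit_dataset")
}

#' @export
print.mit_dataset <- function(x, ...) {
  cat(sprintf("<mit_dataset> %d samples: signals %d features, targets %d voxels (%g dB noise)\n",
              nrow(x$signals), ncol(x$signals), ncol(x$targets), x$snr_db))
  invisible(x)
}

#' Split a dataset into training / test / validation sets
#'
#' Split assignment is by geometric case, not by sample: all conductivity
#' combinations of one placement land in the same split, so no geometry leaks
#' between training and evaluation.
#'
#' @param manifest a `dataset_manifest`.
#' @param fractions named fractions `c(train=, test=, val=)` summing to 1;
#'   default the 65 / 25 / 10 split.
#' @param seed shuffling seed.
#' @return factor of length `nrow(manifest)` with levels
#'   `train`, `test`, `val`.
#' @export
split_dataset <- function(manifest, fractions = c(train = 0.65, test = 0.25,
                                                  val = 0.10), seed = 1) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("split fractions must sum to 1")
  stopifnot(all(c("train", "test", "val") %in% names(fractions)))
  cases <- unique(manifest$case_id)
  set.seed(seed)
  shuffled <- sample(cases)
  nc <- length(cases)
  n_train <- round(fractions[["train"]] * nc)
  n_test <- round(fractions[["test"]] * nc)
  lab <- rep("val", nc)
  lab[seq_len(n_train)] <- "train"
  if (n_test > 0) lab[n_train + seq_len(min(n_test, nc - n_train))] <- "test"
  case_split <- stats::setNames(lab, shuffled)
  factor(case_split[as.character(manifest$case_id)],
         levels = c("train", "test", "val"))
}

#' Fit a per-feature standardizer on training signals
#'
#' Per-feature mean and population standard deviation (divide-by-N) over the
#' training samples; each of the signal entries is standardized across
#' samples. Constant features get their standard deviation floored at
#' `eps` and are flagged.
#'
#' @param x `N x p` matrix of training signals.
#' @param eps floor for the standard deviation.
#' @return a `standardizer` with fields `m` and `s`.
#' @export
fit_standardizer <- function(x, eps = 1e-12) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("cannot fit a standardizer on an empty training set")
  m <- colMeans(x)
  s <- sqrt(colMeans(sweep(x, 2, m)^2))   # population formula
  flagged <- s < eps
  s[flagged] <- eps
  structure(list(m = m, s = s, n = nrow(x), flagged = flagged),
            class = "standardizer")
}

#' Apply (or invert) a fitted standardizer
#'
#' `z = (x - m) / s` per feature; identical transform for training,
#' validation, test and real inputs.
#'
#' @param std a `standardizer`.
#' @param x matrix (`N x p`) or vector of signals.
#' @param inverse undo the transform.
#' @return standardized matrix/vector of the same shape.
#' @export
apply_standardizer <- function(std, x, inverse = FALSE) {
  stopifnot(inherits(std, "standardizer"))
  vec <- is.null(dim(x))
  x <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != length(std$m))
    stop(sprintf("feature dimension %d does not match standardizer (%d)",
                 ncol(x), length(std$m)))
  out <- if (inverse) sweep(sweep(x, 2, std$s, "*"), 2, std$m, "+")
         else sweep(sweep(x, 2, std$m), 2, std$s, "/")
  if (vec) out[1, ] else out
}

# deterministic sub-seed derivation: one master seed fans out to named
# substreams so stages can be re-run independently
derive_seed <- function(master, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483647L)
}
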