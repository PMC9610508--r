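#' Residual network architecture specification
#'
#' The reconstruction network maps a standardized receiver signal matrix
#' (`n_receivers x P x 1`) to the flattened coarse conductivity vector. The
#' layout follows the reference design: a 5x5 convolution stem with ELU and
#' 2x2 max pooling compresses the highly correlated neighbouring positions;
#' residual blocks of three 3x5 convolutions (conv -> ELU -> batch norm)
#' alternate with bottleneck blocks whose first convolution and whose 1x1
#' skip convolution carry a 1x3 stride to shrink the position axis; a 2x2
#' average pool, two sigmoid dense layers and a hard-sigmoid output head
#' produce conductivities in `[0, 1]`.
#'
#' @param input_shape `c(n_receivers, positions)`; default `c(6, 206)`.
#' @param output_units coarse voxel count; default 4200.
#' @param stem_filters filters in the stem convolution (64 at full scale).
#' @param block_plan list of `list(type = "residual"|"bottleneck",
#'   filters = ...)` entries. A residual block must keep the incoming filter
#'   count (identity skip); a bottleneck may change it (projection skip).
#' @param dense_units width of the two dense layers (5172 at full scale).
#' @param kernel residual-block kernel, default `c(3, 5)`.
#' @param stem_kernel stem kernel, default `c(5, 5)`.
#' @param init `"paper"` draws all weights from N(0, `init_sd`);
#'   `"scaled"` uses fan-in-scaled (He) normal initialisation. Deep stacks
#'   with unit-variance init routinely diverge, so `"scaled"` is the
#'   practical fallback; its use is recorded in the model log.
#' @param init_sd standard deviation for `init = "paper"`, default 1.0.
#' @return an `arch_spec`.
#' @export
arch_spec <- function(input_shape = c(6, 206), output_units = 4200,
                      stem_filters = 64,
                      block_plan = list(
                        list(type = "residual", filters = 64),
                        list(type = "bottleneck", filters = 128),
                        list(type = "residual", filters = 128),
                        list(type = "bottleneck", filters = 256),
                        list(type = "residual", filters = 256)),
                      dense_units = 5172,
                      kernel = c(3, 5), stem_kernel = c(5, 5),
                      init = c("scaled", "paper"), init_sd = 1.0) {
  structure(list(input_shape = input_shape, output_units = output_units,
                 stem_filters = stem_filters, block_plan = block_plan,
                 dense_units = dense_units, kernel = kernel,
                 stem_kernel = stem_kernel, init = match.arg(init),
                 init_sd = init_sd),
            class = "arch_spec")
}

# conv -> ELU -> BN triple
conv_elu_bn <- function(H, W, Cin, Cout, kH, kW, sH = 1L, sW = 1L,
                        init, init_sd) {
  cv <- layer_conv(H, W, Cin, Cout, kH, kW, sH, sW, init, init_sd)
  list(cv, layer_act("elu"), layer_bn(Cout))
}

#' Build a reconstruction model from an architecture spec
#'
#' Instantiates all layers with shape checking (a shape-incompatible block
#' plan is rejected naming the offending block) and initialises the weights
#' from R's global RNG stream.
#'
#' @param spec an `arch_spec`.
#' @return an (untrained) `mit_model`.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "arch_spec"))
  H <- spec$input_shape[1]; W <- spec$input_shape[2]
  init <- spec$init; isd <- spec$init_sd
  kH <- spec$kernel[1]; kW <- spec$kernel[2]
  layers <- list()
  log <- character(0)
  if (init == "scaled")
    log <- c(log, "init: fan-in-scaled normal (fallback from unit-variance normal)")
  # stem: conv 5x5 -> ELU -> BN -> max pool 2x2
  layers <- c(layers, conv_elu_bn(H, W, 1L, spec$stem_filters,
                                  spec$stem_kernel[1], spec$stem_kernel[2],
                                  1L, 1L, init, isd))
  layers <- c(layers, list(layer_pool("maxpool", H, W)))
  g <- layers[[length(layers)]]$geom
  H <- g$oH; W <- g$oW
  C <- spec$stem_filters
  for (bi in seq_along(spec$block_plan)) {
    bp <- spec$block_plan[[bi]]
    F_ <- bp$filters
    if (bp$type == "residual") {
      if (F_ != C)
        stop(sprintf("block %d (residual): filters %d != incoming channels %d (identity skip impossible)",
                     bi, F_, C))
      main <- c(conv_elu_bn(H, W, C, F_, kH, kW, 1L, 1L, init, isd),
                conv_elu_bn(H, W, F_, F_, kH, kW, 1L, 1L, init, isd),
                conv_elu_bn(H, W, F_, F_, kH, kW, 1L, 1L, init, isd))
      layers <- c(layers, list(layer_block(main)))
    } else if (bp$type == "bottleneck") {
      # first conv strided 1x3; 1x1 stride-1x3 conv on the skip path
      c1 <- conv_elu_bn(H, W, C, F_, kH, kW, 1L, 3L, init, isd)
      oH <- c1[[1]]$geom$oH; oW <- c1[[1]]$geom$oW
      main <- c(c1,
                conv_elu_bn(oH, oW, F_, F_, kH, kW, 1L, 1L, init, isd),
                conv_elu_bn(oH, oW, F_, F_, kH, kW, 1L, 1L, init, isd))
      skip <- list(layer_conv(H, W, C, F_, 1L, 1L, 1L, 3L, init, isd))
      layers <- c(layers, list(layer_block(main, skip)))
      H <- oH; W <- oW
    } else stop(sprintf("block %d: unknown type '%s'", bi, bp$type))
    C <- F_
  }
  layers <- c(layers, list(layer_pool("avgpool", H, W)))
  g <- layers[[length(layers)]]$geom
  H <- g$oH; W <- g$oW
  n_flat <- H * W * C
  layers <- c(layers, list(layer_flatten(),
                           layer_dense(n_flat, spec$dense_units, init, isd),
                           layer_act("sigmoid"),
                           layer_dense(spec$dense_units, spec$dense_units, init, isd),
                           layer_act("sigmoid"),
                           layer_dense(spec$dense_units, spec$output_units, init, isd),
                           layer_act("hardsig")))
  structure(list(spec = spec, layers = layers, standardizer = NULL,
                 log = log, trained = FALSE),
            class = "mit_model")
}

#' @export
print.mit_model <- function(x, ...) {
  np <- sum(vapply(collect_params(x$layers), length, 0L))
  cat(sprintf("<mit_model> input %dx%d -> %d voxels, %d parameters%s\n",
              x$spec$input_shape[1], x$spec$input_shape[2],
              x$spec$output_units, np,
              if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

#' Reshape a flat signal vector into the network's 2D input
#'
#' Row r of the result is receiver r's trace; column p holds all six
#' receiver values at scan position p.
#'
#' @param flat numeric vector of length `n_receivers * P`.
#' @param n_receivers default 6.
#' @return `n_receivers x P` matrix.
#' @export
reshape_signal <- function(flat, n_receivers = 6) {
  if (length(flat) %% n_receivers != 0)
    stop(sprintf("signal length %d is not divisible by %d receivers",
                 length(flat), n_receivers))
  matrix(flat, nrow = n_receivers, byrow = TRUE)
}

# forward pass over the whole layer stack
# x: (batch, H*W) matrix of standardized signals (row-major spatial order,
# which equals the flat receiver-concatenated layout)
model_forward <- function(model, x, training = FALSE) {
  batch <- nrow(x)
  spec <- model$spec
  S <- spec$input_shape[1] * spec$input_shape[2]
  stopifnot(ncol(x) == S)
  a <- x
  dim(a) <- c(batch * S, 1L)
  meta <- list(batch = batch, H = spec$input_shape[1],
               W = spec$input_shape[2], C = 1L)
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    r <- lay_forward(model$layers[[i]], a, meta, training)
    a <- r$x; meta <- r$meta
    caches[[i]] <- r$cache
    if (!is.null(r$layer)) model$layers[[i]] <- r$layer
  }
  list(out = a, caches = caches, model = model)
}

# backward pass: returns per-layer grads (nested like the layers)
model_backward <- function(model, caches, dout) {
  grads <- vector("list", length(model$layers))
  dx <- dout
  for (i in rev(seq_along(model$layers))) {
    r <- lay_backward(model$layers[[i]], dx, caches[[i]])
    dx <- r$dx
    grads[i] <- list(r$grads)   # [[<-]] would drop NULL entries
  }
  grads
}

# elementwise Huber loss and gradient wrt predictions
huber_with_grad <- function(y, yhat, delta) {
  e <- yhat - y
  ae <- abs(e)
  quad <- which(ae <= delta)
  l <- delta * ae - 0.5 * delta^2
  l[quad] <- 0.5 * e[quad]^2
  g <- delta * sign(e)
  g[quad] <- e[quad]
  list(loss = mean(l), grad = g / length(e))
}

#' Training schedule for the two-phase Huber regime
#'
#' Phase 1 pretrains with a wide quadratic zone (delta = 1, batch 64);
#' phase 2 sharpens with delta = 0.05 and batch 32. NADAM with initial
#' learning rate 1e-3; the rate drops by `lr_factor` when the validation
#' correlation coefficient fails to improve for `lr_patience` epochs
#' (floored at `lr_floor`); training stops early when the validation loss
#' fails to improve for `es_patience` epochs. The best-validation-loss
#' weights are kept.
#'
#' @param epochs1,epochs2 epochs per phase (50 and 50 at full scale).
#' @param batch1,batch2 batch sizes per phase.
#' @param delta1,delta2 Huber thresholds per phase.
#' @param lr0 initial learning rate.
#' @param lr_factor,lr_patience,lr_floor plateau schedule on validation CC.
#' @param es_patience early-stopping patience on validation loss.
#' @return a `training_schedule`.
#' @export
training_schedule <- function(epochs1 = 50, epochs2 = 50,
                              batch1 = 64, batch2 = 32,
                              delta1 = 1.0, delta2 = 0.05,
                              lr0 = 1e-3, lr_factor = 0.1, lr_patience = 7,
                              lr_floor = 1e-5, es_patience = 15) {
  structure(list(phases = list(
    list(delta = delta1, batch = batch1, epochs = epochs1),
    list(delta = delta2, batch = batch2, epochs = epochs2)),
    lr0 = lr0, lr_factor = lr_factor, lr_patience = lr_patience,
    lr_floor = lr_floor, es_patience = es_patience),
    class = "training_schedule")
}

# mean per-sample Pearson CC (degenerate samples excluded)
mean_sample_cc <- function(targets, preds) {
  ccs <- vapply(seq_len(nrow(targets)), function(i) {
    as.numeric(pearson_cc(targets[i, ], preds[i, ]))
  }, 0)
  mean(ccs, na.rm = TRUE)
}

#' Train a reconstruction model with the two-phase Huber schedule
#'
#' @param model an untrained `mit_model` (its standardizer slot may already
#'   be set; otherwise pass `std`).
#' @param x_train,y_train standardized training signals (`N x p`) and
#'   targets (`N x n_out`).
#' @param x_val,y_val validation split, used for the learning-rate plateau
#'   (validation CC), early stopping and checkpointing (validation loss).
#' @param schedule a `training_schedule`.
#' @param std the `standardizer` fitted on the training signals (stored in
#'   the model for inference-time use).
#' @param verbose print one line per epoch.
#' @return the trained model, with `history` (one row per epoch: phase,
#'   epoch, lr, train_loss, val_loss, val_cc, events) attached.
#' @export
train_two_phase <- function(model, x_train, y_train, x_val, y_val,
                            schedule = training_schedule(), std = NULL,
                            verbose = FALSE) {
  stopifnot(inherits(model, "mit_model"))
  if (!is.null(std)) model$standardizer <- std
  n <- nrow(x_train)
  hist <- list()
  best <- list(loss = Inf, params = NULL)
  for (ph in seq_along(schedule$phases)) {
    phase <- schedule$phases[[ph]]
    lr <- schedule$lr0
    opt <- nadam_init(collect_params(model$layers))
    best_cc <- -Inf; cc_wait <- 0L
    best_vloss <- Inf; es_wait <- 0L
    for (ep in seq_len(phase$epochs)) {
      events <- character(0)
      perm <- sample.int(n)
      tr_loss <- 0; nb <- 0L
      for (start in seq(1, n, by = phase$batch)) {
        idx <- perm[start:min(start + phase$batch - 1, n)]
        if (length(idx) < 2) next   # batch norm needs > 1 sample
        fw <- model_forward(model, x_train[idx, , drop = FALSE], training = TRUE)
        model <- fw$model
        hw <- huber_with_grad(y_train[idx, , drop = FALSE], fw$out, phase$delta)
        if (!is.finite(hw$loss))
          stop(sprintf("training diverged (non-finite loss) in phase %d, epoch %d", ph, ep))
        grads <- model_backward(model, fw$caches, hw$grad)
        flat_p <- collect_params(model$layers)
        flat_g <- collect_grads(model$layers, grads)
        stepped <- nadam_step(flat_p, flat_g, opt, lr)
        opt <- stepped$state
        model$layers <- assign_params(model$layers, stepped$params)
        tr_loss <- tr_loss + hw$loss; nb <- nb + 1L
      }
      tr_loss <- tr_loss / max(nb, 1L)
      vp <- predict_batched(model, x_val)
      vloss <- huber_with_grad(y_val, vp, phase$delta)$loss
      vcc <- mean_sample_cc(y_val, vp)
      if (vloss < best_vloss - 1e-12) {
        best_vloss <- vloss; es_wait <- 0L
      } else es_wait <- es_wait + 1L
      if (vloss < best$loss) {
        best$loss <- vloss
        best$params <- collect_params(model$layers)
        best$bn <- bn_states(model$layers)
        events <- c(events, "checkpoint")
      }
      if (vcc > best_cc + 1e-12) {
        best_cc <- vcc; cc_wait <- 0L
      } else {
        cc_wait <- cc_wait + 1L
        if (cc_wait >= schedule$lr_patience && lr > schedule$lr_floor) {
          lr <- max(lr * schedule$lr_factor, schedule$lr_floor)
          cc_wait <- 0L
          events <- c(events, sprintf("lr->%g", lr))
        }
      }
      hist[[length(hist) + 1L]] <- data.frame(
        phase = ph, epoch = ep, lr = lr, train_loss = tr_loss,
        val_loss = vloss, val_cc = vcc,
        events = paste(events, collapse = ";"))
      if (verbose)
        message(sprintf("phase %d epoch %3d  lr %g  train %.5f  val %.5f  cc %.4f %s",
                        ph, ep, lr, tr_loss, vloss, vcc,
                        paste(events, collapse = " ")))
      if (es_wait >= schedule$es_patience) {
        hist[[length(hist)]]$events <- paste(c(events, "early-stop"), collapse = ";")
        break
      }
    }
  }
  if (!is.null(best$params)) {
    model$layers <- assign_params(model$layers, best$params)
    model$layers <- restore_bn_states(model$layers, best$bn)
  }
  model$trained <- TRUE
  model$history <- do.call(rbind, hist)
  model
}

# snapshot / restore batch-norm running statistics alongside weights
bn_states <- function(layers, prefix = "L") {
  out <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    tag <- sprintf("%s%d", prefix, i)
    if (l$type == "block") {
      out <- c(out, bn_states(l$main, paste0(tag, "m")))
      if (!is.null(l$skip)) out <- c(out, bn_states(l$skip, paste0(tag, "s")))
    } else if (l$type == "bn") out[[tag]] <- l$state
  }
  out
}

restore_bn_states <- function(layers, states, prefix = "L") {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    tag <- sprintf("%s%d", prefix, i)
    if (l$type == "block") {
      l$main <- restore_bn_states(l$main, states, paste0(tag, "m"))
      if (!is.null(l$skip)) l$skip <- restore_bn_states(l$skip, states, paste0(tag, "s"))
    } else if (l$type == "bn" && !is.null(states[[tag]])) l$state <- states[[tag]]
    layers[[i]] <- l
  }
  layers
}

# inference in manageable chunks (keeps activation memory bounded)
predict_batched <- function(model, x, batch = 256L) {
  n <- nrow(x)
  out <- NULL
  for (start in seq(1, n, by = batch)) {
    idx <- start:min(start + batch - 1, n)
    o <- model_forward(model, x[idx, , drop = FALSE], training = FALSE)$out
    if (is.null(out)) out <- matrix(0, n, ncol(o))
    out[idx, ] <- o
  }
  out
}

#' Reconstruct conductivity distributions from raw differential signals
#'
#' Standardizes the signals with the model's own training-time standardizer,
#' runs the network in inference mode, and unflattens each prediction to the
#' coarse 3D grid. A warning is issued if the inputs look unstandardized yet
#' no standardizer is attached.
#'
#' @param model a trained `mit_model`.
#' @param signals `N x p` matrix (or length-p vector) of raw differential
#'   signals; set `standardized = TRUE` if they are already z-scored.
#' @param coarse_grid optional `voxel_grid` for the 3D reshape.
#' @param standardized inputs are already standardized.
#' @return list with `vectors` (`N x n_out`, values in `[0, 1]`) and,
#'   when `coarse_grid` is given, `grids` (list of `conductivity_grid`).
#' @export
reconstruct <- function(model, signals, coarse_grid = NULL,
                        standardized = FALSE) {
  stopifnot(inherits(model, "mit_model"))
  x <- if (is.null(dim(signals))) matrix(signals, nrow = 1) else as.matrix(signals)
  if (!standardized) {
    if (is.null(model$standardizer)) {
      if (max(abs(x)) > 50)
        warning("inputs look raw-scale but the model has no standardizer attached")
    } else {
      x <- apply_standardizer(model$standardizer, x)
    }
  }
  vectors <- predict_batched(model, x)
  out <- list(vectors = vectors)
  if (!is.null(coarse_grid))
    out$grids <- lapply(seq_len(nrow(vectors)), function(i)
      unflatten_fortran(vectors[i, ], coarse_grid))
  out
}
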