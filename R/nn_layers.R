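# Minimal neural-network engine used by the reconstructor.
#
# Activations travel through the network as a matrix of shape
# (batch * S, C) where S = H * W spatial positions in row-major order
# (row index = b + (s - 1) * batch, matching R's column-major reshape of an
# array (batch, S, C)), together with a `meta` list (batch, H, W, C).
# Convolutions are evaluated as a sum over kernel offsets of gathered-slice
# GEMMs against precomputed index maps; all heavy lifting is BLAS.

# index maps for a "same"-padded convolution/pooling window
conv_indices <- function(H, W, kH, kW, sH = 1L, sW = 1L) {
  oH <- ceiling(H / sH); oW <- ceiling(W / sW)
  padH <- max((oH - 1L) * sH + kH - H, 0L)
  padW <- max((oW - 1L) * sW + kW - W, 0L)
  pt <- padH %/% 2L; pl <- padW %/% 2L
  Hp <- H + padH; Wp <- W + padW
  inner <- as.integer(outer(seq_len(W) + pl, (seq_len(H) + pt - 1L) * Wp, "+"))
  # inner is ordered x-fastest within y: linear s = (y-1)*W + x  -> row-major
  oy <- rep(seq_len(oH), each = oW); ox <- rep(seq_len(oW), times = oH)
  offsets <- vector("list", kH * kW)
  k <- 0L
  for (a in seq_len(kH)) for (b in seq_len(kW)) {
    k <- k + 1L
    ry <- (oy - 1L) * sH + a
    rx <- (ox - 1L) * sW + b
    offsets[[k]] <- as.integer((ry - 1L) * Wp + rx)
  }
  inner_mask <- logical(Hp * Wp); inner_mask[inner] <- TRUE
  # padded-position -> original spatial index (0 = padding), composed with
  # the kernel offset maps for the C++ im2col kernel
  inv <- integer(Hp * Wp); inv[inner] <- seq_len(H * W)
  list(H = H, W = W, oH = oH, oW = oW, Hp = Hp, Wp = Wp,
       kH = kH, kW = kW, inner = inner, offsets = offsets,
       src_all = inv[unlist(offsets)], inner_mask = inner_mask)
}

pad_activation <- function(x, meta, geom, fill = 0) {
  batch <- meta$batch; C <- meta$C
  S <- geom$H * geom$W
  Xp <- array(fill, dim = c(batch, geom$Hp * geom$Wp, C))
  dim(x) <- c(batch, S, C)
  Xp[, geom$inner, ] <- x
  Xp
}

gather_offset <- function(Xp, geom, k, batch, C) {
  Xk <- Xp[, geom$offsets[[k]], , drop = FALSE]
  dim(Xk) <- c(batch * geom$oH * geom$oW, C)
  Xk
}


## ---- layer constructors -------------------------------------------------

init_weights <- function(dims, fan_in, init, init_sd) {
  n <- prod(dims)
  sd <- if (init == "scaled") sqrt(2 / fan_in) else init_sd
  array(stats::rnorm(n, 0, sd), dim = dims)
}

layer_conv <- function(H, W, Cin, Cout, kH, kW, sH = 1L, sW = 1L,
                       init = "scaled", init_sd = 1.0) {
  geom <- conv_indices(H, W, kH, kW, sH, sW)
  k <- kH * kW
  list(type = "conv", geom = geom, Cin = Cin, Cout = Cout,
       params = list(W = init_weights(c(k, Cin, Cout), fan_in = k * Cin,
                                      init, init_sd),
                     b = numeric(Cout)))
}

layer_bn <- function(C, momentum = 0.99, eps = 1e-5) {
  list(type = "bn", C = C, momentum = momentum, eps = eps,
       params = list(gamma = rep(1, C), beta = rep(0, C)),
       state = list(mean = rep(0, C), var = rep(1, C)))
}

layer_act <- function(type) list(type = type, params = list())

layer_pool <- function(type, H, W, k = 2L, s = 2L) {
  list(type = type, geom = conv_indices(H, W, k, k, s, s), params = list())
}

layer_flatten <- function() list(type = "flatten", params = list())

layer_dense <- function(n_in, n_out, init = "scaled", init_sd = 1.0) {
  list(type = "dense",
       params = list(W = init_weights(c(n_in, n_out), fan_in = n_in,
                                      init, init_sd),
                     b = numeric(n_out)))
}

layer_block <- function(main, skip = NULL) {
  list(type = "block", main = main, skip = skip, params = list())
}

## ---- forward ------------------------------------------------------------

lay_forward <- function(layer, x, meta, training = FALSE) {
  switch(layer$type,
    conv = {
      # im2col patches (batch*oS, K*Cin) via the C++ kernel, one GEMM
      g <- layer$geom; batch <- meta$batch
      oS <- g$oH * g$oW
      K <- length(g$offsets)
      P <- .im2col(x, g$src_all, batch, oS, K, meta$C)
      W2 <- layer$params$W
      dim(W2) <- c(K * meta$C, layer$Cout)
      Z <- P %*% W2
      Z <- Z + rep(layer$params$b, each = nrow(Z))
      list(x = Z, meta = list(batch = batch, H = g$oH, W = g$oW, C = layer$Cout),
           cache = list(P = P, meta_in = meta))
    },
    bn = {
      R <- nrow(x)
      if (training) {
        mu <- colMeans(x)
        v <- colMeans(x^2) - mu^2
        v[v < 0] <- 0
        layer$state$mean <- layer$momentum * layer$state$mean + (1 - layer$momentum) * mu
        layer$state$var <- layer$momentum * layer$state$var + (1 - layer$momentum) * v
      } else {
        mu <- layer$state$mean; v <- layer$state$var
      }
      invstd <- 1 / sqrt(v + layer$eps)
      xhat <- x * rep(invstd, each = R) - rep(mu * invstd, each = R)
      g <- layer$params$gamma
      y <- xhat * rep(g, each = R) + rep(layer$params$beta, each = R)
      list(x = y, meta = meta,
           cache = list(xhat = xhat, invstd = invstd),
           layer = layer)
    },
    elu = {
      neg <- which(x <= 0)
      y <- x
      y[neg] <- expm1(x[neg])
      list(x = y, meta = meta, cache = list(y = y, neg = neg))
    },
    sigmoid = {
      y <- 1 / (1 + exp(-x))
      list(x = y, meta = meta, cache = list(y = y))
    },
    hardsig = {
      y <- pmin(pmax(0.2 * x + 0.5, 0), 1)
      list(x = y, meta = meta, cache = list(active = x > -2.5 & x < 2.5))
    },
    maxpool = {
      g <- layer$geom; batch <- meta$batch
      Xp <- pad_activation(x, meta, g, fill = -Inf)
      oS <- g$oH * g$oW
      best <- gather_offset(Xp, g, 1L, batch, meta$C)
      arg <- matrix(1L, nrow(best), ncol(best))
      for (k in seq_along(g$offsets)[-1]) {
        cand <- gather_offset(Xp, g, k, batch, meta$C)
        upd <- which(cand > best)   # which() drops NA: NaN inputs propagate
        best[upd] <- cand[upd]
        arg[upd] <- k
      }
      list(x = best, meta = list(batch = batch, H = g$oH, W = g$oW, C = meta$C),
           cache = list(arg = arg, meta_in = meta))
    },
    avgpool = {
      g <- layer$geom; batch <- meta$batch
      Xp <- pad_activation(x, meta, g, fill = 0)
      oS <- g$oH * g$oW
      cnt <- vapply(seq_len(oS), function(s)
        sum(vapply(g$offsets, function(o) g$inner_mask[o[s]], TRUE)), 0)
      Z <- matrix(0, batch * oS, meta$C)
      for (k in seq_along(g$offsets))
        Z <- Z + gather_offset(Xp, g, k, batch, meta$C)
      Z <- Z / rep(cnt, each = batch)
      list(x = Z, meta = list(batch = batch, H = g$oH, W = g$oW, C = meta$C),
           cache = list(cnt = cnt, meta_in = meta))
    },
    flatten = {
      batch <- meta$batch; S <- meta$H * meta$W
      dim(x) <- c(batch, S * meta$C)
      list(x = x, meta = list(batch = batch, F = S * meta$C),
           cache = list(meta_in = meta))
    },
    dense = {
      y <- x %*% layer$params$W
      y <- y + rep(layer$params$b, each = nrow(y))
      list(x = y, meta = list(batch = meta$batch, F = ncol(y)),
           cache = list(x_in = x))
    },
    block = {
      main_caches <- vector("list", length(layer$main))
      xm <- x; mm <- meta
      layers_out <- layer$main
      for (i in seq_along(layer$main)) {
        r <- lay_forward(layer$main[[i]], xm, mm, training)
        xm <- r$x; mm <- r$meta
        main_caches[[i]] <- r$cache
        if (!is.null(r$layer)) layers_out[[i]] <- r$layer
      }
      skip_caches <- NULL
      if (is.null(layer$skip)) {
        xs <- x
      } else {
        skip_caches <- vector("list", length(layer$skip))
        xs <- x; ms <- meta
        skips_out <- layer$skip
        for (i in seq_along(layer$skip)) {
          r <- lay_forward(layer$skip[[i]], xs, ms, training)
          xs <- r$x; ms <- r$meta
          skip_caches[[i]] <- r$cache
          if (!is.null(r$layer)) skips_out[[i]] <- r$layer
        }
        layer$skip <- skips_out
      }
      if (!all(dim(xm) == dim(xs)))
        stop("residual addition shape mismatch inside block")
      layer$main <- layers_out
      list(x = xm + xs, meta = mm,
           cache = list(main = main_caches, skip = skip_caches),
           layer = layer)
    },
    stop(sprintf("unknown layer type '%s'", layer$type)))
}

## ---- backward -----------------------------------------------------------

# returns list(dx, grads); grads mirrors layer$params (NULL when none)
lay_backward <- function(layer, dx, cache) {
  switch(layer$type,
    conv = {
      g <- layer$geom
      meta_in <- cache$meta_in
      batch <- meta_in$batch; Cin <- meta_in$C
      K <- length(g$offsets)
      db <- colSums(dx)
      dW <- crossprod(cache$P, dx)
      dim(dW) <- c(K, Cin, layer$Cout)
      W2 <- layer$params$W
      dim(W2) <- c(K * Cin, layer$Cout)
      dP <- dx %*% t(W2)
      dxi <- .col2im_add(dP, g$src_all, batch, g$H * g$W, Cin)
      list(dx = dxi, grads = list(W = dW, b = db))
    },
    bn = {
      R <- nrow(dx)
      xhat <- cache$xhat
      dgamma <- colSums(dx * xhat)
      dbeta <- colSums(dx)
      R <- nrow(dx)
      dxhat <- dx * rep(layer$params$gamma, each = R)
      t1 <- dxhat - rep(colMeans(dxhat), each = R)
      t2 <- xhat * rep(colMeans(dxhat * xhat), each = R)
      dxi <- (t1 - t2) * rep(cache$invstd, each = R)
      list(dx = dxi, grads = list(gamma = dgamma, beta = dbeta))
    },
    elu = {
      dxi <- dx
      neg <- cache$neg
      dxi[neg] <- dx[neg] * (cache$y[neg] + 1)
      list(dx = dxi, grads = NULL)
    },
    sigmoid = {
      y <- cache$y
      list(dx = dx * y * (1 - y), grads = NULL)
    },
    hardsig = {
      list(dx = dx * 0.2 * cache$active, grads = NULL)
    },
    maxpool = {
      g <- layer$geom
      meta_in <- cache$meta_in
      batch <- meta_in$batch; C <- meta_in$C
      oS <- g$oH * g$oW
      dXp <- array(0, dim = c(batch, g$Hp * g$Wp, C))
      for (k in seq_along(g$offsets)) {
        Ck <- dx * (cache$arg == k)
        dim(Ck) <- c(batch, oS, C)
        dXp[, g$offsets[[k]], ] <- dXp[, g$offsets[[k]], , drop = FALSE] + Ck
      }
      dxi <- dXp[, g$inner, , drop = FALSE]
      dim(dxi) <- c(batch * g$H * g$W, C)
      list(dx = dxi, grads = NULL)
    },
    avgpool = {
      g <- layer$geom
      meta_in <- cache$meta_in
      batch <- meta_in$batch; C <- meta_in$C
      oS <- g$oH * g$oW
      dZ <- dx / rep(cache$cnt, each = batch)
      dXp <- array(0, dim = c(batch, g$Hp * g$Wp, C))
      for (k in seq_along(g$offsets)) {
        Ck <- dZ
        dim(Ck) <- c(batch, oS, C)
        dXp[, g$offsets[[k]], ] <- dXp[, g$offsets[[k]], , drop = FALSE] + Ck
      }
      dxi <- dXp[, g$inner, , drop = FALSE]
      dim(dxi) <- c(batch * g$H * g$W, C)
      list(dx = dxi, grads = NULL)
    },
    flatten = {
      m <- cache$meta_in
      dim(dx) <- c(m$batch * m$H * m$W, m$C)
      list(dx = dx, grads = NULL)
    },
    dense = {
      dW <- crossprod(cache$x_in, dx)
      db <- colSums(dx)
      list(dx = dx %*% t(layer$params$W), grads = list(W = dW, b = db))
    },
    block = {
      dmain <- dx
      grads_main <- vector("list", length(layer$main))
      for (i in rev(seq_along(layer$main))) {
        r <- lay_backward(layer$main[[i]], dmain, cache$main[[i]])
        dmain <- r$dx
        grads_main[i] <- list(r$grads)
      }
      if (is.null(layer$skip)) {
        dskip <- dx
        grads_skip <- NULL
      } else {
        dskip <- dx
        grads_skip <- vector("list", length(layer$skip))
        for (i in rev(seq_along(layer$skip))) {
          r <- lay_backward(layer$skip[[i]], dskip, cache$skip[[i]])
          dskip <- r$dx
          grads_skip[i] <- list(r$grads)
        }
      }
      list(dx = dmain + dskip,
           grads = list(main = grads_main, skip = grads_skip))
    },
    stop(sprintf("unknown layer type '%s'", layer$type)))
}

## ---- parameter traversal (for the optimizer) ----------------------------

# flatten all trainable parameter arrays of a layer list into one named list
collect_params <- function(layers, prefix = "L") {
  out <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    tag <- sprintf("%s%d", prefix, i)
    if (l$type == "block") {
      out <- c(out, collect_params(l$main, paste0(tag, "m")))
      if (!is.null(l$skip)) out <- c(out, collect_params(l$skip, paste0(tag, "s")))
    } else if (length(l$params) > 0) {
      for (nm in names(l$params)) out[[paste(tag, nm, sep = ".")]] <- l$params[[nm]]
    }
  }
  out
}

collect_grads <- function(layers, grads, prefix = "L") {
  out <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]; gr <- grads[[i]]
    tag <- sprintf("%s%d", prefix, i)
    if (l$type == "block") {
      out <- c(out, collect_grads(l$main, gr$main, paste0(tag, "m")))
      if (!is.null(l$skip)) out <- c(out, collect_grads(l$skip, gr$skip, paste0(tag, "s")))
    } else if (length(l$params) > 0) {
      for (nm in names(l$params)) out[[paste(tag, nm, sep = ".")]] <- gr[[nm]]
    }
  }
  out
}

# write updated parameter values back into the nested layer structure
assign_params <- function(layers, flat, prefix = "L") {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    tag <- sprintf("%s%d", prefix, i)
    if (l$type == "block") {
      l$main <- assign_params(l$main, flat, paste0(tag, "m"))
      if (!is.null(l$skip)) l$skip <- assign_params(l$skip, flat, paste0(tag, "s"))
    } else if (length(l$params) > 0) {
      for (nm in names(l$params)) l$params[[nm]] <- flat[[paste(tag, nm, sep = ".")]]
    }
    layers[[i]] <- l
  }
  layers
}

## ---- NADAM optimizer -----------------------------------------------------

nadam_init <- function(flat_params) {
  list(m = lapply(flat_params, function(p) p * 0),
       v = lapply(flat_params, function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-7)
}

# Nesterov-accelerated adaptive moment estimation step
nadam_step <- function(flat_params, flat_grads, state, lr) {
  state$t <- state$t + 1L
  t <- state$t
  b1 <- state$beta1; b2 <- state$beta2
  for (nm in names(flat_params)) {
    g <- flat_grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- b1 * state$m[[nm]] / (1 - b1^(t + 1)) + (1 - b1) * g / (1 - b1^t)
    vhat <- state$v[[nm]] / (1 - b2^t)
    flat_params[[nm]] <- flat_params[[nm]] - lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(params = flat_params, state = state)
}
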