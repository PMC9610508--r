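test_that("signal reshaping stacks receivers row-major and round-trips", {
  flat <- as.vector(sapply(1:6, function(r) r * 10000 + 1:206))
  m <- reshape_signal(flat)
  expect_equal(dim(m), c(6L, 206L))
  for (r in c(1, 4, 6)) for (p in c(1, 100, 206))
    expect_equal(m[r, p], r * 10000 + p)
  expect_equal(flatten_signal(m), flat)
  expect_error(reshape_signal(1:100), "divisible")
})

test_that("stem shape arithmetic matches the reference layout", {
  # conv 5x5 same padding keeps (6, 206); max pool 2x2 halves to (3, 103)
  g1 <- mitnet:::conv_indices(6, 206, 5, 5, 1, 1)
  expect_equal(c(g1$oH, g1$oW), c(6, 206))
  g2 <- mitnet:::conv_indices(6, 206, 2, 2, 2, 2)
  expect_equal(c(g2$oH, g2$oW), c(3, 103))
  # bottleneck stride 1x3 compresses the position axis
  g3 <- mitnet:::conv_indices(3, 103, 3, 5, 1, 3)
  expect_equal(c(g3$oH, g3$oW), c(3, 35))
})

test_that("the full-scale architecture emits 4200 voxels in [0, 1]", {
  set.seed(1)
  model <- build_model(arch_spec(init = "scaled"))
  x <- matrix(rnorm(2 * 6 * 206), 2)
  out <- mitnet:::predict_batched(model, x)
  expect_equal(dim(out), c(2L, 4200L))
  expect_true(all(out >= 0 & out <= 1))
  out0 <- mitnet:::predict_batched(model, matrix(0, 1, 6 * 206))
  expect_true(all(is.finite(out0)))
})

test_that("shape-incompatible block plans are rejected naming the block", {
  spec <- tiny_arch()
  spec$block_plan <- list(list(type = "residual", filters = 99))
  expect_error(build_model(spec), "block 1")
})

test_that("model gradients agree with finite differences", {
  set.seed(3)
  model <- build_model(tiny_arch())
  n <- 4
  x <- matrix(rnorm(n * 72), n, 72)
  y <- matrix(runif(n * 8), n, 8)
  delta <- 0.5
  fw <- mitnet:::model_forward(model, x, training = TRUE)
  model2 <- fw$model
  hw <- mitnet:::huber_with_grad(y, fw$out, delta)
  grads <- mitnet:::model_backward(model2, fw$caches, hw$grad)
  fg <- mitnet:::collect_grads(model2$layers, grads)
  fp <- mitnet:::collect_params(model2$layers)
  loss_at <- function(flat) {
    m <- model
    m$layers <- mitnet:::assign_params(m$layers, flat)
    f <- mitnet:::model_forward(m, x, training = TRUE)
    mitnet:::huber_with_grad(y, f$out, delta)$loss
  }
  set.seed(11)
  eps <- 1e-5
  for (nm in sample(names(fp), 8)) {
    i <- sample(length(fp[[nm]]), 1)
    up <- fp; up[[nm]][i] <- up[[nm]][i] + eps
    dn <- fp; dn[[nm]][i] <- dn[[nm]][i] - eps
    num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
    ana <- fg[[nm]][i]
    expect_equal(ana, num, tolerance = 1e-4)
  }
})

test_that("inference is deterministic and batch-size independent", {
  set.seed(5)
  model <- build_model(tiny_arch())
  x <- matrix(rnorm(10 * 72), 10, 72)
  o1 <- mitnet:::predict_batched(model, x, batch = 10)
  o2 <- mitnet:::predict_batched(model, x, batch = 3)
  expect_identical(o1, mitnet:::predict_batched(model, x, batch = 10))
  expect_equal(o1, o2, tolerance = 1e-12)
})

test_that("training reduces the loss on a small synthetic problem", {
  set.seed(7)
  # learnable mapping: targets depend linearly on a few signal entries
  n <- 120
  x <- matrix(rnorm(n * 72), n, 72)
  y <- 0.5 + 0.4 * tanh(x[, 1:8]) / 2
  model <- build_model(tiny_arch())
  sch <- training_schedule(epochs1 = 4, epochs2 = 4, batch1 = 16, batch2 = 16,
                           es_patience = 50)
  model <- train_two_phase(model, x[1:100, ], y[1:100, ],
                           x[101:120, ], y[101:120, ], sch)
  h <- model$history
  p1 <- h[h$phase == 1, ]
  expect_lt(p1$train_loss[4], p1$train_loss[1])
  expect_true(model$trained)
  expect_true(all(c("phase", "epoch", "lr", "train_loss", "val_loss",
                    "val_cc", "events") %in% names(h)))
})

test_that("early stopping halts when validation loss stops improving", {
  set.seed(9)
  n <- 60
  x <- matrix(rnorm(n * 72), n, 72)
  y <- matrix(runif(n * 8), n, 8)   # unlearnable noise targets
  model <- build_model(tiny_arch())
  sch <- training_schedule(epochs1 = 30, epochs2 = 0, batch1 = 16,
                           es_patience = 3, lr0 = 0)  # frozen weights
  sch$phases[[2]]$epochs <- 0
  model <- train_two_phase(model, x[1:40, ], y[1:40, ], x[41:60, ], y[41:60, ], sch)
  h <- model$history
  # with lr = 0 the validation loss never improves after the first epoch:
  # training must stop after es_patience more epochs, well before 30
  expect_lte(max(h$epoch[h$phase == 1]), 1 + 3 + 1)
  expect_true(any(grepl("early-stop", h$events)))
})

test_that("the learning rate plateaus on stagnant validation CC and floors", {
  set.seed(13)
  n <- 60
  x <- matrix(rnorm(n * 72), n, 72)
  y <- matrix(runif(n * 8), n, 8)
  model <- build_model(tiny_arch())
  sch <- training_schedule(epochs1 = 12, epochs2 = 0, batch1 = 16,
                           lr_patience = 2, lr_floor = 1e-4, lr0 = 1e-2,
                           es_patience = 100)
  sch$phases[[2]]$epochs <- 0
  model <- train_two_phase(model, x[1:40, ], y[1:40, ], x[41:60, ], y[41:60, ], sch)
  h <- model$history
  expect_true(any(grepl("lr->", h$events)))
  expect_gte(min(h$lr), 1e-4)   # never below the floor
})

test_that("non-finite losses abort training naming phase and epoch", {
  set.seed(15)
  model <- build_model(tiny_arch())
  x <- matrix(rnorm(40 * 72), 40, 72)
  x[3, 5] <- NaN   # a corrupted sample poisons its batch's loss
  y <- matrix(runif(40 * 8), 40, 8)
  sch <- training_schedule(epochs1 = 2, epochs2 = 0, batch1 = 40)
  sch$phases[[2]]$epochs <- 0
  expect_error(
    suppressWarnings(train_two_phase(model, x[1:32, ], y[1:32, ],
                                     x[33:40, ], y[33:40, ], sch)),
    "phase 1")
})

test_that("reconstruct standardizes inputs and restores the 3D grid", {
  set.seed(17)
  model <- build_model(tiny_arch())
  std <- fit_standardizer(matrix(rnorm(20 * 72, sd = 100), 20, 72))
  model$standardizer <- std
  raw <- matrix(rnorm(3 * 72, sd = 100), 3, 72)
  g <- make_body_grid(c(4, 4, 4), 2)   # 2x2x2 = 8 coarse voxels
  out <- reconstruct(model, raw, coarse_grid = g)
  expect_equal(dim(out$vectors), c(3L, 8L))
  expect_true(all(out$vectors >= 0 & out$vectors <= 1))
  expect_equal(flatten_fortran(out$grids[[2]]), out$vectors[2, ])
  # a model without standardizer warns on raw-scale input
  model2 <- build_model(tiny_arch())
  expect_warning(reconstruct(model2, raw), "standardizer")
})

test_that("unit-variance initialisation is available and logged as fallback off", {
  set.seed(19)
  spec <- tiny_arch(); spec$init <- "paper"; spec$init_sd <- 1.0
  m <- build_model(spec)
  expect_length(m$log, 0)       # no fallback note for the reference init
  w <- m$layers[[1]]$params$W
  expect_gt(stats::sd(w), 0.8)  # unit-scale draws
  spec$init <- "scaled"
  m2 <- build_model(spec)
  expect_true(any(grepl("fallback", m2$log)))
})
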