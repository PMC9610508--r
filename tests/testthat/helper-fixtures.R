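# shared fixtures; heavyweight objects are built once per test run

.fixtures <- new.env(parent = emptyenv())

# desk-profile scan caches (a couple of seconds to build)
desk_caches <- function() {
  if (is.null(.fixtures$desk)) {
    cfg <- experiment_config("desk")
    .fixtures$desk <- list(config = cfg, caches = config_caches(cfg))
  }
  .fixtures$desk
}

# a tiny fully-connected conducting grid with random sources for oracle tests
random_system <- function(shape, seed = 1, sigma_range = c(0.2, 1)) {
  set.seed(seed)
  g <- make_body_grid(shape, 1)
  sig <- array(runif(g$n, sigma_range[1], sigma_range[2]), dim = g$shape)
  cg <- conductivity_grid(g, sig)
  edges <- mitnet:::grid_edges(g)
  A <- matrix(rnorm(length(edges$axis) * 3), ncol = 3)
  list(grid = g, cgrid = cg, edges = edges, A = A)
}

# small architecture for fast network tests
tiny_arch <- function(input_shape = c(6, 12), output_units = 8) {
  arch_spec(input_shape = input_shape, output_units = output_units,
            stem_filters = 4,
            block_plan = list(list(type = "residual", filters = 4),
                              list(type = "bottleneck", filters = 6)),
            dense_units = 12, init = "scaled")
}
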