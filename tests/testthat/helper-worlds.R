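# Small synthetic worlds shared across tests. All are deterministic given
# their seeds; sizes are kept small so the whole suite runs in minutes.

small_config <- function(seed = 42, ...) {
  landscape_config(nrow = 40, ncol = 40, cell_km = 10, n_climate = 3,
                   n_veg = 1, autocorr_km = 40, seed = seed, ...)
}

thermal_species <- function(id = "sp1", optimum = 2, breadth = 0.8) {
  species_spec(id, list(bio1 = list(type = "gaussian", optimum = optimum,
                                    breadth = breadth)))
}

# A fitted model plus its maps, for tests that need a realistic object.
fitted_toy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- small_config()
      cur <- generate_env_stack(cfg, "current")
      fut <- generate_env_stack(cfg, "future")
      sp <- thermal_species()
      occ <- sample_occurrences(sp, cur, bias = sampling_bias(cur),
                                n = 200, seed = 1)
      occ <- thin_to_grid(occ, 10, seed = 2)
      model <- fit_species_model(occ, cur, background_size = 800, seed = 3,
                                 max_iter = 200)
      cache <<- list(cfg = cfg, cur = cur, fut = fut, sp = sp, occ = occ,
                     model = model,
                     map_cur = project(model, cur),
                     map_fut = project(model, fut))
    }
    cache
  }
})

# Random binary ranges on a shared grid.
random_range <- function(nrow = 20, ncol = 20, p = 0.4, cell_km = 10,
                         seed = 1) {
  withr::with_seed(seed, {
    binary_range(matrix(runif(nrow * ncol) < p, nrow, ncol), cell_km)
  })
}

range_from <- function(cells, cell_km = 10) {
  binary_range(cells, cell_km)
}
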