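# Lazily computed shared fixtures (built once per test run).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small noiseless membrane population with segmentation and network
membrane_scene <- function() {
  fixture("membrane_scene", function() {
    cfg <- population_config(n_cells = 12, image_height = 256,
                             image_width = 256, poisson_noise = FALSE,
                             seed = 3)
    sample <- generate_population(cfg)
    seg <- segment_nuclei(preprocess(sample$nuclei_channel))
    net <- build_network(seg)
    list(cfg = cfg, sample = sample, seg = seg, net = net)
  })
}

# warped Poisson stacks from the membrane template, with their fits
warped_fits <- function(seeds = 1:5) {
  lapply(seeds, function(s)
    fixture(paste0("warped_fit_", s), function() {
      sim <- simulate_warped_stack(membrane_template, M = 30, N = 101,
                                   noise = "poisson", seed = s)
      fit <- compensate(sim$Y, noise = "poisson", symmetric = TRUE)
      list(sim = sim, fit = fit, map = compensated_map(fit))
    }))
}
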