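# Shared fixtures: small phantoms and helper oracles used across files.

small_spec <- function(noise_sd = 2, seed = 42L, radii = c(6, 4, 2.5)) {
  phantom_spec(grid_shape = c(48L, 48L, 16L), region_radii = radii,
               noise_sd = noise_sd, seed = seed)
}

# independent geometric oracle for tumor-bearing voxels of a phantom spec
analytic_tumor_voxels <- function(sp) {
  g <- expand.grid(i = seq_len(sp$grid_shape[1]),
                   j = seq_len(sp$grid_shape[2]),
                   k = seq_len(sp$grid_shape[3]))
  semi <- sp$brain_radius_frac * sp$grid_shape
  ctr <- (sp$grid_shape + 1) / 2
  brain <- ((g$i - ctr[1]) / semi[1])^2 + ((g$j - ctr[2]) / semi[2])^2 +
    ((g$k - ctr[3]) / semi[3])^2 <= 1
  d2 <- (g$i - sp$tumor_center[1])^2 + (g$j - sp$tumor_center[2])^2 +
    (g$k - sp$tumor_center[3])^2
  g[brain & d2 <= sp$region_radii[1]^2, ]
}

# independent voxel-count oracle: enumerate grid points inside a sphere
sphere_count <- function(shape, center, radius) {
  g <- expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                   k = seq_len(shape[3]))
  sum((g$i - center[1])^2 + (g$j - center[2])^2 + (g$k - center[3])^2 <=
        radius^2)
}

tiny_net <- function(input_size = 32L, width = 0.05, seed = 7L,
                     attention = TRUE) {
  build_segmenter(network_config(input_size = input_size,
                                 width_factor = width,
                                 attention_enabled = attention),
                  seed = seed)
}

random_bipolar <- function(H, W, seed) {
  set.seed(seed)
  matrix(sample(c(-1L, 1L), H * W, replace = TRUE), H, W)
}
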