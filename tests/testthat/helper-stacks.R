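# Shared fixtures, all built in code.

table2_stack <- function(d2 = 2.0, d1 = 0.03, mu_a = 0.024, mu_s = 28.4) {
  preset_stack("table2", flesh_thickness = d2, skin_thickness = d1,
               flesh_mu_a = mu_a, flesh_mu_s = mu_s)
}

# single matched slab (no refractive mismatch anywhere)
matched_slab <- function(mu_a, mu_s, g = 0, d = 1, name = NULL) {
  fruit_stack(optical_layer(1, mu_a, mu_s, g, d, name = name),
              n_above = 1, n_below = 1)
}

flesh_only_stack <- function(d = 1.5) {
  fruit_stack(optical_layer(1.342, 0.024, 28.4, 0.61, d, name = "flesh"),
              n_above = 1, n_below = 1.46)
}

small_config <- function(n = 2e4, seed = 1, ...) {
  sim_config(n_photons = n, seed = seed, ...)
}

# Build an mc_result from hand-made accumulators (for deterministic checks
# of the normalization arithmetic). `raw` entries override a zero template.
fake_result <- function(raw = list(), nr = 10, na = 6, nz = 4,
                        n_photons = 100, dr = 0.1, dz = 0.1,
                        stack = flesh_only_stack()) {
  cfg <- sim_config(n_photons = n_photons, dr = dr, dz = dz,
                    nr = nr, nz = nz, na = na)
  nl <- length(stack$layers)
  template <- list(
    rsp = 0,
    refl_r_alpha = matrix(0, nr, na), absorb_r_z = matrix(0, nr, nz),
    below_r = numeric(nr),
    eff_weight_r = numeric(nr), total_weight_r = numeric(nr),
    eff_count_r = numeric(nr), total_count_r = numeric(nr),
    flesh_path_r = numeric(nr), total_path_r = numeric(nr),
    a_layer = numeric(nl), rd_total = 0, t_below = 0,
    lost_roulette = 0, refl_overflow = 0,
    rd_sum = 0, rd_sum2 = 0, below_sum = 0, below_sum2 = 0,
    a_sum = numeric(nl), a_sum2 = numeric(nl))
  raw <- utils::modifyList(template, raw)
  fruitmc:::new_mc_result(raw, stack, cfg, nz = nz,
                          flesh_layer = fruitmc:::flesh_index(stack))
}
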