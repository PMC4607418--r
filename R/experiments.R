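#' Built-in peach optical-property presets
#'
#' The measured 808 nm optical properties of a peach: air above
#' (n = 1.00), skin (n = 1.337, mu_a = 0.075 cm^-1, mu_s = 102 cm^-1,
#' g = 0.65, d = 0.03 cm), flesh (n = 1.342, mu_a = 0.024 cm^-1,
#' mu_s = 28.4 cm^-1, g = 0.61, d = 2.34 cm) over a stone core represented
#' by its refractive index n = 1.46. `"table2_no_core"` is identical but
#' with air (n = 1.00) below the flesh, for isolating the core's effect.
#'
#' @param name `"table2"` or `"table2_no_core"`.
#' @param flesh_thickness Flesh layer thickness in cm (default the measured
#'   2.34 cm; sweeps override it).
#' @param skin_thickness Skin layer thickness in cm (default 0.03).
#' @param flesh_mu_a,flesh_mu_s Optional overrides of the flesh absorption
#'   and scattering coefficients (cm^-1).
#' @return A [fruit_stack()].
#' @examples
#' preset_stack("table2", flesh_thickness = 2)
#' @export
preset_stack <- function(name = c("table2", "table2_no_core"),
                         flesh_thickness = 2.34, skin_thickness = 0.03,
                         flesh_mu_a = 0.024, flesh_mu_s = 28.4) {
  name <- match.arg(name)
  fruit_stack(
    optical_layer(1.337, 0.075, 102, 0.65, skin_thickness, name = "skin"),
    optical_layer(1.342, flesh_mu_a, flesh_mu_s, 0.61, flesh_thickness,
                  name = "flesh"),
    n_above = 1.00,
    n_below = if (name == "table2") 1.46 else 1.00)
}

# one totals row for a sweep point; seeds are derived per run so sweep
# points are statistically independent
run_totals_row <- function(stack, n_photons, seed, ...) {
  res <- run_simulation(stack, sim_config(n_photons = n_photons, seed = seed))
  tibble(
    ...,
    Rd_total = res$rd_total, Rd_se = res$rd_se,
    A_skin = res$a_by_layer[1], A_skin_se = res$a_se[1],
    A_flesh = res$a_by_layer[2], A_flesh_se = res$a_se[2],
    T_core = res$t_below, T_core_se = res$t_below_se,
    seed = seed)
}

#' Effect of the stone core on light transport
#'
#' Sweeps the flesh thickness with and without the refractive core below
#' (n_below 1.46 vs 1.00). With a core present, part of the light reaching
#' the distal flesh boundary refracts into the stone and is lost, lowering
#' both the total diffuse reflectance and the flesh-absorbed fraction;
#' the gap narrows as the flesh thickens and less light reaches the
#' boundary.
#'
#' @param flesh_thickness Flesh thicknesses (cm) to sweep.
#' @param n_photons Photons per sweep point.
#' @param seed Base seed; each run uses `seed + run index`.
#' @return A tibble with `core`, `d2_cm`, totals and their standard errors.
#' @export
scenario_core_effect <- function(flesh_thickness = c(1.5, 2.0, 2.5, 3.0),
                                 n_photons = 1e6, seed = 1) {
  stopifnot(all(flesh_thickness > 0))
  grid <- expand.grid(core = c(TRUE, FALSE), d2 = sort(flesh_thickness))
  purrr::map2_dfr(grid$core, grid$d2, function(core, d2) {
    i <- which(grid$core == core & grid$d2 == d2)
    st <- preset_stack(if (core) "table2" else "table2_no_core",
                       flesh_thickness = d2)
    run_totals_row(st, n_photons, seed + i, core = core, d2_cm = d2)
  })
}

#' Effect of the skin thickness
#'
#' Sweeps the skin thickness at fixed flesh thickness (1.5 cm). The highly
#' scattering skin back-scatters more light near the incident point
#' (raising near-axis reflectance) while shielding the flesh (lowering
#' mid-range reflectance and the detection efficiency close to the
#' source).
#'
#' @param skin_thickness Skin thicknesses (cm) to sweep.
#' @param flesh_thickness Fixed flesh thickness (cm).
#' @inheritParams scenario_core_effect
#' @return A list with `totals` (one row per thickness) and `radial`
#'   (per-thickness [radial_profile()] rows with a `d1_cm` column,
#'   including `Peff_percent` and `Sflesh`).
#' @export
scenario_skin_effect <- function(skin_thickness = c(0.01, 0.03, 0.05),
                                 flesh_thickness = 1.5,
                                 n_photons = 1e6, seed = 1) {
  stopifnot(all(skin_thickness > 0))
  runs <- purrr::imap(sort(skin_thickness), function(d1, i) {
    st <- preset_stack("table2", flesh_thickness = flesh_thickness,
                       skin_thickness = d1)
    res <- run_simulation(st, sim_config(n_photons = n_photons,
                                         seed = seed + i))
    list(d1 = d1, res = res)
  })
  totals <- purrr::map_dfr(runs, function(x) {
    g <- glance(x$res)
    tibble(d1_cm = x$d1, Rd_total = g$rd_total, A_skin = g$a_skin,
           A_flesh = g$a_flesh, T_core = g$t_below, seed = g$seed)
  })
  radial <- purrr::map_dfr(runs, function(x)
    mutate(radial_profile(x$res), d1_cm = x$d1))
  list(totals = totals, radial = radial)
}

#' Effect of the flesh thickness
#'
#' Sweeps the flesh thickness over the range of real stone fruit. Total
#' reflectance and flesh absorption rise mildly with thickness while the
#' core-absorbed fraction falls; spatial profiles stop changing once the
#' flesh is thicker than ~1.5 cm.
#'
#' @inheritParams scenario_core_effect
#' @return A list with `totals` and `radial` (profiles with a `d2_cm`
#'   column).
#' @export
scenario_flesh_effect <- function(flesh_thickness = c(0.5, 1.0, 1.5, 2.0, 3.0),
                                  n_photons = 1e6, seed = 1) {
  stopifnot(all(flesh_thickness > 0))
  runs <- purrr::imap(sort(flesh_thickness), function(d2, i) {
    st <- preset_stack("table2", flesh_thickness = d2)
    res <- run_simulation(st, sim_config(n_photons = n_photons,
                                         seed = seed + i))
    list(d2 = d2, res = res)
  })
  totals <- purrr::map_dfr(runs, function(x)
    run_totals_row_from(x$res, d2_cm = x$d2))
  radial <- purrr::map_dfr(runs, function(x)
    mutate(radial_profile(x$res), d2_cm = x$d2))
  list(totals = totals, radial = radial)
}

run_totals_row_from <- function(res, ...) {
  tibble(
    ...,
    Rd_total = res$rd_total, Rd_se = res$rd_se,
    A_skin = res$a_by_layer[1], A_skin_se = res$a_se[1],
    A_flesh = res$a_by_layer[2], A_flesh_se = res$a_se[2],
    T_core = res$t_below, T_core_se = res$t_below_se,
    seed = res$config$seed %||% NA_integer_)
}

#' Flesh optical-property grid
#'
#' Runs the five flesh (mu_a, mu_s) combinations spanning a +/-20% range
#' around the measured means (0.024, 28.4 cm^-1) — the mean pair plus the
#' four corner pairs — at fixed skin 0.03 cm and flesh 2.0 cm, and reports
#' the energy budget of each.
#'
#' @inheritParams scenario_core_effect
#' @return A tibble with `mu_a`, `mu_s`, totals and standard errors.
#' @export
scenario_optics_grid <- function(n_photons = 1e6, seed = 1) {
  pairs <- optics_grid_pairs()
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    st <- preset_stack("table2", flesh_thickness = 2.0,
                       flesh_mu_a = pairs$mu_a[i], flesh_mu_s = pairs$mu_s[i])
    run_totals_row(st, n_photons, seed + i,
                   mu_a = pairs$mu_a[i], mu_s = pairs$mu_s[i])
  })
}

optics_grid_pairs <- function() {
  tibble(
    mu_a = c(0.024, 0.029, 0.029, 0.019, 0.019),
    mu_s = c(28.4, 34.1, 22.7, 34.1, 22.7))
}

#' Angularly resolved reflectance for the finite beam
#'
#' Runs the baseline stack, convolves each exit-angle slice of the angular
#' reflectance with the Gaussian beam (convolution acts radially and is
#' linear, so slices convolve independently), and returns the beam
#' response per unit perpendicular area per steradian. Coarse 10-degree
#' bins keep per-bin Monte Carlo noise low.
#'
#' @inheritParams scenario_core_effect
#' @param beam The incident [gaussian_beam()].
#' @param na Number of exit-angle bins over 0-90 degrees.
#' @param flesh_thickness Flesh thickness (cm) of the baseline stack.
#' @return A tibble with `r_cm`, `alpha_deg`, `impulse_per_cm2_per_sr` and
#'   the convolved `response_J_per_cm2_per_sr`.
#' @export
scenario_angular <- function(n_photons = 1e6, seed = 1,
                             beam = gaussian_beam(0.5, 0.05), na = 9,
                             flesh_thickness = 2.34) {
  st <- preset_stack("table2", flesh_thickness = flesh_thickness)
  res <- run_simulation(st, sim_config(n_photons = n_photons, seed = seed,
                                       na = na))
  ang <- angular_profile(res)
  purrr::map_dfr(unique(ang$alpha_deg), function(a) {
    slice <- filter(ang, .data$alpha_deg == a)
    conv <- convolve_beam(
      tibble(r_cm = slice$r_cm, Rd_per_cm2 = slice$Rd_per_cm2_per_sr),
      beam)
    tibble(r_cm = slice$r_cm, alpha_deg = a,
           impulse_per_cm2_per_sr = slice$Rd_per_cm2_per_sr,
           response_J_per_cm2_per_sr = conv$response_J_per_cm2)
  })
}

#' Normalize a radial profile at a reference radius
#'
#' Divides a profile by its value at the grid point nearest `r_ref` (the
#' convention for comparing simulated and measured reflectance profiles,
#' which are only known up to a collection constant).
#'
#' @param profile A tibble with `r_cm` and the column named by `value`.
#' @param r_ref Reference radius in cm; must fall within half a grid step
#'   of a grid point with a positive, finite value.
#' @param value Name of the profile column.
#' @return The profile tibble with `value` replaced by its normalized
#'   version (exactly 1 at the reference point).
#' @export
normalize_profile <- function(profile, r_ref = 0.3, value = "Rd_per_cm2") {
  if (!all(c("r_cm", value) %in% names(profile)))
    abort(sprintf("`profile` needs columns `r_cm` and `%s`", value))
  i <- which.min(abs(profile$r_cm - r_ref))
  step <- if (nrow(profile) > 1) min(diff(sort(unique(profile$r_cm)))) else Inf
  if (abs(profile$r_cm[i] - r_ref) > step / 2 + 1e-12)
    abort("`r_ref` is not on the profile grid")
  ref <- profile[[value]][i]
  if (!is.finite(ref) || ref <= 0)
    abort("profile value at `r_ref` must be positive and finite")
  profile[[value]] <- profile[[value]] / ref
  profile
}

#' Read a simulation configuration file
#'
#' JSON or YAML (by extension) with blocks `stack` (`n_above`, `n_below`,
#' `layers`: list of `n`/`mua`/`mus`/`g`/`d`/optional `name`), `sim`
#' (`photons`, `wth`, `m`, `dr`, `dz`, `nr`, `nz`, `na`, `seed`; all
#' optional) and `beam` (`profile`, `energy_J`, `radius_cm`). See
#' `system.file("extdata", "table2.json", package = "fruitmc")`.
#'
#' @param path File path.
#' @return A list with `stack` ([fruit_stack()]), `config` ([sim_config()])
#'   and `beam`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- if (grepl("\\.(ya?ml)$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(cfg$stack) || is.null(cfg$stack$layers))
    abort("config must define `stack.layers`")
  layers <- lapply(cfg$stack$layers, function(l)
    optical_layer(l$n, l$mua, l$mus, l$g, l$d, name = l$name %||% NULL))
  stack <- fruit_stack(layers,
                       n_above = cfg$stack$n_above %||% 1.00,
                       n_below = cfg$stack$n_below %||% 1.00)
  sim <- cfg$sim %||% list()
  config <- sim_config(
    n_photons = sim$photons %||% 1e6,
    w_th = sim$wth %||% 1e-4,
    roulette_m = sim$m %||% 10,
    dr = sim$dr %||% 0.01, dz = sim$dz %||% 0.01,
    nr = sim$nr %||% 400, nz = sim$nz %||% NULL, na = sim$na %||% 90,
    seed = sim$seed %||% NULL)
  bm <- cfg$beam %||% list(profile = "pencil")
  beam <- if ((bm$profile %||% "pencil") == "gaussian")
    gaussian_beam(bm$energy_J %||% 0.5, bm$radius_cm %||% 0.05)
  else pencil_beam(bm$energy_J %||% 1)
  list(stack = stack, config = config, beam = beam)
}
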