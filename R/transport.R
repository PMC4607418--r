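#' Simulation configuration
#'
#' Controls for the Monte Carlo kernel: photon budget, the Russian-roulette
#' variance-reduction settings, scoring-grid resolutions and the RNG seed.
#'
#' @param n_photons Number of photons to launch, >= 1.
#' @param w_th Roulette weight threshold in (0, 1). A photon whose weight
#'   drops below `w_th` after an absorption deposit enters the roulette.
#' @param roulette_m Roulette survival factor (> 1): the photon survives
#'   with probability `1/roulette_m`, its weight multiplied by
#'   `roulette_m`, so the expected weight is unchanged (unbiased).
#' @param dr,dz Radial and depth grid resolution in cm.
#' @param nr,nz Radial and depth bin counts. `nz = NULL` (default) takes
#'   `ceiling(total thickness / dz)`, capped at 2000 bins. Escapes beyond
#'   the last radial bin collapse into it (and are flagged in the result).
#' @param na Number of angular bins over \[0, 90\] degrees of exit angle.
#' @param seed Optional integer seed, applied with [set.seed()] before the
#'   run; identical seed and configuration give bit-identical results.
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(n_photons = 1e5, seed = 1)
#' @export
sim_config <- function(n_photons = 1e6, w_th = 1e-4, roulette_m = 10,
                       dr = 0.01, dz = 0.01, nr = 400, nz = NULL, na = 90,
                       seed = NULL) {
  if (n_photons < 1) abort("`n_photons` must be >= 1")
  if (w_th <= 0 || w_th >= 1) abort("`w_th` must lie in (0, 1)")
  if (roulette_m <= 1) abort("`roulette_m` must be > 1")
  if (dr <= 0 || dz <= 0) abort("`dr` and `dz` must be > 0")
  if (nr < 1 || na < 1 || (!is.null(nz) && nz < 1))
    abort("grid bin counts must be >= 1")
  structure(
    list(n_photons = as.integer(n_photons), w_th = w_th,
         roulette_m = roulette_m, dr = dr, dz = dz, nr = as.integer(nr),
         nz = if (is.null(nz)) NULL else as.integer(nz), na = as.integer(na),
         seed = seed),
    class = "sim_config")
}

#' Sample a free-path step length
#'
#' Step lengths between interactions are exponentially distributed:
#' `s = -log(xi) / (mu_a + mu_s)` with `xi` uniform on (0, 1), giving mean
#' free path `1 / mu_t`.
#'
#' @inheritParams optical_layer
#' @param xi Uniform deviate(s) in (0, 1); drawn from the session RNG when
#'   omitted.
#' @return Step length(s) in cm.
#' @examples
#' sample_step(0.024, 28.4, xi = exp(-1))  # one mean free path
#' @export
sample_step <- function(mu_a, mu_s, xi = runif(1)) {
  mu_t <- mu_a + mu_s
  if (mu_t <= 0) abort("`mu_a + mu_s` must be > 0 to sample a step")
  if (any(xi <= 0) || any(xi > 1)) abort("`xi` must lie in (0, 1]")
  -log(xi) / mu_t
}

#' Henyey-Greenstein deflection cosine
#'
#' Inverse-CDF sample of the scattering deflection cosine under the
#' Henyey-Greenstein phase function with anisotropy `g`; for `g = 0` the
#' cosine is uniform (`2 * xi - 1`). The first moment of the distribution
#' equals `g`.
#'
#' @param g Anisotropy factor in \[-1, 1\].
#' @param xi Uniform deviate(s) in (0, 1); drawn from the session RNG when
#'   omitted.
#' @return Deflection cosine(s) in \[-1, 1\].
#' @examples
#' mean(hg_cosine(0.61, runif(1e4)))  # ~0.61
#' @export
hg_cosine <- function(g, xi = runif(1)) {
  if (abs(g) > 1) abort("`g` must lie in [-1, 1]")
  if (any(xi < 0) || any(xi > 1)) abort("`xi` must lie in [0, 1]")
  vapply(xi, function(x) .cpp_hg_cosine(g, x), numeric(1))
}

#' Rotate a direction by a scattering deflection
#'
#' Standard spherical direction update: deflect the unit vector `dir` by
#' the angle whose cosine is `cos_theta`, at azimuth `psi` about the
#' incoming direction. A dedicated branch handles near-vertical directions
#' (`|uz| > 1 - 1e-5`) where the general formula loses precision.
#'
#' @param dir Unit 3-vector (ux, uy, uz).
#' @param cos_theta Deflection cosine in \[-1, 1\].
#' @param psi Azimuthal angle in radians.
#' @return The rotated unit 3-vector.
#' @examples
#' spin_direction(c(0, 0, 1), cos(0.3), 1.2)
#' @export
spin_direction <- function(dir, cos_theta, psi) {
  stopifnot(length(dir) == 3)
  if (abs(sum(dir^2) - 1) > 1e-6) abort("`dir` must be a unit vector")
  if (abs(cos_theta) > 1) abort("`cos_theta` must lie in [-1, 1]")
  st <- sqrt(max(0, 1 - cos_theta^2))
  cp <- cos(psi); sp <- sin(psi)
  ux <- dir[1]; uy <- dir[2]; uz <- dir[3]
  if (abs(uz) > 1 - 1e-5) {
    out <- c(st * cp, st * sp, sign(uz) * cos_theta)
  } else {
    tmp <- sqrt(1 - uz^2)
    out <- c(st * (ux * uz * cp - uy * sp) / tmp + ux * cos_theta,
             st * (uy * uz * cp + ux * sp) / tmp + uy * cos_theta,
             -st * cp * tmp + uz * cos_theta)
  }
  out / sqrt(sum(out^2))
}

#' Launch a photon into the stack
#'
#' The impulse-response source: a photon at the origin heading straight
#' down, its initial unit weight decremented by the specular reflectance of
#' the surface. Finite beams are handled afterwards by [convolve_beam()].
#'
#' @param stack A [fruit_stack()].
#' @return A list with `position`, `direction`, `weight`, `layer_index`
#'   (1-based), `path_by_layer` and `interacted_in_flesh`.
#' @examples
#' launch_photon(preset_stack("table2"))$weight  # 1 - R_sp
#' @export
launch_photon <- function(stack) {
  stopifnot(inherits(stack, "fruit_stack"))
  rsp <- specular_reflectance(stack$n_above, stack$layers[[1]]$n)
  list(position = c(0, 0, 0), direction = c(0, 0, 1), weight = 1 - rsp,
       layer_index = 1L,
       path_by_layer = numeric(length(stack$layers)),
       interacted_in_flesh = FALSE)
}

#' Distance to the current layer's boundary
#'
#' Geometric distance along the flight direction from depth `z` to the
#' upper or lower plane of the current layer; `NA` for horizontal flight
#' (`uz = 0`), which meets no boundary.
#'
#' @param z Current depth in cm.
#' @param uz z-component of the unit direction.
#' @param z_top,z_bottom Depths (cm) of the layer's upper and lower planes.
#' @return A list with `distance` (cm, or `NA`) and `boundary`
#'   (`"upper"`, `"lower"`, or `NA`).
#' @examples
#' distance_to_boundary(0.01, 1, 0, 0.03)   # 0.02 cm to the lower plane
#' distance_to_boundary(0.02, -0.5, 0, 0.03) # 0.04 cm to the upper plane
#' @export
distance_to_boundary <- function(z, uz, z_top, z_bottom) {
  if (z < z_top - 1e-12 || z > z_bottom + 1e-12)
    abort("photon depth is outside its recorded layer")
  if (uz == 0) return(list(distance = NA_real_, boundary = NA_character_))
  if (uz > 0) list(distance = (z_bottom - z) / uz, boundary = "lower")
  else list(distance = (z - z_top) / (-uz), boundary = "upper")
}

#' Absorption deposit at an interaction site
#'
#' At each interaction the photon deposits the fraction
#' `mu_a / (mu_a + mu_s)` of its current weight into the medium.
#'
#' @param w Current photon weight.
#' @inheritParams optical_layer
#' @return The deposited weight `w * mu_a / (mu_a + mu_s)`.
#' @examples
#' absorb_deposit(1, 0.024, 28.4)
#' @export
absorb_deposit <- function(w, mu_a, mu_s) {
  if (any(w < 0)) abort("`w` must be >= 0")
  w * mu_a / (mu_a + mu_s)
}

#' Decide a boundary crossing
#'
#' On hitting a boundary the photon is internally reflected with the
#' Fresnel probability [fresnel_reflectance()], compared against a uniform
#' deviate; otherwise it refracts by Snell's law into the next medium. The
#' transverse direction components scale by `n_i / n_t` and the axial
#' component becomes the refraction cosine (sign preserved).
#'
#' @param n_i,n_t Refractive indices either side of the boundary.
#' @param direction Unit direction vector at incidence.
#' @param xi Uniform deviate in \[0, 1); drawn from the session RNG when
#'   omitted.
#' @return A list with `outcome` (`"reflected"` or `"transmitted"`) and the
#'   updated `direction`.
#' @examples
#' boundary_outcome(1.342, 1.46, c(0, 0, 1), xi = 0.5)  # enters the core
#' @export
boundary_outcome <- function(n_i, n_t, direction, xi = runif(1)) {
  stopifnot(length(direction) == 3)
  cos_ai <- abs(direction[3])
  R <- fresnel_reflectance(n_i, n_t, cos_ai)
  if (xi < R) {
    return(list(outcome = "reflected",
                direction = direction * c(1, 1, -1)))
  }
  ratio <- n_i / n_t
  sin_at <- ratio * sqrt(max(0, 1 - cos_ai^2))
  cos_at <- sqrt(max(0, 1 - sin_at^2))
  list(outcome = "transmitted",
       direction = c(direction[1] * ratio, direction[2] * ratio,
                     sign(direction[3]) * cos_at))
}

#' Russian-roulette termination
#'
#' Gives a low-weight photon a `1/m` chance of surviving with weight `m*w`;
#' otherwise it is terminated with nothing scored. The expected
#' post-roulette weight equals `w`, so the scheme is unbiased.
#'
#' @param w Current photon weight.
#' @param m Survival factor, > 1.
#' @param xi Uniform deviate in \[0, 1); drawn from the session RNG when
#'   omitted.
#' @return The new weight: `m * w` on survival, 0 on termination.
#' @examples
#' roulette_weight(5e-5, m = 10, xi = 0.05)  # survives with weight 5e-4
#' @export
roulette_weight <- function(w, m = 10, xi = runif(1)) {
  if (m <= 1) abort("`m` must be > 1")
  if (xi < 1 / m) m * w else 0
}

#' Run the Monte Carlo simulation
#'
#' Traces `n_photons` weighted photons through the stack with the
#' hop-drop-spin scheme: exponential free paths, Henyey-Greenstein
#' scattering, Fresnel/Snell boundary logic with the carried-over
#' dimensionless residual step, absorption deposits on a radial-by-depth
#' grid, Russian-roulette termination, and per-layer pathlength
#' bookkeeping. Weight escaping through the top surface is scored by exit
#' radius and exit angle (in the ambient medium, measured from the outward
#' normal); weight refracted through the bottom boundary is scored as
#' absorbed by the medium below (the stone core) and never returns.
#'
#' @param stack A [fruit_stack()].
#' @param config A [sim_config()].
#' @return An `mc_result` object; see [tidy.mc_result()],
#'   [radial_profile()], [angular_profile()], [absorption_profile()].
#' @examples
#' st <- preset_stack("table2", flesh_thickness = 2)
#' res <- run_simulation(st, sim_config(n_photons = 2e4, seed = 7))
#' glance(res)
#' @export
run_simulation <- function(stack, config = sim_config()) {
  stopifnot(inherits(stack, "fruit_stack"), inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  nz <- config$nz %||% min(2000L, max(1L, as.integer(
    ceiling(stack_thickness(stack) / config$dz))))
  fl <- flesh_index(stack)
  raw <- .cpp_run_mc(
    stack_field(stack, "n"), stack_field(stack, "mu_a"),
    stack_field(stack, "mu_s"), stack_field(stack, "g"),
    stack_field(stack, "thickness"),
    stack$n_above, stack$n_below,
    config$n_photons, config$w_th, config$roulette_m,
    config$dr, config$dz, config$nr, nz, config$na,
    fl - 1L)
  new_mc_result(raw, stack, config, nz = nz, flesh_layer = fl)
}
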