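#' Define one homogeneous tissue layer
#'
#' A layer is a slab with a refractive index `n`, absorption coefficient
#' `mu_a` (cm^-1), scattering coefficient `mu_s` (cm^-1), scattering
#' anisotropy `g` (mean cosine of the deflection angle) and a thickness in
#' cm. Layers are stacked top-to-bottom with [fruit_stack()].
#'
#' @param n Refractive index, >= 1.
#' @param mu_a Absorption coefficient in cm^-1, >= 0.
#' @param mu_s Scattering coefficient in cm^-1, >= 0. `mu_a + mu_s` must be
#'   positive: a photon must interact somewhere.
#' @param g Anisotropy factor in \[-1, 1\]; 0 is isotropic, values near 1 are
#'   strongly forward-peaked (typical for fruit tissue).
#' @param thickness Slab thickness in cm, > 0. Use a large value for an
#'   effectively semi-infinite medium.
#' @param name Optional label ("skin", "flesh", ...). The label "flesh"
#'   marks the layer used for detection-efficiency statistics.
#' @return An object of class `optical_layer`.
#' @examples
#' optical_layer(1.342, 0.024, 28.4, 0.61, 2.0, name = "flesh")
#' @export
optical_layer <- function(n, mu_a, mu_s, g, thickness, name = NULL) {
  stopifnot(length(n) == 1, length(mu_a) == 1, length(mu_s) == 1,
            length(g) == 1, length(thickness) == 1)
  if (!is.finite(n) || n < 1) abort("`n` must be a finite number >= 1")
  if (mu_a < 0) abort("`mu_a` must be >= 0")
  if (mu_s < 0) abort("`mu_s` must be >= 0")
  if (mu_a + mu_s <= 0) abort("`mu_a + mu_s` must be > 0")
  if (abs(g) > 1) abort("`g` must lie in [-1, 1]")
  if (!is.finite(thickness) || thickness <= 0) abort("`thickness` must be > 0")
  structure(
    list(n = n, mu_a = mu_a, mu_s = mu_s, g = g, thickness = thickness,
         name = name),
    class = "optical_layer")
}

#' Assemble a layered fruit stack
#'
#' Orders [optical_layer()] slabs top to bottom between two ambient media
#' that enter only through their refractive indices. For stone fruit the
#' medium below the flesh is the stone (core), modeled purely as a
#' refractive boundary: weight refracted through the bottom boundary is
#' scored as core-absorbed and never returns.
#'
#' @param ... `optical_layer` objects, top first.
#' @param n_above Refractive index of the ambient medium above (air = 1).
#' @param n_below Refractive index of the medium below the last layer
#'   (1.46 for a peach stone, 1 for air).
#' @return An object of class `fruit_stack`.
#' @examples
#' fruit_stack(
#'   optical_layer(1.337, 0.075, 102, 0.65, 0.03, name = "skin"),
#'   optical_layer(1.342, 0.024, 28.4, 0.61, 2.0, name = "flesh"),
#'   n_above = 1.00, n_below = 1.46)
#' @export
fruit_stack <- function(..., n_above = 1.00, n_below = 1.00) {
  layers <- list(...)
  if (length(layers) == 1 && is.list(layers[[1]]) &&
      !inherits(layers[[1]], "optical_layer")) {
    layers <- layers[[1]]
  }
  if (length(layers) < 1) abort("a stack needs at least one layer")
  ok <- vapply(layers, inherits, logical(1), what = "optical_layer")
  if (!all(ok)) abort("all layers must be `optical_layer` objects")
  if (n_above < 1 || n_below < 1) abort("ambient indices must be >= 1")
  structure(
    list(n_above = n_above, layers = layers, n_below = n_below),
    class = "fruit_stack")
}

#' @export
print.fruit_stack <- function(x, ...) {
  cat(sprintf("<fruit_stack> %d layer(s), n_above = %.3f, n_below = %.3f\n",
              length(x$layers), x$n_above, x$n_below))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    cat(sprintf(
      "  [%d]%s n = %.3f, mu_a = %.3f, mu_s = %.1f cm-1, g = %.2f, d = %g cm\n",
      i, if (is.null(l$name)) "" else paste0(" ", l$name),
      l$n, l$mu_a, l$mu_s, l$g, l$thickness))
  }
  invisible(x)
}

stack_thickness <- function(stack) {
  sum(vapply(stack$layers, `[[`, numeric(1), "thickness"))
}

stack_field <- function(stack, field) {
  vapply(stack$layers, `[[`, numeric(1), field)
}

# index of the layer detection metrics refer to: the one named "flesh",
# else the last layer
flesh_index <- function(stack) {
  nms <- vapply(stack$layers, function(l) l$name %||% "", character(1))
  i <- which(nms == "flesh")
  if (length(i) >= 1) i[[1]] else length(stack$layers)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Describe the incident beam
#'
#' The transport kernel always simulates the impulse response of an
#' infinitely narrow beam injected orthogonally at the origin; a finite
#' Gaussian source is applied afterwards by [convolve_beam()]. `energy` is
#' the total beam energy in joules and `radius_1e2` the radius (cm) at
#' which irradiance falls to 1/e^2 of its axial value.
#'
#' @param energy Total beam energy in J, > 0.
#' @param radius_1e2 1/e^2 radius in cm (Gaussian only), > 0.
#' @return An object of class `mc_beam`.
#' @examples
#' gaussian_beam(0.5, 0.05)
#' pencil_beam()
#' @export
gaussian_beam <- function(energy = 0.5, radius_1e2 = 0.05) {
  if (energy <= 0) abort("`energy` must be > 0")
  if (radius_1e2 <= 0) abort("`radius_1e2` must be > 0")
  structure(list(profile = "gaussian", energy = energy,
                 radius_1e2 = radius_1e2), class = "mc_beam")
}

#' @rdname gaussian_beam
#' @export
pencil_beam <- function(energy = 1) {
  if (energy <= 0) abort("`energy` must be > 0")
  structure(list(profile = "pencil", energy = energy, radius_1e2 = NA_real_),
            class = "mc_beam")
}

#' Unpolarized Fresnel reflection probability
#'
#' Average of the s- and p-polarized Fresnel reflectances for a ray
#' crossing from refractive index `n_i` into `n_t` with incidence-angle
#' cosine `cos_i`. The angular form is singular at normal incidence and at
#' grazing incidence; both endpoints are replaced by their analytic limits,
#' `((n_i - n_t)/(n_i + n_t))^2` and 1. At or beyond the critical angle
#' (possible when `n_i > n_t`) the ray is totally internally reflected and
#' the function returns exactly 1.
#'
#' @param n_i,n_t Refractive indices of the incident and transmitting
#'   media, both >= 1.
#' @param cos_i Cosine of the incidence angle measured from the boundary
#'   normal, in \[0, 1\]. Vectorized.
#' @return Reflection probability in \[0, 1\].
#' @examples
#' fresnel_reflectance(1.00, 1.337, 1)          # normal incidence, air -> skin
#' fresnel_reflectance(1.342, 1.00, cos(pi / 3)) # beyond critical angle: 1
#' @export
fresnel_reflectance <- function(n_i, n_t, cos_i) {
  if (any(!is.finite(c(n_i, n_t))) || n_i < 1 || n_t < 1)
    abort("refractive indices must be finite and >= 1")
  if (any(!is.finite(cos_i)) || any(cos_i < 0) || any(cos_i > 1))
    abort("`cos_i` must lie in [0, 1]")
  vapply(cos_i, function(ci) .cpp_fresnel(n_i, n_t, ci), numeric(1))
}

#' Specular reflectance of the collimated beam at the surface
#'
#' Fraction of the orthogonally incident beam reflected at the air-tissue
#' interface before any propagation: the normal-incidence Fresnel value
#' `((n_above - n1)/(n_above + n1))^2`. The launched photon weight is
#' `1 - specular_reflectance(...)`.
#'
#' @param n_above Ambient refractive index.
#' @param n_first Refractive index of the first tissue layer.
#' @return Fraction in \[0, 1).
#' @examples
#' specular_reflectance(1.00, 1.337)  # ~0.0208 at an air-skin interface
#' @export
specular_reflectance <- function(n_above, n_first) {
  fresnel_reflectance(n_above, n_first, 1)
}

#' Effective attenuation coefficient of diffusion theory
#'
#' Deep inside a scattering medium the fluence decays as
#' `exp(-mu_eff * z)` with `mu_eff = sqrt(3 * mu_a * (mu_a + mu_s'))`,
#' where `mu_s' = (1 - g) * mu_s` is the reduced scattering coefficient.
#'
#' @inheritParams optical_layer
#' @return `mu_eff` in cm^-1. Vectorized over its arguments.
#' @examples
#' effective_attenuation(0.024, 28.4, 0.61)  # peach flesh: ~0.894 cm^-1
#' @export
effective_attenuation <- function(mu_a, mu_s, g) {
  if (any(mu_a < 0) || any(mu_s < 0)) abort("coefficients must be >= 0")
  if (any(abs(g) > 1)) abort("`g` must lie in [-1, 1]")
  sqrt(3 * mu_a * (mu_a + (1 - g) * mu_s))
}

#' Penetration depth at a given attenuation fraction
#'
#' Depth at which the diffuse intensity has decayed to `fraction` of its
#' incident value: `-log(fraction) / mu_eff`. The conventional "1%
#' penetration depth" uses `fraction = 0.01`.
#'
#' @param mu_eff Effective attenuation coefficient in cm^-1, > 0.
#' @param fraction Remaining intensity fraction in (0, 1).
#' @return Depth in cm.
#' @examples
#' mu <- effective_attenuation(0.024, 28.4, 0.61)
#' penetration_depth(mu)  # ~5.15 cm
#' @export
penetration_depth <- function(mu_eff, fraction = 0.01) {
  if (any(mu_eff <= 0)) abort("`mu_eff` must be > 0: depth is undefined")
  if (any(fraction <= 0) || any(fraction >= 1))
    abort("`fraction` must lie in (0, 1)")
  -log(fraction) / mu_eff
}

#' Diffusion-theory attenuation through a layered stack
#'
#' Fraction of the incident intensity remaining after traversing `depth` cm
#' of the stack at normal incidence, taking each layer's own `mu_eff`:
#' the product of `exp(-mu_eff_k * path_k)` over the traversed layers.
#' This is the analytic companion to the Monte Carlo kernel (it is never
#' used inside it): it reproduces the simple exponential picture of how
#' much light reaches the distal flesh boundary.
#'
#' @param stack A [fruit_stack()].
#' @param depth Depth(s) in cm, within \[0, total stack thickness\].
#' @return Fraction(s) in \[0, 1\].
#' @examples
#' st <- preset_stack("table2", flesh_thickness = 3)
#' layered_attenuation(st, 3.03)  # reaching the distal flesh boundary
#' @export
layered_attenuation <- function(stack, depth) {
  stopifnot(inherits(stack, "fruit_stack"))
  if (any(depth < 0)) abort("`depth` must be >= 0")
  total <- stack_thickness(stack)
  if (any(depth > total + 1e-9))
    abort("`depth` exceeds the total stack thickness")
  mu_eff <- effective_attenuation(stack_field(stack, "mu_a"),
                                  stack_field(stack, "mu_s"),
                                  stack_field(stack, "g"))
  d <- stack_field(stack, "thickness")
  bounds <- cumsum(c(0, d))
  vapply(depth, function(z) {
    path <- pmax(0, pmin(z, bounds[-1]) - bounds[-length(bounds)])
    exp(-sum(mu_eff * path))
  }, numeric(1))
}

#' Summarise diffusion analytics for a stack
#'
#' Per-layer effective attenuation and 1% penetration depth, plus the
#' fraction of intensity predicted to reach a reference depth (by default
#' the bottom of the stack, i.e. the distal flesh boundary).
#'
#' @param stack A [fruit_stack()].
#' @param boundary_depth Depth (cm) for the reported boundary fraction;
#'   defaults to the total stack thickness.
#' @return A tibble with one row per layer (`layer`, `name`, `mu_eff`,
#'   `penetration_depth_1pct`, `boundary_fraction`); `boundary_fraction` is
#'   the same stack-level value repeated.
#' @examples
#' diffusion_summary(preset_stack("table2", flesh_thickness = 2))
#' @export
diffusion_summary <- function(stack, boundary_depth = NULL) {
  stopifnot(inherits(stack, "fruit_stack"))
  boundary_depth <- boundary_depth %||% stack_thickness(stack)
  mu_eff <- effective_attenuation(stack_field(stack, "mu_a"),
                                  stack_field(stack, "mu_s"),
                                  stack_field(stack, "g"))
  tibble(
    layer = seq_along(stack$layers),
    name = vapply(stack$layers, function(l) l$name %||% NA_character_,
                  character(1)),
    mu_eff = mu_eff,
    penetration_depth_1pct = ifelse(mu_eff > 0, -log(0.01) / mu_eff, Inf),
    boundary_fraction = layered_attenuation(stack, boundary_depth))
}
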