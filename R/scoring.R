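# Raw kernel accumulators -> mc_result. Normalization conventions:
#   - totals are fractions of launched photon count (initial weight 1 each,
#     minus the specular decrement), diffuse reflectance EXCLUDES specular;
#   - per-area profiles divide by launched count and bin geometry; the last
#     radial bin doubles as the overflow catch-all and is reported as NA in
#     per-area profiles whenever overflow actually landed there.
new_mc_result <- function(raw, stack, config, nz, flesh_layer) {
  n <- config$n_photons
  se <- function(s, s2) sqrt(pmax(0, s2 / n - (s / n)^2) / n)
  layer_names <- vapply(seq_along(stack$layers), function(i) {
    nm <- stack$layers[[i]]$name
    if (is.null(nm)) paste0("layer", i) else nm
  }, character(1))
  structure(
    list(
      stack = stack, config = config, nz = nz, flesh_layer = flesh_layer,
      layer_names = layer_names,
      rsp = raw$rsp,
      rd_total = raw$rd_total / n,
      a_by_layer = as.numeric(raw$a_layer) / n,
      t_below = raw$t_below / n,
      lost_roulette = raw$lost_roulette / n,
      rd_se = se(raw$rd_sum, raw$rd_sum2),
      a_se = se(as.numeric(raw$a_sum), as.numeric(raw$a_sum2)),
      t_below_se = se(raw$below_sum, raw$below_sum2),
      refl_r_alpha = raw$refl_r_alpha,
      absorb_r_z = raw$absorb_r_z,
      below_r = as.numeric(raw$below_r),
      eff_weight_r = as.numeric(raw$eff_weight_r),
      total_weight_r = as.numeric(raw$total_weight_r),
      eff_count_r = as.numeric(raw$eff_count_r),
      total_count_r = as.numeric(raw$total_count_r),
      flesh_path_r = as.numeric(raw$flesh_path_r),
      total_path_r = as.numeric(raw$total_path_r),
      refl_overflow = raw$refl_overflow),
    class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("<mc_result> %s photons, seed %s\n",
              format(x$config$n_photons, big.mark = ","),
              x$config$seed %||% "unset"))
  cat(sprintf("  specular reflectance     %.4f\n", x$rsp))
  cat(sprintf("  total diffuse reflectance %.4f (se %.1e)\n",
              x$rd_total, x$rd_se))
  for (i in seq_along(x$a_by_layer))
    cat(sprintf("  absorbed in %-12s %.4f (se %.1e)\n",
                x$layer_names[i], x$a_by_layer[i], x$a_se[i]))
  cat(sprintf("  absorbed below (core)    %.4f (se %.1e)\n",
              x$t_below, x$t_below_se))
  invisible(x)
}

radial_centers <- function(result) {
  (seq_len(result$config$nr) - 0.5) * result$config$dr
}

#' Tidy the simulation totals
#'
#' One row per scored energy channel: the specular reflectance, the total
#' diffuse reflectance (specular excluded), the absorbed fraction in each
#' layer, the fraction crossing into the medium below (core absorbed), and
#' the weight lost to roulette termination. All values are fractions of
#' launched photons with Monte Carlo standard errors.
#'
#' @param x An `mc_result`.
#' @param ... Unused.
#' @return A tibble with columns `quantity`, `value`, `stderr`.
#' @method tidy mc_result
#' @export
tidy.mc_result <- function(x, ...) {
  tibble(
    quantity = c("specular_reflectance", "diffuse_reflectance",
                 paste0("absorbed_", x$layer_names), "core_absorbed",
                 "roulette_lost"),
    value = c(x$rsp, x$rd_total, x$a_by_layer, x$t_below, x$lost_roulette),
    stderr = c(0, x$rd_se, x$a_se, x$t_below_se, NA_real_))
}

#' One-row summary of a simulation
#'
#' @param x An `mc_result`.
#' @param ... Unused.
#' @return A one-row tibble with the totals, the energy-balance residual
#'   `balance` (should be ~0: roulette is unbiased), photon count and seed.
#' @method glance mc_result
#' @export
glance.mc_result <- function(x, ...) {
  out <- tibble(
    rsp = x$rsp, rd_total = x$rd_total, t_below = x$t_below,
    balance = x$rsp + x$rd_total + sum(x$a_by_layer) + x$t_below +
      x$lost_roulette - 1,
    n_photons = x$config$n_photons,
    seed = x$config$seed %||% NA_integer_)
  for (i in seq_along(x$a_by_layer))
    out[[paste0("a_", x$layer_names[i])]] <- x$a_by_layer[i]
  out
}

#' Radial diffuse-reflectance profile with detection metrics
#'
#' Diffuse reflectance per unit area versus exit radius, together with the
#' detection-efficiency statistics: the percentage of effective photons
#' `Peff_percent` (escaping weight that interacted at least once in the
#' flesh layer, over all escaping weight, per Eq. of weights) and the flesh
#' sensitivity `Sflesh` (pooled weighted pathlength in the flesh over total
#' pathlength). The last radial bin collects all overflow escapes and its
#' per-area value is reported as `NA` when overflow occurred.
#'
#' @param result An `mc_result`.
#' @return A tibble with `r_cm` (bin centers), `Rd_per_cm2` (J cm^-2 per
#'   launched J), `Peff_percent`, `Sflesh`.
#' @examples
#' st <- preset_stack("table2", flesh_thickness = 2)
#' radial_profile(run_simulation(st, sim_config(n_photons = 2e4, seed = 1)))
#' @export
radial_profile <- function(result) {
  stopifnot(inherits(result, "mc_result"))
  n <- result$config$n_photons
  r <- radial_centers(result)
  area <- 2 * pi * r * result$config$dr
  rd <- rowSums(result$refl_r_alpha) / (n * area)
  if (result$refl_overflow > 0) rd[length(rd)] <- NA_real_
  tibble(
    r_cm = r,
    Rd_per_cm2 = rd,
    Peff_percent = detection_efficiency(result)$Peff_percent,
    Sflesh = flesh_sensitivity(result)$Sflesh)
}

#' Percentage of effective photons per radial bin
#'
#' An "effective" photon interacted at least once inside the flesh layer
#' before escaping; a photon diffusely reflected by the skin alone carries
#' no information about the flesh. Reported as the percentage of escaping
#' weight (default) or of escape counts (`counts = TRUE`) per radial bin;
#' bins with no escapes are `NA`.
#'
#' @param result An `mc_result`.
#' @param counts Use raw escape counts instead of weights.
#' @return A tibble with `r_cm`, `Peff_percent`.
#' @export
detection_efficiency <- function(result, counts = FALSE) {
  stopifnot(inherits(result, "mc_result"))
  num <- if (counts) result$eff_count_r else result$eff_weight_r
  den <- if (counts) result$total_count_r else result$total_weight_r
  tibble(r_cm = radial_centers(result),
         Peff_percent = ifelse(den > 0, 100 * (num / den), NA_real_))
}

#' Flesh pathlength sensitivity per radial bin
#'
#' Fraction of the detected photons' pathlength spent in the flesh layer:
#' the pooled ratio of weight-multiplied flesh pathlength to
#' weight-multiplied total pathlength in each radial bin. Bounded in
#' \[0, 1\]; `NA` for empty bins.
#'
#' @param result An `mc_result`.
#' @return A tibble with `r_cm`, `Sflesh`.
#' @export
flesh_sensitivity <- function(result) {
  stopifnot(inherits(result, "mc_result"))
  tibble(r_cm = radial_centers(result),
         Sflesh = ifelse(result$total_path_r > 0,
                         result$flesh_path_r / result$total_path_r,
                         NA_real_))
}

#' Angularly resolved diffuse reflectance
#'
#' Escaped energy per unit area perpendicular to the photon direction per
#' steradian, versus exit radius and exit angle: bin weight divided by
#' launched count, annulus area `2 pi r dr`, the cosine of the bin-center
#' exit angle, and the bin solid angle `2 pi (cos a_lo - cos a_hi)`.
#'
#' @param result An `mc_result`.
#' @return A tibble with `r_cm`, `alpha_deg` (bin centers),
#'   `Rd_per_cm2_per_sr`. The overflow radial bin is reported as `NA` when
#'   overflow occurred.
#' @export
angular_profile <- function(result) {
  stopifnot(inherits(result, "mc_result"))
  cfg <- result$config
  n <- cfg$n_photons
  r <- radial_centers(result)
  da <- (pi / 2) / cfg$na
  a_lo <- (seq_len(cfg$na) - 1) * da
  a_mid <- a_lo + da / 2
  solid <- 2 * pi * (cos(a_lo) - cos(a_lo + da))
  area <- 2 * pi * r * cfg$dr
  denom <- n * outer(area, cos(a_mid) * solid)
  vals <- result$refl_r_alpha / denom
  if (result$refl_overflow > 0) vals[nrow(vals), ] <- NA_real_
  tibble(
    r_cm = rep(r, times = cfg$na),
    alpha_deg = rep(a_mid * 180 / pi, each = cfg$nr),
    Rd_per_cm2_per_sr = as.vector(vals))
}

#' Absorbed energy density grid
#'
#' Deposited weight per unit volume versus radius and depth: bin weight
#' over launched count and bin volume `2 pi r dr dz`.
#'
#' @param result An `mc_result`.
#' @return A tibble with `r_cm`, `z_cm` (bin centers), `A_per_cm3`.
#' @export
absorption_profile <- function(result) {
  stopifnot(inherits(result, "mc_result"))
  cfg <- result$config
  r <- radial_centers(result)
  z <- (seq_len(result$nz) - 0.5) * cfg$dz
  vol <- 2 * pi * r * cfg$dr * cfg$dz
  vals <- result$absorb_r_z / (cfg$n_photons * vol)
  tibble(
    r_cm = rep(r, times = result$nz),
    z_cm = rep(z, each = cfg$nr),
    A_per_cm3 = as.vector(vals))
}

#' Write simulation results as CSV files
#'
#' Writes `radial.csv` (r_cm, Rd_per_cm2, Peff_percent, Sflesh),
#' `angular.csv` (r_cm, alpha_deg, Rd_per_cm2_per_sr), `absorption.csv`
#' (r_cm, z_cm, A_per_cm3) and `totals.csv` (quantity, value, stderr)
#' into `dir`.
#'
#' @param result An `mc_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_result <- function(result, dir) {
  stopifnot(inherits(result, "mc_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(radial_profile(result), file.path(dir, "radial.csv"),
            row.names = FALSE)
  write.csv(angular_profile(result), file.path(dir, "angular.csv"),
            row.names = FALSE)
  write.csv(absorption_profile(result), file.path(dir, "absorption.csv"),
            row.names = FALSE)
  write.csv(tidy.mc_result(result), file.path(dir, "totals.csv"),
            row.names = FALSE)
  invisible(dir)
}
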