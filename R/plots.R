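#' Plot a simulation result
#'
#' Quick-look ggplot2 graphics for an `mc_result`: the radial
#' diffuse-reflectance profile (log scale), the angularly resolved
#' reflectance, the absorbed-energy map, or the detection metrics
#' (percentage of effective photons and flesh sensitivity vs radius).
#'
#' @param object An `mc_result`.
#' @param type One of `"radial"`, `"angular"`, `"absorption"`,
#'   `"detection"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mc_result
#' @export
autoplot.mc_result <- function(object, type = c("radial", "angular",
                                                "absorption", "detection"),
                               ...) {
  type <- match.arg(type)
  switch(type,
    radial = {
      dat <- filter(radial_profile(object), .data$Rd_per_cm2 > 0)
      ggplot2::ggplot(dat, ggplot2::aes(.data$r_cm, .data$Rd_per_cm2)) +
        ggplot2::geom_line() +
        ggplot2::scale_y_log10() +
        ggplot2::labs(x = "radius (cm)",
                      y = expression(R[d] ~ (cm^-2 ~ per ~ J)),
                      title = "Spatially resolved diffuse reflectance")
    },
    angular = {
      dat <- filter(angular_profile(object),
                    is.finite(.data$Rd_per_cm2_per_sr),
                    .data$Rd_per_cm2_per_sr > 0)
      ggplot2::ggplot(dat, ggplot2::aes(.data$r_cm, .data$Rd_per_cm2_per_sr,
                                        colour = factor(.data$alpha_deg))) +
        ggplot2::geom_line() +
        ggplot2::scale_y_log10() +
        ggplot2::labs(x = "radius (cm)", y = expression(cm^-2 ~ sr^-1),
                      colour = "exit angle (deg)",
                      title = "Angularly resolved diffuse reflectance")
    },
    absorption = {
      dat <- filter(absorption_profile(object), .data$A_per_cm3 > 0)
      ggplot2::ggplot(dat, ggplot2::aes(.data$r_cm, .data$z_cm,
                                        fill = log10(.data$A_per_cm3))) +
        ggplot2::geom_raster() +
        ggplot2::scale_y_reverse() +
        ggplot2::labs(x = "radius (cm)", y = "depth (cm)",
                      fill = expression(log[10] ~ A ~ (cm^-3)),
                      title = "Absorbed energy density")
    },
    detection = {
      prof <- radial_profile(object)
      dat <- tidyr::pivot_longer(
        dplyr::transmute(prof, r_cm = .data$r_cm,
                         `P_eff (%)` = .data$Peff_percent,
                         `S_flesh` = 100 * .data$Sflesh),
        -"r_cm", names_to = "metric", values_to = "value")
      ggplot2::ggplot(filter(dat, is.finite(.data$value)),
                      ggplot2::aes(.data$r_cm, .data$value)) +
        ggplot2::geom_line() +
        ggplot2::facet_wrap(~metric, scales = "free_y") +
        ggplot2::labs(x = "radius (cm)", y = NULL,
                      title = "Detection efficiency vs source-detector distance")
    })
}

#' Plot a beam-convolved profile
#'
#' @param conv Output of [convolve_beam()].
#' @return A ggplot object.
#' @export
plot_convolved <- function(conv) {
  dat <- filter(conv, .data$response_J_per_cm2 > 0)
  ggplot2::ggplot(dat, ggplot2::aes(.data$r_cm, .data$response_J_per_cm2)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "radius (cm)", y = expression(J ~ cm^-2),
                  title = "Beam-convolved diffuse reflectance")
}
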