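test_that("grid total reflectance equals the scalar total exactly", {
  res <- run_simulation(table2_stack(), small_config(n = 1e4, seed = 31))
  expect_equal(sum(res$refl_r_alpha) / 1e4, res$rd_total, tolerance = 1e-13)
  expect_true(all(res$refl_r_alpha >= 0))
  expect_true(all(res$eff_weight_r <= res$total_weight_r + 1e-12))
  expect_true(all(res$flesh_path_r <= res$total_path_r + 1e-12))
})

test_that("a flesh-only stack makes every detected photon effective", {
  res <- run_simulation(flesh_only_stack(), small_config(n = 1e4, seed = 32))
  eff <- detection_efficiency(res)
  occupied <- !is.na(eff$Peff_percent)
  expect_true(any(occupied))
  expect_true(all(eff$Peff_percent[occupied] == 100))
  effc <- detection_efficiency(res, counts = TRUE)
  expect_true(all(effc$Peff_percent[!is.na(effc$Peff_percent)] == 100))
  sf <- flesh_sensitivity(res)
  expect_true(all(abs(sf$Sflesh[!is.na(sf$Sflesh)] - 1) < 1e-12))
})

test_that("detection metrics are bounded for the layered stack", {
  res <- run_simulation(table2_stack(d2 = 1.5), small_config(n = 5e4, seed = 33))
  eff <- detection_efficiency(res)$Peff_percent
  sf <- flesh_sensitivity(res)$Sflesh
  expect_true(all(eff[!is.na(eff)] >= 0 & eff[!is.na(eff)] <= 100))
  expect_true(all(sf[!is.na(sf)] >= 0 & sf[!is.na(sf)] <= 1))
  # with a skin layer present neither metric can be perfect near the source
  expect_lt(eff[1], 100)
  expect_lt(sf[1], 1)
})

test_that("angular normalization is exactly flat for a uniform-radiance field", {
  # construct escape weights proportional to annulus area x cos(angle) x
  # solid angle: the normalized profile must then be constant everywhere
  nr <- 8; na <- 9; n_ph <- 1000; dr <- 0.05
  r <- (seq_len(nr) - 0.5) * dr
  da <- (pi / 2) / na
  a_lo <- (seq_len(na) - 1) * da
  solid <- 2 * pi * (cos(a_lo) - cos(a_lo + da))
  area <- 2 * pi * r * dr
  w <- outer(area, cos(a_lo + da / 2) * solid) * 0.37 * n_ph
  res <- fake_result(list(refl_r_alpha = w, rd_total = sum(w) / n_ph),
                     nr = nr, na = na, n_photons = n_ph, dr = dr)
  ang <- angular_profile(res)
  expect_equal(ang$Rd_per_cm2_per_sr, rep(0.37, nr * na), tolerance = 1e-12)
  # zero-weight bins report zero
  res0 <- fake_result(list(), nr = nr, na = na, n_photons = n_ph, dr = dr)
  expect_true(all(angular_profile(res0)$Rd_per_cm2_per_sr == 0))
})

test_that("radial and absorption normalization divide by bin geometry", {
  nr <- 10; nz <- 4; n_ph <- 200; dr <- 0.1; dz <- 0.1
  w <- matrix(0, nr, 6); w[4, 2] <- 0.5   # one escape of weight 0.5 in bin 4
  ab <- matrix(0, nr, nz); ab[2, 3] <- 0.25
  res <- fake_result(list(refl_r_alpha = w, absorb_r_z = ab,
                          rd_total = 0.5 / n_ph),
                     nr = nr, nz = nz, n_photons = n_ph, dr = dr, dz = dz)
  prof <- radial_profile(res)
  r4 <- (4 - 0.5) * dr
  expect_equal(prof$Rd_per_cm2[4], 0.5 / (n_ph * 2 * pi * r4 * dr),
               tolerance = 1e-12)
  expect_equal(prof$Rd_per_cm2[1], 0)
  abs_prof <- absorption_profile(res)
  r2 <- (2 - 0.5) * dr
  val <- abs_prof$A_per_cm3[abs_prof$r_cm == r2 & abs_prof$z_cm == 2.5 * dz]
  expect_equal(val, 0.25 / (n_ph * 2 * pi * r2 * dr * dz), tolerance = 1e-12)
})

test_that("overflow escapes collapse into the flagged last radial bin", {
  # shrink the grid so distant escapes overflow
  res <- run_simulation(table2_stack(), small_config(n = 2e4, seed = 34,
                                                     nr = 5))
  expect_gt(res$refl_overflow, 0)
  prof <- radial_profile(res)
  expect_true(is.na(prof$Rd_per_cm2[5]))       # excluded from per-area profile
  expect_true(all(is.finite(prof$Rd_per_cm2[1:4])))
  # but the overflow weight still counts toward the total
  expect_equal(sum(res$refl_r_alpha) / 2e4, res$rd_total, tolerance = 1e-12)
})

test_that("detection ratios are invariant to the photon-count scale", {
  r1 <- run_simulation(table2_stack(d2 = 1.5), small_config(n = 2e4, seed = 35))
  p1 <- detection_efficiency(r1)$Peff_percent
  s1 <- flesh_sensitivity(r1)$Sflesh
  # independent run with double the photons: the ratio statistics estimate
  # the same quantity, so well-populated bins must agree up to MC noise
  r2 <- run_simulation(table2_stack(d2 = 1.5), small_config(n = 4e4, seed = 36))
  p2 <- detection_efficiency(r2)$Peff_percent
  keep <- which(r1$total_weight_r > 10 & r2$total_weight_r > 20)
  expect_gt(length(keep), 5)
  expect_lt(max(abs(p1[keep] - p2[keep])), 10)
  expect_true(all(s1[!is.na(s1)] >= 0 & s1[!is.na(s1)] <= 1))
})

test_that("tidy and glance summarise the energy budget", {
  res <- run_simulation(table2_stack(), small_config(n = 5e3, seed = 37))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("quantity", "value", "stderr"))
  expect_true(all(c("specular_reflectance", "diffuse_reflectance",
                    "absorbed_skin", "absorbed_flesh", "core_absorbed")
                  %in% td$quantity))
  expect_true(all(td$value >= 0))
  g <- glance(res)
  expect_equal(g$rd_total,
               td$value[td$quantity == "diffuse_reflectance"])
  expect_equal(g$n_photons, 5e3)
})

test_that("write_result emits the four CSV dialects", {
  res <- run_simulation(table2_stack(), small_config(n = 2e3, seed = 38,
                                                     nr = 20, na = 6))
  dir <- withr::local_tempdir()
  write_result(res, dir)
  radial <- read.csv(file.path(dir, "radial.csv"))
  expect_named(radial, c("r_cm", "Rd_per_cm2", "Peff_percent", "Sflesh"))
  angular <- read.csv(file.path(dir, "angular.csv"))
  expect_named(angular, c("r_cm", "alpha_deg", "Rd_per_cm2_per_sr"))
  absorption <- read.csv(file.path(dir, "absorption.csv"))
  expect_named(absorption, c("r_cm", "z_cm", "A_per_cm3"))
  totals <- read.csv(file.path(dir, "totals.csv"))
  expect_named(totals, c("quantity", "value", "stderr"))
})
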