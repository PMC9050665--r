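## eye-patch counting helper (polarity held constant)
subplate_from_rasters_test <- function(eye) {
  cortimap:::subplate_from_rasters(eye, matrix(1, nrow(eye), ncol(eye)))
}

test_that("axon arbors peak at the centre and truncate at the radius", {
  sp <- plate_from(eye = c(1, 1), polarity = c(1, 1),
                   rx = c(0, 100), ry = c(0, 0), shape = c(2L, 1L))
  sheet <- spread_arbors(sp, sigma_arbor = 3, radius = 10)
  ## weight of each afferent at its own slot is the maximum, 1
  expect_equal(sheet$W[1L, 1L], 1)
  expect_equal(sheet$W[2L, 2L], 1)
  ## symmetric neighbours get equal weights
  expect_equal(sheet$W[1L, 2L], sheet$W[2L, 1L])
  expect_equal(sheet$W[1L, 2L], exp(-1 / (2 * 9)))

  ## radius below 1: each pixel keeps only its own afferent
  sheet0 <- spread_arbors(sp, sigma_arbor = 3, radius = 0.5)
  expect_equal(length(pixel_afferents(sheet0, 1L)$ids), 1L)

  ## beyond the radius the weight is exactly zero (no stored entry)
  n <- 25L
  spl <- plate_from(eye = rep(1, n), polarity = rep(1, n),
                    rx = seq_len(n), ry = 1, shape = c(25L, 1L))
  shl <- spread_arbors(spl, sigma_arbor = 3, radius = 5)
  expect_equal(shl$W[1L, 7L], 0)      # 6 slots away > radius 5
  expect_gt(shl$W[1L, 5L], 0)
  expect_error(spread_arbors(sp, sigma_arbor = 0), "positive")
})

test_that("ON-OFF competition applies 1 - DW inside the zone and spares the outside", {
  sigma <- 2
  run_case <- function(d_off) {
    sp <- plate_from(eye = c(1, 1), polarity = c(1, -1),
                     rx = c(0, d_off), ry = c(0, 0), shape = c(2L, 1L),
                     sigma = sigma)
    sheet <- spread_arbors(sp, sigma_arbor = 3, radius = 10)
    w_before <- sheet$W[2L, 1L]
    sheet2 <- synaptic_competition(sheet, zone_deg = 1)
    list(before = w_before, after = sheet2$W[2L, 1L])
  }
  ## OFF afferent exactly at the dominant peak: weight falls to zero
  z <- run_case(0)
  expect_equal(z$after, 0)
  ## DW = 0.3: choose the distance where exp(-d^2 / (2 sigma^2)) = 0.3
  d3 <- sqrt(-2 * sigma^2 * log(0.3))
  c3 <- run_case(d3)
  expect_equal(c3$after, c3$before * 0.7, tolerance = 1e-9)
  ## outside the 1-degree zone (radius 250/22/2 retinal px): unchanged
  far <- run_case(8)
  expect_equal(far$after, far$before)
})

test_that("population receptive fields sum signed afferent Gaussians", {
  sp <- plate_from(eye = 1, polarity = 1, rx = 10, ry = 10, shape = c(1L, 1L))
  sheet <- spread_arbors(sp, sigma_arbor = 3, radius = 10)
  prf <- population_rf(sheet, 1L, window = 16L)
  ref <- gaussian_rf(c(10, 10), 2, prf$RX, prf$RY)
  expect_equal(prf$rf, ref)

  ## equal-weight ON and OFF at the same centre cancel
  sp2 <- plate_from(eye = c(1, 1), polarity = c(1, -1),
                    rx = c(10, 10), ry = c(10, 10), shape = c(2L, 1L))
  sheet2 <- spread_arbors(sp2, sigma_arbor = 3, radius = 10)
  ## give both afferents weight 1 at pixel 1 by symmetry of slots 1,2
  prf2 <- population_rf(sheet2, 1L, window = 16L)
  w <- prf2$sel$w
  expect_equal(w[1L] * 1 + w[2L] * -1 != 0,
               max(abs(prf2$rf)) > 1e-12)

  ## flanking opposite-polarity afferents: zero-crossing on the midline
  sp3 <- plate_from(eye = c(1, 1), polarity = c(1, -1),
                    rx = c(7, 13), ry = c(10, 10), shape = c(2L, 1L))
  sheet3 <- spread_arbors(sp3, sigma_arbor = 3, radius = 0.5)  # own pixels only
  ## build a two-lobe field directly from the afferent table
  rf <- gaussian_rf(c(7, 10), 2, 1:20, 1:20) -
    gaussian_rf(c(13, 10), 2, 1:20, 1:20)
  expect_equal(max(abs(rf[10, ])), 0, tolerance = 1e-12)  # midline rx = 10

  expect_warning(population_rf(sheet, 1L, eye = -1), "empty")
})

test_that("FFT orientation tuning identifies lobe orientation and isotropy", {
  RX <- RY <- 1:32
  ## two lobes displaced along x: bars run vertically (90 degrees)
  rf_v <- gaussian_rf(c(13, 16), 2, RX, RY) - gaussian_rf(c(19, 16), 2, RX, RY)
  tun_v <- orientation_response(rf_v)
  expect_lt(circ_diff_pi(tun_v$preferred_theta, pi / 2), pi / 16 + 1e-9)

  ## same RF rotated 45 degrees: preferred sector shifts by 4 sectors
  off <- 3 / sqrt(2)
  rf_45 <- gaussian_rf(c(16 - off, 16 - off), 2, RX, RY) -
    gaussian_rf(c(16 + off, 16 + off), 2, RX, RY)
  tun_45 <- orientation_response(rf_45)
  expect_lt(abs(circ_diff_pi(tun_v$preferred_theta, tun_45$preferred_theta) -
                  pi / 4), pi / 16 + 1e-9)

  ## circularly symmetric RF: no orientation signal. The discrete sector
  ## sums keep the grid's four-fold anisotropy, so exact equality holds
  ## between orientations 90 degrees apart (which is what makes CV = 1),
  ## not across all 16 sectors.
  rf_c <- gaussian_rf(c(16, 16), 2, RX, RY)
  tun_c <- orientation_response(rf_c)
  expect_equal(tun_c$sectors[1:8], tun_c$sectors[9:16], tolerance = 0.01)
  expect_gt(tun_c$cv, 0.999)

  ## all-zero RF: undefined preference, flagged
  tun_0 <- orientation_response(matrix(0, 32, 32))
  expect_true(tun_0$flat)
  expect_true(is.na(tun_0$preferred_theta))

  ## 16 sectors of 11.25 degrees each
  expect_equal(length(tun_v$sectors), 16L)
  expect_equal(diff(tun_v$theta)[1L] * 180 / pi, 11.25)
})

test_that("coverage optimization builds 12 candidates and improves coverage", {
  base <- make_sorting_filter(250, 500, 500)
  expect_equal(length(coverage_filters(base)), 4L)

  ## a uniform-orientation cluster gains coverage from optimization
  n <- 24L
  pom <- matrix(pi / 3, n, n)
  clusters <- matrix(1L, n, n)
  opt <- optimize_coverage(pom, clusters, base)
  expect_equal(opt$n_candidates, 12L)
  expect_equal(nrow(unique(expand.grid(alpha = c(0, 45, 90, 135),
                                       beta = c(45, 90, 135)))), 12L)
  expect_gt(orientation_coverage(opt$om[clusters == 1L]),
            orientation_coverage(pom[clusters == 1L]))

  ## degenerate: cluster smaller than the minimum support is skipped
  small <- matrix(0L, n, n); small[1:2, 1:2] <- 1L
  expect_warning(optimize_coverage(pom, small, base), "skipped")
})

test_that("orientation coverage is maximal for a full cycle and zero for a constant", {
  full <- seq(0, pi, length.out = 33L)[-33L]
  expect_equal(orientation_coverage(full), 1)
  expect_equal(orientation_coverage(rep(1.2, 50)), 0)
})

test_that("monocular deprivation shrinks arbors and no-op experiences do nothing", {
  set.seed(1)
  n <- 6L
  sp <- plate_from(eye = rep(c(1, -1), length.out = n * n),
                   polarity = rep(c(1, 1, -1, -1), length.out = n * n),
                   rx = runif(n * n, 0, 30), ry = runif(n * n, 0, 30),
                   shape = c(n, n))
  sheet <- spread_arbors(sp, sigma_arbor = 3, radius = 5)
  expect_identical(apply_experience(sheet, "normal")$W, sheet$W)
  expect_identical(apply_experience(sheet, "orientation_bias", pcl = 0)$W,
                   sheet$W)
  dep <- apply_experience(sheet, "monocular_deprivation", deprived_eye = -1)
  ipsi_rows <- which(sp$afferents$eye == -1)
  con_rows <- which(sp$afferents$eye == 1)
  expect_lt(sum(dep$W[ipsi_rows, ]), sum(sheet$W[ipsi_rows, ]))
  expect_equal(sum(dep$W[con_rows, ]), sum(sheet$W[con_rows, ]))
  ## a weight of exactly 1 (arbor centre) is unchanged by w^5 renormalized
  expect_equal(dep$W[ipsi_rows[1L], ipsi_rows[1L]], 1)
  expect_error(apply_experience(sheet, "orientation_bias", pcl = 2), "pcl")
})

test_that("OD-map-seeded simulation yields orthogonal gradients and per-patch pinwheels", {
  stripes <- make_fixtures("stripe_od", n = 64L, period = 16L)
  res <- simulate_from_od_map(stripes, seed = 2L)
  expect_identical(res$ODM, stripes)
  ## same raster and seed reproduce the map exactly
  res2 <- simulate_from_od_map(stripes, seed = 2L)
  expect_identical(res$OM, res2$OM)
  ## iso-orientation lines tend to cross the OD stripes orthogonally;
  ## the tendency is weak per map, so angles are pooled across seeds
  smooth_od <- matrix(sin(2 * pi * (col(stripes) - 1) / 16), 64L, 64L)
  angs <- unlist(lapply(1:5, function(sd) {
    r <- simulate_from_od_map(stripes, seed = sd)
    gradient_intersection_angles(r$OM, smooth_od)$angles
  }))
  counts <- table(cut(angs, seq(0, 90, 10), include.lowest = TRUE))
  expect_gt((counts[[9L]] + 0.5) / (counts[[1L]] + 0.5), 1)

  beaded <- make_fixtures("beaded_od", seed = 5L, n = 48L, period = 20L)
  resb <- simulate_from_od_map(beaded, seed = 5L)
  om4 <- upsample_orientation(resb$OM, 2L)
  pw <- find_pinwheels(om4, pitch_um = 25)
  n_patches <- max(afferent_clusters(subplate_from_rasters_test(beaded)))
  expect_gte(nrow(pw$pinwheels) / n_patches, 1)

  expect_error(simulate_from_od_map(matrix(1, 10, 10)), "blank")
})

test_that("retinotopic-sector simulation fits elongated domains to elongated sectors", {
  res <- simulate_from_retinotopic_sectors(seed = 1L)
  expect_equal(max(res$sectors), 12L)              # 3 + 3 lines, clipped outline
  expect_true(all(is.na(res$OM[!res$outline])))

  ## single square sector: roughly isotropic domains, about one cycle
  sq <- simulate_from_retinotopic_sectors(outline = matrix(TRUE, 32L, 32L),
                                          azimuth_lines = 0L,
                                          elevation_lines = 0L, seed = 2L)
  expect_equal(max(sq$sectors), 1L)
  expect_gt(orientation_coverage(sq$OM), 0.5)      # fits an orientation cycle
  iso <- orientation_corr_lengths(sq$OM)
  expect_lt(abs(log(iso["x"] / iso["y"])), log(2))

  ## 2:1 sector: domains elongated along the sector's long axis
  el <- simulate_from_retinotopic_sectors(outline = matrix(TRUE, 32L, 64L),
                                          azimuth_lines = 0L,
                                          elevation_lines = 0L, seed = 2L)
  al <- orientation_corr_lengths(el$OM)
  expect_gt(al["y"] / al["x"], 1.3)
})

test_that("identical sheets give identical primordial maps", {
  set.seed(4)
  n <- 8L
  sp <- plate_from(eye = rep(c(1, -1), length.out = n * n),
                   polarity = sample(c(1, -1), n * n, TRUE),
                   rx = runif(n * n, 5, 35), ry = runif(n * n, 5, 35),
                   shape = c(n, n))
  sheet <- spread_arbors(sp, sigma_arbor = 2, radius = 4)
  p1 <- primordial_map(sheet, window = 16L)
  p2 <- primordial_map(sheet, window = 16L)
  expect_identical(p1$pom, p2$pom)
  expect_identical(p1$dominant, p2$dominant)
})
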