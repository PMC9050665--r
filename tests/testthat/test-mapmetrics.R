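test_that("circular variance handles flat, sharp and paired-orthogonal tuning", {
  theta16 <- (0:15) * pi / 16
  expect_equal(circular_variance(rep(3, 16), theta16), 1)
  one <- rep(0, 16); one[5L] <- 7
  expect_equal(circular_variance(one, theta16), 0)
  two <- rep(0, 16); two[1L] <- 5; two[9L] <- 5    # orthogonal pair cancels
  expect_equal(circular_variance(two, theta16), 1)
  expect_warning(cv0 <- circular_variance(rep(0, 16), theta16), "undefined")
  expect_true(is.na(cv0))
  expect_error(circular_variance(c(-1, 2)), "non-negative")
})

test_that("local homogeneity index matches a direct evaluation of its formula", {
  ## uniform map: exactly 1 everywhere
  u <- matrix(0.7, 12L, 12L)
  expect_equal(local_homogeneity_index(u), matrix(1, 12L, 12L))

  ## direct-formula oracle at one pixel of an alternating 0/90-degree map
  om <- matrix(0, 9L, 9L)
  om[, seq(2L, 9L, 2L)] <- pi / 2
  px <- c(5L, 5L)
  sigma_um <- 100; pitch <- 50
  acc <- 0 + 0i; k <- 0
  for (i in 1:9) for (j in 1:9) {
    d <- sqrt((i - px[1L])^2 + (j - px[2L])^2) * pitch
    if (d <= sigma_um) {
      w <- exp(-d^2 / (2 * sigma_um^2))
      acc <- acc + w * exp(2i * om[i, j])
      k <- k + w
    }
  }
  expect_equal(local_homogeneity_index(om, pixel = px), Mod(acc) / k,
               tolerance = 1e-12)
  ## alternating halves largely cancel
  expect_lt(local_homogeneity_index(om, pixel = px), 0.35)

  ## random orientations: low homogeneity on average
  set.seed(10)
  vals <- replicate(200, {
    m <- matrix(runif(81, 0, pi), 9L, 9L)
    local_homogeneity_index(m, pixel = c(5L, 5L))
  })
  expect_lt(mean(vals), 0.3)
})

test_that("SF50 and LPI read the right features of a tuning curve", {
  ## pure low-pass: maximum at 0, halving exactly at 0.5 cpd
  sf <- seq(0, 2, by = 0.05)
  resp <- 2^(-(sf / 0.5))
  m <- sf_metrics(sf, resp)
  expect_equal(m$lpi, 1)
  expect_equal(m$sf50, 0.5, tolerance = 1e-9)
  expect_false(m$censored)

  ## band-pass with zero response at zero SF
  bp <- exp(-(sf - 1)^2 / 0.1); bp[1L] <- 0
  expect_equal(sf_metrics(sf, bp)$lpi, 0)

  ## rectangular response over 0.2-0.8 cpd: upper half-max crossing ~ 0.8
  sf2 <- seq(0, 1.2, by = 0.01)
  rect <- as.numeric(sf2 >= 0.2 & sf2 <= 0.8)
  expect_equal(sf_metrics(sf2, rect)$sf50, 0.8, tolerance = 0.011)

  ## censored: response still above half max at the end of the grid
  mono <- seq(0.5, 1, length.out = length(sf))
  expect_true(sf_metrics(sf, mono)$censored)
})

test_that("ocular dominance index is the dominant/non-dominant weight ratio", {
  expect_equal(ocular_dominance_index(c(0.5, 0.5), c(0.5, 0.5))$odi, 1)
  expect_equal(ocular_dominance_index(0.8, 0.4)$odi, 2)
  mono <- ocular_dominance_index(c(1, 1), numeric(0))
  expect_true(mono$monocular)
  expect_equal(mono$odi, Inf)
})

test_that("pinwheel detection finds constructed singularities with the right sign", {
  pwf <- make_fixtures("pinwheel_field", n = 21L)
  res <- find_pinwheels(pwf)
  expect_equal(nrow(res$pinwheels), 1L)
  expect_equal(res$pinwheels$sign, 1L)               # counter-clockwise
  expect_equal(res$pinwheels$x, 10.5, tolerance = 0.1)
  expect_equal(res$pinwheels$y, 10.5, tolerance = 0.1)
  ## mirroring flips the winding direction
  resm <- find_pinwheels(pwf[, 21:1])
  expect_equal(resm$pinwheels$sign, -1L)

  ## total signed charge over a periodic map is zero (count with wrap-around)
  set.seed(2)
  n <- 32L
  z <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  F <- stats::fft(z)
  keep <- outer(c(0:(n / 2), (n / 2 - 1):1), c(0:(n / 2), (n / 2 - 1):1),
                function(a, b) sqrt(a^2 + b^2)) < 6
  om <- (Arg(stats::fft(F * keep, inverse = TRUE)) / 2) %% pi
  wrapped <- rbind(cbind(om, om[, 1L]), c(om[1L, ], om[1L, 1L]))
  expect_equal(sum(find_pinwheels(wrapped)$pinwheels$sign), 0)
})

test_that("map periodicity recovers constructed wavelengths and isotropy", {
  n <- 60L
  px <- 50
  ## plane-wave orientation map with a 1 mm period (20 pixels)
  om <- (pi * ((row(matrix(0, n, n)) - 1) %% 20) / 20) %% pi
  mp <- map_periodicity(om, pitch_um = px)
  expect_equal(mp$wavelength_um, 1000, tolerance = 0.1)
  ## rotation by 90 degrees leaves the radially averaged wavelength unchanged
  mp_rot <- map_periodicity(t(om), pitch_um = px)
  expect_equal(mp$wavelength_um, mp_rot$wavelength_um, tolerance = 1e-9)

  ## white-noise map: no prominent peak relative to its own shuffle
  set.seed(3)
  noise <- matrix(runif(n * n, 0, pi), n, n)
  prominence <- function(m) {
    p <- map_periodicity(m, pitch_um = px)$power
    max(p[-1L]) / mean(p[-1L])
  }
  shuffled <- matrix(sample(noise), n, n)
  expect_lt(prominence(noise), 1.5 * prominence(shuffled))
  expect_gt(prominence(om), 2 * prominence(noise))
})

test_that("gradient intersection angles separate orthogonal, parallel and random cases", {
  n <- 48L
  stripes <- matrix(sin(2 * pi * (col(matrix(0, n, n)) - 1) / 16), n, n)
  ## orientation plane wave varying along x: iso-lines along y, orthogonal
  ## to the OD stripe borders (which run along x)
  om_orth <- (pi * (row(matrix(0, n, n)) - 1) / 12) %% pi
  expect_gt(gradient_intersection_angles(om_orth, stripes)$orthogonality_ratio, 5)
  ## varying along y: iso-lines parallel to the borders
  om_par <- (pi * (col(matrix(0, n, n)) - 1) / 12) %% pi
  expect_lt(gradient_intersection_angles(om_par, stripes)$orthogonality_ratio, 0.2)

  ## random maps: no orthogonality bias on average
  set.seed(4)
  logr <- replicate(50, {
    z <- matrix(rnorm(n * n), n, n)
    k <- exp(-outer((-9:9)^2, (-9:9)^2, "+") / 8)
    a <- cortimap:::conv2_same(z, k)
    b <- cortimap:::conv2_same(matrix(rnorm(n * n), n, n), k)
    om <- (atan2(a, b) / 2) %% pi
    log(gradient_intersection_angles(om, stripes)$orthogonality_ratio)
  })
  expect_lt(abs(mean(logr)), 0.35)
  expect_error(gradient_intersection_angles(matrix(0, 4, 4), matrix(0, 4, 4)))
})

test_that("pattern similarity error is zero for identical and translated patches", {
  set.seed(5)
  n <- 32L
  k <- exp(-outer((-6:6)^2, (-6:6)^2, "+") / 6)
  a <- cortimap:::conv2_same(matrix(rnorm(n * n), n, n), k)
  expect_equal(pattern_similarity_error(a, a), 0)
  ## circular translation: amplitude spectrum invariant
  shift <- a[c(9:n, 1:8), c(5:n, 1:4)]
  expect_lt(pattern_similarity_error(a, shift), 1e-9)
  ## symmetry
  b <- cortimap:::conv2_same(matrix(rnorm(n * n), n, n), k)
  expect_equal(pattern_similarity_error(a, b), pattern_similarity_error(b, a))
  ## independent white-noise patches: error near 1
  errs <- replicate(20, {
    pattern_similarity_error(matrix(rnorm(n * n), n, n),
                             matrix(rnorm(n * n), n, n))
  })
  expect_gt(mean(errs), 0.8)
  expect_error(pattern_similarity_error(matrix(1, 4, 4), matrix(1, 4, 4)),
               "constant")
})

test_that("track screening passes everything under empty criteria", {
  set.seed(6)
  n <- 50L
  maps <- list(cv = matrix(runif(n * n), n, n),
               sf50 = matrix(runif(n * n), n, n),
               lpi = matrix(runif(n * n), n, n),
               lhi = matrix(runif(n * n), n, n))
  all_pass <- screen_simulated_tracks(maps, n_tracks = 50L, track_len = 40L,
                                      strength = 0, n_required = 0L,
                                      check_sign = FALSE, seed = 2L)
  expect_equal(all_pass$n_pass, 50L)
  ## random maps essentially never satisfy 5 strong signed correlations
  strict <- screen_simulated_tracks(maps, n_tracks = 100L, strength = 0.5,
                                    n_required = 5L, seed = 2L)
  expect_lt(strict$n_pass, 3L)
  expect_error(screen_simulated_tracks(maps, track_len = 60L), "too small")
})

test_that("CV, LHI and LPI remain in [0, 1] under fuzzing", {
  set.seed(7)
  for (i in 1:50) {
    resp <- runif(16, 0, 10^runif(1, -3, 3))
    cv <- circular_variance(resp)
    expect_true(cv >= 0 && cv <= 1)
    om <- matrix(runif(36, 0, pi), 6L, 6L)
    lhi <- local_homogeneity_index(om)
    expect_true(all(lhi >= 0 & lhi <= 1))
    sf <- sort(runif(10, 0, 2)); sf[1L] <- 0
    m <- sf_metrics(sf, runif(10))
    expect_true(is.na(m$lpi) || (m$lpi >= 0 && m$lpi <= 1))
  }
})
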