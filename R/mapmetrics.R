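## Map-level statistics: circular variance, local homogeneity index, SF50 /
## LPI / ODI, pinwheel detection, map periodicity, gradient intersection
## angles, FFT pattern similarity, and simulated-track screening.

#' Circular variance of orientation responses
#'
#' `CV = 1 - |sum(R * exp(2i theta)) / sum(R)|` over the sampled
#' orientations; 1 means flat tuning, 0 a single-orientation response.
#'
#' @param responses non-negative responses per orientation.
#' @param theta orientations in radians (mod pi); defaults to an equal grid.
#' @return CV in `[0, 1]`; `NA` (with a warning) for all-zero responses.
#' @export
circular_variance <- function(responses,
                              theta = (seq_along(responses) - 1) * pi / length(responses)) {
  if (length(responses) < 2L) stop("need responses for at least 2 orientations")
  if (any(responses < 0)) stop("responses must be non-negative")
  tot <- sum(responses)
  if (tot == 0) {
    warning("all responses zero; circular variance undefined")
    return(NA_real_)
  }
  1 - Mod(sum(responses * exp(2i * theta))) / tot
}

#' Local homogeneity index of an orientation map
#'
#' `LHI = k * |sum_j exp(-d_j^2 / (2 sigma^2)) * exp(2i theta_j)|` over the
#' map locations within a circular radius `sigma` of each pixel, with `k`
#' normalizing a fully uniform patch to exactly 1.
#'
#' @param OM orientation map (radians mod pi).
#' @param pixel optional `c(x, y)`; when given, returns the scalar LHI there.
#' @param sigma_um radius / Gaussian SD in microns (default 100).
#' @param pitch_um map pixel pitch in microns (default 50).
#' @return LHI map matrix (or scalar for one pixel), values in `[0, 1]`.
#' @export
local_homogeneity_index <- function(OM, pixel = NULL, sigma_um = 100,
                                    pitch_um = 50) {
  h <- as.integer(floor(sigma_um / pitch_um))
  off <- (-h):h
  D2 <- outer(off^2, off^2, "+") * pitch_um^2
  G <- exp(-D2 / (2 * sigma_um^2))
  G[sqrt(D2) > sigma_um] <- 0
  num_c <- conv2_same(cos(2 * OM), G)
  num_s <- conv2_same(sin(2 * OM), G)
  den <- conv2_same(matrix(1, nrow(OM), ncol(OM)), G)  # per-pixel k^-1
  lhi <- sqrt(num_c^2 + num_s^2) / den
  lhi <- pmin(lhi, 1)
  if (!is.null(pixel)) return(lhi[pixel[1L], pixel[2L]])
  lhi
}

#' Permutation test for orientation clustering
#'
#' Tests whether a map's mean local homogeneity index exceeds that of a
#' spatially shuffled control. Because thalamocortical convergence makes
#' neighbouring pixels pool largely the same afferents, short-range
#' smoothness is present in any convergent model regardless of map
#' organization; the shuffle therefore permutes blocks of `block` pixels
#' (the pooling scale) rather than single pixels, so the null preserves
#' the trivial within-pool smoothness and the test is sensitive to
#' orientation organization beyond it.
#'
#' @param om orientation map (radians mod pi).
#' @param block shuffle block side in pixels (default 8, ~400 um: the axon
#'   arbor scale).
#' @param n_perm permutations (default 200).
#' @param sigma_um,pitch_um passed to [local_homogeneity_index()].
#' @param seed integer seed.
#' @return list with `observed` (mean LHI), `null_mean`, `p` (one-sided).
#' @export
orientation_clustering_test <- function(om, block = 8L, n_perm = 200L,
                                        sigma_um = 100, pitch_um = 50,
                                        seed = 1L) {
  nbx <- nrow(om) %/% block; nby <- ncol(om) %/% block
  if (nbx * nby < 4L) stop("map too small for block permutation")
  om <- om[seq_len(nbx * block), seq_len(nby * block), drop = FALSE]
  stat <- function(m) mean(local_homogeneity_index(m, sigma_um = sigma_um,
                                                   pitch_um = pitch_um))
  obs <- stat(om)
  null <- with_seed(sub_seed(seed, "clustering-null"), {
    vapply(seq_len(n_perm), function(i) {
      perm <- sample.int(nbx * nby)
      shuf <- om
      for (k in seq_len(nbx * nby)) {
        src <- perm[k]
        bx_d <- (k - 1L) %% nbx; by_d <- (k - 1L) %/% nbx
        bx_s <- (src - 1L) %% nbx; by_s <- (src - 1L) %/% nbx
        shuf[bx_d * block + seq_len(block), by_d * block + seq_len(block)] <-
          om[bx_s * block + seq_len(block), by_s * block + seq_len(block)]
      }
      stat(shuf)
    }, numeric(1))
  })
  list(observed = obs, null_mean = mean(null),
       p = (1 + sum(null >= obs)) / (n_perm + 1))
}

#' Spatial-frequency metrics from a tuning curve
#'
#' `SF50` is the highest spatial frequency whose response reaches half the
#' maximum, interpolated linearly on log spatial frequency between grid
#' points; `LPI` is the response at zero spatial frequency divided by the
#' maximum response.
#'
#' @param sf spatial frequencies (cpd), ascending, ideally including 0.
#' @param resp responses at `sf`.
#' @return list with `sf50`, `lpi`, `pref_sf`, and `censored` (TRUE when the
#'   response has not fallen to half maximum by the highest sampled
#'   frequency).
#' @export
sf_metrics <- function(sf, resp) {
  stopifnot(length(sf) == length(resp), !is.unsorted(sf))
  mx <- max(resp)
  if (mx <= 0) return(list(sf50 = NA_real_, lpi = NA_real_,
                           pref_sf = NA_real_, censored = TRUE))
  half <- mx / 2
  lpi <- if (sf[1L] == 0) resp[1L] / mx else NA_real_
  pref_sf <- sf[which.max(resp)]
  n <- length(sf)
  ab <- resp >= half
  ## ignore isolated single-sample excursions above half maximum: a lone
  ## grid point with both neighbours below half is sampling noise, not a
  ## half-maximal response band
  if (n >= 3L) {
    iso <- ab & !c(FALSE, ab[-n]) & !c(ab[-1L], FALSE)
    iso[which.max(resp)] <- FALSE           # never drop the peak itself
    ab[iso] <- FALSE
  }
  above <- which(ab)
  i <- max(above)
  if (i == n) {
    return(list(sf50 = sf[n], lpi = lpi, pref_sf = pref_sf, censored = TRUE))
  }
  ## interpolate the downward half-max crossing between sf[i] and sf[i+1]
  f <- (resp[i] - half) / (resp[i] - resp[i + 1L])
  sf50 <- if (sf[i] > 0) exp(log(sf[i]) + f * (log(sf[i + 1L]) - log(sf[i])))
          else sf[i] + f * (sf[i + 1L] - sf[i])
  list(sf50 = sf50, lpi = lpi, pref_sf = pref_sf, censored = FALSE)
}

#' Ocular dominance index
#'
#' Average afferent weight from the dominant eye divided by the average
#' weight from the non-dominant eye (>= 1 by construction).
#'
#' @param weights_dom_eye,weights_nondom_eye afferent weight vectors.
#' @return list with `odi` and `monocular` (TRUE when the non-dominant eye
#'   contributes no weight, ODI infinite).
#' @export
ocular_dominance_index <- function(weights_dom_eye, weights_nondom_eye) {
  md <- mean(weights_dom_eye); mn <- mean(weights_nondom_eye)
  if (length(weights_nondom_eye) == 0L || mn == 0) {
    return(list(odi = Inf, monocular = TRUE))
  }
  list(odi = md / mn, monocular = FALSE)
}

#' Locate orientation pinwheels
#'
#' Finds the singular points of an orientation map: 2x2 plaquettes around
#' which the summed (wrapped) orientation difference equals +-pi. Sign +1 is
#' counter-clockwise winding.
#'
#' @param OM orientation map (radians mod pi).
#' @param pitch_um pixel pitch in microns (for density / distances).
#' @return list with `pinwheels` (data.frame `x`, `y`, `sign`; plaquette
#'   centres in pixel units), `density_mm2`, and nearest-neighbour distance
#'   summaries `same_sign_dist_um` / `opposite_sign_dist_um`.
#' @export
find_pinwheels <- function(OM, pitch_um = 50) {
  nx <- nrow(OM); ny <- ncol(OM)
  wrap <- function(d) (d + pi) %% (2 * pi) - pi   # doubled-angle wrap
  t2 <- 2 * OM
  ## corners ordered counter-clockwise in (x up, y right) convention
  a <- t2[-nx, -ny]; b <- t2[-1L, -ny]; cc <- t2[-1L, -1L]; d <- t2[-nx, -1L]
  wind <- wrap(b - a) + wrap(cc - b) + wrap(d - cc) + wrap(a - d)
  sgn <- round(wind / (2 * pi))
  idx <- which(sgn != 0, arr.ind = TRUE)
  pw <- data.frame(x = idx[, 1L] + 0.5, y = idx[, 2L] + 0.5,
                   sign = sgn[idx])
  area_mm2 <- (nx * pitch_um / 1000) * (ny * pitch_um / 1000)
  res <- list(pinwheels = pw, density_mm2 = nrow(pw) / area_mm2,
              same_sign_dist_um = NA_real_, opposite_sign_dist_um = NA_real_)
  if (nrow(pw) >= 2L) {
    dx <- outer(pw$x, pw$x, "-"); dy <- outer(pw$y, pw$y, "-")
    dm <- sqrt(dx^2 + dy^2) * pitch_um
    diag(dm) <- Inf
    same <- outer(pw$sign, pw$sign, "==")
    nnd <- function(mask) {
      m <- dm; m[!mask] <- Inf
      v <- apply(m, 1L, min)
      v <- v[is.finite(v)]
      if (length(v)) mean(v) else NA_real_
    }
    res$same_sign_dist_um <- nnd(same)
    res$opposite_sign_dist_um <- nnd(!same)
  }
  res
}

#' Dominant wavelength and domain spacing of an orientation map
#'
#' Radially averaged power spectrum of the doubled-angle complex map; the
#' spectral peak gives the dominant wavelength. Orientation-domain
#' peak-to-peak spacing is the mean nearest-neighbour distance between local
#' maxima of the cos(2 OM) component.
#'
#' @param OM orientation map (radians mod pi).
#' @param pitch_um pixel pitch in microns.
#' @return list with `wavelength_um`, `domain_spacing_um`, the radial
#'   spectrum (`freq` cycles/pixel, `power`), and `censored` (map smaller
#'   than ~3 wavelengths).
#' @export
map_periodicity <- function(OM, pitch_um = 50) {
  z <- exp(2i * OM)
  z <- z - mean(z)
  n1 <- nrow(OM); n2 <- ncol(OM)
  P <- Mod(stats::fft(z))^2
  f1 <- c(0:(n1 %/% 2), -((n1 - n1 %/% 2 - 1):1)) / n1
  f2 <- c(0:(n2 %/% 2), -((n2 - n2 %/% 2 - 1):1)) / n2
  FR <- sqrt(outer(f1^2, f2^2, "+"))
  nb <- min(n1, n2) %/% 2
  edges <- seq(0, 0.5, length.out = nb + 1L)
  bin <- cut(FR, edges, include.lowest = TRUE, labels = FALSE)
  pw <- tapply(as.vector(P), as.vector(bin), mean)
  freq <- (edges[-1L] + edges[-length(edges)]) / 2
  power <- rep(0, nb); power[as.integer(names(pw))] <- pw
  pk <- which.max(power[-1L]) + 1L      # exclude the near-DC bin
  ## refine the peak frequency within the winning bin and its neighbours
  ## (bin centres alone quantize the wavelength)
  nb_idx <- bin %in% (pk + c(-1L, 0L, 1L)) & FR > 0
  f_pk <- sum(P[nb_idx] * FR[nb_idx]) / sum(P[nb_idx])
  wavelength_um <- pitch_um / f_pk
  censored <- min(n1, n2) * pitch_um < 3 * wavelength_um
  ## domain peaks: local maxima of the cos component
  cc <- cos(2 * OM)
  is_max <- matrix(TRUE, n1, n2)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    sh <- matrix(-Inf, n1, n2)
    xs <- max(1, 1 + dx):min(n1, n1 + dx)
    ys <- max(1, 1 + dy):min(n2, n2 + dy)
    sh[xs, ys] <- cc[xs - dx, ys - dy]
    is_max <- is_max & (cc >= sh)
  }
  pk_idx <- which(is_max & cc > stats::quantile(cc, 0.6), arr.ind = TRUE)
  domain_spacing_um <- NA_real_
  if (nrow(pk_idx) >= 2L) {
    dmat <- sqrt(outer(pk_idx[, 1L], pk_idx[, 1L], "-")^2 +
                   outer(pk_idx[, 2L], pk_idx[, 2L], "-")^2)
    diag(dmat) <- Inf
    domain_spacing_um <- mean(apply(dmat, 1L, min)) * pitch_um
  }
  list(wavelength_um = wavelength_um, domain_spacing_um = domain_spacing_um,
       freq = freq, power = power, censored = censored)
}

#' Intersection angles between iso-orientation lines and OD borders
#'
#' The angle between an iso-orientation line and an ocular-dominance contour
#' equals the angle between the two map gradients. Gradients are evaluated
#' with centred differences (orientation differences wrapped mod pi) and
#' sampled at pixels lying near the OD contour levels (25, 50 and 75 percent
#' of the absolute maximum, both signs).
#'
#' @param OM orientation map (radians mod pi).
#' @param ODM ocular dominance map (signed), same shape.
#' @param n_bins histogram bins over 0..90 degrees (default 9).
#' @param levels contour levels as fractions of `max(abs(ODM))`.
#' @return list with `angles` (degrees), the histogram `counts`, `breaks`,
#'   and `orthogonality_ratio` = freq(90 deg bin) / freq(0 deg bin).
#' @export
gradient_intersection_angles <- function(OM, ODM, n_bins = 9L,
                                         levels = c(0.25, 0.5, 0.75)) {
  stopifnot(all(dim(OM) == dim(ODM)))
  nx <- nrow(OM); ny <- ncol(OM)
  wrapd <- function(d) ((d + pi / 2) %% pi) - pi / 2
  gx_om <- matrix(0, nx, ny); gy_om <- matrix(0, nx, ny)
  gx_om[2:(nx - 1), ] <- wrapd(OM[3:nx, ] - OM[1:(nx - 2), ]) / 2
  gy_om[, 2:(ny - 1)] <- wrapd(OM[, 3:ny] - OM[, 1:(ny - 2)]) / 2
  gx_od <- matrix(0, nx, ny); gy_od <- matrix(0, nx, ny)
  gx_od[2:(nx - 1), ] <- (ODM[3:nx, ] - ODM[1:(nx - 2), ]) / 2
  gy_od[, 2:(ny - 1)] <- (ODM[, 3:ny] - ODM[, 1:(ny - 2)]) / 2
  mx <- max(abs(ODM))
  lv <- c(-levels, levels) * mx
  tol <- 0.05 * mx
  near <- Reduce(`|`, lapply(lv, function(l) abs(ODM - l) <= tol))
  mag_om <- sqrt(gx_om^2 + gy_om^2)
  mag_od <- sqrt(gx_od^2 + gy_od^2)
  use <- near & mag_om > 1e-9 & mag_od > 1e-9
  use[c(1L, nx), ] <- FALSE; use[, c(1L, ny)] <- FALSE
  if (!any(use)) stop("no contour intersections found")
  a_om <- atan2(gy_om[use], gx_om[use]) %% pi
  a_od <- atan2(gy_od[use], gx_od[use]) %% pi
  ang <- circ_diff_pi(a_om, a_od) * 180 / pi   # 0..90 degrees
  breaks <- seq(0, 90, length.out = n_bins + 1L)
  counts <- as.vector(table(cut(ang, breaks, include.lowest = TRUE)))
  ratio <- (counts[n_bins] + 0.5) / (counts[1L] + 0.5)
  list(angles = ang, counts = counts, breaks = breaks,
       orthogonality_ratio = ratio)
}

#' FFT pattern-similarity error between two map patches
#'
#' One minus the correlation between the FFT amplitude spectra of the two
#' patches (DC removed): 0 for identical patches (and for translated copies,
#' since amplitude spectra are translation invariant), about 1 for
#' independent patterns.
#'
#' @param mapA,mapB equal-shape numeric matrices.
#' @return error in `[0, 1]` (clipped).
#' @export
pattern_similarity_error <- function(mapA, mapB) {
  stopifnot(all(dim(mapA) == dim(mapB)))
  if (stats::sd(mapA) == 0 || stats::sd(mapB) == 0) {
    stop("constant patch: pattern correlation undefined")
  }
  a <- Mod(stats::fft(mapA - mean(mapA)))
  b <- Mod(stats::fft(mapB - mean(mapB)))
  a[1L, 1L] <- NA; b[1L, 1L] <- NA
  r <- stats::cor(as.vector(a), as.vector(b), use = "complete.obs")
  min(max(1 - r, 0), 1)
}

#' Largest SF50 change within a horizontal window
#'
#' Scans horizontal tracks of the SF50 map with a sliding window of `win`
#' pixels (400 um at the default 50-um pitch and `win = 8`) and returns the
#' largest within-window range. `border` excludes a frame of pixels first:
#' pixels closer to the plate edge than the axon arbor radius have clipped
#' arbors, a boundary artefact whose share of the map vanishes at full
#' scale but dominates extreme-value statistics on reduced plates.
#'
#' @param sf50 SF50 map (cpd).
#' @param win window length in pixels (default 8).
#' @param border border width in pixels to exclude (default 0).
#' @return the maximum within-window SF50 range (cpd).
#' @export
sf50_window_range <- function(sf50, win = 8L, border = 0L) {
  if (border > 0L) {
    keep_r <- (border + 1L):(nrow(sf50) - border)
    keep_c <- (border + 1L):(ncol(sf50) - border)
    sf50 <- sf50[keep_r, keep_c, drop = FALSE]
  }
  if (ncol(sf50) < win) stop("map narrower than the window")
  mx <- 0
  for (i in seq_len(nrow(sf50))) {
    v <- sf50[i, ]
    for (j in seq_len(length(v) - win + 1L)) {
      r <- diff(range(v[j:(j + win - 1L)], na.rm = TRUE))
      if (is.finite(r)) mx <- max(mx, r)
    }
  }
  mx
}

#' Expected correlation signs between stimulus-map dimensions
#'
#' Signs of the pairwise correlations among circular variance (cv),
#' spatial resolution (sf50), low-pass index (lpi) and local homogeneity
#' (lhi) used by the track screening; configurable rather than hard-coded.
#' @return named numeric vector of +-1 per dimension pair.
#' @export
track_correlation_signs <- function() {
  c("cv:sf50" = -1, "cv:lpi" = 1, "cv:lhi" = -1,
    "sf50:lpi" = -1, "sf50:lhi" = 1, "lpi:lhi" = -1)
}

#' Screen simulated recording tracks for correlated map gradients
#'
#' Samples straight tracks of `track_len` cortical pixels at random
#' positions and directions, computes all pairwise rank correlations among
#' the four stimulus dimensions (cv, sf50, lpi, lhi) along each track, and
#' counts the tracks satisfying the criteria: at least `n_required` pairwise
#' correlations with `|r| >= strength` (with the expected sign when
#' `check_sign`), and, when `ranges` is given, a per-dimension value range
#' of at least `range_frac` times the reference range.
#'
#' @param maps list with matrices `cv`, `sf50`, `lpi`, `lhi` (equal shape).
#' @param n_tracks number of tracks (default 1000).
#' @param track_len pixels per track (default 40).
#' @param strength correlation strength threshold.
#' @param n_required number of qualifying pairs required (3-5 of the 6).
#' @param check_sign require the expected correlation signs.
#' @param ranges optional named reference ranges (cv, sf50, lpi, lhi).
#' @param range_frac fraction of the reference range required (default 0.2).
#' @param signs expected signs, see [track_correlation_signs()].
#' @param seed integer seed.
#' @return list with `n_pass`, `n_tracks`, and the per-track logical `pass`.
#' @export
screen_simulated_tracks <- function(maps, n_tracks = 1000L, track_len = 40L,
                                    strength = 0.5, n_required = 5L,
                                    check_sign = TRUE, ranges = NULL,
                                    range_frac = 0.2,
                                    signs = track_correlation_signs(),
                                    seed = 1L) {
  dims <- c("cv", "sf50", "lpi", "lhi")
  stopifnot(all(dims %in% names(maps)))
  nx <- nrow(maps$cv); ny <- ncol(maps$cv)
  if (min(nx, ny) <= track_len) stop("map too small for the track length")
  pairs <- utils::combn(dims, 2L)
  pass <- logical(n_tracks)
  with_seed(sub_seed(seed, "tracks"), {
    t_i <- 0L
    while (t_i < n_tracks) {
      x0 <- stats::runif(1, 1, nx); y0 <- stats::runif(1, 1, ny)
      a <- stats::runif(1, 0, 2 * pi)
      xs <- round(x0 + (seq_len(track_len) - 1L) * cos(a))
      ys <- round(y0 + (seq_len(track_len) - 1L) * sin(a))
      if (any(xs < 1 | xs > nx | ys < 1 | ys > ny)) next  # resample
      t_i <- t_i + 1L
      idx <- cbind(xs, ys)
      vals <- lapply(maps[dims], function(m) m[idx])
      ok_n <- 0L
      for (p in seq_len(ncol(pairs))) {
        d1 <- pairs[1L, p]; d2 <- pairs[2L, p]
        r <- suppressWarnings(
          stats::cor(vals[[d1]], vals[[d2]], method = "spearman"))
        if (is.na(r)) next
        want <- signs[[paste0(d1, ":", d2)]]
        good <- abs(r) >= strength && (!check_sign || sign(r) == want)
        if (good) ok_n <- ok_n + 1L
      }
      ok_range <- TRUE
      if (!is.null(ranges)) {
        for (d1 in dims) {
          if (diff(range(vals[[d1]])) < range_frac * ranges[[d1]]) {
            ok_range <- FALSE
            break
          }
        }
      }
      pass[t_i] <- ok_n >= n_required && ok_range
    }
  })
  list(n_pass = sum(pass), n_tracks = n_tracks, pass = pass)
}

#' Compare two track-screening outcomes
#'
#' Chi-squared test on the pass/fail counts of two screening runs (e.g.
#' with and without afferent sorting).
#'
#' @param a,b results from [screen_simulated_tracks()].
#' @return the `htest` object from [stats::chisq.test()].
#' @export
compare_track_screens <- function(a, b) {
  tab <- rbind(c(a$n_pass, a$n_tracks - a$n_pass),
               c(b$n_pass, b$n_tracks - b$n_pass))
  stats::chisq.test(tab)
}
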