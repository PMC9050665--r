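## Species-map simulation modes: seeding the subplate from a binary ocular
## dominance raster, or from iso-retinotopic sectors drawn on an outline.

## pseudo-subplate whose afferents are one-per-pixel with given eye and
## polarity values (used by the raster-seeded simulation modes)
subplate_from_rasters <- function(eye, polarity) {
  nx <- nrow(eye); ny <- ncol(eye)
  aff <- data.frame(eye = as.vector(eye), polarity = as.vector(polarity),
                    rx = as.vector(row(eye)), ry = as.vector(col(eye)),
                    sigma = 1)
  structure(list(occupancy = matrix(seq_len(nx * ny), nx, ny),
                 active = matrix(TRUE, nx, ny),
                 afferents = aff, shape = c(nx, ny),
                 pitch_um = SLOT_PITCH_UM),
            class = "subplate")
}

## dominant wavelength (pixels) of a signed domain raster
domain_wavelength_px <- function(m) {
  z <- m - mean(m)
  n1 <- nrow(m); n2 <- ncol(m)
  P <- Mod(stats::fft(z))^2
  f1 <- c(0:(n1 %/% 2), -((n1 - n1 %/% 2 - 1):1)) / n1
  f2 <- c(0:(n2 %/% 2), -((n2 - n2 %/% 2 - 1):1)) / n2
  FR <- sqrt(outer(f1^2, f2^2, "+"))
  nb <- min(n1, n2) %/% 2
  edges <- seq(0, 0.5, length.out = nb + 1L)
  bin <- cut(FR, edges, include.lowest = TRUE, labels = FALSE)
  pw <- tapply(as.vector(P), as.vector(bin), mean)
  power <- rep(0, nb); power[as.integer(names(pw))] <- pw
  freq <- (edges[-1L] + edges[-length(edges)]) / 2
  pk <- which.max(power[-1L]) + 1L
  1 / freq[pk]
}

#' Simulate an orientation map from an ocular dominance raster
#'
#' Binarizes the grayscale raster into contra/ipsi territory, assigns a
#' random ON-OFF polarity to every pixel, sorts the polarities within each
#' eye's territory with a sorting filter whose centre diameter is estimated
#' from the ocular-dominance band width, and maximizes orientation coverage
#' per resulting afferent cluster to synthesize the orientation map.
#'
#' @param od_raster numeric matrix (grayscale; any range).
#' @param seed integer seed.
#' @param n_steps polarity sorting steps (default 10).
#' @param filter optional `sorting_filter` override (else estimated).
#' @return list with `OM`, `ODM` (binary eye map), `CPM` (sorted polarity),
#'   `clusters`, and the estimated `filter`.
#' @export
simulate_from_od_map <- function(od_raster, seed = 1L, n_steps = 10L,
                                 filter = NULL) {
  if (diff(range(od_raster)) == 0) stop("blank ocular dominance raster")
  eye <- ifelse(od_raster >= stats::median(od_raster), 1, -1)
  nx <- nrow(eye); ny <- ncol(eye)
  pol <- with_seed(sub_seed(seed, "od-polarity"),
                   matrix(sample(c(-1, 1), nx * ny, replace = TRUE), nx, ny))
  if (is.null(filter)) {
    lam_px <- domain_wavelength_px(eye)
    ## filter centre diameter ~ band width (half a wavelength)
    sigma_c <- max(lam_px / 4, 1.5) * SLOT_PITCH_UM
    ## striped (anisotropic) ocular dominance: the polarity filter is
    ## elongated orthogonally to the stripes, so ON/OFF clusters slice the
    ## stripe along its length and orientation varies along the stripe
    z <- eye - mean(eye)
    P <- Mod(stats::fft(z))^2
    f1 <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / nx
    f2 <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / ny
    FXm <- matrix(f1, nx, ny); FYm <- matrix(f2, nx, ny, byrow = TRUE)
    P[1L, 1L] <- 0
    pk <- arrayInd(which.max(P), dim(P))
    wave_angle <- atan2(FYm[pk], FXm[pk])
    ## anisotropy: power concentration along vs across the peak direction
    proj <- FXm * cos(wave_angle) + FYm * sin(wave_angle)
    perp <- -FXm * sin(wave_angle) + FYm * cos(wave_angle)
    anis <- sqrt(sum(P * proj^2) / sum(P * perp^2))
    if (is.finite(anis) && anis > 1.3) {
      ## domains elongate orthogonally to the surround's long axis, so the
      ## surround long axis sits 90 degrees from the OD wave direction
      filter <- make_sorting_filter(sigma_c, 2 * sigma_c * sqrt(2),
                                    sqrt(2) * sigma_c,
                                    angle = wave_angle * 180 / pi + 90)
    } else {
      filter <- make_sorting_filter(sigma_c, 2 * sigma_c, 2 * sigma_c)
    }
  }
  sp <- subplate_from_rasters(eye, pol)
  for (st in seq_len(n_steps)) {
    sp <- sorting_step(sp, filter, "polarity",
                       seed = sub_seed(seed, paste0("od-pol-step-", st)))
  }
  pol_sorted <- channel_map(sp, "polarity")
  clusters <- afferent_clusters(sp)
  ## primordial orientations from the local ON-OFF dipole geometry: the
  ## receptive-field dipole axis runs across the local ON/OFF border, so
  ## the preferred bars run parallel to it
  h <- max(2, round(filter$sigma_c / SLOT_PITCH_UM / 2))
  G <- exp(-outer((-3 * h):(3 * h), (-3 * h):(3 * h),
                  function(a, b) (a^2 + b^2)) / (2 * h^2))
  sm <- conv2_same(pol_sorted, G / sum(G))
  gx <- matrix(0, nx, ny); gy <- matrix(0, nx, ny)
  gx[2:(nx - 1), ] <- (sm[3:nx, ] - sm[1:(nx - 2), ]) / 2
  gy[, 2:(ny - 1)] <- (sm[, 3:ny] - sm[, 1:(ny - 2)]) / 2
  pom <- (atan2(gy, gx) + pi / 2) %% pi
  flat <- sqrt(gx^2 + gy^2) < 1e-9
  pom[flat] <- with_seed(sub_seed(seed, "od-pom"),
                         stats::runif(sum(flat), 0, pi))
  opt <- suppressWarnings(optimize_coverage(pom, clusters, filter))
  list(OM = opt$om, ODM = eye, CPM = pol_sorted, clusters = clusters,
       filter = filter)
}

#' Default sector outline for retinotopic-sector simulations
#'
#' A rectangle with the four corner blocks removed, so that three
#' iso-azimuth and three iso-elevation lines partition it into 12 large
#' retinotopic sectors.
#'
#' @param shape raster shape (default 64 x 64).
#' @return logical outline matrix.
#' @export
default_sector_outline <- function(shape = c(64L, 64L)) {
  nx <- shape[1L]; ny <- shape[2L]
  out <- matrix(TRUE, nx, ny)
  cx <- ceiling(nx / 4); cy <- ceiling(ny / 4)
  out[c(seq_len(cx), (nx - cx + 1L):nx), c(seq_len(cy), (ny - cy + 1L):ny)] <- FALSE
  out
}

#' Simulate an orientation map from iso-retinotopic sectors
#'
#' Divides the outline into retinotopic sectors with equally spaced
#' iso-azimuth and iso-elevation lines and fits orientation domains within
#' each sector: each sector receives an independent orientation patch
#' synthesized by smoothing doubled-angle noise with an anisotropic
#' Gaussian whose axes scale with the sector's width and height, so that
#' elongated sectors carry correspondingly elongated iso-orientation
#' domains.
#'
#' @param outline logical matrix (default [default_sector_outline()]).
#' @param azimuth_lines,elevation_lines number of interior iso-lines.
#' @param seed integer seed.
#' @param smooth_frac Gaussian SD as a fraction of the sector side
#'   (default 1/6, about one orientation cycle per sector).
#' @return list with `OM` (`NA` outside the outline), `sectors` (labels),
#'   `outline`.
#' @export
simulate_from_retinotopic_sectors <- function(outline = default_sector_outline(),
                                              azimuth_lines = 3L,
                                              elevation_lines = 3L,
                                              seed = 1L, smooth_frac = 1 / 6) {
  nx <- nrow(outline); ny <- ncol(outline)
  band <- function(n, k) {
    if (k < 1L) rep(1L, n) else cut(seq_len(n), breaks = k + 1L, labels = FALSE)
  }
  xb <- band(nx, azimuth_lines)
  yb <- band(ny, elevation_lines)
  cell <- outer(xb, yb, function(a, b) (a - 1L) * (elevation_lines + 1L) + b)
  cell[!outline] <- 0L
  ## sectors are the connected pieces of the line-partition cells inside
  ## the outline
  labs0 <- sort(setdiff(unique(as.vector(cell)), 0L))
  sectors <- matrix(0L, nx, ny)
  nxt <- 0L
  for (v in labs0) {
    li <- label_components(cell == v)
    add <- li > 0L
    sectors[add] <- li[add] + nxt
    nxt <- nxt + max(li)
  }
  if (nxt == 0L) stop("degenerate sectors: outline is empty")
  om <- matrix(NA_real_, nx, ny)
  for (s in seq_len(nxt)) {
    idx <- which(sectors == s)
    if (length(idx) < 4L) next
    xs <- ((idx - 1L) %% nx) + 1L
    ys <- ((idx - 1L) %/% nx) + 1L
    w <- diff(range(xs)) + 1L; h <- diff(range(ys)) + 1L
    sx <- max(w * smooth_frac, 1); sy <- max(h * smooth_frac, 1)
    hx <- ceiling(3 * sx); hy <- ceiling(3 * sy)
    G <- exp(-outer((-hx:hx)^2 / (2 * sx^2), (-hy:hy)^2 / (2 * sy^2), "+"))
    noise <- with_seed(sub_seed(seed, paste0("sector-", s)), {
      list(c = matrix(stats::rnorm(w * h), w, h),
           s = matrix(stats::rnorm(w * h), w, h))
    })
    cc <- conv2_same(noise$c, G)
    ss <- conv2_same(noise$s, G)
    th <- (atan2(ss, cc) / 2) %% pi
    om[idx] <- th[cbind(xs - min(xs) + 1L, ys - min(ys) + 1L)]
  }
  list(OM = om, sectors = sectors, outline = outline)
}
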