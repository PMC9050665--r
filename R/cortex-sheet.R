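## Model stage 3 (part 1): thalamic axon arbor spread over the cortical
## sheet, ON-OFF synaptic competition, population receptive fields and their
## FFT orientation / spatial-frequency tuning.

#' Spread thalamic axon arbors over the cortical sheet
#'
#' Each afferent keeps its sorted subplate slot as arbor centre and
#' contributes a Gaussian synaptic weight `exp(-d^2 / (2 sigma^2))` to every
#' cortical pixel within `radius` pixels (weight 1 at the centre, hard zero
#' at and beyond the radius). Pixel pitch is 50 um.
#'
#' @param sp a sorted `subplate`.
#' @param sigma_arbor arbor SD in cortical pixels (default 3).
#' @param radius arbor radius in cortical pixels (default 10).
#' @return a `cortical_sheet`: sparse afferent-by-pixel weight matrix `W`,
#'   `central` afferent per pixel (pre-spread occupant), afferent table with
#'   slot coordinates, and geometry parameters.
#' @export
spread_arbors <- function(sp, sigma_arbor = 3, radius = 10) {
  if (sigma_arbor <= 0) stop("sigma_arbor must be positive")
  nx <- sp$shape[1L]; ny <- sp$shape[2L]
  occ <- sp$occupancy
  aff <- sp$afferents
  n_aff <- nrow(aff)
  slot_x <- integer(n_aff); slot_y <- integer(n_aff)
  ok <- which(!is.na(occ))
  slot_x[occ[ok]] <- ((ok - 1L) %% nx) + 1L
  slot_y[occ[ok]] <- ((ok - 1L) %/% nx) + 1L
  aff$slot_x <- slot_x; aff$slot_y <- slot_y
  ## disk template of offsets
  R <- as.integer(ceiling(radius))
  dd <- expand.grid(dx = -R:R, dy = -R:R)
  d <- sqrt(dd$dx^2 + dd$dy^2)
  keep <- d < radius
  dd <- dd[keep, ]; w0 <- exp(-d[keep]^2 / (2 * sigma_arbor^2))
  K <- nrow(dd)
  ai <- rep(seq_len(n_aff), each = K)
  px <- rep(slot_x, each = K) + rep(dd$dx, n_aff)
  py <- rep(slot_y, each = K) + rep(dd$dy, n_aff)
  wv <- rep(w0, n_aff)
  inb <- px >= 1L & px <= nx & py >= 1L & py <= ny
  W <- Matrix::sparseMatrix(i = ai[inb], j = (py[inb] - 1L) * nx + px[inb],
                            x = wv[inb], dims = c(n_aff, nx * ny))
  structure(list(W = W, central = occ, afferents = aff,
                 shape = sp$shape, pitch_um = sp$pitch_um,
                 sigma_arbor = sigma_arbor, radius = radius),
            class = "cortical_sheet")
}

#' @export
print.cortical_sheet <- function(x, ...) {
  cat(sprintf("cortical_sheet: %d x %d pixels (50 um), %d afferents, %d synapses\n",
              x$shape[1L], x$shape[2L], nrow(x$afferents),
              length(x$W@x)))
  cat(sprintf("  arbor sigma %g px, radius %g px\n", x$sigma_arbor, x$radius))
  invisible(x)
}

## arbor weight of afferent `a` at slot (x, y) (same law as spread_arbors)
arbor_weight <- function(sheet, a, x, y) {
  d2 <- (sheet$afferents$slot_x[a] - x)^2 + (sheet$afferents$slot_y[a] - y)^2
  w <- exp(-d2 / (2 * sheet$sigma_arbor^2))
  w[sqrt(d2) >= sheet$radius] <- 0
  w
}

#' ON-OFF synaptic competition
#'
#' For each cortical pixel and eye, the dominant receptive field is the
#' arbor-weighted, max-normalized sum of the receptive fields of converging
#' afferents sharing the polarity of the pixel's central afferent (the
#' pre-spread occupant); the central afferent's own arbor provides the
#' weights. Converging afferents of the opposite polarity whose receptive
#' field centres fall inside a circular competition zone (diameter
#' `zone_deg` degrees, centred on the dominant receptive field peak) have
#' their synaptic weight multiplied by `1 - DW` evaluated at their
#' retinotopic position (`DW^2` when `sharpen = TRUE`, which makes
#' non-dominant afferents more competitive where receptive fields are
#' large).
#'
#' With `mode = "retinotopic"` (the variant without ON-OFF afferent
#' clusters), the non-dominant afferents take their weight directly from
#' the dominant weight matrix (`wf = DW` instead of `1 - DW`, no
#' competition zone), so the competition is purely retinotopic and no
#' ON-OFF antagonism develops.
#'
#' @param sheet a `cortical_sheet`.
#' @param zone_deg competition zone diameter in degrees (default 1).
#' @param microns_per_retinal_pixel,microns_per_degree conversion constants.
#' @param sharpen logical; square the dominant weight matrix.
#' @param mode `"onoff"` (default) or `"retinotopic"`.
#' @return the sheet with competed weights.
#' @export
synaptic_competition <- function(sheet, zone_deg = 1,
                                 microns_per_retinal_pixel = 22,
                                 microns_per_degree = 250,
                                 sharpen = FALSE,
                                 mode = c("onoff", "retinotopic")) {
  mode <- match.arg(mode)
  aff <- sheet$afferents
  W <- as(sheet$W, "TsparseMatrix")   # triplets for column access
  Wc <- sheet$W                        # dgCMatrix: fast column slices
  nx <- sheet$shape[1L]
  zone_r_px <- zone_deg / 2 * microns_per_degree / microns_per_retinal_pixel
  new_x <- Wc@x
  p <- Wc@p; ri <- Wc@i
  for (pix in seq_len(ncol(Wc))) {
    cols <- if (p[pix + 1L] > p[pix]) (p[pix] + 1L):p[pix + 1L] else next
    ids <- ri[cols] + 1L
    w <- new_x[cols]
    cen <- sheet$central[pix]
    if (is.na(cen)) next
    dompol <- aff$polarity[cen]
    px_x <- ((pix - 1L) %% nx) + 1L
    px_y <- ((pix - 1L) %/% nx) + 1L
    for (ev in c(1, -1)) {
      dom <- which(aff$eye[ids] == ev & aff$polarity[ids] == dompol)
      nd <- which(aff$eye[ids] == ev & aff$polarity[ids] != dompol)
      if (!length(dom) || !length(nd)) next
      dom_ids <- ids[dom]
      wc <- arbor_weight(sheet, cen, aff$slot_x[dom_ids], aff$slot_y[dom_ids])
      if (all(wc == 0)) next
      cx <- aff$rx[dom_ids]; cy <- aff$ry[dom_ids]
      sg <- aff$sigma[dom_ids]
      ## dominant RF on a local grid to find its peak and max
      gx <- seq(floor(min(cx) - 2 * max(sg)), ceiling(max(cx) + 2 * max(sg)))
      gy <- seq(floor(min(cy) - 2 * max(sg)), ceiling(max(cy) + 2 * max(sg)))
      Gx <- exp(-outer(gx, cx, "-")^2 / (2 * rep(sg^2, each = length(gx))))
      Gy <- exp(-outer(gy, cy, "-")^2 / (2 * rep(sg^2, each = length(gy))))
      coef <- wc / (2 * pi * sg^2)
      D <- Gx %*% (coef * t(Gy))
      dmax <- max(D)
      if (dmax <= 0) next
      pk <- arrayInd(which.max(D), dim(D))
      peak <- c(gx[pk[1L]], gy[pk[2L]])
      ## DW at the competing afferents' retinotopic positions
      nd_ids <- ids[nd]
      inzone <- if (mode == "retinotopic") rep(TRUE, length(nd_ids)) else
        sqrt((aff$rx[nd_ids] - peak[1L])^2 +
               (aff$ry[nd_ids] - peak[2L])^2) <= zone_r_px
      if (!any(inzone)) next
      tx <- aff$rx[nd_ids][inzone]; ty <- aff$ry[nd_ids][inzone]
      dw <- numeric(length(tx))
      for (q in seq_along(tx)) {
        dw[q] <- sum(coef * exp(-((tx[q] - cx)^2 + (ty[q] - cy)^2) / (2 * sg^2)))
      }
      dw <- dw / dmax
      if (sharpen) dw <- dw^2
      sel <- cols[nd[inzone]]
      new_x[sel] <- if (mode == "retinotopic") new_x[sel] * pmin(dw, 1) else
        new_x[sel] * pmax(0, 1 - dw)
    }
  }
  Wc@x <- new_x
  sheet$W <- Wc
  sheet
}

## Pixel-level afferent selection helper: returns ids + weights of afferents
## converging at `pix`, optionally restricted by eye (+1/-1) / polarity.
pixel_afferents <- function(sheet, pix, eye = NULL, polarity = NULL) {
  p <- sheet$W@p
  if (p[pix + 1L] == p[pix]) return(list(ids = integer(0), w = numeric(0)))
  cols <- (p[pix] + 1L):p[pix + 1L]
  ids <- sheet$W@i[cols] + 1L
  w <- sheet$W@x[cols]
  keep <- rep(TRUE, length(ids))
  if (!is.null(eye)) keep <- keep & sheet$afferents$eye[ids] == eye
  if (!is.null(polarity)) keep <- keep & sheet$afferents$polarity[ids] == polarity
  list(ids = ids[keep], w = w[keep])
}

#' Population receptive field of a cortical pixel
#'
#' Signed weighted sum of the converging afferents' Gaussian receptive
#' fields (+ON, -OFF), evaluated on a square retinal window centred on the
#' pixel's (weighted mean) retinotopic position.
#'
#' @param sheet a `cortical_sheet`.
#' @param pix pixel index (column-major) or `c(x, y)`.
#' @param eye optional eye selector (+1 contra / -1 ipsi).
#' @param polarity optional polarity selector (+1 ON / -1 OFF).
#' @param window window side length in retinal pixels (default 32).
#' @param center optional `(rx, ry)` window centre override.
#' @return list with the `rf` matrix, its `RX`, `RY` grids and the selection.
#' @export
population_rf <- function(sheet, pix, eye = NULL, polarity = NULL,
                          window = 32L, center = NULL) {
  if (length(pix) == 2L) pix <- (pix[2L] - 1L) * sheet$shape[1L] + pix[1L]
  sel <- pixel_afferents(sheet, pix, eye, polarity)
  h <- window %/% 2L
  if (!length(sel$ids)) {
    warning("empty afferent selection; returning zero receptive field")
    RX <- seq_len(window); RY <- seq_len(window)
    return(list(rf = matrix(0, window, window), RX = RX, RY = RY, sel = sel))
  }
  aff <- sheet$afferents
  if (is.null(center)) {
    center <- c(stats::weighted.mean(aff$rx[sel$ids], sel$w),
                stats::weighted.mean(aff$ry[sel$ids], sel$w))
  }
  RX <- floor(center[1L]) + seq(-h + 1L, window - h)
  RY <- floor(center[2L]) + seq(-h + 1L, window - h)
  cx <- aff$rx[sel$ids]; cy <- aff$ry[sel$ids]; sg <- aff$sigma[sel$ids]
  coef <- sel$w * aff$polarity[sel$ids] / (2 * pi * sg^2)
  Gx <- exp(-outer(RX, cx, "-")^2 / (2 * rep(sg^2, each = length(RX))))
  Gy <- exp(-outer(RY, cy, "-")^2 / (2 * rep(sg^2, each = length(RY))))
  list(rf = Gx %*% (coef * t(Gy)), RX = RX, RY = RY, sel = sel)
}

## cached FFT sector / ray geometry per (n, n_sectors)
.geom_cache <- new.env(parent = emptyenv())

sector_geometry <- function(n, n_sectors) {
  key <- paste0(n, "_", n_sectors)
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  fr <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  FX <- matrix(fr, n, n); FY <- t(FX)
  nonzero <- (FX != 0 | FY != 0)
  theta_bin <- (atan2(FY, FX) + pi / 2) %% pi
  sector <- pmin(floor(theta_bin / (pi / n_sectors)) + 1L, n_sectors)
  sector_idx <- lapply(seq_len(n_sectors),
                       function(s) which(nonzero & sector == s))
  theta <- (seq_len(n_sectors) - 0.5) * pi / n_sectors
  s_px <- (0:(n %/% 2)) / n
  rays <- lapply(theta, function(th) {
    psi <- th + pi / 2
    iu <- (s_px * cos(psi) * n) %% n
    iv <- (s_px * sin(psi) * n) %% n
    u0 <- floor(iu); v0 <- floor(iv)
    fu <- iu - u0; fv <- iv - v0
    lin <- function(a, b) ((b %% n)) * n + ((a %% n)) + 1L
    list(i00 = lin(u0, v0), i10 = lin(u0 + 1, v0),
         i01 = lin(u0, v0 + 1), i11 = lin(u0 + 1, v0 + 1),
         w00 = (1 - fu) * (1 - fv), w10 = fu * (1 - fv),
         w01 = (1 - fu) * fv, w11 = fu * fv)
  })
  g <- list(sector_idx = sector_idx, theta = theta, s_px = s_px, rays = rays)
  .geom_cache[[key]] <- g
  g
}

#' Orientation and spatial-frequency tuning of a receptive field
#'
#' Two-dimensional FFT of the receptive field; amplitude is summed over all
#' spatial frequencies within each of `n_sectors` equal orientation sectors
#' (11.25 degrees per sector for the default 16). The preferred orientation
#' is the centre of the sector with the maximum summed response. Responses
#' per spatial frequency are read at the preferred orientation sector and
#' converted to cycles per degree.
#'
#' @param rf receptive field matrix (square).
#' @param n_sectors number of orientation sectors (default 16).
#' @param deg_per_pixel visual degrees per retinal pixel (default 22/250).
#' @param pad zero-padding factor for the FFT (default 4); padding refines
#'   the frequency sampling so orientation is resolved even when the
#'   receptive field's spectral energy sits at low spatial frequencies.
#' @return list: `sectors` (summed response per sector), `theta` (sector
#'   centre orientations, radians), `preferred_sector`, `preferred_theta`,
#'   `cv` (circular variance), `sf` (data.frame: `sf` cpd, `resp`), and
#'   `flat` (TRUE when the receptive field is all zero, preference
#'   undefined).
#' @export
orientation_response <- function(rf, n_sectors = 16L, deg_per_pixel = 22 / 250,
                                 pad = 2L) {
  n0 <- nrow(rf)
  stopifnot(ncol(rf) == n0)
  n <- n0 * pad
  if (pad > 1L) {
    padded <- matrix(0, n, n)
    padded[seq_len(n0), seq_len(n0)] <- rf
    rf <- padded
  }
  if (all(rf == 0)) {
    return(list(sectors = rep(0, n_sectors),
                theta = (seq_len(n_sectors) - 0.5) * pi / n_sectors,
                preferred_sector = NA_integer_, preferred_theta = NA_real_,
                cv = NA_real_, sf = data.frame(sf = 0, resp = 0), flat = TRUE))
  }
  A <- Mod(stats::fft(rf))
  dc <- A[1L, 1L]
  A[1L, 1L] <- 0
  geom <- sector_geometry(n, n_sectors)
  ## orientation sectors: spectral power summed over all spatial
  ## frequencies within each sector (bar orientation orthogonal to the
  ## wave vector); power, not amplitude, so the oriented spectral peak is
  ## not swamped by the broadband residue of the discrete window
  A2 <- A^2
  sectors <- vapply(geom$sector_idx, function(idx) sum(A2[idx]), numeric(1))
  theta <- geom$theta
  ps <- which.max(sectors)
  cv <- circular_variance(sectors, theta)
  ## spatial-frequency tuning: amplitude sampled along the wave-vector ray
  ## of the preferred orientation, bilinear in the frequency plane (single
  ## discrete bins are too noisy a radial profile)
  rg <- geom$rays[[ps]]
  resp <- A[rg$i00] * rg$w00 + A[rg$i10] * rg$w10 +
    A[rg$i01] * rg$w01 + A[rg$i11] * rg$w11
  resp[1L] <- dc                             # true zero-frequency response
  sf <- data.frame(sf = geom$s_px / deg_per_pixel, resp = resp)
  list(sectors = sectors, theta = theta, preferred_sector = ps,
       preferred_theta = theta[ps], cv = cv, sf = sf, flat = FALSE)
}
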