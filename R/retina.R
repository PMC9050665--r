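## Model stage 1: ON/OFF retinal ganglion cell mosaics and their Gaussian
## receptive fields, for the contralateral and ipsilateral eyes.

#' Retinal mosaic configuration
#'
#' Parameters of one ON/OFF retinal ganglion cell mosaic. Cell grids are
#' `nx x ny` per polarity; inter-cell spacing is `dx`, `dy` retinal pixels;
#' positions are jittered uniformly by up to `rjx*dx` / `rjy*dy`. After ON-OFF
#' pairing, pair distances are rescaled onto `[Mindr, Maxdr]` so that no ON
#' cell coincides with an OFF cell. Receptive fields are isotropic Gaussians
#' with standard deviation `rf_sigma` retinal pixels.
#'
#' @param nx,ny integer cell counts per axis (per polarity).
#' @param dx,dy inter-cell spacing in retinal pixels.
#' @param rjx,rjy jitter ranges as fractions of the spacing (>= 0).
#' @param Mindr,Maxdr target minimum/maximum ON-OFF pair distance (retinal px).
#' @param rf_sigma receptive field standard deviation (retinal px, > 0).
#' @param microns_per_retinal_pixel physical scale (default 22 um/px).
#' @param microns_per_degree visual-angle scale (default 250 um/deg, cat).
#' @param seed integer seed for the jitter.
#' @return a `mosaic_config` list.
#' @export
mosaic_config <- function(nx = 20L, ny = 20L, dx = 5, dy = 5,
                          rjx = 0.3, rjy = 0.3,
                          Mindr = 2, Maxdr = 6,
                          rf_sigma = 3,
                          microns_per_retinal_pixel = 22,
                          microns_per_degree = 250,
                          seed = 1L) {
  if (nx < 1L || ny < 1L) stop("nx and ny must be >= 1")
  if (dx <= 0 || dy <= 0) stop("inter-cell spacing dx, dy must be positive")
  if (rjx < 0 || rjy < 0) stop("jitter fractions rjx, rjy must be >= 0")
  if (Mindr < 0 || Maxdr < Mindr) stop("need Maxdr >= Mindr >= 0")
  if (rf_sigma <= 0) stop("rf_sigma must be positive")
  structure(list(nx = as.integer(nx), ny = as.integer(ny), dx = dx, dy = dy,
                 rjx = rjx, rjy = rjy, Mindr = Mindr, Maxdr = Maxdr,
                 rf_sigma = rf_sigma,
                 microns_per_retinal_pixel = microns_per_retinal_pixel,
                 microns_per_degree = microns_per_degree,
                 seed = as.integer(seed)),
            class = "mosaic_config")
}

#' Jittered retinal cell grid for one polarity
#'
#' Places `nx * ny` cells at grid positions `(rx*dx + jx, ry*dy + jy)` with
#' 1-based grid indices and uniform jitter `jx in [-rjx*dx, rjx*dx]`,
#' `jy in [-rjy*dy, rjy*dy]`. Deterministic under the config seed; the two
#' polarities draw from distinct sub-streams.
#'
#' @param cfg a [mosaic_config()].
#' @param polarity `"ON"` or `"OFF"`.
#' @return data.frame with columns `rx`, `ry` (real retinal-pixel coordinates).
#' @export
build_jittered_grid <- function(cfg, polarity = c("ON", "OFF")) {
  polarity <- match.arg(polarity)
  if (cfg$dx <= 0 || cfg$dy <= 0) stop("non-positive spacing")
  gx <- rep(seq_len(cfg$nx), times = cfg$ny)
  gy <- rep(seq_len(cfg$ny), each = cfg$nx)
  n <- cfg$nx * cfg$ny
  jit <- with_seed(sub_seed(cfg$seed, paste0("retina-", polarity)), {
    cbind(stats::runif(n, -cfg$rjx * cfg$dx, cfg$rjx * cfg$dx),
          stats::runif(n, -cfg$rjy * cfg$dy, cfg$rjy * cfg$dy))
  })
  data.frame(rx = gx * cfg$dx + jit[, 1L], ry = gy * cfg$dy + jit[, 2L])
}

#' Match ON cells to their nearest OFF cells
#'
#' Greedy mutual-nearest-neighbour matching: unmatched ON/OFF pairs are taken
#' in order of increasing distance (the globally closest remaining pair is
#' always a mutual nearest pair), ties broken by lower index; each cell joins
#' at most one pair.
#'
#' @param on_positions,off_positions data.frames with `rx`, `ry`.
#' @return data.frame with columns `on`, `off` (row indices) and `dist`
#'   (retinal pixels).
#' @export
pair_onoff_cells <- function(on_positions, off_positions) {
  n_on <- nrow(on_positions); n_off <- nrow(off_positions)
  if (n_on < 1L || n_off < 1L) stop("both ON and OFF position lists must be non-empty")
  dmat <- outer(on_positions$rx, off_positions$rx, "-")^2 +
    outer(on_positions$ry, off_positions$ry, "-")^2
  ord <- order(dmat)            # ascending distance; ties keep lower index
  used_on <- logical(n_on); used_off <- logical(n_off)
  npair <- min(n_on, n_off)
  on_i <- integer(npair); off_i <- integer(npair); dd <- numeric(npair)
  k <- 0L
  for (p in ord) {
    i <- ((p - 1L) %% n_on) + 1L
    j <- ((p - 1L) %/% n_on) + 1L
    if (used_on[i] || used_off[j]) next
    used_on[i] <- TRUE; used_off[j] <- TRUE
    k <- k + 1L
    on_i[k] <- i; off_i[k] <- j; dd[k] <- sqrt(dmat[p])
    if (k == npair) break
  }
  data.frame(on = on_i, off = off_i, dist = dd)
}

#' Rescale ON-OFF pair distances onto a target range
#'
#' Affine map of the observed distance range `[Mind, Maxd]` onto
#' `[Mindr, Maxdr]`: the closest observed pair maps to `Mindr`, the farthest
#' to `Maxdr`. With `eq2_as_printed = TRUE` the subtracted constant is `Mindr`
#' instead of the observed minimum (a variant that does not pin the observed
#' minimum to `Mindr`).
#'
#' @param dists observed pair distances.
#' @param Mindr,Maxdr target range.
#' @param eq2_as_printed logical; see Details.
#' @return numeric vector of new distances, same length as `dists`.
#' @export
rescale_pair_distances <- function(dists, Mindr, Maxdr, eq2_as_printed = FALSE) {
  if (any(dists < 0)) stop("distances must be non-negative")
  Mind <- min(dists); Maxd <- max(dists)
  if (Maxd == Mind) {
    warning("all pair distances equal; returning Mindr for all pairs")
    return(rep(Mindr, length(dists)))
  }
  lo <- if (eq2_as_printed) Mindr else Mind
  (dists - lo) * (Maxdr - Mindr) / (Maxd - Mind) + Mindr
}

#' Apply ON-OFF pair interactions to a mosaic
#'
#' Displaces the two cells of each matched pair symmetrically along their
#' connecting line, in opposite directions, so that the post-move separation
#' equals the prescribed new distance exactly. Coincident pairs (zero
#' separation) are split along the azimuth axis.
#'
#' @param on_positions,off_positions data.frames with `rx`, `ry`.
#' @param pairs pairing table from [pair_onoff_cells()].
#' @param new_dists target separation per pair (same order as `pairs`).
#' @return list with adjusted `on`, `off` position data.frames.
#' @export
apply_pair_interaction <- function(on_positions, off_positions, pairs, new_dists) {
  if (any(new_dists < 0)) stop("new distances must be non-negative")
  stopifnot(length(new_dists) == nrow(pairs))
  on <- on_positions; off <- off_positions
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$on[k]; j <- pairs$off[k]
    vx <- off$rx[j] - on$rx[i]; vy <- off$ry[j] - on$ry[i]
    d <- sqrt(vx^2 + vy^2)
    if (d == 0) { ux <- 1; uy <- 0 } else { ux <- vx / d; uy <- vy / d }
    half <- (new_dists[k] - d) / 2
    on$rx[i] <- on$rx[i] - half * ux; on$ry[i] <- on$ry[i] - half * uy
    off$rx[j] <- off$rx[j] + half * ux; off$ry[j] <- off$ry[j] + half * uy
  }
  list(on = on, off = off)
}

#' Gaussian receptive field raster
#'
#' Normalized two-dimensional Gaussian centred at `center`, evaluated on the
#' given retinal-pixel grids. The thalamic receptive field of an afferent is
#' identical to the receptive field of its retinal input, so the same raster
#' serves both.
#'
#' @param center numeric `(rx, ry)` centre.
#' @param sigma standard deviation (retinal px, > 0).
#' @param RX,RY coordinate vectors defining the evaluation grid.
#' @return matrix of size `length(RX) x length(RY)`.
#' @export
gaussian_rf <- function(center, sigma, RX, RY) {
  if (sigma <= 0) stop("sigma must be positive")
  gx <- exp(-(RX - center[1L])^2 / (2 * sigma^2))
  gy <- exp(-(RY - center[2L])^2 / (2 * sigma^2))
  outer(gx, gy) / (2 * pi * sigma^2)
}

#' Build a full retinal mosaic for one eye
#'
#' Runs the stage-1 sequence: jittered ON and OFF grids, mutual-nearest
#' ON-OFF pairing, affine rescaling of pair distances onto
#' `[Mindr, Maxdr]`, and the pair interaction that enforces the rescaled
#' separations.
#'
#' @param cfg a [mosaic_config()].
#' @param eye `"contra"` or `"ipsi"`.
#' @return a `retinal_mosaic`: list with `on`, `off` position tables, `pairs`
#'   (with pre- and post-interaction distances), `eye` and `cfg`.
#' @export
build_retinal_mosaic <- function(cfg, eye = c("contra", "ipsi")) {
  eye <- match.arg(eye)
  cfg_eye <- cfg
  cfg_eye$seed <- sub_seed(cfg$seed, paste0("eye-", eye))
  on <- build_jittered_grid(cfg_eye, "ON")
  off <- build_jittered_grid(cfg_eye, "OFF")
  pairs <- pair_onoff_cells(on, off)
  dnew <- suppressWarnings(
    rescale_pair_distances(pairs$dist, cfg$Mindr, cfg$Maxdr))
  adj <- apply_pair_interaction(on, off, pairs, dnew)
  pairs$dist_new <- dnew
  structure(list(on = adj$on, off = adj$off, pairs = pairs,
                 eye = eye, cfg = cfg),
            class = "retinal_mosaic")
}

#' @export
print.retinal_mosaic <- function(x, ...) {
  cat(sprintf("retinal_mosaic (%s eye): %d ON + %d OFF cells\n",
              x$eye, nrow(x$on), nrow(x$off)))
  cat(sprintf("  ON-OFF pair distance: %.2f-%.2f retinal px (n = %d pairs)\n",
              min(x$pairs$dist_new), max(x$pairs$dist_new), nrow(x$pairs)))
  invisible(x)
}

#' Scatter plot of a retinal mosaic
#'
#' ON cells are drawn as filled red circles, OFF cells as filled blue
#' circles, on the retinal-pixel coordinate frame.
#'
#' @param x a `retinal_mosaic`.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.retinal_mosaic <- function(x, ...) {
  graphics::plot(x$on$rx, x$on$ry, col = "red3", pch = 19, asp = 1,
                 xlab = "azimuth (retinal px)", ylab = "elevation (retinal px)",
                 main = sprintf("%s eye mosaic", x$eye), ...)
  graphics::points(x$off$rx, x$off$ry, col = "blue3", pch = 19)
  invisible(x)
}

#' Build the thalamic afferent population from two retinal mosaics
#'
#' With divergence 1 (the default) each retinal ganglion cell drives exactly
#' one thalamic afferent whose receptive field equals the retinal one.
#' Divergence 2 additionally inserts, between every matched pair of
#' same-polarity neighbouring cells, an interpolated afferent whose receptive
#' field is the overlap-weighted sum of the two parents (weights are the
#' rectified, normalized dot products of the parent receptive fields).
#'
#' @param contra,ipsi `retinal_mosaic` objects sharing a coordinate frame.
#' @param divergence 1 or 2.
#' @return data.frame of afferents: `eye` (+1 contra, -1 ipsi), `polarity`
#'   (+1 ON, -1 OFF), `rx`, `ry`, `sigma`.
#' @export
build_afferent_population <- function(contra, ipsi, divergence = 1L) {
  if (!divergence %in% c(1L, 2L)) stop("unsupported divergence (must be 1 or 2)")
  one_eye <- function(m, eye_val) {
    rbind(data.frame(eye = eye_val, polarity = 1, rx = m$on$rx, ry = m$on$ry,
                     sigma = m$cfg$rf_sigma),
          data.frame(eye = eye_val, polarity = -1, rx = m$off$rx, ry = m$off$ry,
                     sigma = m$cfg$rf_sigma))
  }
  aff <- rbind(one_eye(contra, 1), one_eye(ipsi, -1))
  if (divergence == 2L) {
    extra <- lapply(list(list(contra, 1), list(ipsi, -1)), function(me) {
      m <- me[[1L]]; ev <- me[[2L]]
      do.call(rbind, lapply(list(list(m$on, 1), list(m$off, -1)), function(pp) {
        pos <- pp[[1L]]; pol <- pp[[2L]]
        interp_afferents(pos, pol, ev, m$cfg$rf_sigma)
      }))
    })
    aff <- rbind(aff, do.call(rbind, extra))
  }
  rownames(aff) <- NULL
  aff
}

#' Overlap weights for an interpolated afferent
#'
#' Given two parent receptive fields and an interpolation point, returns the
#' rectified, normalized dot products between the receptive field placed at
#' the interpolation point and each parent receptive field. These are the
#' weights of the parents in the interpolated receptive field sum.
#'
#' @param parents 2x2 matrix of parent centres (rows are `(rx, ry)`).
#' @param sigma shared receptive field standard deviation.
#' @param at interpolation centre, default the parents' midpoint.
#' @return numeric length-2 weight vector summing to 1.
#' @export
interp_rf_weights <- function(parents, sigma, at = colMeans(parents)) {
  ## dot product of two equal-sigma Gaussians separated by d is
  ## proportional to exp(-d^2 / (4 sigma^2)); rectify then normalize
  d2 <- (parents[, 1L] - at[1L])^2 + (parents[, 2L] - at[2L])^2
  w <- pmax(exp(-d2 / (4 * sigma^2)), 0)
  w / sum(w)
}

## Divergence-2 helper: pair same-polarity neighbours and add the midpoint
## afferent. The interpolated RF is w1*RF1 + w2*RF2 with weights from the
## rectified normalized RF dot products; for equal-sigma Gaussians the dot
## product is symmetric in the two parents, so w1 = w2 and the interpolated
## RF reduces to a symmetric two-parent blend centred at the overlap-weighted
## mean position.
interp_afferents <- function(pos, pol, eye_val, sigma) {
  n <- nrow(pos)
  if (n < 2L) return(NULL)
  d2 <- outer(pos$rx, pos$rx, "-")^2 + outer(pos$ry, pos$ry, "-")^2
  diag(d2) <- Inf
  nn <- apply(d2, 1L, which.min)
  take <- which(seq_len(n) < nn)     # each unordered neighbour pair once
  if (!length(take)) return(NULL)
  i <- take; j <- nn[take]
  ## Gaussian RF overlap: exp(-d^2 / 4 sigma^2), rectified (already >= 0)
  w <- exp(-d2[cbind(i, j)] / (4 * sigma^2))
  w1 <- pmax(w, 0); w2 <- pmax(w, 0)
  tot <- w1 + w2
  data.frame(eye = eye_val, polarity = pol,
             rx = (w1 * pos$rx[i] + w2 * pos$rx[j]) / tot,
             ry = (w1 * pos$ry[i] + w2 * pos$ry[j]) / tot,
             sigma = sigma)
}
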