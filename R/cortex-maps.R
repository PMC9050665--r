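## Model stage 3 (part 2): primordial orientation map, orientation-coverage
## optimization per afferent cluster, binocular matching, and experience
## manipulations.

#' Per-pixel receptive-field tuning over the cortical sheet
#'
#' Computes, for every cortical pixel, the population receptive field for
#' the given selection and its FFT tuning: preferred orientation, circular
#' variance, preferred SF, SF50 and LPI, plus the retinotopic centre and the
#' summed afferent weight of the selection.
#'
#' @param sheet a `cortical_sheet`.
#' @param eye,polarity optional selectors passed to [population_rf()].
#' @param window retinal window (default 32).
#' @param pixels optional vector of pixel indices (default all).
#' @param deg_per_pixel degrees per retinal pixel.
#' @return list of matrices: `theta`, `cv`, `sf50`, `lpi`, `sfm`, `rm_x`,
#'   `rm_y` (degrees), `wsum`.
#' @export
sheet_tuning <- function(sheet, eye = NULL, polarity = NULL, window = 32L,
                         pixels = NULL, deg_per_pixel = 22 / 250) {
  nx <- sheet$shape[1L]; ny <- sheet$shape[2L]
  if (is.null(pixels)) pixels <- seq_len(nx * ny)
  out <- list()
  for (nm in c("theta", "cv", "sf50", "lpi", "sfm", "rm_x", "rm_y", "wsum")) {
    out[[nm]] <- matrix(NA_real_, nx, ny)
  }
  aff <- sheet$afferents
  for (pix in pixels) {
    if (is.na(sheet$central[pix])) next
    prf <- suppressWarnings(
      population_rf(sheet, pix, eye = eye, polarity = polarity, window = window))
    if (!length(prf$sel$ids)) next
    tun <- orientation_response(prf$rf, deg_per_pixel = deg_per_pixel)
    out$wsum[pix] <- sum(prf$sel$w)
    out$rm_x[pix] <- stats::weighted.mean(aff$rx[prf$sel$ids], prf$sel$w) * deg_per_pixel
    out$rm_y[pix] <- stats::weighted.mean(aff$ry[prf$sel$ids], prf$sel$w) * deg_per_pixel
    if (tun$flat) next
    out$theta[pix] <- tun$preferred_theta
    out$cv[pix] <- tun$cv
    sfm <- sf_metrics(tun$sf$sf, tun$sf$resp)
    out$sf50[pix] <- sfm$sf50
    out$lpi[pix] <- sfm$lpi
    out$sfm[pix] <- sfm$pref_sf
  }
  out
}

#' Primordial orientation map and its variants
#'
#' Preferred orientation of the population receptive field at every cortical
#' pixel before maturation: the binocular map plus the contralateral,
#' ipsilateral and dominant-eye variants.
#'
#' @param sheet a `cortical_sheet` (after competition).
#' @param window retinal window (default 32).
#' @param deg_per_pixel degrees per retinal pixel.
#' @param variants also compute the per-eye and dominant-eye variants
#'   (default TRUE; each costs a full tuning pass).
#' @return an `orientation_map_state`: list with `pom` (binocular), `contra`,
#'   `ipsi`, `dominant` orientation matrices (radians mod pi) and the
#'   per-eye weight sums (`NULL` when `variants = FALSE`).
#' @export
primordial_map <- function(sheet, window = 32L, deg_per_pixel = 22 / 250,
                           variants = TRUE) {
  bin <- sheet_tuning(sheet, window = window, deg_per_pixel = deg_per_pixel)
  con <- ips <- NULL
  dominant <- NULL
  if (variants) {
    con <- sheet_tuning(sheet, eye = 1, window = window,
                        deg_per_pixel = deg_per_pixel)
    ips <- sheet_tuning(sheet, eye = -1, window = window,
                        deg_per_pixel = deg_per_pixel)
    dominant <- ifelse(!is.na(con$wsum) &
                         (is.na(ips$wsum) | con$wsum >= ips$wsum),
                       con$theta, ips$theta)
    dominant <- matrix(dominant, sheet$shape[1L], sheet$shape[2L])
  }
  structure(list(pom = bin$theta, contra = con$theta,
                 ipsi = ips$theta, dominant = dominant,
                 wsum_contra = con$wsum, wsum_ipsi = ips$wsum,
                 tuning = bin),
            class = "orientation_map_state")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Afferent cluster labels of a sorted subplate
#'
#' Connected components (4-connectivity) of constant (eye, polarity) over
#' the slot lattice: the eye-polarity grid of ON-contra, OFF-contra,
#' ON-ipsi and OFF-ipsi afferent clusters.
#'
#' @param sp a `subplate` (or a `cortical_sheet`, whose afferent slots are
#'   used).
#' @return integer label matrix (0 on inert slots).
#' @export
afferent_clusters <- function(sp) {
  if (inherits(sp, "cortical_sheet")) {
    nx <- sp$shape[1L]; ny <- sp$shape[2L]
    occ <- sp$central
    eye <- matrix(0, nx, ny); pol <- matrix(0, nx, ny)
    ok <- !is.na(occ)
    eye[ok] <- sp$afferents$eye[occ[ok]]
    pol[ok] <- sp$afferents$polarity[occ[ok]]
  } else {
    eye <- channel_map(sp, "eye"); pol <- channel_map(sp, "polarity")
  }
  combo <- eye * 2 + pol     # 4 distinct values on active slots
  lab <- matrix(0L, nrow(eye), ncol(eye))
  nxt <- 0L
  for (v in c(-3, -1, 1, 3)) {
    li <- label_components(combo == v & eye != 0)
    add <- li > 0L
    lab[add] <- li[add] + nxt
    nxt <- nxt + max(li)
  }
  lab
}

#' Orientation coverage of a patch
#'
#' Circular spread `1 - |mean(exp(2i theta))|` of the patch orientations:
#' 1 when the patch covers all orientations evenly (a full cycle), 0 when
#' it is constant.
#'
#' @param theta orientations in radians (mod pi), `NA` ignored.
#' @return coverage in `[0, 1]`.
#' @export
orientation_coverage <- function(theta) {
  theta <- theta[!is.na(theta)]
  if (!length(theta)) return(NA_real_)
  1 - circ_resultant(theta)
}

#' Build the bank of orientation-coverage filters
#'
#' The orientation-coverage filter equals the afferent sorting filter made
#' 25 percent smaller, with the surround elongated 2:1 (equal area) and
#' rotated to each of 0, 45, 90 and 135 degrees.
#'
#' @param base a `sorting_filter` (the afferent sorting filter).
#' @return named list of four `sorting_filter` kernels (angles as names).
#' @export
coverage_filters <- function(base) {
  sc <- 0.75 * base$sigma_c
  sbar <- 0.75 * sqrt(base$sigma_sx * base$sigma_sy)
  s_long <- sbar * sqrt(2); s_short <- sbar / sqrt(2)
  angs <- c(0, 45, 90, 135)
  out <- lapply(angs, function(a) {
    make_sorting_filter(sc, s_long, s_short, rho = 0, angle = a,
                        pitch_um = base$pitch_um)
  })
  names(out) <- as.character(angs)
  out
}

#' Maximize orientation coverage within each afferent cluster
#'
#' For each afferent cluster, builds 12 candidate orientation patches by
#' combining a convolution of the doubled-angle cosine component with a
#' coverage filter at angle `alpha` (0, 45, 90, 135 degrees) and a
#' convolution of the sine component with a filter at `beta = alpha + 45,
#' 90, 135` (mod 180), recovering the candidate orientations with the
#' two-argument arctangent. The candidate with the largest orientation
#' coverage wins (ties broken by the distance of its nearest pinwheel to the
#' cluster centroid) and replaces the cluster's patch in the matured map.
#'
#' @param pom primordial orientation map (radians mod pi).
#' @param clusters integer cluster label matrix (0 = outside).
#' @param base_filter the afferent sorting filter the coverage filters are
#'   derived from.
#' @param min_cluster clusters with fewer pixels are skipped with a warning.
#' @param cov_margin coverage margin within which the pinwheel-distance
#'   criterion decides the winner (default 0.15).
#' @return list with the matured `om`, per-cluster chosen `alpha`/`beta`
#'   and `coverage`.
#' @export
optimize_coverage <- function(pom, clusters, base_filter, min_cluster = 9L,
                              cov_margin = 0.15) {
  ocf <- coverage_filters(base_filter)
  cosm <- cos(2 * pom); sinm <- sin(2 * pom)
  cosm[is.na(cosm)] <- 0; sinm[is.na(sinm)] <- 0
  Cc <- lapply(ocf, function(f) conv2_same(cosm, f$kernel))
  Cs <- lapply(ocf, function(f) conv2_same(sinm, f$kernel))
  angs <- c(0, 45, 90, 135)
  combos <- do.call(rbind, lapply(angs, function(a) {
    data.frame(alpha = a, beta = (a + c(45, 90, 135)) %% 180)
  }))
  om <- pom
  labs <- setdiff(sort(unique(as.vector(clusters))), 0L)
  info <- data.frame(cluster = labs, alpha = NA_real_, beta = NA_real_,
                     coverage = NA_real_)
  skipped <- 0L
  for (li in seq_along(labs)) {
    mask <- clusters == labs[li]
    if (sum(mask) < min_cluster) { skipped <- skipped + 1L; next }
    idx <- which(mask)
    centroid <- c(mean(((idx - 1L) %% nrow(pom)) + 1L),
                  mean(((idx - 1L) %/% nrow(pom)) + 1L))
    cands <- vector("list", nrow(combos))
    covs <- numeric(nrow(combos)); pds <- numeric(nrow(combos))
    for (k in seq_len(nrow(combos))) {
      ca <- as.character(combos$alpha[k]); cb <- as.character(combos$beta[k])
      cand <- (atan2(Cs[[cb]][idx], Cc[[ca]][idx]) / 2) %% pi
      cands[[k]] <- cand
      covs[k] <- orientation_coverage(cand)
      patch <- om; patch[] <- NA
      patch[idx] <- cand
      pds[k] <- cluster_pinwheel_distance(patch, idx, centroid)
    }
    ## the winning patch has maximum coverage, which is the patch whose
    ## pinwheel sits closest to the cluster centre: among candidates within
    ## a small coverage margin of the best, take the nearest pinwheel
    top <- which(covs >= max(covs) - cov_margin)
    best_k <- top[which.min(pds[top])]
    om[idx] <- cands[[best_k]]
    info$alpha[li] <- combos$alpha[best_k]
    info$beta[li] <- combos$beta[best_k]
    info$coverage[li] <- covs[best_k]
  }
  if (skipped > 0L) {
    warning(sprintf("%d cluster(s) smaller than %d pixels skipped", skipped,
                    min_cluster))
  }
  list(om = om, info = info, n_candidates = nrow(combos))
}

## distance from the cluster centroid to the nearest pinwheel of the
## candidate patch (Inf when the patch has none)
cluster_pinwheel_distance <- function(patch, idx, centroid) {
  nx <- nrow(patch)
  xs <- ((idx - 1L) %% nx) + 1L
  ys <- ((idx - 1L) %/% nx) + 1L
  sub <- patch[min(xs):max(xs), min(ys):max(ys), drop = FALSE]
  if (any(is.na(sub)) || min(dim(sub)) < 3L) return(Inf)
  pw <- find_pinwheels(sub)$pinwheels
  if (!nrow(pw)) return(Inf)
  min(sqrt((pw$x + min(xs) - 1 - centroid[1L])^2 +
             (pw$y + min(ys) - 1 - centroid[2L])^2))
}

## Euclidean distance (in pixels) from every pixel to the nearest of `pts`
## (n x 2 matrix); Inf when pts is empty.
dist_to_points <- function(shape, pts) {
  nx <- shape[1L]; ny <- shape[2L]
  if (is.null(pts) || nrow(pts) == 0L) return(matrix(Inf, nx, ny))
  px <- matrix(rep(seq_len(nx), ny), nx, ny)
  py <- matrix(rep(seq_len(ny), each = nx), nx, ny)
  d <- matrix(Inf, nx, ny)
  for (k in seq_len(nrow(pts))) {
    d <- pmin(d, sqrt((px - pts[k, 1L])^2 + (py - pts[k, 2L])^2))
  }
  d
}

## border pixels of a cluster labelling (4-neighbour label change)
cluster_border_points <- function(clusters) {
  nx <- nrow(clusters); ny <- ncol(clusters)
  b <- matrix(FALSE, nx, ny)
  b[-nx, ] <- b[-nx, ] | (clusters[-nx, ] != clusters[-1L, ])
  b[-1L, ] <- b[-1L, ] | (clusters[-1L, ] != clusters[-nx, ])
  b[, -ny] <- b[, -ny] | (clusters[, -ny] != clusters[, -1L])
  b[, -1L] <- b[, -1L] | (clusters[, -1L] != clusters[, -ny])
  which(b, arr.ind = TRUE)
}

## Steer the afferent weights of one pixel so the receptive field prefers
## theta_t: non-dominant-polarity afferents are kept in proportion to the
## alignment of their retinotopic displacement with the axis normal to
## theta_t (the flank axis), scaled by the border/pinwheel taper; dominant
## afferents, when adjusted, are kept in proportion to alignment with
## theta_t itself (elongating the dominant lobe along the preferred bars).
## Operates on `x`, the sheet's weight vector (`sheet$W@x`), and returns the
## updated vector; callers write it back once per pass (assigning into the
## sparse-matrix slot copies the whole vector, so per-pixel slot writes are
## avoided).
steer_pixel <- function(sheet, wenv, pix, theta_t, taper = 1, gamma = 2,
                        eps = 0.1, adjust_dominant = FALSE, eyes = c(1, -1)) {
  p <- sheet$W@p
  if (p[pix + 1L] == p[pix]) return(invisible(NULL))
  cols <- (p[pix] + 1L):p[pix + 1L]
  ids <- sheet$W@i[cols] + 1L
  aff <- sheet$afferents
  cen <- sheet$central[pix]
  if (is.na(cen)) return(invisible(NULL))
  dompol <- aff$polarity[cen]
  w <- wenv$x[cols]
  for (ev in eyes) {
    in_eye <- aff$eye[ids] == ev
    if (!any(in_eye)) next
    dom <- in_eye & aff$polarity[ids] == dompol
    if (any(dom)) {
      cx <- stats::weighted.mean(aff$rx[ids][dom], w[dom])
      cy <- stats::weighted.mean(aff$ry[ids][dom], w[dom])
    } else {
      cx <- stats::weighted.mean(aff$rx[ids][in_eye], w[in_eye])
      cy <- stats::weighted.mean(aff$ry[ids][in_eye], w[in_eye])
    }
    phi <- atan2(aff$ry[ids] - cy, aff$rx[ids] - cx)
    nd <- in_eye & !dom
    if (any(nd)) {
      m <- eps + (1 - eps) * abs(cos(phi[nd] - (theta_t + pi / 2)))^gamma
      w[nd] <- w[nd] * m * taper
    }
    if (adjust_dominant && any(dom)) {
      m <- eps + (1 - eps) * abs(cos(phi[dom] - theta_t))^gamma
      w[dom] <- w[dom] * m
    }
  }
  wenv$x[cols] <- w
  invisible(NULL)
}

## Rotation-based weight adjustment: evaluate the pixel's current
## receptive field rotated by `delta` (to the map orientation) at every
## afferent's retinotopic position, and keep each afferent in proportion to
## how well the rotated field matches its polarity there.
rotate_pixel_weights <- function(sheet, wenv, pix, eye, delta, eps = 0.05) {
  p <- sheet$W@p
  if (p[pix + 1L] == p[pix]) return(invisible(NULL))
  cols <- (p[pix] + 1L):p[pix + 1L]
  ids <- sheet$W@i[cols] + 1L
  aff <- sheet$afferents
  in_eye <- aff$eye[ids] == eye
  if (sum(in_eye) < 2L) return(invisible(NULL))
  w <- wenv$x[cols]
  sel <- which(in_eye)
  rx <- aff$rx[ids[sel]]; ry <- aff$ry[ids[sel]]
  sg <- aff$sigma[ids[sel]]; s <- aff$polarity[ids[sel]]
  wk <- w[sel]
  cx <- stats::weighted.mean(rx, wk); cy <- stats::weighted.mean(ry, wk)
  ## afferent positions rotated by -delta about the RF centre
  qx <- cx + cos(-delta) * (rx - cx) - sin(-delta) * (ry - cy)
  qy <- cy + sin(-delta) * (rx - cx) + cos(-delta) * (ry - cy)
  coef <- wk * s / (2 * pi * sg^2)
  G <- exp(-(outer(qx, rx, "-")^2 + outer(qy, ry, "-")^2) / (2 * sg[1L]^2))
  tvals <- as.vector(G %*% coef) * s
  mx <- max(abs(tvals))
  if (mx <= 0) return(invisible(NULL))
  m <- eps + (1 - eps) * pmax(tvals, 0) / mx
  ## re-assign from the rotated template, preserving the weight scale so
  ## repeated adjustments do not collapse the receptive field
  w[sel] <- max(wk) * m
  wenv$x[cols] <- w
  invisible(NULL)
}

## Last-resort adjustment for pixels whose receptive field has lost its
## opposite-polarity flanks (e.g. crushed by competition plus tapering):
## re-assign the eye's weights from an oriented Gabor template at the
## target orientation, so flank structure is rebuilt explicitly.
template_pixel_weights <- function(sheet, wenv, pix, eye, theta_t,
                                   eps = 0.02) {
  p <- sheet$W@p
  if (p[pix + 1L] == p[pix]) return(invisible(NULL))
  cols <- (p[pix] + 1L):p[pix + 1L]
  ids <- sheet$W@i[cols] + 1L
  aff <- sheet$afferents
  in_eye <- aff$eye[ids] == eye
  if (sum(in_eye) < 2L) return(invisible(NULL))
  w <- wenv$x[cols]
  sel <- which(in_eye)
  rx <- aff$rx[ids[sel]]; ry <- aff$ry[ids[sel]]
  s <- aff$polarity[ids[sel]]; wk <- w[sel]
  sg <- aff$sigma[ids[sel]][1L]
  cx <- stats::weighted.mean(rx, wk); cy <- stats::weighted.mean(ry, wk)
  p0 <- if (sum(wk[s == 1]) >= sum(wk[s == -1])) 1 else -1
  u <- (rx - cx) * cos(theta_t + pi / 2) + (ry - cy) * sin(theta_t + pi / 2)
  r2 <- (rx - cx)^2 + (ry - cy)^2
  lambda <- 4 * sg
  gab <- p0 * exp(-r2 / (2 * (2 * sg)^2)) * cos(2 * pi * u / lambda)
  tv <- gab * s
  mx <- max(abs(tv))
  if (mx <= 0) return(invisible(NULL))
  m <- eps + (1 - eps) * pmax(tv, 0) / mx
  w[sel] <- max(wk) * m
  wenv$x[cols] <- w
  invisible(NULL)
}

#' Binocular matching of the cortical receptive fields to the mature map
#'
#' Iteration 1 adjusts, at every cortical pixel, the synaptic weights of the
#' non-dominant-polarity afferents of each eye until the receptive-field
#' preferred orientation matches the mature map orientation, tapering the
#' non-dominant weights linearly from 1 at the afferent-cluster border
#' through 0.5 midway to 0 at pinwheel centres; where the non-dominant
#' changes are insufficient, the dominant-polarity weights are adjusted as
#' well. Iteration 2 then minimizes the residual contralateral/ipsilateral
#' differences in orientation preference (and dominant polarity) by
#' re-steering the deviant eye with a sharper adjustment.
#'
#' @param sheet a `cortical_sheet` (after competition).
#' @param OM matured orientation map (radians mod pi).
#' @param clusters afferent cluster labels (for the border taper).
#' @param sector_deg matching tolerance, one FFT sector (default 11.25).
#' @param gamma steering exponent; `eps` steering floor.
#' @param window retinal window for tuning evaluation.
#' @param deg_per_pixel degrees per retinal pixel.
#' @return list: the matched `sheet`, `match_frac_iter1` (fraction of
#'   binocular pixels whose two eyes share the preferred-orientation
#'   sector), `median_diff_iter1` / `median_diff_iter2` (radians), and the
#'   per-eye orientation maps after each iteration.
#' @export
binocular_match <- function(sheet, OM, clusters, sector_deg = 11.25,
                            gamma = 2, eps = 0.1, window = 32L,
                            deg_per_pixel = 22 / 250) {
  nx <- sheet$shape[1L]; ny <- sheet$shape[2L]
  pw <- find_pinwheels(OM)$pinwheels
  d_pw <- dist_to_points(sheet$shape, as.matrix(pw[, c("x", "y")]))
  d_bd <- dist_to_points(sheet$shape, cluster_border_points(clusters))
  taper <- ifelse(is.finite(d_pw), d_pw / (d_pw + d_bd), 1)
  taper[!is.finite(d_pw) & !is.finite(d_bd)] <- 1
  tol <- sector_deg * pi / 180
  active <- which(!is.na(sheet$central))
  ## monocular pixels (input from one eye only) are left untouched
  aff_eye <- sheet$afferents$eye
  active <- active[vapply(active, function(pix) {
    sel <- pixel_afferents(sheet, pix)
    length(unique(aff_eye[sel$ids])) == 2L
  }, logical(1))]
  ## pass 1: taper + non-dominant steering everywhere
  wenv <- new.env(parent = emptyenv())
  wenv$x <- sheet$W@x
  for (pix in active) {
    steer_pixel(sheet, wenv, pix, OM[pix], taper = taper[pix],
                gamma = gamma, eps = eps)
  }
  sheet$W@x <- wenv$x
  con <- sheet_tuning(sheet, eye = 1, window = window,
                      deg_per_pixel = deg_per_pixel)
  ips <- sheet_tuning(sheet, eye = -1, window = window,
                      deg_per_pixel = deg_per_pixel)
  ## remaining passes of iteration 1: where a receptive field still
  ## mismatches the map, adjust the weights (dominant polarity included)
  ## from the receptive field rotated to the map orientation, repeating
  ## until the preference matches
  sdiff <- function(a, b) ((a - b + pi / 2) %% pi) - pi / 2  # signed, mod pi
  sec_of <- function(th) pmin(floor((th %% pi) / (pi / 16)) + 1L, 16L)
  sec_center <- function(th) (sec_of(th) - 0.5) * pi / 16
  for (round in 1:6) {
    n_bad <- 0L
    for (side in list(list(ev = 1, maps = quote(con)),
                      list(ev = -1, maps = quote(ips)))) {
      cur <- eval(side$maps)
      mism <- active[!is.na(cur$theta[active]) &
                       circ_diff_pi(cur$theta[active], OM[active]) > tol]
      n_bad <- n_bad + length(mism)
      if (!length(mism)) next
      wenv$x <- sheet$W@x
      for (pix in mism) {
        rotate_pixel_weights(sheet, wenv, pix, side$ev,
                             sdiff(OM[pix], cur$theta[pix]),
                             eps = eps / 2)
      }
      sheet$W@x <- wenv$x
      upd <- sheet_tuning(sheet, eye = side$ev, window = window,
                          pixels = mism, deg_per_pixel = deg_per_pixel)
      for (f in c("theta", "cv", "sf50", "lpi", "sfm")) {
        cur[[f]][mism] <- upd[[f]][mism]
      }
      if (side$ev == 1) con <- cur else ips <- cur
    }
    if (n_bad == 0L) break
  }
  binoc <- active[!is.na(con$theta[active]) & !is.na(ips$theta[active])]
  ## closing passes of iteration 1: where the two eyes have converged to
  ## different sectors, re-match the eye that deviates more from the map to
  ## the other eye's preference. The first pass uses the rotated-template
  ## rule; pixels that persist (typically fields whose opposite-polarity
  ## flanks were crushed by competition and tapering, leaving nothing for a
  ## rotation to reorient) are re-assigned from an oriented template.
  for (round in 1:4) {
    bad <- binoc[sec_of(con$theta[binoc]) != sec_of(ips$theta[binoc])]
    if (!length(bad)) break
    fix_c <- integer(0); fix_i <- integer(0)
    wenv$x <- sheet$W@x
    for (pix in bad) {
      dc <- circ_diff_pi(con$theta[pix], OM[pix])
      di <- circ_diff_pi(ips$theta[pix], OM[pix])
      ev <- if (dc >= di) 1 else -1
      th_now <- if (ev == 1) con$theta[pix] else ips$theta[pix]
      th_tgt <- if (ev == 1) ips$theta[pix] else con$theta[pix]
      if (round == 1L) {
        rotate_pixel_weights(sheet, wenv, pix, ev, sdiff(th_tgt, th_now),
                             eps = eps / 2)
      } else {
        template_pixel_weights(sheet, wenv, pix, ev, th_tgt)
      }
      if (ev == 1) fix_c <- c(fix_c, pix) else fix_i <- c(fix_i, pix)
    }
    sheet$W@x <- wenv$x
    if (length(fix_c)) {
      upd <- sheet_tuning(sheet, eye = 1, window = window, pixels = fix_c,
                          deg_per_pixel = deg_per_pixel)
      for (f in c("theta", "cv", "sf50", "lpi", "sfm")) {
        con[[f]][fix_c] <- upd[[f]][fix_c]
      }
    }
    if (length(fix_i)) {
      upd <- sheet_tuning(sheet, eye = -1, window = window, pixels = fix_i,
                          deg_per_pixel = deg_per_pixel)
      for (f in c("theta", "cv", "sf50", "lpi", "sfm")) {
        ips[[f]][fix_i] <- upd[[f]][fix_i]
      }
    }
  }
  match1 <- mean(sec_of(con$theta[binoc]) == sec_of(ips$theta[binoc]))
  diff1 <- circ_diff_pi(con$theta[binoc], ips$theta[binoc])
  ## iteration 2: re-steer the deviant eye where the two eyes still differ
  still <- binoc[diff1 > tol / 2]
  wenv$x <- sheet$W@x
  for (pix in still) {
    dc <- circ_diff_pi(con$theta[pix], OM[pix])
    di <- circ_diff_pi(ips$theta[pix], OM[pix])
    ev <- if (dc >= di) 1 else -1
    th_now <- if (ev == 1) con$theta[pix] else ips$theta[pix]
    rotate_pixel_weights(sheet, wenv, pix, ev,
                         ((OM[pix] - th_now + pi / 2) %% pi) - pi / 2,
                         eps = eps / 4)
  }
  sheet$W@x <- wenv$x
  if (length(still)) {
    upd_c <- sheet_tuning(sheet, eye = 1, window = window, pixels = still,
                          deg_per_pixel = deg_per_pixel)
    upd_i <- sheet_tuning(sheet, eye = -1, window = window, pixels = still,
                          deg_per_pixel = deg_per_pixel)
    for (f in c("theta", "cv", "sf50", "lpi", "sfm")) {
      con[[f]][still] <- upd_c[[f]][still]
      ips[[f]][still] <- upd_i[[f]][still]
    }
  }
  diff2 <- circ_diff_pi(con$theta[binoc], ips$theta[binoc])
  list(sheet = sheet,
       match_frac_iter1 = match1,
       median_diff_iter1 = stats::median(diff1),
       median_diff_iter2 = stats::median(diff2),
       om_contra = con$theta, om_ipsi = ips$theta)
}

#' Apply an experience manipulation to the sheet
#'
#' `monocular_deprivation` shrinks the deprived eye's axon arbors by raising
#' each afferent's weight profile to the fifth power (renormalized to its
#' original peak); `orientation_bias` steers the afferent weights of a
#' random `pcl` fraction of cortical pixels towards a dominant orientation;
#' `normal` is a no-op.
#'
#' @param sheet a `cortical_sheet`.
#' @param mode one of `"normal"`, `"monocular_deprivation"`,
#'   `"orientation_bias"`.
#' @param deprived_eye +1 (contra) or -1 (ipsi) for deprivation.
#' @param theta_dom dominant orientation (radians) for the bias mode.
#' @param pcl fraction of cortical locations biased (default 0.2).
#' @param seed integer seed for the biased-pixel selection.
#' @return the modified sheet.
#' @export
apply_experience <- function(sheet, mode = c("normal", "monocular_deprivation",
                                             "orientation_bias"),
                             deprived_eye = -1, theta_dom = 0, pcl = 0.2,
                             seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "normal") return(sheet)
  if (mode == "monocular_deprivation") {
    W <- as(sheet$W, "TsparseMatrix")
    dep <- sheet$afferents$eye == deprived_eye
    rows_by_aff <- split(seq_along(W@x), W@i + 1L)
    for (a in names(rows_by_aff)) {
      if (!dep[as.integer(a)]) next
      rows <- rows_by_aff[[a]]
      w <- W@x[rows]
      mx <- max(w)
      if (mx > 0) W@x[rows] <- w^5 * mx / mx^5
    }
    sheet$W <- as(W, "CsparseMatrix")
    return(sheet)
  }
  if (pcl < 0 || pcl > 1) stop("pcl must be in [0, 1]")
  if (pcl == 0) return(sheet)
  active <- which(!is.na(sheet$central))
  n_sel <- round(pcl * length(active))
  picked <- with_seed(sub_seed(seed, "experience"),
                      sample(active, n_sel))
  wenv <- new.env(parent = emptyenv())
  wenv$x <- sheet$W@x
  for (pix in picked) {
    steer_pixel(sheet, wenv, pix, theta_dom, taper = 1, gamma = 2,
                eps = 0.2, adjust_dominant = TRUE)
  }
  sheet$W@x <- wenv$x
  sheet
}
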