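## Model stage 2: sorting of thalamic afferents in the cortical subplate,
## first by retinotopy, then by eye input, then by ON-OFF polarity, using
## difference-of-Gaussians sorting filters and local swap moves.

SLOT_PITCH_UM <- 50   # one afferent per 50-um subplate slot

#' Subplate grid shape for an afferent count
#'
#' The subplate accommodates one afferent per 50-um slot on a square lattice;
#' non-square counts are padded to the next square with inert border slots
#' that are excluded from sorting.
#'
#' @param n_afferents number of afferents (>= 1).
#' @return list with `shape` (slots per side), `n_slots`, `n_padded`, and
#'   `physical_um` (side length in microns).
#' @export
subplate_from_afferent_count <- function(n_afferents) {
  if (n_afferents < 1) stop("need at least one afferent")
  side <- as.integer(ceiling(sqrt(n_afferents)))
  list(shape = c(side, side), n_slots = side * side,
       n_padded = side * side - as.integer(n_afferents),
       physical_um = side * SLOT_PITCH_UM)
}

#' Afferent sorting filter (difference of Gaussians)
#'
#' Centre-surround kernel: a circular centre Gaussian (SD `sigma_c`) minus an
#' elongatable surround Gaussian (SDs `sigma_sx`, `sigma_sy`, correlation
#' `rho`), both bivariate Gaussian densities. `angle` rotates the surround's
#' principal axes (degrees); `rho` is kept as the printed correlation term
#' for unrotated filters. All SDs are in microns; the kernel is sampled at
#' the 50-um slot pitch and truncated at 4 times the largest SD.
#'
#' @param sigma_c centre SD (um).
#' @param sigma_sx,sigma_sy surround SDs (um).
#' @param rho surround correlation in (-1, 1).
#' @param angle surround rotation (degrees, default 0).
#' @param pitch_um sampling pitch (um per slot).
#' @return a `sorting_filter`: list with the sampled `kernel`, its centre
#'   index `c0`, and the parameters.
#' @export
make_sorting_filter <- function(sigma_c, sigma_sx, sigma_sy, rho = 0,
                                angle = 0, pitch_um = SLOT_PITCH_UM) {
  if (sigma_c <= 0 || sigma_sx <= 0 || sigma_sy <= 0) stop("filter SDs must be positive")
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  h <- as.integer(ceiling(4 * max(sigma_c, sigma_sx, sigma_sy) / pitch_um))
  off <- (-h:h) * pitch_um
  X <- matrix(off, 2 * h + 1, 2 * h + 1)
  Y <- t(X)
  if (angle != 0) {
    a <- angle * pi / 180
    Xr <- cos(a) * X + sin(a) * Y
    Yr <- -sin(a) * X + cos(a) * Y
  } else {
    Xr <- X; Yr <- Y
  }
  f2 <- function(x, y, sx, sy, r) {
    1 / (2 * pi * sx * sy * sqrt(1 - r^2)) *
      exp(-(x^2 / sx^2 + y^2 / sy^2 - 2 * r * x * y / (sx * sy)) /
            (2 * (1 - r^2)))
  }
  kernel <- f2(X, Y, sigma_c, sigma_c, 0) - f2(Xr, Yr, sigma_sx, sigma_sy, rho)
  structure(list(kernel = kernel, c0 = h + 1L,
                 sigma_c = sigma_c, sigma_sx = sigma_sx, sigma_sy = sigma_sy,
                 rho = rho, angle = angle, pitch_um = pitch_um),
            class = "sorting_filter")
}

#' @export
print.sorting_filter <- function(x, ...) {
  cat(sprintf(
    "sorting_filter: DoG centre SD %g um, surround SDs (%g, %g) um, rho %g, angle %g deg\n",
    x$sigma_c, x$sigma_sx, x$sigma_sy, x$rho, x$angle))
  cat(sprintf("  kernel %d x %d slots (%g um pitch)\n",
              nrow(x$kernel), ncol(x$kernel), x$pitch_um))
  invisible(x)
}

#' Correlation term of two coordinate vectors
#'
#' Helper reproducing the filter-angle definition: the dot product of `X`
#' and `Y` divided by the product of their magnitudes.
#' @param X,Y numeric vectors.
#' @return scalar in `[-1, 1]`.
#' @export
filter_rho <- function(X, Y) sum(X * Y) / (sqrt(sum(X^2)) * sqrt(sum(Y^2)))

#' Assign afferents to subplate slots by retinotopy
#'
#' Each afferent's retinotopy `(rx, ry)` is mapped linearly onto the slot
#' lattice (lowest retinotopy at the top-left, highest at the bottom-right);
#' afferents claim the nearest free slot in a randomized order, so afferents
#' arriving earlier get the best retinotopic match (ties between the eyes
#' are resolved by the arrival order).
#'
#' @param afferents data.frame from [build_afferent_population()].
#' @param grid_shape optional `c(nx, ny)`; defaults to the square grid from
#'   [subplate_from_afferent_count()].
#' @param seed integer seed for the arrival order.
#' @return a `subplate`: list with `occupancy` (slot -> afferent id matrix,
#'   `NA` on inert padded slots), `active` mask, `afferents` table, `shape`.
#' @export
assign_retinotopy <- function(afferents, grid_shape = NULL, seed = 1L) {
  n <- nrow(afferents)
  if (is.null(grid_shape)) grid_shape <- subplate_from_afferent_count(n)$shape
  nx <- grid_shape[1L]; ny <- grid_shape[2L]
  if (nx * ny < n) stop("grid has fewer slots than afferents")
  active <- matrix(TRUE, nx, ny)
  n_pad <- nx * ny - n
  if (n_pad > 0) {       # inert border slots at the lexicographic end
    idx <- seq(nx * ny - n_pad + 1L, nx * ny)
    active[idx] <- FALSE
  }
  tx <- 1 + (afferents$rx - min(afferents$rx)) /
    max(diff(range(afferents$rx)), .Machine$double.eps) * (nx - 1)
  ty <- 1 + (afferents$ry - min(afferents$ry)) /
    max(diff(range(afferents$ry)), .Machine$double.eps) * (ny - 1)
  order_aff <- with_seed(sub_seed(seed, "assignment"), sample.int(n))
  occupancy <- matrix(NA_integer_, nx, ny)
  free <- active
  for (a in order_aff) {
    xi <- min(max(round(tx[a]), 1L), nx)
    yi <- min(max(round(ty[a]), 1L), ny)
    s <- nearest_free_slot(free, xi, yi, tx[a], ty[a])
    occupancy[s[1L], s[2L]] <- a
    free[s[1L], s[2L]] <- FALSE
  }
  structure(list(occupancy = occupancy, active = active,
                 afferents = afferents, shape = c(nx, ny),
                 pitch_um = SLOT_PITCH_UM),
            class = "subplate")
}

## Nearest free slot to target (txa, tya), searching Chebyshev rings out from
## (xi, yi); among candidates within the first non-empty ring band, picks the
## minimum Euclidean distance, ties by lowest (y, x).
nearest_free_slot <- function(free, xi, yi, txa, tya) {
  nx <- nrow(free); ny <- ncol(free)
  for (r in 0:(max(nx, ny))) {
    xs <- max(1L, xi - r):min(nx, xi + r)
    ys <- max(1L, yi - r):min(ny, yi + r)
    sub <- free[xs, ys, drop = FALSE]
    if (!any(sub)) next
    ## widen band so true Euclidean nearest is included
    r2 <- min(max(nx, ny), as.integer(ceiling(r * 1.5)) + 1L)
    xs <- max(1L, xi - r2):min(nx, xi + r2)
    ys <- max(1L, yi - r2):min(ny, yi + r2)
    sub <- free[xs, ys, drop = FALSE]
    w <- which(sub, arr.ind = TRUE)
    cand_x <- xs[w[, 1L]]; cand_y <- ys[w[, 2L]]
    d <- (cand_x - txa)^2 + (cand_y - tya)^2
    best <- which(d == min(d))
    if (length(best) > 1L) {
      o <- order(cand_y[best], cand_x[best])
      best <- best[o[1L]]
    }
    return(c(cand_x[best], cand_y[best]))
  }
  stop("no free slot available")
}

## Signed channel map (+1/-1, 0 on inert slots) for a subplate.
channel_map <- function(sp, channel = c("eye", "polarity")) {
  channel <- match.arg(channel)
  m <- matrix(0, sp$shape[1L], sp$shape[2L])
  occ <- sp$occupancy
  ok <- !is.na(occ)
  m[ok] <- sp$afferents[[channel]][occ[ok]]
  m
}

#' One developmental sorting step
#'
#' Visits every afferent once (random permutation order under `seed`); for
#' each, evaluates the sorting-filter response centred at the current slot
#' and the eight adjacent slots, with the afferent's value placed at the
#' candidate slot (the displaced afferent taking the vacated one), and moves
#' it to the candidate maximizing the signed response (the afferent's value
#' times the response; set `abs_rule = TRUE` for the literal absolute-value
#' rule). Moves are applied sequentially. During polarity sorting, candidate
#' slots are restricted to slots whose afferent shares the moving afferent's
#' eye, so polarity sorting never crosses an eye border.
#'
#' @param sp a `subplate`.
#' @param filter a [make_sorting_filter()] kernel.
#' @param channel `"eye"` or `"polarity"`.
#' @param seed integer seed for the visit order.
#' @param abs_rule logical; use `|response|` instead of the signed product.
#' @return the updated `subplate`.
#' @export
sorting_step <- function(sp, filter, channel = c("eye", "polarity"),
                         seed = 1L, abs_rule = FALSE) {
  channel <- match.arg(channel)
  M <- channel_map(sp, channel)
  vals <- unique(M[sp$active])
  if (!all(vals %in% c(-1, 1))) stop("channel values must be +1/-1 on active slots")
  eyeM <- if (channel == "polarity") channel_map(sp, "eye") else NULL
  K <- filter$kernel; h <- filter$c0 - 1L; K0 <- K[filter$c0, filter$c0]
  C <- conv2_same(M, K)
  nx <- sp$shape[1L]; ny <- sp$shape[2L]
  occ <- sp$occupancy
  n_aff <- nrow(sp$afferents)
  visit <- with_seed(sub_seed(seed, "sorting-visit"), sample.int(n_aff))
  ## slot of each afferent
  slot_of <- integer(n_aff)
  ok <- which(!is.na(occ))
  slot_of[occ[ok]] <- ok
  ## candidate offsets in fixed lexicographic (dy, dx) order for tie-breaks
  offs <- expand.grid(dx = -1:1, dy = -1:1)
  offs <- offs[order(offs$dy, offs$dx), ]
  for (a in visit) {
    s <- slot_of[a]
    i <- ((s - 1L) %% nx) + 1L
    j <- ((s - 1L) %/% nx) + 1L
    v <- M[i, j]
    best_score <- -Inf; best_k <- NA_integer_
    cur_score <- NA_real_
    cand_i <- integer(0); cand_j <- integer(0); cand_score <- numeric(0)
    for (k in seq_len(9L)) {
      ii <- i + offs$dx[k]; jj <- j + offs$dy[k]
      if (ii < 1L || ii > nx || jj < 1L || jj > ny) next
      if (!sp$active[ii, jj]) next
      if (!is.null(eyeM) && eyeM[ii, jj] != eyeM[i, j]) next
      if (ii == i && jj == j) {
        R <- C[i, j]
      } else {
        mp <- M[ii, jj]
        dk <- K[filter$c0 + (ii - i), filter$c0 + (jj - j)]
        R <- C[ii, jj] + (v - mp) * K0 + (mp - v) * dk
      }
      sc <- if (abs_rule) abs(R) else v * R
      if (ii == i && jj == j) cur_score <- sc
      cand_i <- c(cand_i, ii); cand_j <- c(cand_j, jj)
      cand_score <- c(cand_score, sc)
    }
    mx <- max(cand_score)
    if (cur_score >= mx - 1e-12) next      # keep current position on ties
    pick <- which(cand_score >= mx - 1e-12)[1L]  # offs already (dy,dx)-ordered
    ii <- cand_i[pick]; jj <- cand_j[pick]
    ## swap afferent a with the occupant of (ii, jj)
    b <- occ[ii, jj]
    occ[ii, jj] <- a; occ[i, j] <- b
    slot_of[a] <- (jj - 1L) * nx + ii
    slot_of[b] <- (j - 1L) * nx + i
    mp <- M[ii, jj]
    if (mp != v) {
      M[ii, jj] <- v; M[i, j] <- mp
      ## incremental update of the convolution field
      C <- add_kernel_patch(C, K, h, i, j, mp - v)
      C <- add_kernel_patch(C, K, h, ii, jj, v - mp)
    }
  }
  sp$occupancy <- occ
  sp
}

## C(q) += delta * K(q - s) for all q within the kernel support of slot (i, j).
add_kernel_patch <- function(C, K, h, i, j, delta) {
  nx <- nrow(C); ny <- ncol(C)
  xs <- max(1L, i - h):min(nx, i + h)
  ys <- max(1L, j - h):min(ny, j + h)
  C[xs, ys] <- C[xs, ys] + delta * K[xs - i + h + 1L, ys - j + h + 1L, drop = FALSE]
  C
}

#' Sort afferents by eye input, then by ON-OFF polarity
#'
#' Runs `n_steps` developmental steps of eye sorting followed by `n_steps`
#' steps of eye-constrained polarity sorting.
#'
#' @param sp a `subplate` with retinotopic assignment done.
#' @param filter_eye,filter_pol sorting filters for the two channels.
#' @param n_steps developmental steps per channel (default 10).
#' @param seed integer seed (one visit-order sub-stream per step).
#' @param abs_rule see [sorting_step()].
#' @return the sorted `subplate`.
#' @export
sort_afferents <- function(sp, filter_eye, filter_pol = filter_eye,
                           n_steps = 10L, seed = 1L, abs_rule = FALSE) {
  for (s in seq_len(n_steps)) {
    sp <- sorting_step(sp, filter_eye, "eye",
                       seed = sub_seed(seed, paste0("eye-step-", s)),
                       abs_rule = abs_rule)
  }
  for (s in seq_len(n_steps)) {
    sp <- sorting_step(sp, filter_pol, "polarity",
                       seed = sub_seed(seed, paste0("pol-step-", s)),
                       abs_rule = abs_rule)
  }
  sp
}

#' Randomly shuffle afferent slots (unsorted control)
#'
#' Replaces the current occupancy with a random permutation over the active
#' slots; used for no-sorting control simulations.
#'
#' @param sp a `subplate`.
#' @param channel `"all"` permutes every afferent; `"polarity"` permutes
#'   afferents only within each eye's territory.
#' @param seed integer seed.
#' @return the shuffled `subplate`.
#' @export
shuffle_subplate <- function(sp, channel = c("all", "polarity"), seed = 1L) {
  channel <- match.arg(channel)
  occ <- sp$occupancy
  if (channel == "all") {
    slots <- which(!is.na(occ))
    occ[slots] <- with_seed(sub_seed(seed, "shuffle"), occ[sample(slots)])
  } else {
    eye <- channel_map(sp, "eye")
    for (ev in c(1, -1)) {
      slots <- which(!is.na(occ) & eye == ev)
      occ[slots] <- with_seed(sub_seed(seed, paste0("shuffle", ev)),
                              occ[sample(slots)])
    }
  }
  sp$occupancy <- occ
  sp
}

#' @export
print.subplate <- function(x, ...) {
  cat(sprintf("subplate: %d x %d slots (%g um pitch), %d afferents\n",
              x$shape[1L], x$shape[2L], x$pitch_um, nrow(x$afferents)))
  eye <- channel_map(x, "eye")
  cat(sprintf("  contra/ipsi slots: %d / %d; ON/OFF: %d / %d\n",
              sum(eye == 1), sum(eye == -1),
              sum(channel_map(x, "polarity") == 1),
              sum(channel_map(x, "polarity") == -1)))
  invisible(x)
}
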