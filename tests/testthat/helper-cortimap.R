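## Shared helpers: memoised model runs (several tests reuse the same
## reduced-scale simulations) and small measurement utilities.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

## tiny hand-built subplate for sheet-level unit tests
plate_from <- function(eye, polarity, rx, ry, shape, sigma = 2) {
  aff <- data.frame(eye = eye, polarity = polarity, rx = rx, ry = ry,
                    sigma = sigma)
  structure(list(occupancy = matrix(seq_len(shape[1L] * shape[2L]),
                                    shape[1L], shape[2L]),
                 active = matrix(TRUE, shape[1L], shape[2L]),
                 afferents = aff, shape = shape, pitch_um = 50),
            class = "subplate")
}

## full reduced cat-preset run (48x48 subplate) used by several tests
cat48_run <- function(seed) {
  cached(paste0("cat48_", seed), {
    cfg <- cortimap_config("cat", seed = seed,
                           retina = list(nx = 24L, ny = 24L))
    run_cortical_model(cfg)
  })
}

## direct (loop-based) evaluation of the filter response centred at
## candidate slot (ci, cj) on map M with the swap applied -- the
## independent oracle for sorting_step
brute_force_response <- function(M, K, c0, i, j, ci, cj) {
  Ms <- M
  tmp <- Ms[i, j]; Ms[i, j] <- Ms[ci, cj]; Ms[ci, cj] <- tmp
  acc <- 0
  for (u in seq_len(nrow(M))) {
    for (v in seq_len(ncol(M))) {
      du <- u - ci + c0; dv <- v - cj + c0
      if (du >= 1 && du <= nrow(K) && dv >= 1 && dv <= ncol(K)) {
        acc <- acc + K[du, dv] * Ms[u, v]
      }
    }
  }
  acc
}

## fraction of 4-neighbour slot pairs sharing the same channel value
same_neighbor_fraction <- function(M) {
  nx <- nrow(M); ny <- ncol(M)
  h <- M[-nx, ] == M[-1L, ]
  v <- M[, -ny] == M[, -1L]
  mean(c(h, v))
}

## correlation length along each axis of the doubled-angle components
orientation_corr_lengths <- function(om) {
  cc <- cos(2 * om); ss <- sin(2 * om)
  len <- function(m, axis) {
    ac <- function(v) {
      v <- v - mean(v)
      a <- stats::acf(v, lag.max = length(v) - 1L, plot = FALSE,
                      demean = FALSE)$acf[, 1L, 1L]
      which(a < 0.5)[1L] %||% length(a)
    }
    if (axis == 1L) mean(apply(m, 2L, ac)) else mean(apply(m, 1L, ac))
  }
  `%||%` <- function(a, b) if (is.na(a) || is.null(a)) b else a
  c(x = (len(cc, 1L) + len(ss, 1L)) / 2, y = (len(cc, 2L) + len(ss, 2L)) / 2)
}
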