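## Internal numerical helpers shared across modules.

#' Derive a named sub-stream seed from a global seed
#'
#' One global seed fans out to independent named streams (retina, assignment,
#' sorting, tracks, ...) so that individual stages can be re-run reproducibly.
#'
#' @param seed integer global seed.
#' @param stream character stream name.
#' @return an integer seed below 2^31.
#' @export
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  ## cheap string hash, kept well below .Machine$integer.max
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483587L)
}

## Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## 2-D linear convolution with zero padding, evaluated on the input's grid
## ("same" output size, kernel centre aligned). FFT-based.
conv2_same <- function(x, k) {
  nx <- nrow(x); ny <- ncol(x)
  kx <- nrow(k); ky <- ncol(k)
  px <- nx + kx - 1L; py <- ny + ky - 1L
  X <- matrix(0, px, py); X[seq_len(nx), seq_len(ny)] <- x
  K <- matrix(0, px, py); K[seq_len(kx), seq_len(ky)] <- k
  full <- Re(fft(fft(X) * fft(K), inverse = TRUE)) / (px * py)
  ox <- (kx - 1L) %/% 2L; oy <- (ky - 1L) %/% 2L
  full[ox + seq_len(nx), oy + seq_len(ny)]
}

## Acute difference between two orientations (radians, mod pi).
circ_diff_pi <- function(a, b) {
  d <- (a - b) %% pi
  pmin(d, pi - d)
}

## Resultant length of doubled-angle unit vectors; theta in radians mod pi.
circ_resultant <- function(theta, w = NULL) {
  if (is.null(w)) w <- rep(1, length(theta))
  s <- sum(w * exp(2i * theta))
  Mod(s) / sum(w)
}

## Circular mean orientation (radians in [0, pi)).
circ_mean_pi <- function(theta, w = NULL) {
  if (is.null(w)) w <- rep(1, length(theta))
  (Arg(sum(w * exp(2i * theta))) / 2) %% pi
}

## Bilinear upsampling of a matrix by an integer factor.
upsample_bilinear <- function(m, factor = 4L) {
  nx <- nrow(m); ny <- ncol(m)
  if (nx < 2L || ny < 2L) return(m[rep(seq_len(nx), each = factor),
                                   rep(seq_len(ny), each = factor), drop = FALSE])
  xo <- seq(1, nx, length.out = nx * factor)
  yo <- seq(1, ny, length.out = ny * factor)
  x0 <- pmin(floor(xo), nx - 1L); fx <- xo - x0
  y0 <- pmin(floor(yo), ny - 1L); fy <- yo - y0
  m00 <- m[x0, y0, drop = FALSE]; m10 <- m[x0 + 1L, y0, drop = FALSE]
  m01 <- m[x0, y0 + 1L, drop = FALSE]; m11 <- m[x0 + 1L, y0 + 1L, drop = FALSE]
  FX <- matrix(fx, length(xo), length(yo))
  FY <- matrix(fy, length(xo), length(yo), byrow = TRUE)
  m00 * (1 - FX) * (1 - FY) + m10 * FX * (1 - FY) +
    m01 * (1 - FX) * FY + m11 * FX * FY
}

## Upsample an orientation map (radians mod pi) on its doubled-angle
## cos/sin components, then recombine.
upsample_orientation <- function(om, factor = 4L) {
  cc <- upsample_bilinear(cos(2 * om), factor)
  ss <- upsample_bilinear(sin(2 * om), factor)
  (atan2(ss, cc) / 2) %% pi
}

## 4-connected labelling of TRUE regions in a logical matrix.
label_components <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      i <- ((p - 1L) %% nx) + 1L
      j <- ((p - 1L) %/% nx) + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ii <- i + d[1L]; jj <- j + d[2L]
        if (ii >= 1L && ii <= nx && jj >= 1L && jj <= ny) {
          q <- (jj - 1L) * nx + ii
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}
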