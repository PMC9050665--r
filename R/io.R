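## Fixtures, map-set serialization and rendering.

#' Generate small deterministic test fixtures
#'
#' Kinds: `tiny_retina` (a 6x6-per-polarity two-eye mosaic table),
#' `stripe_od` (alternating +-1 bands), `beaded_od` (thresholded smoothed
#' noise), `synthetic_tracks` (one [make_synthetic_track()] track), and
#' `pinwheel_field` (`theta = atan2(y, x) / 2` raster with a single
#' singularity).
#'
#' @param kind fixture kind.
#' @param seed integer seed.
#' @param n raster side / cell count parameter (kind-dependent).
#' @param period stripe period in pixels (stripe_od).
#' @param dir optional directory; when given, the fixture is also written
#'   as tabular text.
#' @return the fixture object (matrix, data.frame or list).
#' @export
make_fixtures <- function(kind = c("tiny_retina", "stripe_od", "beaded_od",
                                   "synthetic_tracks", "pinwheel_field"),
                          seed = 1L, n = 64L, period = 16L, dir = NULL) {
  kind <- match.arg(kind)
  obj <- switch(kind,
    tiny_retina = {
      cfg <- mosaic_config(nx = 6L, ny = 6L, seed = seed)
      con <- build_retinal_mosaic(cfg, "contra")
      ips <- build_retinal_mosaic(cfg, "ipsi")
      aff <- build_afferent_population(con, ips)
      data.frame(eye = ifelse(aff$eye == 1, "contra", "ipsi"),
                 polarity = ifelse(aff$polarity == 1, "ON", "OFF"),
                 rx = aff$rx, ry = aff$ry)
    },
    stripe_od = {
      m <- matrix(0, n, n)
      m[] <- ifelse(((col(m) - 1L) %/% (period %/% 2L)) %% 2L == 0L, 1, -1)
      m
    },
    beaded_od = {
      z <- with_seed(sub_seed(seed, "beaded"), matrix(stats::rnorm(n * n), n, n))
      h <- period / 4
      k <- exp(-outer((-24:24)^2, (-24:24)^2, "+") / (2 * h^2))
      sm <- conv2_same(z, k)
      ifelse(sm >= stats::median(sm), 1, -1)
    },
    synthetic_tracks = make_synthetic_track(seed = seed),
    pinwheel_field = {
      cx <- floor(n / 2) + 0.5      # singularity between grid nodes
      (atan2(outer(rep(1, n), seq_len(n) - cx),
             outer(seq_len(n) - cx, rep(1, n))) / 2) %% pi
    })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(dir, paste0(kind, ".tsv"))
    if (is.matrix(obj)) {
      write_raster(obj, path)
    } else if (is.data.frame(obj)) {
      utils::write.table(obj, path, sep = "\t", row.names = FALSE,
                         quote = FALSE)
    }
  }
  obj
}

write_raster <- function(m, path) {
  utils::write.table(formatC(m, format = "g", digits = 17), path,
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

read_raster <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}

#' Write a map set to a directory
#'
#' One tabular-text raster per map dimension plus a JSON manifest recording
#' the geometry, seed, conventions and package version; the round trip
#' through [read_mapset()] is lossless.
#'
#' @param ms a `map_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mapset <- function(ms, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dims <- setdiff(names(ms), "meta")
  dims <- dims[!vapply(ms[dims], is.null, logical(1))]
  for (nm in dims) write_raster(ms[[nm]], file.path(dir, paste0(nm, ".tsv")))
  manifest <- c(ms$meta, list(dimensions = dims,
                              shape = dim(ms$OM),
                              raster_layout = "row-major, origin top-left, y down"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a map set from a directory
#'
#' @param dir directory written by [write_mapset()].
#' @return a `map_set`.
#' @export
read_mapset <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  cur <- as.character(utils::packageVersion("cortimap"))
  if (!identical(manifest$version, cur)) {
    warning(sprintf("map set written by version %s, reading with %s",
                    manifest$version, cur))
  }
  ms <- list()
  for (nm in manifest$dimensions) {
    path <- file.path(dir, paste0(nm, ".tsv"))
    if (!file.exists(path)) stop("missing raster for dimension '", nm, "'")
    ms[[nm]] <- read_raster(path)
  }
  ms$meta <- manifest[setdiff(names(manifest),
                              c("dimensions", "shape", "raster_layout"))]
  class(ms) <- "map_set"
  ms
}

#' Render a map as a PNG image
#'
#' Orientation maps are rendered on an HSV hue wheel (hue = orientation /
#' 180 degrees); other maps on a signed grayscale. Requires the `png`
#' package.
#'
#' @param m matrix to render.
#' @param path output PNG path.
#' @param orientation logical; treat values as radians mod pi.
#' @return `path`, invisibly.
#' @export
render_map_png <- function(m, path, orientation = FALSE) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG rendering")
  }
  if (orientation) {
    hue <- (m %% pi) / pi
    col <- grDevices::hsv(pmin(pmax(hue, 0), 1), 1, 1)
  } else {
    v <- (m - min(m, na.rm = TRUE)) /
      max(diff(range(m, na.rm = TRUE)), .Machine$double.eps)
    col <- grDevices::gray(pmin(pmax(v, 0), 1))
  }
  rgb <- grDevices::col2rgb(col) / 255
  img <- array(0, c(ncol(m), nrow(m), 3))   # rows of the image = y axis
  for (ch in 1:3) img[, , ch] <- t(matrix(rgb[ch, ], nrow(m), ncol(m)))
  png::writePNG(img, path)
  invisible(path)
}
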