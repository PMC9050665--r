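## Run configuration: nested blocks (retina / subplate / cortex / metrics),
## species presets, validation, and YAML round-trip.

preset_defaults <- function(preset = c("cat", "cat_full", "macaque", "lowdensity")) {
  preset <- match.arg(preset)
  base <- list(
    preset = preset,
    seed = 1L,
    retina = list(nx = 30L, ny = 30L, dx = 5, dy = 5, rjx = 0.3, rjy = 0.3,
                  Mindr = 2, Maxdr = 6, rf_sigma = 3,
                  microns_per_retinal_pixel = 22, microns_per_degree = 250),
    subplate = list(sigma_c_um = 250, sigma_sx_um = 500, sigma_sy_um = 500,
                    pol_sigma_c_um = 250, pol_sigma_sx_um = 500,
                    pol_sigma_sy_um = 500, pol_angle = 0,
                    rho = 0, n_steps = 10L,
                    sort = "full"),      # "full" | "eye_only" | "none"
    cortex = list(sigma_arbor = 3, radius = 10, competition = TRUE,
                  zone_deg = 1, sharpen = FALSE, window = 32L,
                  coverage = TRUE, binocular = TRUE, pom_variants = FALSE,
                  experience = "normal", deprived_eye = -1,
                  theta_dom = 0, pcl = 0.2, interpolate = 4L),
    metrics = list(track_len = 40L, n_tracks = 1000L,
                   signs = as.list(track_correlation_signs()),
                   ranges = list(cv = 0.5, sf50 = 1.0, lpi = 0.5, lhi = 0.5),
                   range_frac = 0.2)
  )
  switch(preset,
    cat = base,                      # reduced-scale cat preset
    cat_full = {
      base$retina$nx <- base$retina$ny <- 300L
      base$subplate$sigma_c_um <- 500
      base$subplate$sigma_sx_um <- base$subplate$sigma_sy_um <- 1000
      base$subplate$pol_sigma_c_um <- 500
      base$subplate$pol_sigma_sx_um <- base$subplate$pol_sigma_sy_um <- 1000
      base
    },
    macaque = {                      # elongated surround -> OD stripes;
      base$subplate$sigma_sx_um <- 250      # polarity filter orthogonal
      base$subplate$sigma_sy_um <- 500
      base$subplate$pol_sigma_sx_um <- 250
      base$subplate$pol_sigma_sy_um <- 500
      base$subplate$pol_angle <- 90
      base
    },
    lowdensity = {                   # same mosaic geometry, sparse sampling;
      base$retina$dx <- base$retina$dy <- 15
      ## axon arbors only spread over cortex with overlapping retinotopy, so
      ## the arbor shrinks with the iso-retinotopic domain
      base$cortex$sigma_arbor <- 1
      base$cortex$radius <- 3
      base
    })
}

#' Build a validated run configuration
#'
#' Starts from a species preset (`cat` is the reduced-scale cat preset;
#' `cat_full` carries the published full-scale geometry; `macaque` uses
#' elongated, mutually orthogonal sorting filters; `lowdensity` keeps the
#' cat mosaic geometry but samples visual space three times more sparsely)
#' and applies the overrides given in `...` as named nested values, e.g.
#' `cortimap_config("cat", seed = 7, retina = list(nx = 24))`.
#'
#' @param preset preset name.
#' @param ... overrides for the nested blocks or top-level fields.
#' @return a validated `cortimap_config` list.
#' @export
cortimap_config <- function(preset = "cat", ...) {
  cfg <- preset_defaults(preset)
  cfg <- merge_config(cfg, list(...))
  validate_config(cfg)
}

merge_config <- function(cfg, over, path = "") {
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) {
      stop(sprintf("unknown configuration key%s: '%s%s'",
                   if (nzchar(path)) " in block" else "", path, nm))
    }
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]) &&
        !is.null(names(cfg[[nm]]))) {
      cfg[[nm]] <- merge_config(cfg[[nm]], over[[nm]],
                                path = paste0(path, nm, "$"))
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  cfg
}

validate_config <- function(cfg) {
  r <- cfg$retina
  bad <- character(0)
  chk <- function(cond, msg) if (!cond) bad <<- c(bad, msg)
  chk(r$nx >= 1 && r$ny >= 1, "retina$nx, retina$ny must be >= 1")
  chk(r$dx > 0 && r$dy > 0, "retina$dx, retina$dy must be > 0")
  chk(r$rjx >= 0 && r$rjy >= 0, "retina$rjx, retina$rjy must be >= 0")
  chk(r$Maxdr >= r$Mindr && r$Mindr >= 0, "need retina$Maxdr >= Mindr >= 0")
  chk(r$rf_sigma > 0, "retina$rf_sigma must be > 0")
  s <- cfg$subplate
  chk(all(c(s$sigma_c_um, s$sigma_sx_um, s$sigma_sy_um,
            s$pol_sigma_c_um, s$pol_sigma_sx_um, s$pol_sigma_sy_um) > 0),
      "subplate filter SDs must be > 0")
  chk(abs(s$rho) < 1, "subplate$rho must be in (-1, 1)")
  chk(s$n_steps >= 0, "subplate$n_steps must be >= 0")
  chk(s$sort %in% c("full", "eye_only", "none"),
      "subplate$sort must be 'full', 'eye_only' or 'none'")
  cx <- cfg$cortex
  chk(cx$sigma_arbor > 0, "cortex$sigma_arbor must be > 0")
  chk(cx$radius > 0, "cortex$radius must be > 0")
  chk(cx$zone_deg > 0, "cortex$zone_deg must be > 0")
  chk(cx$pcl >= 0 && cx$pcl <= 1, "cortex$pcl must be in [0, 1]")
  chk(cx$experience %in% c("normal", "monocular_deprivation",
                           "orientation_bias"),
      "cortex$experience must be normal/monocular_deprivation/orientation_bias")
  if (length(bad)) stop("invalid configuration:\n  ", paste(bad, collapse = "\n  "))
  class(cfg) <- "cortimap_config"
  cfg
}

#' @export
print.cortimap_config <- function(x, ...) {
  cat(sprintf("cortimap_config (preset '%s', seed %d)\n", x$preset, x$seed))
  cat(sprintf("  retina: %dx%d cells/polarity/eye, spacing (%g, %g) px, RF sigma %g px\n",
              x$retina$nx, x$retina$ny, x$retina$dx, x$retina$dy,
              x$retina$rf_sigma))
  cat(sprintf("  subplate: eye filter [%g, %g, %g] um, %d steps, sort = %s\n",
              x$subplate$sigma_c_um, x$subplate$sigma_sx_um,
              x$subplate$sigma_sy_um, x$subplate$n_steps, x$subplate$sort))
  cat(sprintf("  cortex: arbor sigma %g px / radius %g px, competition = %s, experience = %s\n",
              x$cortex$sigma_arbor, x$cortex$radius, x$cortex$competition,
              x$cortex$experience))
  invisible(x)
}

#' Load a run configuration from a YAML file
#'
#' Applies the file's preset defaults first, then the file's own overrides;
#' unknown keys are rejected with their full names.
#'
#' @param path YAML file path.
#' @return a validated `cortimap_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  preset <- raw$preset %||% "cat"
  raw$preset <- NULL
  do.call(cortimap_config, c(list(preset = preset), raw))
}

#' Save a run configuration to a YAML file
#' @param cfg a `cortimap_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
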