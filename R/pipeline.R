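## End-to-end model run: retinas -> afferents -> subplate sorting -> arbor
## spread -> competition -> primordial map -> coverage optimization ->
## binocular matching -> experience -> map set.

#' Run the full afferent-density model
#'
#' Executes the three developmental stages under one configuration and
#' returns the matured map set together with the intermediate state. All
#' randomness derives from `cfg$seed` through named sub-streams, so two runs
#' with the same configuration are bit-identical.
#'
#' @param cfg a [cortimap_config()].
#' @param keep_state keep the heavier intermediates (sheet, subplate) in the
#'   result (default TRUE).
#' @return a `cortimap_run`: list with `maps` (a `map_set`), `match`
#'   (binocular matching summary or NULL), `pom_state`, `clusters`, and,
#'   when `keep_state`, `sheet`, `subplate`, `mosaics`.
#' @export
run_cortical_model <- function(cfg, keep_state = TRUE) {
  stopifnot(inherits(cfg, "cortimap_config"))
  r <- cfg$retina
  mcfg <- mosaic_config(nx = r$nx, ny = r$ny, dx = r$dx, dy = r$dy,
                        rjx = r$rjx, rjy = r$rjy, Mindr = r$Mindr,
                        Maxdr = r$Maxdr, rf_sigma = r$rf_sigma,
                        microns_per_retinal_pixel = r$microns_per_retinal_pixel,
                        microns_per_degree = r$microns_per_degree,
                        seed = sub_seed(cfg$seed, "retina"))
  contra <- build_retinal_mosaic(mcfg, "contra")
  ipsi <- build_retinal_mosaic(mcfg, "ipsi")
  aff <- build_afferent_population(contra, ipsi)
  deg_per_pixel <- r$microns_per_retinal_pixel / r$microns_per_degree

  sp <- assign_retinotopy(aff, seed = sub_seed(cfg$seed, "assignment"))
  s <- cfg$subplate
  f_eye <- make_sorting_filter(s$sigma_c_um, s$sigma_sx_um, s$sigma_sy_um,
                               rho = s$rho)
  f_pol <- make_sorting_filter(s$pol_sigma_c_um, s$pol_sigma_sx_um,
                               s$pol_sigma_sy_um, rho = s$rho,
                               angle = s$pol_angle)
  if (s$sort == "full") {
    sp <- sort_afferents(sp, f_eye, f_pol, n_steps = s$n_steps,
                         seed = sub_seed(cfg$seed, "sorting"))
  } else if (s$sort == "eye_only") {
    for (st in seq_len(s$n_steps)) {
      sp <- sorting_step(sp, f_eye, "eye",
                         seed = sub_seed(cfg$seed, paste0("eye-step-", st)))
    }
  }

  cx <- cfg$cortex
  sheet <- spread_arbors(sp, sigma_arbor = cx$sigma_arbor, radius = cx$radius)
  if (cx$experience == "monocular_deprivation") {
    sheet <- apply_experience(sheet, "monocular_deprivation",
                              deprived_eye = cx$deprived_eye)
  }
  ## competition = TRUE is the full ON-OFF synaptic competition; FALSE is
  ## the variant without ON-OFF clusters, where only retinotopic
  ## competition applies and weights come directly from the dominant
  ## weight matrix
  sheet <- synaptic_competition(sheet, zone_deg = cx$zone_deg,
                                microns_per_retinal_pixel = r$microns_per_retinal_pixel,
                                microns_per_degree = r$microns_per_degree,
                                sharpen = cx$sharpen,
                                mode = if (isTRUE(cx$competition)) "onoff"
                                       else "retinotopic")
  pom_state <- primordial_map(sheet, window = cx$window,
                              deg_per_pixel = deg_per_pixel,
                              variants = isTRUE(cx$pom_variants))
  clusters <- afferent_clusters(sheet)
  om <- pom_state$pom
  if (isTRUE(cx$coverage)) {
    opt <- suppressWarnings(optimize_coverage(om, clusters, f_pol))
    om <- opt$om
  }
  match <- NULL
  if (isTRUE(cx$binocular)) {
    match <- binocular_match(sheet, om, clusters, window = cx$window,
                             deg_per_pixel = deg_per_pixel)
    sheet <- match$sheet
    match$sheet <- NULL
  }
  if (cx$experience == "orientation_bias") {
    sheet <- apply_experience(sheet, "orientation_bias",
                              theta_dom = cx$theta_dom, pcl = cx$pcl,
                              seed = sub_seed(cfg$seed, "bias"))
  }
  maps <- build_map_set(sheet, om, cfg, match = match,
                        deg_per_pixel = deg_per_pixel)
  out <- list(maps = maps, match = match, pom_state = pom_state,
              clusters = clusters, config = cfg)
  if (keep_state) {
    out$sheet <- sheet
    out$subplate <- sp
    out$mosaics <- list(contra = contra, ipsi = ipsi)
  }
  structure(out, class = "cortimap_run")
}

#' @export
print.cortimap_run <- function(x, ...) {
  cat(sprintf("cortimap_run: preset '%s', seed %d, %d x %d cortical pixels\n",
              x$config$preset, x$config$seed,
              nrow(x$maps$OM), ncol(x$maps$OM)))
  if (!is.null(x$match)) {
    cat(sprintf("  binocular orientation match (iteration 1): %.1f%%\n",
                100 * x$match$match_frac_iter1))
  }
  cat(sprintf("  pinwheel density %.2f / mm^2; mean CV %.2f; SF50 %.2f-%.2f cpd\n",
              find_pinwheels(x$maps$OM)$density_mm2,
              mean(x$maps$OSM, na.rm = TRUE),
              min(x$maps$SF50, na.rm = TRUE), max(x$maps$SF50, na.rm = TRUE)))
  invisible(x)
}

#' Assemble the aligned map set from a matured sheet
#'
#' Computes the final per-pixel tuning and the weight-based maps: OM
#' (matured orientation), OSM (circular variance), OHM (local homogeneity),
#' SFM / SF50 / LPI (spatial frequency), RM (receptive-field centres in
#' degrees), ODM (signed contra-ipsi weight balance), CPM (signed ON-OFF
#' weight balance) and ODI.
#'
#' @param sheet matured `cortical_sheet`.
#' @param om matured orientation map.
#' @param cfg the run configuration (recorded in the meta block).
#' @param match optional binocular matching summary (per-eye maps reused).
#' @param deg_per_pixel degrees per retinal pixel.
#' @return a `map_set` (list of aligned matrices + `meta`).
#' @export
build_map_set <- function(sheet, om, cfg, match = NULL,
                          deg_per_pixel = 22 / 250) {
  tun <- sheet_tuning(sheet, window = cfg$cortex$window,
                      deg_per_pixel = deg_per_pixel)
  aff <- sheet$afferents
  W <- sheet$W
  wsum <- function(rows) Matrix::colSums(W[rows, , drop = FALSE])
  nsel <- function(rows) Matrix::colSums(W[rows, , drop = FALSE] > 0)
  shp <- sheet$shape
  msh <- function(v) matrix(v, shp[1L], shp[2L])
  w_con <- wsum(aff$eye == 1); w_ips <- wsum(aff$eye == -1)
  w_on <- wsum(aff$polarity == 1); w_off <- wsum(aff$polarity == -1)
  n_con <- nsel(aff$eye == 1); n_ips <- nsel(aff$eye == -1)
  odm <- msh((w_con - w_ips) / pmax(w_con + w_ips, .Machine$double.eps))
  cpm <- msh((w_on - w_off) / pmax(w_on + w_off, .Machine$double.eps))
  m_con <- ifelse(n_con > 0, w_con / n_con, 0)
  m_ips <- ifelse(n_ips > 0, w_ips / n_ips, 0)
  odi <- msh(pmax(m_con, m_ips) / ifelse(pmin(m_con, m_ips) > 0,
                                         pmin(m_con, m_ips), NA))
  structure(list(
    OM = om, OSM = tun$cv, OHM = local_homogeneity_index(om),
    SFM = tun$sfm, SF50 = tun$sf50, LPI = tun$lpi,
    RM_x = tun$rm_x, RM_y = tun$rm_y,
    ODM = odm, CPM = cpm, ODI = odi,
    OM_contra = if (!is.null(match)) match$om_contra else NULL,
    OM_ipsi = if (!is.null(match)) match$om_ipsi else NULL,
    meta = list(pitch_um = sheet$pitch_um, seed = cfg$seed,
                preset = cfg$preset, interpolate = 1L,
                pinwheel_sign = "counter-clockwise winding = +1",
                version = as.character(utils::packageVersion("cortimap")))),
    class = "map_set")
}

#' @export
print.map_set <- function(x, ...) {
  dims <- setdiff(names(x), "meta")
  dims <- dims[!vapply(x[dims], is.null, logical(1))]
  cat(sprintf("map_set: %d x %d pixels (%g um), dimensions: %s\n",
              nrow(x$OM), ncol(x$OM), x$meta$pitch_um,
              paste(dims, collapse = ", ")))
  invisible(x)
}

#' Interpolate all maps of a map set
#'
#' Bilinear upsampling by an integer factor; orientation maps are
#' interpolated on their doubled-angle cosine and sine components
#' separately and then recombined.
#'
#' @param ms a `map_set`.
#' @param factor integer upsampling factor (default 4).
#' @return the interpolated `map_set` (pixel pitch divided accordingly).
#' @export
interpolate_map_set <- function(ms, factor = 4L) {
  orient <- c("OM", "OM_contra", "OM_ipsi")
  for (nm in setdiff(names(ms), "meta")) {
    if (is.null(ms[[nm]])) next
    ms[[nm]] <- if (nm %in% orient) upsample_orientation(ms[[nm]], factor)
                else upsample_bilinear(ms[[nm]], factor)
  }
  ms$meta$pitch_um <- ms$meta$pitch_um / factor
  ms$meta$interpolate <- ms$meta$interpolate * factor
  ms
}
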