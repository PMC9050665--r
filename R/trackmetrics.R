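## Analysis formulas for linear-track tuning data: von Mises orientation
## fits, difference-of-Gaussians spatial-frequency fits, track LHI, ON-OFF
## response balance, and recording-quality filters. A synthetic track
## generator makes the whole pipeline testable without recordings.

#' Orientation tuning fit (von Mises)
#'
#' Fits `R(theta) = b + A * exp(kappa * (cos(2 (theta - theta0)) - 1))` by
#' least squares with multiple starting phases, and reports the preferred
#' orientation from the fit, the circular variance of the raw responses
#' (shared implementation with [circular_variance()]), and the orientation
#' selectivity index `OSI = 1 - NP/PO` (response at the orthogonal
#' orientation over the response at the preferred one, from the fit).
#'
#' @param responses spike counts / rates per orientation (>= 8 values).
#' @param orientations_deg stimulus orientations in degrees (default an
#'   equal grid over 0..180).
#' @return list: `theta_deg`, `kappa`, `cv`, `osi`, `converged` (FALSE when
#'   the fit failed; CV is still reported).
#' @export
fit_orientation <- function(responses,
                            orientations_deg = (seq_along(responses) - 1) *
                              180 / length(responses)) {
  if (length(responses) < 8L) stop("need at least 8 orientations")
  th <- orientations_deg * pi / 180
  cv <- circular_variance(responses, th)
  obj <- function(p) {
    pred <- p[1L] + p[2L] * exp(p[3L] * (cos(2 * (th - p[4L])) - 1))
    sum((pred - responses)^2)
  }
  best <- NULL
  for (th0 in (0:7) * pi / 8) {
    fit <- tryCatch(
      stats::optim(c(min(responses), diff(range(responses)), 2, th0), obj,
                   method = "Nelder-Mead",
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best) || best$par[2L] <= 0 || best$par[3L] <= 0) {
    return(list(theta_deg = NA_real_, kappa = NA_real_, cv = cv,
                osi = NA_real_, converged = FALSE))
  }
  p <- best$par
  theta0 <- (p[4L] %% pi)
  po <- p[1L] + p[2L]                       # fit at preferred
  np <- p[1L] + p[2L] * exp(-2 * p[3L])     # fit at orthogonal
  list(theta_deg = theta0 * 180 / pi, kappa = p[3L], cv = cv,
       osi = 1 - np / po, converged = TRUE)
}

#' Spatial-frequency tuning fit (difference of Gaussians)
#'
#' Fits `R(sf) = Ae * exp(-sf^2 / (2 se^2)) - Ai * exp(-sf^2 / (2 si^2))`
#' to responses sampled on a logarithmic spatial-frequency grid, and reads
#' SF50 (highest SF at half-maximum response) and LPI (zero-frequency
#' response over maximum) from the fitted curve.
#'
#' @param sf spatial frequencies (cpd, >= 6 points).
#' @param resp responses.
#' @return list: `sf50`, `lpi`, `pref_sf`, `pars`, `converged` (FALSE and
#'   `NA` metrics when the fit does not converge).
#' @export
fit_sf <- function(sf, resp) {
  if (length(sf) < 6L) stop("need at least 6 spatial-frequency points")
  df <- data.frame(sf = sf, resp = resp)
  mx <- max(resp)
  med <- stats::median(sf)
  starts <- list(
    list(Ae = mx, se = med, Ai = mx / 2, si = med / 3),
    list(Ae = mx, se = med, Ai = mx / 100, si = med / 2),
    list(Ae = 2 * mx, se = max(sf) / 2, Ai = mx, si = med / 5))
  fit <- NULL
  for (st in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(resp ~ Ae * exp(-sf^2 / (2 * se^2)) -
                          Ai * exp(-sf^2 / (2 * si^2)),
                        data = df, start = st,
                        lower = c(0, 1e-4, 0, 1e-4),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f) &&
        (is.null(fit) || stats::deviance(f) < stats::deviance(fit))) {
      fit <- f
    }
  }
  p <- if (!is.null(fit)) stats::coef(fit) else NULL
  if (is.null(p)) {
    ## degenerate surround (e.g. a purely low-pass profile): fall back to a
    ## single-Gaussian fit with the suppressive term fixed at zero
    f0 <- tryCatch(
      minpack.lm::nlsLM(resp ~ Ae * exp(-sf^2 / (2 * se^2)), data = df,
                        start = list(Ae = mx, se = med),
                        lower = c(0, 1e-4)),
      error = function(e) NULL)
    if (!is.null(f0)) p <- c(stats::coef(f0), Ai = 0, si = 1)
  }
  if (is.null(p)) {
    return(list(sf50 = NA_real_, lpi = NA_real_, pref_sf = NA_real_,
                pars = NULL, converged = FALSE))
  }
  grid <- exp(seq(log(max(min(sf[sf > 0], 1e-3), 1e-4)),
                  log(max(sf) * 1.5), length.out = 400L))
  pred <- p["Ae"] * exp(-grid^2 / (2 * p["se"]^2)) -
    p["Ai"] * exp(-grid^2 / (2 * p["si"]^2))
  r0 <- p["Ae"] - p["Ai"]
  pk <- max(c(pred, r0))
  above <- which(pred >= pk / 2)
  sf50 <- if (length(above)) grid[max(above)] else NA_real_
  list(sf50 = unname(sf50), lpi = unname(max(min(r0 / pk, 1), 0)),
       pref_sf = unname(grid[which.max(pred)]), pars = p, converged = TRUE)
}

#' Relative SF50 within a track
#'
#' Divides each SF50 by the average across the simultaneously recorded
#' sites of the track.
#' @param sf50 SF50 per site (`NA` ignored in the average).
#' @return SF50r vector.
#' @export
track_sf50r <- function(sf50) sf50 / mean(sf50, na.rm = TRUE)

#' Local homogeneity index along a linear track
#'
#' LHI per site over the neighbouring electrodes within `radius_um` of the
#' reference site (the 6 closest at the default 100-um pitch and 300-um
#' radius), weighted by `exp(-d^2 / (2 sigma_um^2))` and normalized so a
#' uniform track yields 1. Edge sites use their available neighbours and
#' are flagged.
#'
#' @param theta_deg preferred orientation per site (degrees).
#' @param positions_um electrode positions (default 100-um pitch).
#' @param radius_um neighbourhood radius (default 300).
#' @param sigma_um Gaussian SD (default 100).
#' @return data.frame: `lhi`, `n_neighbors`, `edge`.
#' @export
track_lhi <- function(theta_deg, positions_um = (seq_along(theta_deg) - 1) * 100,
                      radius_um = 300, sigma_um = 100) {
  n <- length(theta_deg)
  if (n < 7L) stop("need at least 7 sites")
  th <- theta_deg * pi / 180
  full_n <- max(vapply(seq_len(n), function(i) {
    sum(abs(positions_um - positions_um[i]) <= radius_um)
  }, integer(1)))
  out <- data.frame(lhi = numeric(n), n_neighbors = integer(n),
                    edge = logical(n))
  for (i in seq_len(n)) {
    d <- abs(positions_um - positions_um[i])
    nb <- which(d <= radius_um)
    w <- exp(-d[nb]^2 / (2 * sigma_um^2))
    out$lhi[i] <- Mod(sum(w * exp(2i * th[nb]))) / sum(w)
    out$n_neighbors[i] <- length(nb) - 1L
    out$edge[i] <- length(nb) < full_n
  }
  out
}

#' ON-OFF response balance
#'
#' `1 - |ON - OFF| / (ON + OFF)` over receptive-field frame sequences, after
#' normalizing each polarity by its maximum and zeroing responses below 20
#' percent of the maximum. Variants: `mean` (balance of the per-frame
#' maxima, averaged over frames), `maximum` (its maximum over frames),
#' `mean_average` (frames averaged first, then ON/OFF means), and
#' `maximum_average` (frames averaged first, then ON/OFF maxima).
#'
#' @param on_frames,off_frames 3-D arrays (x, y, frame) or matrices.
#' @param variant one of `"mean"`, `"maximum"`, `"mean_average"`,
#'   `"maximum_average"`.
#' @param floor_frac sub-threshold zeroing fraction (default 0.2).
#' @return balance in `[0, 1]` (`NA` with a warning when both polarities
#'   are silent).
#' @export
onoff_balance <- function(on_frames, off_frames,
                          variant = c("mean", "maximum", "mean_average",
                                      "maximum_average"),
                          floor_frac = 0.2) {
  variant <- match.arg(variant)
  as3d <- function(a) if (length(dim(a)) == 3L) a else
    array(a, c(dim(a)[1L], dim(a)[2L], 1L))
  on <- as3d(on_frames); off <- as3d(off_frames)
  mx <- max(max(on), max(off))      # joint maximum across both polarities
  if (mx > 0) { on <- on / mx; off <- off / mx }
  on[on < floor_frac] <- 0
  off[off < floor_frac] <- 0
  if (max(on) == 0 && max(off) == 0) {
    warning("no ON or OFF response; balance undefined")
    return(NA_real_)
  }
  bal <- function(a, b) if (a + b == 0) NA_real_ else 1 - abs(a - b) / (a + b)
  nt <- dim(on)[3L]
  if (variant %in% c("mean", "maximum")) {
    per <- vapply(seq_len(nt), function(t) {
      bal(max(on[, , t]), max(off[, , t]))
    }, numeric(1))
    per <- per[!is.na(per)]
    if (!length(per)) return(0)
    if (variant == "mean") mean(per) else max(per)
  } else {
    avg_on <- apply(on, c(1L, 2L), mean)
    avg_off <- apply(off, c(1L, 2L), mean)
    if (variant == "mean_average") bal(mean(avg_on), mean(avg_off))
    else bal(max(avg_on), max(avg_off))
  }
}

#' Recording-quality filters
#'
#' Inclusion criteria for a recording site: grating signal-to-noise
#' `snr >= 3.5` (maximum response over baseline rate), receptive-field
#' `rf_snr > 12`, orientation `or_snr > 6`, peak orientation response
#' `or_resp > 10` spikes, and agreement between the moving-bar and
#' FFT-predicted preferred orientations `or_diff < 30` degrees (acute,
#' mod 180).
#'
#' @param snr,rf_snr,or_snr,or_resp,or_diff_deg site metrics (`NA` allowed,
#'   treated as failing).
#' @return one-row data.frame of per-criterion booleans plus `include`.
#' @export
quality_filters <- function(snr, rf_snr, or_snr, or_resp, or_diff_deg) {
  ## acute circular difference computed in degrees (exact at the boundary)
  ordiff <- abs(or_diff_deg) %% 180
  ordiff <- pmin(ordiff, 180 - ordiff)
  ok <- function(x) !is.na(x) & x
  out <- data.frame(
    snr_ok = ok(snr >= 3.5),
    rf_snr_ok = ok(rf_snr > 12),
    or_snr_ok = ok(or_snr > 6),
    or_resp_ok = ok(or_resp > 10),
    or_diff_ok = ok(ordiff < 30))
  out$include <- Reduce(`&`, out)
  out
}

#' Generate a synthetic recording track
#'
#' Produces per-site tuning data with configurable coupled gradients: a
#' smooth latent gradient g in [0, 1] along the track drives ON-OFF balance,
#' orientation selectivity (von Mises kappa), spatial resolution (SF50) and
#' local orientation homogeneity, mirroring the covariation structure the
#' model predicts; independent Gaussian noise is added to the responses.
#'
#' @param n_sites sites (default 40, 100-um pitch).
#' @param n_orientations,n_sf stimulus grid sizes.
#' @param sf_range spatial-frequency range in cpd (default 0.03..2).
#' @param noise response noise SD as a fraction of the peak (default 0.05).
#' @param seed integer seed.
#' @return list: `sites` (list of per-site data: `or_resp`,
#'   `orientations_deg`, `sf_resp`, `sf`, `on_frames`, `off_frames`),
#'   `truth` (data.frame of generating parameters per site).
#' @export
make_synthetic_track <- function(n_sites = 40L, n_orientations = 8L,
                                 n_sf = 11L, sf_range = c(0.03, 2),
                                 noise = 0.05, seed = 1L) {
  with_seed(sub_seed(seed, "synthetic-track"), {
    x <- seq(0, 1, length.out = n_sites)
    g <- (sin(2 * pi * x * 1.5 + stats::runif(1, 0, 2 * pi)) + 1) / 2
    theta0 <- (cumsum(stats::rnorm(n_sites, 0, 8)) + 90) %% 180
    kappa <- 0.3 + 3 * g
    balance <- 0.2 + 0.8 * g
    sf50 <- 0.3 + 1.2 * g
    ors <- (0:(n_orientations - 1L)) * 180 / n_orientations
    sfs <- exp(seq(log(sf_range[1L]), log(sf_range[2L]), length.out = n_sf))
    sites <- vector("list", n_sites)
    for (i in seq_len(n_sites)) {
      orr <- 5 + 20 * exp(kappa[i] * (cos(2 * (ors - theta0[i]) * pi / 180) - 1))
      se <- sf50[i] / sqrt(2 * log(2))    # single Gaussian: half-max at sf50
      ai_frac <- 0.8 * g[i]               # more antagonism -> more band-pass
      sfr <- exp(-sfs^2 / (2 * se^2)) - ai_frac * exp(-sfs^2 / (2 * (se / 3)^2))
      sfr <- 20 * pmax(sfr, 0)
      onpk <- 1
      offpk <- balance[i] / (2 - balance[i])  # so 1-|on-off|/(on+off)=balance
      fr <- function(pk) {
        a <- array(0, c(5, 5, 6))
        for (t in 1:6) a[3, 3, t] <- pk * exp(-((t - 3) / 2)^2)
        a
      }
      sites[[i]] <- list(
        or_resp = pmax(orr + stats::rnorm(n_orientations, 0, noise * 25), 0),
        orientations_deg = ors,
        sf_resp = pmax(sfr + stats::rnorm(n_sf, 0, noise * 20), 0),
        sf = sfs,
        on_frames = fr(onpk), off_frames = fr(offpk),
        position_um = (i - 1L) * 100)
    }
    list(sites = sites,
         truth = data.frame(theta_deg = theta0, kappa = kappa,
                            balance = balance, sf50 = sf50, g = g))
  })
}
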