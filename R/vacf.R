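# Time-correlation analyses: velocity autocorrelation, vibrational density
# of states (cosine transform of the VACF), band metrics, residence times.

#' Velocity autocorrelation function
#'
#' `C(tau) = <v_i(t) . v_i(t + tau)>` averaged over the selected atoms and
#' all valid time origins (FFT-accelerated), normalised so `C(0) = 1`.
#'
#' @param traj a `trajectory` whose frames carry velocities.
#' @param sel selection expression or atom ids (evaluated on frame 1).
#' @param max_lag maximum lag, ps; default half the trajectory length.
#' @param mass_weighted weight atoms by mass (for a mass-weighted spectrum).
#' @return object of class `correlation_series` with `lags` (ps) and
#'   `values` (`values[1] = 1`).
#' @export
compute_vacf <- function(traj, sel, max_lag = NULL, mass_weighted = FALSE) {
  if (is.null(traj$frames[[1]]$velocities)) {
    stop("trajectory has no velocities; load a velocity stream ",
         "(read_trajectory(velocity_paths = ...))")
  }
  nf <- n_frames(traj)
  ids <- .resolve_sel(traj$topology, traj$frames[[1]], sel)
  if (is.null(max_lag)) max_lag <- (nf - 1) * traj$dt / 2
  nlag <- min(nf, floor(max_lag / traj$dt) + 1L)
  V <- array(0, c(nf, length(ids), 3))
  for (f in seq_len(nf)) {
    v <- traj$frames[[f]]$velocities
    if (is.null(v)) stop("frame ", f, " has no velocities")
    V[f, , ] <- v[ids, ]
  }
  w <- if (mass_weighted) traj$topology$atoms$mass[ids] else rep(1, length(ids))
  acc <- numeric(nlag)
  npad <- 2L * stats::nextn(nf, 2)
  for (a in seq_along(ids)) {
    for (k in 1:3) {
      s <- c(V[, a, k], numeric(npad - nf))
      co <- Re(stats::fft(Mod(stats::fft(s))^2, inverse = TRUE)) / npad
      acc <- acc + w[a] * co[seq_len(nlag)] / (nf - seq_len(nlag) + 1L)
    }
  }
  vals <- acc / acc[1]
  structure(list(lags = (seq_len(nlag) - 1L) * traj$dt, values = vals,
                 n_atoms = length(ids), n_origins = nf,
                 mass_weighted = mass_weighted),
            class = "correlation_series")
}

#' @export
print.correlation_series <- function(x, ...) {
  cat(sprintf("correlation_series: %d lags up to %g ps (%d atoms)\n",
              length(x$lags), max(x$lags), x$n_atoms))
  invisible(x)
}

#' Vibrational density of states from a VACF
#'
#' Discrete cosine transform of the (optionally Hann-windowed) VACF:
#' `D(nu) = 2 dt sum_tau w(tau) C(tau) cos(2 pi c nu tau)`. The wavenumber
#' axis is `nu_k = k / (c T_total)` with resolution `1 / (c T_total)` cm^-1.
#'
#' @param vacf a `correlation_series` with uniform lag spacing.
#' @param window `"hann"` (default, suppresses truncation lobes) or
#'   `"none"`.
#' @param wavenumber_max upper axis limit, cm^-1 (default 4500).
#' @return object of class `spectrum` with `wavenumbers` (cm^-1, uniformly
#'   spaced from 0), `intensity`, `resolution`, `window`.
#' @export
compute_vdos <- function(vacf, window = c("hann", "none"),
                         wavenumber_max = 4500) {
  window <- match.arg(window)
  lags <- vacf$lags
  d <- diff(lags)
  if (length(d) && any(abs(d - d[1]) > 1e-9 * d[1])) {
    stop("non-uniform lag spacing")
  }
  M <- length(lags)
  dt_s <- d[1] * 1e-12                       # ps -> s
  T_total <- M * dt_s
  res <- 1 / (hf_constants$c_cm_s * T_total) # cm^-1
  kmax <- max(1L, floor(wavenumber_max / res))
  nu <- (0:kmax) * res
  w <- switch(window,
              none = rep(1, M),
              hann = 0.5 * (1 + cos(pi * (seq_len(M) - 1L) / (M - 1L))))
  cw <- vacf$values * w
  # I(nu_k) = 2 dt sum_tau cw_tau cos(2 pi k tau / M)
  tau <- seq_len(M) - 1L
  C <- cos(2 * pi * outer(0:kmax, tau) / M)
  intensity <- as.numeric(2 * d[1] * (C %*% cw))
  structure(list(wavenumbers = nu, intensity = intensity, resolution = res,
                 window = window), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("spectrum: 0..%.0f cm^-1, resolution %.2f cm^-1 (%s window)\n",
              max(x$wavenumbers), x$resolution, x$window))
  invisible(x)
}

#' Peak and integral metrics of a spectral band
#'
#' @param spec a `spectrum`.
#' @param band `c(lo, hi)` in cm^-1, inside the spectrum range.
#' @return list with `peak_position` (parabolically interpolated, cm^-1),
#'   `peak_intensity`, and `band_integral` (trapezoidal).
#' @export
band_metrics <- function(spec, band) {
  keep <- which(spec$wavenumbers >= band[1] & spec$wavenumbers <= band[2])
  if (length(keep) < 2L) stop("empty band: ", band[1], "-", band[2], " cm^-1")
  nu <- spec$wavenumbers[keep]
  y <- spec$intensity[keep]
  i <- which.max(y)
  pk <- nu[i]; pv <- y[i]
  if (i > 1L && i < length(y)) {
    den <- y[i - 1] - 2 * y[i] + y[i + 1]
    if (abs(den) > 0) {
      shift <- 0.5 * (y[i - 1] - y[i + 1]) / den
      pk <- nu[i] + shift * (nu[2] - nu[1])
      pv <- y[i] - 0.25 * (y[i - 1] - y[i + 1]) * shift
    }
  }
  list(peak_position = pk, peak_intensity = pv,
       band_integral = .trapz(nu, y))
}

#' Water residence survival curve and time
#'
#' Tracks the molecules selected by `region` on every frame; `S(tau)` is the
#' fraction of origin molecules that remain continuously inside for `tau`,
#' tolerating excursions of at most `allowed_blip` frames. `tau` comes from
#' a least-squares exponential fit to `S(tau) >= fit_floor`.
#'
#' @param traj a `trajectory`.
#' @param region selection expression re-evaluated per frame (membership is
#'   per molecule: any selected atom marks its molecule inside).
#' @param allowed_blip tolerated excursion length, frames (default 2).
#' @param fit_floor smallest survival value used in the fit (default 0.01).
#' @param max_lag largest lag reported, ps; default half the trajectory.
#'   Time origins are restricted to frames where the full lag window is
#'   observable, which makes the curve nonincreasing by construction.
#' @return object of class `survival_curve` with `lags` (ps), `survival`
#'   (nonincreasing, `survival[1] = 1`), fitted `tau` (ps; `NA` with
#'   `fit = "non-identifiable"` when the curve never decays).
#' @export
residence_time <- function(traj, region, allowed_blip = 2L, fit_floor = 0.01,
                           max_lag = NULL) {
  nf <- n_frames(traj)
  if (is.null(max_lag)) max_lag <- (nf - 1) * traj$dt / 2
  nlag <- min(nf, floor(max_lag / traj$dt) + 1L)
  mol <- traj$topology$atoms$molecule_id
  inside_sets <- vector("list", nf)
  for (f in seq_len(nf)) {
    ids <- select_atoms(traj$topology, traj$frames[[f]], region)
    inside_sets[[f]] <- unique(mol[ids])
  }
  mols <- sort(unique(unlist(inside_sets)))
  if (!length(mols)) stop("region is empty at every frame")
  numer <- numeric(nlag)  # origins continuously inside for >= lag
  t0_max <- nf - nlag + 1L
  for (m in mols) {
    io <- vapply(inside_sets, function(s) m %in% s, logical(1))
    if (allowed_blip > 0L) {
      r <- rle(io)
      gap <- !r$values & r$lengths <= allowed_blip
      inner <- seq_along(r$values) > 1 & seq_along(r$values) < length(r$values)
      r$values[gap & inner] <- TRUE
      io <- inverse.rle(r)
    }
    r <- rle(io)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      t0 <- starts[k]:min(ends[k], t0_max)
      if (!length(t0) || t0[1] > t0_max) next
      stay <- pmin(ends[k] - t0 + 1L, nlag)
      for (s in stay) numer[seq_len(s)] <- numer[seq_len(s)] + 1
    }
  }
  if (numer[1] == 0) stop("region has no origins in the observable window")
  S <- numer / numer[1]
  lags <- (seq_len(nlag) - 1L) * traj$dt
  keep <- !is.na(S) & S >= fit_floor
  tau <- NA_real_; fit <- "non-identifiable"
  if (sum(keep) >= 3L && any(S[keep] < 1)) {
    df <- data.frame(t = lags[keep], s = S[keep])
    t0 <- {
      below <- which(S < exp(-1))
      if (length(below)) lags[below[1]] else max(lags[keep])
    }
    ft <- tryCatch(
      stats::nls(s ~ exp(-t / tau), data = df, start = list(tau = max(t0, traj$dt))),
      error = function(e) NULL)
    if (!is.null(ft)) {
      tau <- stats::coef(ft)[["tau"]]
      fit <- "exponential"
    } else {
      pos <- df$s > 0
      lf <- stats::lm(log(s) ~ t - 1 + offset(rep(0, sum(pos))), data = df[pos, ])
      tau <- -1 / stats::coef(lf)[["t"]]
      fit <- "log-linear"
    }
  }
  structure(list(lags = lags, survival = S, tau = tau, fit = fit,
                 allowed_blip = allowed_blip, n_molecules = length(mols)),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("survival_curve: %d lags, tau = %s ps (%s fit, blip <= %d)\n",
              length(x$lags),
              if (is.na(x$tau)) "NA" else sprintf("%.3g", x$tau),
              x$fit, x$allowed_blip))
  invisible(x)
}
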