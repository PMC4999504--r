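# Umbrella-sampling free energies: self-consistent WHAM and the
# two-temperature enthalpy/entropy decomposition.

#' Construct an umbrella window
#'
#' @param center harmonic bias centre, Angstrom.
#' @param k spring constant, kcal/mol/A^2 (0 for an unbiased window).
#' @param samples reaction-coordinate samples, Angstrom (>= 100 for a
#'   meaningful fit).
#' @param temperature K.
#' @return object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, k, samples, temperature = 300) {
  if (k < 0) stop("spring constant must be >= 0")
  if (length(samples) < 100L) stop("need >= 100 samples per window")
  structure(list(center = center, k = k, samples = as.numeric(samples),
                 temperature = temperature), class = "umbrella_window")
}

#' Read umbrella windows from TSV files
#'
#' One file per window: a commented header line `# center <c> k <k>
#' temperature <T>` followed by one sample per line.
#'
#' @param paths file paths.
#' @return list of `umbrella_window` objects.
#' @export
read_umbrella_windows <- function(paths) {
  lapply(paths, function(p) {
    lines <- readLines(p)
    hd <- strsplit(sub("^#\\s*", "", lines[1]), "\\s+")[[1]]
    get <- function(key) as.numeric(hd[match(key, hd) + 1L])
    umbrella_window(get("center"), get("k"),
                    as.numeric(lines[-1]), get("temperature"))
  })
}

#' Write an umbrella window to TSV
#'
#' @param w an `umbrella_window`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_umbrella_window <- function(w, path) {
  writeLines(c(sprintf("# center %g k %g temperature %g",
                       w$center, w$k, w$temperature),
               sprintf("%.10g", w$samples)), path)
  invisible(path)
}

# core self-consistency loop on precomputed histograms; returns P and f
.wham_solve <- function(h, n_i, U, kT, tol, max_iter) {
  nw <- ncol(h)
  f <- numeric(nw)
  expU <- exp(-U / kT)  # nbin x nw
  hsum <- rowSums(h)
  for (it in seq_len(max_iter)) {
    denom <- as.numeric(expU %*% (n_i * exp(f / kT)))
    P <- hsum / denom
    P[!is.finite(P)] <- 0
    fnew <- -kT * log(as.numeric(crossprod(expU, P)))
    fnew <- fnew - fnew[1]
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tol) {
      return(list(P = P / sum(P), f = f, iterations = it, residual = delta))
    }
  }
  stop("WHAM did not converge in ", max_iter, " iterations (residual ",
       signif(delta, 3), " kcal/mol)")
}

#' Weighted-histogram PMF from umbrella windows
#'
#' Iterates the WHAM self-consistency equations
#' `P(b) = sum_i h_i(b) / sum_i n_i exp[(f_i - U_i(b)) / kT]` and
#' `f_i = -kT ln sum_b P(b) exp(-U_i(b) / kT)` to tolerance `tol`, then
#' reports `W = -kT ln P` shifted to `min(W) = 0`. All windows must share
#' one temperature, and adjacent windows must overlap (share occupied
#' bins). Per-bin uncertainties come from a seeded block bootstrap.
#'
#' @param windows list of `umbrella_window` objects.
#' @param bins bin count (default 100 over the pooled sample range) or a
#'   vector of bin edges.
#' @param tol convergence tolerance on the window free energies, kcal/mol.
#' @param max_iter iteration cap.
#' @param min_count occupancy floor: bins with fewer pooled samples are
#'   reported as `NA`.
#' @param n_boot bootstrap resamples (0 disables uncertainties).
#' @param n_blocks blocks per window for the block bootstrap.
#' @param boot_seed bootstrap RNG seed.
#' @return object of class `pmf_profile` with `bin_centers`, `W`
#'   (kcal/mol, min 0), `uncertainty`, `P`, `f` (window free energies),
#'   `temperature`.
#' @export
wham <- function(windows, bins = 100, tol = 1e-8, max_iter = 1e5,
                 min_count = 5L, n_boot = 200L, n_blocks = 20L,
                 boot_seed = 1L) {
  temps <- vapply(windows, `[[`, numeric(1), "temperature")
  if (max(temps) - min(temps) > 1e-9) {
    stop("WHAM requires one temperature per solve; got ",
         paste(unique(temps), collapse = ", "), " K")
  }
  kT <- hf_constants$kB * temps[1]
  all_x <- unlist(lapply(windows, `[[`, "samples"))
  edges <- if (length(bins) > 1L) bins else
    seq(min(all_x), max(all_x), length.out = bins + 1L)
  nbin <- length(edges) - 1L
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  h <- vapply(windows, function(w) .bincount(w$samples, edges),
              numeric(nbin))
  n_i <- colSums(h)
  # overlap check between windows adjacent in centre order
  ord <- order(vapply(windows, `[[`, numeric(1), "center"))
  for (j in seq_len(length(ord) - 1L)) {
    a <- ord[j]; b <- ord[j + 1L]
    if (!any(h[, a] > 0 & h[, b] > 0)) {
      stop("no histogram overlap between windows centred at ",
           windows[[a]]$center, " and ", windows[[b]]$center)
    }
  }
  U <- vapply(windows, function(w) 0.5 * w$k * (centers - w$center)^2,
              numeric(nbin))
  sol <- .wham_solve(h, n_i, U, kT, tol, max_iter)
  W <- -kT * log(sol$P)
  occupied <- rowSums(h) >= min_count
  W[!occupied] <- NA
  W <- W - min(W, na.rm = TRUE)
  unc <- rep(NA_real_, nbin)
  if (n_boot > 0L) {
    set.seed(boot_seed)
    blocks <- lapply(windows, function(w) {
      split(w$samples, cut(seq_along(w$samples), n_blocks, labels = FALSE))
    })
    Wb <- matrix(NA_real_, nbin, n_boot)
    for (r in seq_len(n_boot)) {
      hb <- vapply(seq_along(windows), function(i) {
        pick <- sample.int(n_blocks, n_blocks, replace = TRUE)
        .bincount(unlist(blocks[[i]][pick]), edges)
      }, numeric(nbin))
      sb <- tryCatch(.wham_solve(hb, colSums(hb), U, kT, tol * 100, max_iter),
                     error = function(e) NULL)
      if (!is.null(sb)) {
        wv <- -kT * log(sb$P)
        Wb[, r] <- wv - min(wv[occupied], na.rm = TRUE)
      }
    }
    unc <- apply(Wb, 1, stats::sd, na.rm = TRUE)
    unc[!occupied] <- NA
  }
  structure(list(bin_centers = centers, W = W, uncertainty = unc,
                 P = sol$P, f = sol$f, temperature = temps[1],
                 iterations = sol$iterations, dH = NULL, minus_TdS = NULL),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("pmf_profile: %d bins over [%.3g, %.3g] A at %g K%s\n",
              length(x$W), min(x$bin_centers), max(x$bin_centers),
              x$temperature,
              if (!is.null(x$dH)) ", with dH / -TdS decomposition" else ""))
  invisible(x)
}

#' Two-temperature enthalpy/entropy decomposition of a PMF
#'
#' Finite-difference decomposition on a shared grid:
#' `dS(x) = -(W(x, T2) - W(x, T1)) / (T2 - T1)`, evaluated at the mean
#' temperature, with `W(x, Tbar)` the mean of the two profiles and
#' `dH = W(x, Tbar) + Tbar dS`. The identity `W = dH - Tbar dS` holds
#' exactly on the grid.
#'
#' @param pmf_T1,pmf_T2 `pmf_profile`s at two temperatures (`T2 > T1`) on
#'   identical bin grids.
#' @return a `pmf_profile` at `Tbar = (T1 + T2)/2` with `dH` and
#'   `minus_TdS` filled in.
#' @export
decompose_pmf <- function(pmf_T1, pmf_T2) {
  if (pmf_T2$temperature <= pmf_T1$temperature) stop("need T2 > T1")
  if (length(pmf_T1$bin_centers) != length(pmf_T2$bin_centers) ||
      max(abs(pmf_T1$bin_centers - pmf_T2$bin_centers)) > 1e-9) {
    stop("bin grids differ between the two profiles")
  }
  T1 <- pmf_T1$temperature; T2 <- pmf_T2$temperature
  Tbar <- (T1 + T2) / 2
  dS <- -(pmf_T2$W - pmf_T1$W) / (T2 - T1)
  Wbar <- (pmf_T1$W + pmf_T2$W) / 2
  dH <- Wbar + Tbar * dS
  structure(list(bin_centers = pmf_T1$bin_centers, W = Wbar,
                 uncertainty = sqrt((pmf_T1$uncertainty^2 +
                                       pmf_T2$uncertainty^2) / 4),
                 P = NULL, f = NULL, temperature = Tbar, iterations = NA,
                 dH = dH, minus_TdS = -Tbar * dS),
            class = "pmf_profile")
}
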