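# Analytic 1-D potentials and an overdamped Langevin (Euler-Maruyama)
# sampler: the validation substrate for the umbrella-sampling PMF and for
# residence-time kinetics.

#' Construct an analytic 1-D potential
#'
#' Supported forms (x in Angstrom, energies kcal/mol):
#' \describe{
#'   \item{harmonic}{`0.5 * kappa * (x - x0)^2`; params `kappa`
#'     (kcal/mol/A^2), `x0` (default 0).}
#'   \item{double_well_quartic}{`barrier * ((x/a)^2 - 1)^2`: minima at
#'     `+-a`, barrier height `barrier` at x = 0; params `a`, `barrier`.}
#'   \item{piecewise_flat_wells}{0 inside `[lo, hi]`, harmonic walls of
#'     stiffness `k_wall` outside; params `lo`, `hi`, `k_wall`.}
#' }
#'
#' @param form potential name.
#' @param ... form-specific parameters, see Details.
#' @return object of class `analytic_potential` with `value(x)` and
#'   `grad(x)` functions.
#' @export
analytic_potential <- function(form = c("harmonic", "double_well_quartic",
                                        "piecewise_flat_wells"), ...) {
  form <- match.arg(form)
  p <- list(...)
  obj <- switch(form,
    harmonic = {
      kappa <- p$kappa %||% 1
      x0 <- p$x0 %||% 0
      list(value = function(x) 0.5 * kappa * (x - x0)^2,
           grad = function(x) kappa * (x - x0))
    },
    double_well_quartic = {
      a <- p$a %||% 1
      barrier <- p$barrier %||% 2
      list(value = function(x) barrier * ((x / a)^2 - 1)^2,
           grad = function(x) barrier * 4 * x * ((x / a)^2 - 1) / a^2)
    },
    piecewise_flat_wells = {
      lo <- p$lo %||% -5
      hi <- p$hi %||% 5
      kw <- p$k_wall %||% 10
      list(value = function(x) {
        0.5 * kw * (pmax(lo - x, 0)^2 + pmax(x - hi, 0)^2)
      },
      grad = function(x) kw * (-pmax(lo - x, 0) + pmax(x - hi, 0)))
    })
  structure(c(obj, list(form = form, params = p)),
            class = "analytic_potential")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample a 1-D coordinate by overdamped Langevin dynamics
#'
#' Euler-Maruyama integration of
#' `dx = -U'(x)/gamma dt + sqrt(2 kT dt / gamma) xi`, optionally with a
#' harmonic umbrella bias `0.5 k (x - center)^2` added to the potential.
#' The long-time marginal is the Boltzmann density of the (biased)
#' potential.
#'
#' @param potential an [analytic_potential()] (or `NULL` for a free/bias-only
#'   particle).
#' @param bias optional list `(center, k)`: umbrella centre (Angstrom) and
#'   spring constant (kcal/mol/A^2).
#' @param kT thermal energy, kcal/mol.
#' @param friction friction coefficient gamma (kcal/mol ps/A^2).
#' @param dt time step, ps.
#' @param n_steps number of recorded steps.
#' @param seed RNG seed.
#' @param x0 initial coordinate; defaults to the bias centre, else 0.
#' @param burn_in discarded equilibration steps.
#' @param domain throw an error if |x| leaves this half-width (integrator
#'   divergence guard).
#' @return numeric vector of `n_steps` samples.
#' @export
langevin_sample <- function(potential = NULL, bias = NULL, kT = 0.596,
                            friction = 1, dt = 1e-3, n_steps = 1e4, seed,
                            x0 = NULL, burn_in = 1000L, domain = 1e4) {
  set.seed(seed)
  grad <- function(x) {
    g <- if (is.null(potential)) 0 else potential$grad(x)
    if (!is.null(bias)) g <- g + bias$k * (x - bias$center)
    g
  }
  if (is.null(x0)) x0 <- if (!is.null(bias)) bias$center else 0
  # stability guard: local stiffness times dt/gamma must stay well below 1
  k_eff <- abs(grad(x0 + 1e-3) - grad(x0 - 1e-3)) / 2e-3
  if (is.finite(k_eff) && k_eff * dt / friction > 0.5) {
    stop("integrator unstable: reduce dt (k*dt/gamma = ",
         signif(k_eff * dt / friction, 3), ")")
  }
  ntot <- n_steps + burn_in
  noise <- stats::rnorm(ntot, 0, sqrt(2 * kT * dt / friction))
  x <- numeric(ntot)
  xc <- x0
  for (i in seq_len(ntot)) {
    xc <- xc - grad(xc) * dt / friction + noise[i]
    if (abs(xc) > domain) {
      stop("trajectory diverged (|x| > ", domain, "); use a smaller dt")
    }
    x[i] <- xc
  }
  x[(burn_in + 1):ntot]
}
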