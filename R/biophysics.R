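#' Temperature-dependent hydraulic conductivity (Arrhenius model)
#'
#' Lp(T) = Lpg * exp(-(ELp/R) (1/T - 1/T_R)).  Equals \code{Lpg} at the
#' reference temperature and is strictly increasing in T.
#'
#' @param params a [cell_params()] object
#' @param T absolute temperature (K), vectorised
#' @return hydraulic conductivity (m^3 N^-1 s^-1)
#' @export
hydraulic_conductivity <- function(params, T) {
  if (any(T <= 0)) stop("temperature must be positive (K)")
  params$Lpg * exp(-(params$ELp / params$Rgas) * (1 / T - 1 / params$T_R))
}

#' Viscosity of pure supercooled water
#'
#' eta_w(T) = 0.139 (T/225 - 1)^(-1.64), singular at 225 K.
#'
#' @param T absolute temperature (K), must exceed 225 K; vectorised
#' @return viscosity (same units throughout the package; only ratios enter
#'   the nucleation rate)
#' @export
water_viscosity <- function(T) {
  if (any(T <= 225)) stop("water viscosity model is singular at/below 225 K")
  0.139 * (T / 225 - 1)^(-1.64)
}

#' Cytoplasmic viscosity
#'
#' Vand-type suspension viscosity: eta = eta_w(T) exp(2.5 phi_s /
#' (1 - phi_hydro * phi_s)), where \code{phi_s} is the volume fraction of
#' non-water intracellular material (solids plus solutes) and
#' \code{phi_hydro} the hydrodynamic interaction constant.
#'
#' @param phi_s non-water volume fraction, in [0, 1/phi_hydro)
#' @param T absolute temperature (K)
#' @param phi_hydro hydrodynamic interaction constant (default 0.609)
#' @return cytoplasm viscosity
#' @export
cytoplasm_viscosity <- function(phi_s, T, phi_hydro = 0.609) {
  if (any(phi_s < 0) || any(phi_s >= 1 / phi_hydro))
    stop("phi_s must lie in [0, 1/phi_hydro)")
  water_viscosity(T) * exp(2.5 * phi_s / (1 - phi_hydro * phi_s))
}

#' Mole fraction of intracellular water
#'
#' x_w = n_w / (n_w + 2 n_s), with the factor 2 from full NaCl dissociation.
#'
#' @param n_w moles of water
#' @param n_s moles of salt
#' @return mole fraction in [0, 1]
#' @export
mole_fraction_water <- function(n_w, n_s) {
  if (any(n_w < 0) || any(n_s < 0)) stop("mole counts must be nonnegative")
  if (any(n_w + n_s == 0)) stop("n_w and n_s cannot both be zero")
  n_w / (n_w + 2 * n_s)
}

#' Equilibrium freezing point of the cytoplasm
#'
#' Tf = [1/Tf0 - (R/dHf) ln(x_w)]^-1 with dHf in molar-energy units.
#' Equals \code{Tf0} at x_w = 1 and decreases as the cytoplasm concentrates.
#'
#' @param params a [cell_params()] object
#' @param x_w mole fraction of water, in (0, 1]
#' @return freezing temperature (K)
#' @export
freezing_point <- function(params, x_w) {
  if (any(x_w <= 0) || any(x_w > 1)) stop("x_w must lie in (0, 1]")
  1 / (1 / params$Tf0 - (params$Rgas / params$dHf_J) * log(x_w))
}

#' Thermodynamic state of a cell at a given volume and temperature
#'
#' Derives the water volume, mole fraction, non-water volume fraction,
#' cytoplasm freezing point, viscosity and nucleation rate from the current
#' cell volume.  The non-water fraction is defined as phi_s = 1 - V_w/V,
#' i.e. the volume fraction of all non-water intracellular material, which
#' grows from approximately \code{v_b} at isotonic conditions toward 1 on
#' dehydration.
#'
#' @param params a [cell_params()] object
#' @param V current cell volume (um^3); clamped below at the osmotically
#'   inactive volume
#' @param T absolute temperature (K)
#' @return a list of class \code{thermo_state} with elements
#'   \code{V, V_w, n_w, x_w, phi_s, Tf, eta, Ji}
#' @export
thermo_state <- function(params, V, T) {
  V <- pmax(V, params$V_b)
  V_w <- V - params$V_b
  n_w <- V_w / params$v_w
  x_w <- mole_fraction_water(n_w, params$n_s)
  x_w <- pmin(pmax(x_w, .Machine$double.xmin), 1)
  Tf <- freezing_point(params, x_w)
  phi_s <- 1 - V_w / V
  eta <- cytoplasm_viscosity(phi_s, T, params$phi_hydro)
  st <- list(V = V, V_w = V_w, n_w = n_w, x_w = x_w, phi_s = phi_s,
             Tf = Tf, eta = eta)
  st$Ji <- nucleation_rate(params, st, T)
  class(st) <- "thermo_state"
  st
}

#' Intracellular ice nucleation rate
#'
#' Diffusion-limited heterogeneous nucleation kinetics:
#' Ji(T) = A Omega0 (eta0/eta) (T/Tf0)^(1/2)
#'   exp[-kappa0 / (T^3 (Tf - T)^2) * (Tf/Tf0)^4],
#' where eta0 is the cytoplasm viscosity at isotonic conditions and the
#' isotonic freezing point, and the melting point entering the supercooling
#' term is the current cytoplasm freezing point Tf.  Returns 0 when the cell
#' is not supercooled (T >= Tf): without supercooling there is no nucleation.
#'
#' @param params a [cell_params()] object
#' @param state a \code{thermo_state} (or any list with \code{Tf},
#'   \code{eta})
#' @param T absolute temperature (K)
#' @return nucleation rate (s^-1, per cell)
#' @export
nucleation_rate <- function(params, state, T) {
  Tf <- state$Tf
  eta <- state$eta
  eta0 <- cytoplasm_viscosity(params$v_b, params$Tf0, params$phi_hydro)
  A_m2 <- params$A * 1e-12                      # um^2 -> m^2
  pre <- A_m2 * params$Omega0 * (eta0 / eta) * sqrt(pmax(T, 0) / params$Tf0)
  arg <- -params$kappa0 / (T^3 * (Tf - T)^2) * (Tf / params$Tf0)^4
  out <- ifelse(T < Tf, pre * exp(arg), 0)
  pmax(out, 0)
}

#' Right-hand side of the water-transport equation
#'
#' Rate of cell volume change with temperature during linear cooling at rate
#' B, from the difference in water chemical potential between the (ideal,
#' supercooled) intracellular solution and the extracellular solution in
#' equilibrium with ice:
#' dV/dT = (Lp(T) A R T)/(B v_w) [ln(V_w/(V_w + v_w v_s n_s))
#'   - (dHf/R)(1/T_R - 1/T)].
#' The sign convention is such that a supercooled interior loses water as
#' temperature falls (dV/dT > 0 with T decreasing in time), and the rate is
#' exactly zero at chemical equilibrium (vanishing bracket).
#'
#' @param params a [cell_params()] object
#' @param V current cell volume (um^3), strictly above the inactive volume
#' @param T absolute temperature (K)
#' @param B cooling rate (K min^-1)
#' @return dV/dT (um^3 K^-1)
#' @export
water_transport_rhs <- function(params, V, T, B) {
  if (any(T <= 0)) stop("temperature must be positive (K)")
  V_w <- V - params$V_b
  if (any(V_w <= 0)) stop("degenerate volume: V must exceed V_b")
  B_Ks <- B / 60
  lnx <- log(V_w / (V_w + params$v_w * params$v_s * params$n_s))
  bracket <- lnx - (params$dHf_J / params$Rgas) * (1 / params$T_R - 1 / T)
  Lp <- hydraulic_conductivity(params, T)
  A_m2 <- params$A * 1e-12
  v_w_m3 <- params$v_w * 1e-18
  # SI volume flux (m^3/s) per unit bracket, then per K and to um^3
  (Lp * A_m2 * params$Rgas * T / v_w_m3 / B_Ks) * bracket * 1e18
}

#' Integrate the dehydration trajectory over a cooling protocol
#'
#' Solves the water-transport equation on a uniform temperature grid from
#' \code{T0} down to \code{T_end} and derives the full thermodynamic
#' trajectory: water volume, mole fraction, freezing point, viscosity,
#' nucleation rate and the cumulative non-dimensional time tau (composite
#' trapezoidal integral of Ji over dimensional time).  When the remaining
#' water volume falls below \code{1e-6 * V_iso} the volume state is held
#' fixed (fully dehydrated) to avoid the logarithmic singularity.
#'
#' @param params a [cell_params()] object
#' @param protocol a [cooling_protocol()] object
#' @param dT output temperature grid step (K), default 0.05
#' @param rtol,atol integrator tolerances
#' @return a data.frame of class \code{dehydration} with columns
#'   \code{t, T, V, V_w, x_w, Tf, eta, Ji, tau}, plus attributes
#'   \code{params} and \code{protocol}
#' @export
integrate_dehydration <- function(params, protocol, dT = 0.05,
                                  rtol = 1e-8, atol = 1e-6) {
  Tgrid <- seq(protocol$T0, protocol$T_end, by = -dT)
  floor_Vw <- 1e-6 * params$V_iso
  rhs <- function(T, y, p) {
    V <- y[1]
    if (V - params$V_b < floor_Vw) return(list(0))
    list(water_transport_rhs(params, V, T, protocol$B))
  }
  sol <- try(deSolve::ode(y = c(V = params$V_iso), times = Tgrid, func = rhs,
                          parms = NULL, method = "lsoda",
                          rtol = rtol, atol = atol), silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(Tgrid))
    stop("dehydration integrator failed: ", attr(sol, "condition")$message)
  V <- pmax(sol[, "V"], params$V_b + floor_Vw / 2)
  st <- thermo_state(params, V, Tgrid)
  t <- (protocol$T0 - Tgrid) / (protocol$B / 60)
  tau <- tau_of_time(t, st$Ji)
  out <- data.frame(t = t, T = Tgrid, V = st$V, V_w = st$V_w, x_w = st$x_w,
                    Tf = st$Tf, eta = st$eta, Ji = st$Ji, tau = tau)
  attr(out, "params") <- params
  attr(out, "protocol") <- protocol
  class(out) <- c("dehydration", "data.frame")
  out
}

#' @export
print.dehydration <- function(x, ...) {
  pr <- attr(x, "protocol")
  n <- nrow(x)
  cat(sprintf("Dehydration trajectory: B = %g K/min, %.2f -> %.2f K (%d points)\n",
              pr$B, pr$T0, pr$T_end, n))
  cat(sprintf("  retained water fraction %.3f, plateau V/V_iso %.3f, tau_final %.4g\n",
              retained_water_fraction(x), x$V[n] / x$V[1], x$tau[n]))
  invisible(x)
}

#' Retained water fraction at the end of a dehydration trajectory
#'
#' Final osmotically active water volume as a fraction of its initial value.
#'
#' @param traj a trajectory from [integrate_dehydration()]
#' @return scalar fraction in [0, 1]
#' @export
retained_water_fraction <- function(traj) {
  traj$V_w[nrow(traj)] / traj$V_w[1]
}

#' Cumulative non-dimensional time
#'
#' tau(t) is the composite-trapezoid cumulative integral of the nucleation
#' rate over dimensional time; tau(0) = 0 and tau is nondecreasing for
#' nonnegative rates.
#'
#' @param t sample times (s), strictly increasing
#' @param rate nucleation rate samples (s^-1), nonnegative
#' @return numeric vector tau of the same length as \code{t}
#' @export
tau_of_time <- function(t, rate) {
  if (length(t) != length(rate)) stop("t and rate must have equal length")
  if (any(diff(t) <= 0)) stop("t samples must be strictly increasing")
  if (any(rate < 0)) stop("rates must be nonnegative")
  c(0, cumsum(diff(t) * (utils::head(rate, -1) + utils::tail(rate, -1)) / 2))
}

#' Invertible map between non-dimensional time, time and temperature
#'
#' Builds interpolating functions tau(t), t(tau) and T(tau) from a
#' dehydration trajectory.  The inverse is defined by first crossing: for a
#' target tau the reported t is the earliest grid time with tau(t) >= tau.
#'
#' @param traj a trajectory from [integrate_dehydration()], or any data.frame
#'   with columns \code{t}, \code{T}, \code{tau}
#' @return a list of class \code{tau_map} with functions \code{tau_of_t},
#'   \code{t_of_tau}, \code{T_of_tau} and the scalar \code{tau_end}
#' @export
tau_map <- function(traj) {
  t <- traj$t; tau <- traj$tau; Temp <- traj$T
  if (any(diff(tau) < 0)) stop("tau must be nondecreasing")
  tau_of_t <- stats::approxfun(t, tau, rule = 2)
  t_of_tau <- function(x) {
    vapply(x, function(xx) {
      if (xx > tau[length(tau)]) return(NA_real_)
      t[which(tau >= xx)[1]]
    }, numeric(1))
  }
  T_of_tau <- function(x) {
    vapply(x, function(xx) {
      if (xx > tau[length(tau)]) return(NA_real_)
      Temp[which(tau >= xx)[1]]
    }, numeric(1))
  }
  structure(list(tau_of_t = tau_of_t, t_of_tau = t_of_tau,
                 T_of_tau = T_of_tau, tau_end = tau[length(tau)]),
            class = "tau_map")
}
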