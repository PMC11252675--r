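#' Biophysical parameter set for a cell type
#'
#' Bundles the immutable biophysical constants that drive the water-transport
#' and nucleation models.  The latent heat of fusion is supplied in
#' pressure-volume units (um^3 atm / mol, the form used by the water-transport
#' equation) and converted once at construction to molar-energy units
#' (J / mol, the form used by the freezing-point-depression relation), so that
#' both representations are available without repeated unit juggling.
#'
#' @param A cell membrane surface area (um^2)
#' @param Lpg hydraulic conductivity at the reference temperature
#'   (m^3 N^-1 s^-1, equivalently m Pa^-1 s^-1)
#' @param ELp activation energy of the hydraulic conductivity (J mol^-1)
#' @param T_R reference temperature, the equilibrium freezing point of pure
#'   water (K)
#' @param Tf0 freezing point of the cytoplasm at isotonic conditions (K)
#' @param v_w partial molar volume of water (um^3 mol^-1)
#' @param v_s dissociation number for NaCl (-)
#' @param dHf_atm latent heat of fusion of water (um^3 atm mol^-1)
#' @param v_b osmotically inactive volume fraction (-)
#' @param V_iso isotonic cell volume (um^3)
#' @param n_s moles of intracellular salt (mol); default assumes isotonic
#'   physiological saline (0.155 mol/L NaCl) dissolved in the osmotically
#'   active fraction of the isotonic volume
#' @param Omega0 kinetic nucleation coefficient (m^-2 s^-1)
#' @param kappa0 thermodynamic nucleation coefficient (K^5)
#' @param phi_hydro hydrodynamic interaction constant of the cytoplasm
#'   viscosity model (-)
#' @param Rgas universal gas constant (J mol^-1 K^-1)
#'
#' @return An object of class \code{cell_params} (a named list).
#' @seealso [rat_hepatocyte()] for the packaged parameter set.
#' @export
cell_params <- function(A, Lpg, ELp, T_R, Tf0, v_w, v_s, dHf_atm, v_b,
                        V_iso, n_s = NULL, Omega0, kappa0,
                        phi_hydro = 0.609, Rgas = 8.314) {
  if (is.null(n_s)) {
    # 0.155 mol/L in the osmotically active water volume; um^3 -> L is 1e-15
    n_s <- 0.155 * (1 - v_b) * V_iso * 1e-15
  }
  p <- list(A = A, Lpg = Lpg, ELp = ELp, T_R = T_R, Tf0 = Tf0,
            v_w = v_w, v_s = v_s, dHf_atm = dHf_atm,
            dHf_J = dHf_atm * 1.01325e-13,  # 1 um^3 atm = 1.01325e-13 J
            v_b = v_b, V_iso = V_iso, V_b = v_b * V_iso, n_s = n_s,
            Omega0 = Omega0, kappa0 = kappa0, phi_hydro = phi_hydro,
            Rgas = Rgas)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all cell parameters must be finite and strictly positive")
  if (p$v_b >= 1) stop("v_b must lie in (0, 1)")
  if (p$Tf0 >= p$T_R) stop("Tf0 must be below the reference temperature T_R")
  class(p) <- "cell_params"
  p
}

#' Rat hepatocyte parameter set
#'
#' The packaged parameter set for rat hepatocytes.  The isotonic volume is
#' computed from the 21 um cell diameter as a sphere; the surface area is
#' taken at its tabulated value of 1.412e3 um^2.
#'
#' @param diameter cell diameter (um) used to derive the isotonic volume
#' @param ... overrides passed on to [cell_params()]
#' @return A \code{cell_params} object.
#' @export
rat_hepatocyte <- function(diameter = 21, ...) {
  defaults <- list(
    A = 1.412e3,           # um^2
    Lpg = 1.5e-12,         # m^3 N^-1 s^-1 at T_R
    ELp = 3.42e5,          # J mol^-1 (342 kJ/mol)
    T_R = 273.15,
    Tf0 = 272.63,
    v_w = 1.8e13,          # um^3 mol^-1 (18 cm^3/mol)
    v_s = 2,
    dHf_atm = 5.94124e16,  # um^3 atm mol^-1
    v_b = 0.51,
    V_iso = 4 / 3 * pi * (diameter / 2)^3,
    Omega0 = 1.1e10,       # m^-2 s^-1
    kappa0 = 1.4e9         # K^5
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(cell_params, args)
}

#' @export
print.cell_params <- function(x, ...) {
  cat("Cell biophysical parameters\n")
  cat(sprintf("  V_iso = %.1f um^3 (V_b = %.1f), A = %.4g um^2\n",
              x$V_iso, x$V_b, x$A))
  cat(sprintf("  Lpg = %.3g m^3/N/s at %.2f K, ELp = %.3g J/mol\n",
              x$Lpg, x$T_R, x$ELp))
  cat(sprintf("  Tf0 = %.2f K, n_s = %.3g mol, Omega0 = %.3g, kappa0 = %.3g\n",
              x$Tf0, x$n_s, x$Omega0, x$kappa0))
  invisible(x)
}

#' Linear cooling protocol
#'
#' Temperature falls linearly from \code{T0} at rate \code{B} until
#' \code{T_end}: T(t) = T0 - B t.
#'
#' @param T0 initial temperature (K)
#' @param B cooling rate (K min^-1), strictly positive
#' @param T_end stop temperature (K), strictly below \code{T0}
#' @return An object of class \code{cooling_protocol}.
#' @export
cooling_protocol <- function(T0 = 272.15, B, T_end = 230) {
  stopifnot(is.numeric(T0), is.numeric(B), is.numeric(T_end))
  if (B <= 0) stop("cooling rate B must be positive")
  if (T_end >= T0) stop("T_end must be below T0")
  structure(list(T0 = T0, B = B, T_end = T_end), class = "cooling_protocol")
}

#' @export
print.cooling_protocol <- function(x, ...) {
  cat(sprintf("Linear cooling: %.2f K -> %.2f K at %g K/min (%.1f s)\n",
              x$T0, x$T_end, x$B, (x$T0 - x$T_end) / (x$B / 60)))
  invisible(x)
}

#' Read / write flat key-value parameter files
#'
#' Parameter files are plain text, one \code{name = value} pair per line;
#' lines starting with \code{#} are comments.  Field names match the
#' arguments of [cell_params()].
#'
#' @param path file path
#' @return \code{read_cell_params()} returns a \code{cell_params} object.
#' @export
read_cell_params <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=")
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2)))
  args <- as.list(vals)
  names(args) <- keys
  do.call(cell_params, args)
}

#' @param params a \code{cell_params} object
#' @rdname read_cell_params
#' @export
write_cell_params <- function(params, path) {
  fields <- c("A", "Lpg", "ELp", "T_R", "Tf0", "v_w", "v_s", "dHf_atm",
              "v_b", "V_iso", "n_s", "Omega0", "kappa0", "phi_hydro", "Rgas")
  writeLines(sprintf("%s = %.17g", fields, unlist(params[fields])), path)
  invisible(path)
}
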