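#' Dipolar relaxation parameters
#'
#' Physical constants and molecular parameters for the like-spin dipolar
#' relaxation model used to set both pools' R1 and R2. Defaults are the
#' simulation values: rotational correlation time 10 ps, 9.4 T field,
#' 1H gyromagnetic ratio 42.576 MHz/T, hbar = 1.054571628e-34 J s,
#' hydrodynamic radius 158 pm, vacuum permeability 4*pi*1e-7.
#'
#' @param tau_c rotational correlation time (s).
#' @param B0 static field (T).
#' @param gamma_mhz gyromagnetic ratio (MHz/T).
#' @param hbar reduced Planck constant (J s).
#' @param r inter-spin (hydrodynamic) radius (m).
#' @param mu0 vacuum permeability (T m/A).
#' @return A list of class `dipolar_params`.
#' @export
dipolar_params <- function(tau_c = 10e-12, B0 = 9.4, gamma_mhz = 42.576,
                           hbar = 1.054571628e-34, r = 158e-12,
                           mu0 = 4 * pi * 1e-7) {
  vals <- list(tau_c = tau_c, B0 = B0, gamma_mhz = gamma_mhz, hbar = hbar,
               r = r, mu0 = mu0)
  bad <- names(vals)[!vapply(vals, function(v) is.numeric(v) && v > 0, logical(1))]
  if (length(bad))
    stop("dipolar_params: parameters must be strictly positive: ",
         paste(bad, collapse = ", "))
  structure(vals, class = "dipolar_params")
}

#' Like-spin dipolar relaxation rates
#'
#' Longitudinal and transverse relaxation rates for an isolated pair of
#' identical spins 1/2 undergoing isotropic rotational diffusion:
#' \deqn{R_1 = \frac{3}{10} b^2 [J(\omega_0) + 4 J(2\omega_0)], \quad
#'       R_2 = \frac{3}{20} b^2 [3 J(0) + 5 J(\omega_0) + 2 J(2\omega_0)]}
#' with dipolar coupling \eqn{b = (\mu_0/4\pi)\,\hbar\,\gamma^2 / r^3}
#' (\eqn{\gamma} in rad/s/T), Lorentzian spectral density
#' \eqn{J(\omega) = \tau_c / (1 + \omega^2\tau_c^2)} and Larmor frequency
#' \eqn{\omega_0 = \gamma B_0}. In the extreme-narrowing regime
#' (\eqn{\omega_0\tau_c \ll 1}, the case at 10 ps) R1 and R2 coincide to
#' within ~0.1%.
#'
#' @param params a [dipolar_params()] object.
#' @return Named numeric vector with `R1` and `R2` (1/s).
#' @examples
#' dipolar_rates(dipolar_params())  # ~0.548 1/s each
#' @export
dipolar_rates <- function(params = dipolar_params()) {
  if (!inherits(params, "dipolar_params"))
    params <- do.call(dipolar_params, as.list(params))
  gam <- 2 * pi * params$gamma_mhz * 1e6
  b <- (params$mu0 / (4 * pi)) * params$hbar * gam^2 / params$r^3
  w0 <- gam * params$B0
  J <- function(w) params$tau_c / (1 + (w * params$tau_c)^2)
  c(R1 = (3 / 10) * b^2 * (J(w0) + 4 * J(2 * w0)),
    R2 = (3 / 20) * b^2 * (3 * J(0) + 5 * J(w0) + 2 * J(2 * w0)))
}

## solute concentrations (mol/l) for the packaged scenarios
solute_concentrations <- list(
  Fn1   = c(healthy = 1.2e-6, upregulated = 1.2e-5),
  Postn = c(healthy = 1.1e-9, upregulated = 1.1e-8)
)

#' Two-pool exchange system
#'
#' Builds the exchange-coupled two-pool system used in the Bloch-McConnell
#' simulations. Pool A is the solute proton pool with fraction
#' `P_A = c(solute)/c(water)`; pool B is water with `P_B = 1 - P_A`. The
#' chemical-shift offsets are `delta_A = 2*pi*P_B*500` and
#' `delta_B = 2*pi*P_A*500` rad/s, so the tiny solute pool sits ~500 Hz off
#' resonance while water is essentially on resonance. Both pools share the
#' dipolar R1/R2 from [dipolar_rates()].
#'
#' The exchange parameter is quoted as `tau_ex = 0.001 Hz` for the -OH group;
#' by default this is read as a rate constant `k_ex = 0.001` 1/s (effectively
#' no exchange, consistent with the insensitivity of the simulated rates to a
#' 10x concentration change). Set `tau_ex_is_time = TRUE` to read it as a
#' residence time (`k_ex = 1/0.001 = 1000` 1/s) instead. Exchange rates obey
#' detailed balance: `k_AB = k_ex * P_B`, `k_BA = k_ex * P_A`.
#'
#' @param solute `"Fn1"` (fibronectin) or `"Postn"` (periostin), or a numeric
#'   solute concentration in mol/l.
#' @param regulated `"healthy"` or `"upregulated"` scenario (10x
#'   concentration).
#' @param dipolar a [dipolar_params()] object.
#' @param water_conc water concentration (mol/l), default 80.
#' @param tau_ex exchange parameter as printed (0.001).
#' @param tau_ex_is_time interpret `tau_ex` as a residence time in seconds
#'   rather than a rate in 1/s.
#' @return A list of class `two_pool_system` with pool fractions, offsets
#'   (rad/s), shared `R1`/`R2`, exchange rates and a `scenario` label.
#' @export
two_pool_system <- function(solute = "Fn1", regulated = "healthy",
                            dipolar = dipolar_params(), water_conc = 80,
                            tau_ex = 0.001, tau_ex_is_time = FALSE) {
  if (is.character(solute)) {
    solute <- match.arg(solute, names(solute_concentrations))
    regulated <- match.arg(regulated, c("healthy", "upregulated"))
    conc <- solute_concentrations[[solute]][[regulated]]
    label <- sprintf("%s %s", solute, regulated)
  } else {
    conc <- solute
    label <- sprintf("solute %.3g mol/l", conc)
  }
  if (conc <= 0 || conc >= water_conc)
    stop("two_pool_system: solute concentration must be in (0, water_conc)")
  PA <- conc / water_conc
  PB <- 1 - PA
  rates <- dipolar_rates(dipolar)
  k_ex <- if (tau_ex_is_time) 1 / tau_ex else tau_ex
  structure(list(
    P_A = PA, P_B = PB,
    delta_A = 2 * pi * PB * 500,
    delta_B = 2 * pi * PA * 500,
    R1 = unname(rates["R1"]), R2 = unname(rates["R2"]),
    k_ex = k_ex, k_AB = k_ex * PB, k_BA = k_ex * PA,
    solute_conc = conc, water_conc = water_conc,
    scenario = label
  ), class = "two_pool_system")
}

#' @export
print.two_pool_system <- function(x, ...) {
  cat(sprintf("<two_pool_system> %s: P_A = %.3g, R1 = %.4g, R2 = %.4g 1/s, k_ex = %.3g 1/s\n",
              x$scenario, x$P_A, x$R1, x$R2, x$k_ex))
  invisible(x)
}

#' Thermal-equilibrium magnetization state
#'
#' The 6-component magnetization vector (Mx, My, Mz per pool) relative to
#' thermal equilibrium: each pool's Mz equals its fraction, transverse
#' components are zero.
#'
#' @param system a [two_pool_system()].
#' @param polarity `+1` for +Z, `-1` for inverted (-Z) start.
#' @return Numeric vector of length 6:
#'   `(MxA, MyA, MzA, MxB, MyB, MzB)`.
#' @export
equilibrium_state <- function(system, polarity = 1) {
  polarity * c(0, 0, system$P_A, 0, 0, system$P_B)
}
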