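# Seawater thermodynamics: potential density anomaly referenced to the
# surface (sigma0) from the UNESCO/EOS-80 equation of state (surface-
# pressure density of potential temperature). At the 0.01 kg m-3
# resolution used for mixed-layer detection this is indistinguishable
# from the newer TEOS-10 formulation.

# Saunders (1981) pressure from depth, dbar.
pressure_from_depth <- function(depth, latitude) {
  x <- sin(abs(latitude) * pi / 180)
  c1 <- 5.92e-3 + 5.25e-3 * x^2
  ((1 - c1) - sqrt((1 - c1)^2 - 8.84e-6 * depth)) / 4.42e-6
}

# UNESCO 1983 one-atmosphere density, kg m-3.
# Check values: rho(S=0,T=5)=999.96675; rho(35,5)=1027.67547;
# rho(35,25)=1023.34306.
rho_eos80_surface <- function(S, T) {
  rw <- 999.842594 + T * (6.793952e-2 + T * (-9.095290e-3 +
        T * (1.001685e-4 + T * (-1.120083e-6 + T * 6.536332e-9))))
  a <- 8.24493e-1 + T * (-4.0899e-3 + T * (7.6438e-5 +
       T * (-8.2467e-7 + T * 5.3875e-9)))
  b <- -5.72466e-3 + T * (1.0227e-4 - T * 1.6546e-6)
  c <- 4.8314e-4
  rw + S * (a + b * sqrt(S) + c * S)
}

# Adiabatic temperature gradient, degC/dbar (UNESCO 1983).
# Check value: adtg(S=40, T=40, P=10000) = 3.255976e-4.
adiabatic_gradient <- function(S, T, P) {
  ds <- S - 35
  3.5803e-5 + T * (8.5258e-6 + T * (-6.836e-8 + T * 6.6228e-10)) +
    ds * (1.8932e-6 - T * 4.2393e-8) +
    P * (1.8741e-8 + T * (-6.7795e-10 + T * (8.733e-12 -
         T * 5.4481e-14))) +
    ds * P * (-1.1351e-10 + T * 2.7759e-12) +
    P^2 * (-4.6206e-13 + T * (1.8676e-14 - T * 2.1687e-16))
}

# Potential temperature referenced to pr (UNESCO 1983 Runge-Kutta scheme).
# Check value: theta(S=40, T=40, P=10000, pr=0) = 36.89073.
potential_temperature <- function(S, T, P, pr = 0) {
  dp <- pr - P
  dth <- dp * adiabatic_gradient(S, T, P)
  th <- T + 0.5 * dth
  q <- dth
  dth <- dp * adiabatic_gradient(S, th, P + 0.5 * dp)
  th <- th + (1 - 1 / sqrt(2)) * (dth - q)
  q <- (2 - sqrt(2)) * dth + (-2 + 3 / sqrt(2)) * q
  dth <- dp * adiabatic_gradient(S, th, P + 0.5 * dp)
  th <- th + (1 + 1 / sqrt(2)) * (dth - q)
  q <- (2 + sqrt(2)) * dth + (-2 - 3 / sqrt(2)) * q
  dth <- dp * adiabatic_gradient(S, th, P + dp)
  th + (dth - 2 * q) / 6
}

#' Potential density anomaly referenced to the surface
#'
#' sigma0 = rho(S, theta(S, T, p, 0), 0) - 1000 kg m-3, with pressure
#' derived hydrostatically from depth at the profile latitude.
#'
#' @param temperature In-situ temperature, degC.
#' @param salinity Practical salinity.
#' @param depth Depths, m, positive down.
#' @param latitude Latitude, decimal degrees.
#' @return sigma0 per depth, kg m-3 (NA where T or S is invalid).
#' @export
potential_density_anomaly <- function(temperature, salinity, depth,
                                      latitude) {
  n <- length(depth)
  stopifnot(length(temperature) == n, length(salinity) == n)
  ok <- is.finite(temperature) & is.finite(salinity)
  bad <- ok & (temperature < -3 | salinity < 0 | salinity > 42)
  if (any(bad)) {
    stop("validation error: temperature/salinity outside the oceanic range ",
         "(T >= -3 degC, 0 <= S <= 42) at depth ", depth[which(bad)[1L]],
         " m")
  }
  out <- rep(NA_real_, n)
  if (any(ok)) {
    p <- pressure_from_depth(depth[ok], latitude)
    th <- potential_temperature(salinity[ok], temperature[ok], p, 0)
    out[ok] <- rho_eos80_surface(salinity[ok], th) - 1000
  }
  out
}
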