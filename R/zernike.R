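# Noll-indexed Zernike polynomials on the unit disc (orthonormal scaling).
# Only low orders are needed: surface extension uses radial order <= 3.

# Noll index -> (n, m) with the standard ordering used for j = 1..10.
noll_nm <- function(j) {
  n <- 0
  while (j > n + 1) {
    j <- j - (n + 1)
    n <- n + 1
  }
  ms <- if (n %% 2 == 0) {
    c(0, if (n >= 2) rep(seq(2, n, by = 2), each = 2))
  } else {
    rep(seq(1, n, by = 2), each = 2)
  }
  # Noll: within order n, |m| ascends; sign chosen so even j -> cos (+m)
  m_abs <- ms[j]
  list(n = n, m_abs = m_abs)
}

zernike_radial <- function(n, m, rho) {
  s_max <- (n - m) / 2
  out <- 0
  for (s in 0:s_max) {
    out <- out + (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) * factorial((n - m) / 2 - s)) *
      rho^(n - 2 * s)
  }
  out
}

#' Evaluate Noll-indexed Zernike polynomials
#'
#' Orthonormal (Noll) scaling on the unit disc: the j-th mode has unit RMS.
#'
#' @param j Noll index (scalar, >= 1)
#' @param rho radial coordinate in \[0, 1\] (values slightly above 1 allowed
#'   for extrapolation)
#' @param theta azimuth, radians
#' @return numeric vector of mode values
#' @export
zernike_noll <- function(j, rho, theta) {
  nm <- noll_nm(j)
  n <- nm$n
  m <- nm$m_abs
  r <- zernike_radial(n, m, rho)
  if (m == 0) {
    sqrt(n + 1) * r
  } else if (j %% 2 == 0) {
    sqrt(2 * (n + 1)) * r * cos(m * theta)
  } else {
    sqrt(2 * (n + 1)) * r * sin(m * theta)
  }
}

# Design matrix of modes j = 1..n_modes at (rho, theta).
zernike_design <- function(rho, theta, n_modes = 10L) {
  vapply(seq_len(n_modes), function(j) zernike_noll(j, rho, theta),
    numeric(length(rho))
  )
}
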