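# Structural similarity index between normalised maps: local Gaussian-window
# means, standard deviations and cross-covariance combined into luminance,
# contrast and structure terms.

#' SSIM parameters
#'
#' Standard constants: 11 x 11 Gaussian window with sigma = 1.5, dynamic
#' range L = 1 (maps are rescaled from \[-1, 1\] to \[0, 1\] before windowed
#' statistics), `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, `C3 = C2 / 2`, unit
#' exponents.
#'
#' @param alpha,beta,gamma exponents of the luminance, contrast and
#'   structure terms
#' @param window_size odd window width (default 11)
#' @param sigma Gaussian window sigma (default 1.5)
#' @param L dynamic range (default 1)
#' @param C1,C2,C3 regularisation constants
#' @return object of class `ssim_params`
#' @export
ssim_params <- function(alpha = 1, beta = 1, gamma = 1, window_size = 11L,
                        sigma = 1.5, L = 1,
                        C1 = (0.01 * L)^2, C2 = (0.03 * L)^2, C3 = C2 / 2) {
  if (any(c(C1, C2, C3) <= 0)) stop("regularisation constants must be positive")
  if (any(c(alpha, beta, gamma) < 0)) stop("exponents must be >= 0")
  if (window_size %% 2 != 1) stop("window size must be odd")
  structure(
    list(
      alpha = alpha, beta = beta, gamma = gamma,
      window_size = as.integer(window_size), sigma = sigma, L = L,
      C1 = C1, C2 = C2, C3 = C3
    ),
    class = "ssim_params"
  )
}

gaussian_kernel <- function(size, sigma) {
  h <- (size - 1) / 2
  g <- exp(-((-h:h)^2) / (2 * sigma^2))
  g / sum(g)
}

# separable 'valid' convolution with a symmetric 1D kernel on both axes;
# the result keeps the input size with NA in the border of half-window width
filter2_valid <- function(x, g) {
  n1 <- nrow(x)
  n2 <- ncol(x)
  k <- length(g)
  h <- (k - 1L) / 2L
  if (k > n1 || k > n2) stop("window larger than map")
  rowf <- matrix(NA_real_, n1, n2)
  core1 <- (h + 1L):(n1 - h)
  acc <- matrix(0, length(core1), n2)
  for (o in seq_len(k)) {
    acc <- acc + g[o] * x[core1 + (o - 1L) - h, , drop = FALSE]
  }
  rowf[core1, ] <- acc
  out <- matrix(NA_real_, n1, n2)
  core2 <- (h + 1L):(n2 - h)
  acc2 <- matrix(0, n1, length(core2))
  for (o in seq_len(k)) {
    acc2 <- acc2 + g[o] * rowf[, core2 + (o - 1L) - h, drop = FALSE]
  }
  out[, core2] <- acc2
  out
}

# full smoothing filter used for synthetic noise fields (zero-padded edges)
gaussian_filter2 <- function(x, sigma) {
  k <- max(3L, 2L * ceiling(3 * sigma) + 1L)
  g <- gaussian_kernel(k, sigma)
  n1 <- nrow(x)
  n2 <- ncol(x)
  h <- (k - 1L) / 2L
  xp <- matrix(0, n1 + 2L * h, n2 + 2L * h)
  xp[h + seq_len(n1), h + seq_len(n2)] <- x
  filter2_valid(xp, g)[h + seq_len(n1), h + seq_len(n2)]
}

#' SSIM map of two maps
#'
#' `SSIM = l^alpha * c^beta * s^gamma` with `l = (2 mux muy + C1) /
#' (mux^2 + muy^2 + C1)`, `c = (2 sx sy + C2) / (sx^2 + sy^2 + C2)`,
#' `s = (sxy + C3) / (sx sy + C3)`, all statistics over the Gaussian window.
#' Values where the window does not fit inside the map are invalid.
#'
#' @param x,y numeric matrices on one grid (rescale to a non-negative range
#'   first; see [compare_maps()])
#' @param params a [ssim_params()]
#' @return matrix of SSIM values (NA in the half-window border)
#' @export
ssim_map <- function(x, y, params = ssim_params()) {
  if (!identical(dim(x), dim(y))) stop("maps must share a grid")
  g <- gaussian_kernel(params$window_size, params$sigma)
  mux <- filter2_valid(x, g)
  muy <- filter2_valid(y, g)
  sxx <- filter2_valid(x * x, g) - mux^2
  syy <- filter2_valid(y * y, g) - muy^2
  sxy <- filter2_valid(x * y, g) - mux * muy
  sxx <- pmax(sxx, 0)
  syy <- pmax(syy, 0)
  sx <- sqrt(sxx)
  sy <- sqrt(syy)
  l <- (2 * mux * muy + params$C1) / (mux^2 + muy^2 + params$C1)
  cc <- (2 * sx * sy + params$C2) / (sxx + syy + params$C2)
  s <- (sxy + params$C3) / (sx * sy + params$C3)
  (l^params$alpha) * (cc^params$beta) * sign(s) * abs(s)^params$gamma
}

#' Direct SSIM evaluation
#'
#' Literal per-pixel evaluation of the windowed statistics and the
#' luminance/contrast/structure product; quadratic cost, used to verify
#' [ssim_map()].
#'
#' @param x,y matrices
#' @param params a [ssim_params()]
#' @return SSIM matrix
#' @export
ssim_direct <- function(x, y, params = ssim_params()) {
  g <- gaussian_kernel(params$window_size, params$sigma)
  W <- outer(g, g)
  h <- (params$window_size - 1L) / 2L
  n1 <- nrow(x)
  n2 <- ncol(x)
  out <- matrix(NA_real_, n1, n2)
  for (i in (h + 1L):(n1 - h)) {
    for (j in (h + 1L):(n2 - h)) {
      xi <- x[(i - h):(i + h), (j - h):(j + h)]
      yi <- y[(i - h):(i + h), (j - h):(j + h)]
      mux <- sum(W * xi)
      muy <- sum(W * yi)
      sxx <- max(sum(W * xi^2) - mux^2, 0)
      syy <- max(sum(W * yi^2) - muy^2, 0)
      sxy <- sum(W * xi * yi) - mux * muy
      l <- (2 * mux * muy + params$C1) / (mux^2 + muy^2 + params$C1)
      cc <- (2 * sqrt(sxx) * sqrt(syy) + params$C2) / (sxx + syy + params$C2)
      s <- (sxy + params$C3) / (sqrt(sxx) * sqrt(syy) + params$C3)
      out[i, j] <- l^params$alpha * cc^params$beta *
        sign(s) * abs(s)^params$gamma
    }
  }
  out
}
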