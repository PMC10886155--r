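# 2D normalized cross-correlation of masked maps, computed with
# running-sum local statistics (FFT-accelerated correlation sums), and
# band-area classification of coefficient maps.

# full cross-correlation surface of two zero-padded arrays via FFT
xcorr2_fft <- function(a, b) {
  # sum_{x,y} a(x, y) * b(x - u, y - v) over all displacements
  na <- dim(a)
  nb <- dim(b)
  n1 <- na[1] + nb[1] - 1L
  n2 <- na[2] + nb[2] - 1L
  pa <- matrix(0, n1, n2)
  pb <- matrix(0, n1, n2)
  pa[seq_len(na[1]), seq_len(na[2])] <- a
  pb[seq_len(nb[1]), seq_len(nb[2])] <- b
  out <- Re(fft(fft(pa) * Conj(fft(pb)), inverse = TRUE)) / (n1 * n2)
  # wrap so displacement (0,0) is at index (nb[1], nb[2])
  out[c((n1 - nb[1] + 2):n1, 1:(n1 - nb[1] + 1)), c((n2 - nb[2] + 2):n2, 1:(n2 - nb[2] + 1))]
}

#' Normalized cross-correlation of two masked maps
#'
#' Computes the full NCC surface over all integer displacements: at each
#' displacement the overlap statistics (counts, sums, sums of squares and the
#' cross sum) are obtained from running correlation sums of the masked
#' arrays, and the coefficient is the mean-removed, variance-normalised
#' cross-correlation over the cells where both maps are valid. The
#' zero-displacement alignment gives the corneal coefficient map.
#'
#' @param template the RPC `grid_map` (template `t`)
#' @param image the barometer `grid_map` (image `f`)
#' @param min_overlap minimum overlapping valid cells for a coefficient
#' @return object of class `correlation_map`: `surface` (full NCC surface),
#'   `zero_lag` (the zero-displacement coefficient), `grid`
#' @export
ncc_map <- function(template, image, min_overlap = 16L) {
  stopifnot(inherits(template, "grid_map"), inherits(image, "grid_map"))
  if (!identical(dim(template$values), dim(image$values))) {
    stop("maps must share the common grid")
  }
  mt <- template$mask & is.finite(template$values)
  mf <- image$mask & is.finite(image$values)
  tv <- ifelse(mt, template$values, 0)
  fv <- ifelse(mf, image$values, 0)
  if (sd(tv[mt]) < 1e-14) stop("zero-variance template")
  S_ff <- xcorr2_fft(fv^2, 1 * mt)
  S_f <- xcorr2_fft(fv, 1 * mt)
  S_tt <- xcorr2_fft(1 * mf, tv^2)
  S_t <- xcorr2_fft(1 * mf, tv)
  S_ft <- xcorr2_fft(fv, tv)
  N <- xcorr2_fft(1 * mf, 1 * mt)
  num <- S_ft - S_f * S_t / pmax(N, 1)
  den2_f <- S_ff - S_f^2 / pmax(N, 1)
  den2_t <- S_tt - S_t^2 / pmax(N, 1)
  den <- sqrt(pmax(den2_f, 0) * pmax(den2_t, 0))
  gamma <- num / den
  gamma[N < min_overlap | den < 1e-12] <- NA_real_
  gamma <- pmin(pmax(gamma, -1), 1)
  d <- dim(template$values)
  zero_lag <- gamma[d[1], d[2]]
  structure(
    list(
      surface = gamma, zero_lag = zero_lag,
      grid = template$grid,
      template_mask = mt, image_mask = mf
    ),
    class = "correlation_map"
  )
}

#' @exportS3Method base::print
print.correlation_map <- function(x, ...) {
  cat(sprintf(
    "<correlation_map> %dx%d NCC surface, zero-lag coefficient %.4f\n",
    nrow(x$surface), ncol(x$surface), x$zero_lag
  ))
  invisible(x)
}

# direct double-loop evaluation (oracle-style reference, exported for
# verification studies)

#' Direct NCC evaluation
#'
#' Literal double-loop evaluation of the normalized cross-correlation at
#' every displacement; quadratic cost, used to verify the running-sum
#' implementation.
#'
#' @param fv,tv image and template matrices
#' @param mf,mt validity masks
#' @param min_overlap minimum overlap count
#' @return the full NCC surface
#' @export
ncc_direct <- function(fv, tv, mf = NULL, mt = NULL, min_overlap = 16L) {
  if (is.null(mf)) mf <- is.finite(fv)
  if (is.null(mt)) mt <- is.finite(tv)
  nf <- dim(fv)
  nt <- dim(tv)
  out <- matrix(NA_real_, nf[1] + nt[1] - 1L, nf[2] + nt[2] - 1L)
  for (u in seq(-(nt[1] - 1L), nf[1] - 1L)) {
    for (v in seq(-(nt[2] - 1L), nf[2] - 1L)) {
      fs <- numeric(0)
      ts <- numeric(0)
      i_lo <- max(1L, 1L + u)
      i_hi <- min(nf[1], nt[1] + u)
      j_lo <- max(1L, 1L + v)
      j_hi <- min(nf[2], nt[2] + v)
      if (i_lo > i_hi || j_lo > j_hi) next
      fi <- fv[i_lo:i_hi, j_lo:j_hi, drop = FALSE]
      ti <- tv[(i_lo - u):(i_hi - u), (j_lo - v):(j_hi - v), drop = FALSE]
      ok <- mf[i_lo:i_hi, j_lo:j_hi, drop = FALSE] &
        mt[(i_lo - u):(i_hi - u), (j_lo - v):(j_hi - v), drop = FALSE]
      if (sum(ok) < min_overlap) next
      fs <- fi[ok]
      ts <- ti[ok]
      nmr <- sum((fs - mean(fs)) * (ts - mean(ts)))
      dnm <- sqrt(sum((fs - mean(fs))^2) * sum((ts - mean(ts))^2))
      if (dnm < 1e-12) next
      out[u + nt[1], v + nt[2]] <- min(max(nmr / dnm, -1), 1)
    }
  }
  out
}

#' Classify coefficient areas into similarity bands
#'
#' Weak: |coefficient| < 0.4; moderate: 0.4 <= |coefficient| < 0.6; strong:
#' |coefficient| >= 0.6 (half-open band edges). Percentages are computed on
#' cell counts over the analysis mask, so the three bands sum to exactly 100.
#'
#' @param values coefficient matrix in \[-1, 1\]
#' @param mask analysis mask (same shape)
#' @return tibble with `band` and `area_pct`
#' @export
classify_areas <- function(values, mask) {
  sel <- mask & is.finite(values)
  n <- sum(sel)
  if (n == 0) stop("empty analysis mask")
  a <- abs(values[sel])
  n_weak <- sum(a < 0.4)
  n_mod <- sum(a >= 0.4 & a < 0.6)
  n_strong <- sum(a >= 0.6)
  tibble(
    band = factor(c("weak", "moderate", "strong"),
      levels = c("weak", "moderate", "strong")
    ),
    area_pct = c(n_weak, n_mod, n_strong) / n * 100
  )
}
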