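# Seeded synthetic cohort generator: conicoid-plus-astigmatism anterior
# surfaces with cohort metadata, an imposed Ortho-K effect (central
# flattening + annular steepening with decentration), eyelid-bounded coverage
# footprints with eyelash slit artefacts, and correlated validation fields.

# run expr under a deterministic RNG stream without disturbing the caller's
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# per-case substream: hash (seed, index) into a 31-bit seed
case_seed <- function(seed, index, salt = 0L) {
  s <- (as.double(seed) * 2654435761 + as.double(index) * 97561 + salt * 7919)
  as.integer(s %% 2147483647)
}

rnorm_clip <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

#' Cohort specification for the synthetic generator
#'
#' Defaults emulate the clinical cohort: age 14.1 +/- 4 y, IOP 15 +/- 3 mmHg,
#' CCT 0.554 +/- 0.033 mm, pre-wear Sim-K 42.6 +/- 1.3 D (flat) and
#' 44 +/- 1.3 D (steep), asphericity 0.66 +/- 0.1 / 0.4 +/- 0.18 (treated as
#' conicoid eccentricity e by default, Q = -e^2), and a right-eye fraction of
#' 132/249. Decentration is sampled componentwise N(0, 0.25) mm.
#'
#' @param n number of eyes (>= 1)
#' @param seed global integer seed; per-case streams are hashed from it
#' @param age,iop,cct,simk_flat,simk_steep,asph_flat,asph_steep `(mean, sd)`
#'   pairs (ages in years, IOP mmHg, CCT mm, Sim-K dioptres)
#' @param asph_convention how asphericity values are interpreted:
#'   `"eccentricity"` (Q = -e^2), `"Q"`, or `"p"` (Q = p - 1)
#' @param decentration_sd per-component SD of the lens decentration, mm
#' @param central_flattening,annulus_steepening,annulus_radius `(mean, sd)`
#'   of the imposed Ortho-K effect (dioptres / dioptres / mm)
#' @param transition_width effect transition width, mm
#' @param right_eye_prob probability an eye is a right eye
#' @param grid polar measurement grid ([polar_grid()]); the default is the
#'   clinical 300 x 333 dialect with 5.4 mm coverage radius
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(n, seed = 1L,
                        age = c(14.1, 4), iop = c(15, 3), cct = c(0.554, 0.033),
                        simk_flat = c(42.6, 1.3), simk_steep = c(44, 1.3),
                        asph_flat = c(0.66, 0.1), asph_steep = c(0.4, 0.18),
                        asph_convention = c("eccentricity", "Q", "p"),
                        decentration_sd = 0.25,
                        central_flattening = c(-2, 0.6),
                        annulus_steepening = c(1.4, 0.4),
                        annulus_radius = c(2.6, 0.2),
                        transition_width = 0.6,
                        right_eye_prob = 132 / 249,
                        grid = polar_grid(r_max = 5.4)) {
  if (n < 1) stop("cohort size n must be >= 1")
  pairs <- list(
    age = age, iop = iop, cct = cct, simk_flat = simk_flat,
    simk_steep = simk_steep, asph_flat = asph_flat, asph_steep = asph_steep,
    central_flattening = central_flattening,
    annulus_steepening = annulus_steepening, annulus_radius = annulus_radius
  )
  for (nm in names(pairs)) {
    p <- pairs[[nm]]
    if (length(p) != 2 || p[2] < 0) {
      stop("distribution '", nm, "' must be (mean, sd) with sd >= 0")
    }
  }
  if (decentration_sd < 0) stop("decentration_sd must be >= 0")
  structure(
    c(pairs, list(
      n = as.integer(n), seed = as.integer(seed),
      asph_convention = match.arg(asph_convention),
      decentration_sd = decentration_sd,
      transition_width = transition_width,
      right_eye_prob = right_eye_prob, grid = grid
    )),
    class = "cohort_spec"
  )
}

asph_to_q <- function(value, convention) {
  switch(convention,
    eccentricity = -value^2,
    Q = value,
    p = value - 1
  )
}

# conicoid elevation with meridian-dependent apical radius and asphericity
conicoid_elevation <- function(grid, r_flat, r_steep, flat_angle_deg,
                               q_flat, q_steep) {
  th <- grid$azimuths * pi / 180
  phi <- flat_angle_deg * pi / 180
  c_flat <- 1 / r_flat
  c_steep <- 1 / r_steep
  curv <- c_flat * cos(th - phi)^2 + c_steep * sin(th - phi)^2
  qv <- q_flat * cos(th - phi)^2 + q_steep * sin(th - phi)^2
  R <- 1 / curv
  r2 <- outer(rep(1, length(th)), grid$radii^2)
  Rm <- matrix(R, length(th), length(grid$radii))
  Qm <- matrix(qv, length(th), length(grid$radii))
  disc <- 1 - (1 + Qm) * r2 / Rm^2
  if (any(disc <= 0)) stop("conicoid is not defined over the full grid")
  -(r2 / (Rm * (1 + sqrt(disc))))
}

#' Generate one synthetic patient
#'
#' Deterministic for a given `(spec$seed, index)` pair. Metadata are sampled
#' from the cohort normals and clipped to physiological ranges (age > 5,
#' 5 <= IOP <= 40 mmHg, 0.35 <= CCT <= 0.75 mm); the pre-wear surface is a
#' conicoid with toric astigmatism matching the sampled Sim-K.
#'
#' @param spec a [cohort_spec()]
#' @param index case index in `1..spec$n`
#' @return list with `patient` (tibble row), `topography` (pre-wear
#'   [topo_record()]) and `lens` (a [lens_design()])
#' @export
generate_patient <- function(spec, index) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (index < 1 || index > spec$n) stop("index must be in 1..n")
  with_seed(case_seed(spec$seed, index), {
    age <- rnorm_clip(1, spec$age[1], spec$age[2], 6, 60)
    iop <- rnorm_clip(1, spec$iop[1], spec$iop[2], 5, 40)
    cct <- rnorm_clip(1, spec$cct[1], spec$cct[2], 0.35, 0.75)
    kf <- rnorm_clip(1, spec$simk_flat[1], spec$simk_flat[2], 38, 48)
    ks <- rnorm_clip(1, max(kf, spec$simk_steep[1]), spec$simk_steep[2], kf, 50)
    ef <- rnorm_clip(1, spec$asph_flat[1], spec$asph_flat[2], 0, 0.95)
    es <- rnorm_clip(1, spec$asph_steep[1], spec$asph_steep[2], 0, 0.95)
    flat_angle <- runif(1, 0, 180)
    eye <- if (runif(1) < spec$right_eye_prob) "right" else "left"
    r_flat <- 337.5 / kf
    r_steep <- 337.5 / ks
    elev <- conicoid_elevation(
      spec$grid, r_flat, r_steep, flat_angle,
      asph_to_q(ef, spec$asph_convention), asph_to_q(es, spec$asph_convention)
    )
    topo <- topo_record(elev, spec$grid, meta = list(
      eye = eye, exam_date = sprintf("2023-%02d-%02d", 1 + index %% 12, 1 + index %% 28),
      simk_flat = kf, simk_steep = ks,
      flat_angle = flat_angle, steep_angle = (flat_angle + 90) %% 180
    ))
    patient <- tibble(
      id = sprintf("SYN-%05d", index),
      age = age, iop = iop, cct = cct, eye = eye,
      exam_date = topo$meta$exam_date
    )
    list(patient = patient, topography = topo, lens = lens_design())
  })
}

#' Ortho-K effect specification
#'
#' @param central_flattening central power change, dioptres (< 0)
#' @param annulus_steepening annular power change, dioptres (> 0)
#' @param annulus_radius radius of the steepened annulus, mm (> 0)
#' @param decentration `(dx, dy)` of the effect centre, mm
#' @param transition_width Gaussian width of the profile lobes, mm
#' @return object of class `orthok_effect`
#' @export
orthok_effect <- function(central_flattening, annulus_steepening,
                          annulus_radius, decentration = c(0, 0),
                          transition_width = 0.6) {
  zero <- central_flattening == 0 && annulus_steepening == 0
  if (!zero) {
    if (central_flattening >= 0) stop("central_flattening must be negative")
    if (annulus_steepening <= 0) stop("annulus_steepening must be positive")
  }
  if (annulus_radius <= 0) stop("annulus_radius must be positive")
  structure(
    list(
      central_flattening = central_flattening,
      annulus_steepening = annulus_steepening,
      annulus_radius = annulus_radius,
      decentration = decentration,
      transition_width = transition_width
    ),
    class = "orthok_effect"
  )
}

#' Sample the Ortho-K effect for one case
#'
#' @param spec a [cohort_spec()]
#' @param index case index
#' @return an [orthok_effect()] (deterministic per (seed, index))
#' @export
generate_orthok_effect <- function(spec, index) {
  with_seed(case_seed(spec$seed, index, salt = 1L), {
    orthok_effect(
      central_flattening = rnorm_clip(
        1, spec$central_flattening[1], spec$central_flattening[2], -6, -0.5
      ),
      annulus_steepening = rnorm_clip(
        1, spec$annulus_steepening[1], spec$annulus_steepening[2], 0.3, 3
      ),
      annulus_radius = rnorm_clip(
        1, spec$annulus_radius[1], spec$annulus_radius[2], 2, 3.0
      ),
      decentration = rnorm_clip(2, 0, spec$decentration_sd, -0.7, 0.7),
      transition_width = spec$transition_width
    )
  })
}

#' Impose an Ortho-K effect on a pre-wear topography
#'
#' The effect is imposed in elevation space: a radially symmetric sag
#' perturbation about the (possibly decentred) effect centre whose curvature
#' signature matches the requested power changes. The curvature profile is
#' central flattening + annular steepening + one outer compensation lobe whose
#' amplitude is solved so the perturbation has zero apex slope; integrating
#' inward from the compact-support rim guarantees the surface is conserved
#' exactly outside `annulus_radius + 2 * transition_width`.
#'
#' @param pre pre-wear [topo_record()]
#' @param effect an [orthok_effect()]
#' @param keratometric_constant dioptre-per-(1/mm) conversion, `1000 (nh - 1)`
#' @return post-wear [topo_record()]
#' @export
apply_orthok_effect <- function(pre, effect, keratometric_constant = 337.5) {
  stopifnot(inherits(pre, "topo_record"), inherits(effect, "orthok_effect"))
  rho_max <- effect$annulus_radius + 2 * effect$transition_width
  need <- rho_max + sqrt(sum(effect$decentration^2))
  if (need > max(pre$grid$radii) + 1e-9) {
    stop("effect support (", round(need, 2), " mm) extends beyond the measured radius")
  }
  if (effect$central_flattening == 0 && effect$annulus_steepening == 0) {
    return(pre)
  }
  w_c <- effect$annulus_radius / 1.8
  w_t <- effect$transition_width
  r_a <- effect$annulus_radius
  r_o <- r_a + 1.2 * w_t
  rr <- seq(0, rho_max, by = 0.002)
  taper <- function(f, r0, w) {
    raw <- exp(-((rr - r0) / w)^2)
    edge <- exp(-((rho_max - r0) / w)^2)
    pmax((raw - edge) / (1 - edge), 0)
  }
  f_c <- taper(NULL, 0, w_c)
  f_a <- taper(NULL, r_a, w_t)
  f_o <- taper(NULL, r_o, w_t)
  # slope factor of the pre-wear sphere-like surface (mean keratometry)
  k_mean <- mean(c(pre$meta$simk_flat, pre$meta$simk_steep), na.rm = TRUE)
  R0 <- if (is.finite(k_mean)) keratometric_constant / k_mean else 7.8
  slope_fac <- (R0^2 / pmax(R0^2 - rr^2, 1e-6))^1.5
  at <- function(f, r0) approx(rr, f, xout = r0, rule = 2)$y
  # solve amplitudes: curvature at centre, curvature at annulus, zero net
  # integral of the sag second derivative (smooth apex after inward integration)
  M <- rbind(
    c(at(f_c, 0), at(f_a, 0), at(f_o, 0)),
    c(at(f_c, r_a), at(f_a, r_a), at(f_o, r_a)),
    c(
      sum(f_c * slope_fac) * 0.002,
      sum(f_a * slope_fac) * 0.002,
      sum(f_o * slope_fac) * 0.002
    )
  )
  rhs <- c(
    effect$central_flattening / keratometric_constant,
    effect$annulus_steepening / keratometric_constant,
    0
  )
  amp <- solve(M, rhs)
  d2s <- (amp[1] * f_c + amp[2] * f_a + amp[3] * f_o) * slope_fac
  # integrate inward from the compact-support rim: ds(rho_max) = ds'(rho_max) = 0
  n <- length(rr)
  ds1 <- rev(-cumsum(rev(c(d2s[-1] + d2s[-n], 0)) / 2 * 0.002)) # ds' with ds'(end)=0
  ds <- rev(-cumsum(rev(c(ds1[-1] + ds1[-n], 0)) / 2 * 0.002))
  dsf <- splinefun(rr, ds, method = "natural")
  xy <- polar_to_cartesian(pre$grid)
  rho <- sqrt((xy$x - effect$decentration[1])^2 + (xy$y - effect$decentration[2])^2)
  dz <- matrix(0, nrow(rho), ncol(rho))
  inside <- rho < rho_max
  dz[inside] <- -dsf(rho[inside]) # elevation z = -sag
  post <- pre
  post$elevation <- pre$elevation + dz
  post
}

#' Generate a coverage mask bounded by eyelid parabolas
#'
#' The mask is TRUE inside the device coverage disc and inside the palpebral
#' aperture (below the upper and above the lower lid parabola), with optional
#' radial slit-like gaps near the lid edges emulating eyelash shadows.
#'
#' @param boundary an [eyelid_boundary()] (upper parabola opens down, lower
#'   opens up)
#' @param grid a [polar_grid()]
#' @param device_radius coverage disc radius, mm (default: outermost station)
#' @param n_slits number of eyelash slit artefacts (default 6)
#' @param slit_width angular half-width of each slit, degrees
#' @param slit_depth radial depth of each slit, mm
#' @param seed RNG seed for slit placement
#' @return logical matrix (n_az x n_r)
#' @export
generate_coverage_mask <- function(boundary, grid, device_radius = NULL,
                                   n_slits = 6L, slit_width = 1.8,
                                   slit_depth = 0.9, seed = 1L) {
  stopifnot(inherits(boundary, "eyelid_boundary"))
  if (is.null(device_radius)) device_radius <- max(grid$radii)
  up <- boundary$upper
  lo <- boundary$lower
  if (up["a"] >= 0 || lo["a"] <= 0) {
    stop("upper lid parabola must open downward (a < 0) and lower upward (a > 0)")
  }
  xy <- polar_to_cartesian(grid)
  r <- sqrt(xy$x^2 + xy$y^2)
  y_up <- up["a"] * xy$x^2 + up["b"] * xy$x + up["c"]
  y_lo <- lo["a"] * xy$x^2 + lo["b"] * xy$x + lo["c"]
  mask <- (r <= device_radius + 1e-12) & (xy$y <= y_up) & (xy$y >= y_lo)
  if (!any(mask)) stop("eyelid curves do not leave any aperture inside the coverage disc")
  if (n_slits > 0) {
    # angular sectors of dropped samples reaching inward from the lid edge
    n_az <- nrow(mask)
    az <- grid$azimuths
    rmax_az <- apply(mask, 1L, function(m) if (any(m)) max(grid$radii[m]) else NA_real_)
    lid_az <- which(is.finite(rmax_az) & rmax_az < device_radius - 1e-9)
    if (length(lid_az)) {
      with_seed(seed, {
        centres <- sample(lid_az, min(n_slits, length(lid_az)))
        for (ctr in centres) {
          dd <- pmin(abs(az - az[ctr]), 360 - abs(az - az[ctr]))
          rows <- which(dd <= slit_width)
          for (i in rows) {
            if (!is.finite(rmax_az[i])) next
            drop <- grid$radii > rmax_az[i] - slit_depth
            mask[i, drop] <- FALSE
          }
        }
      })
    }
  }
  mask
}

#' Generate a field with a prescribed zero-lag correlation to an RPC map
#'
#' Returns `rho * z + sqrt(1 - rho^2) * w` where `z` is the standardized RPC
#' and `w` is standardized smooth noise empirically orthogonalized against
#' `z`, so the zero-lag correlation over the valid mask equals `rho` up to
#' floating point.
#'
#' @param rpc a `grid_map` (common-grid map with a validity mask)
#' @param rho target correlation in \[-1, 1\]
#' @param seed RNG seed
#' @param smooth_sigma Gaussian smoothing of the noise, in grid cells
#' @return a `grid_map` with the same mask
#' @export
generate_correlated_field <- function(rpc, rho, seed = 1L, smooth_sigma = 6) {
  stopifnot(inherits(rpc, "grid_map"))
  if (abs(rho) > 1) stop("rho must be in [-1, 1]")
  m <- rpc$mask & is.finite(rpc$values)
  v <- rpc$values[m]
  if (sd(v) < 1e-14) stop("RPC map is constant: standardization undefined")
  z <- (v - mean(v)) / sd(v)
  w <- with_seed(seed, {
    noise <- matrix(rnorm(length(rpc$values)), nrow(rpc$values))
    sm <- gaussian_filter2(noise, smooth_sigma)
    sm[m]
  })
  w <- w - mean(w)
  w <- w - sum(w * z) / sum(z * z) * z
  if (sd(w) < 1e-14) stop("degenerate noise field")
  w <- w / sd(w)
  out <- rpc
  out$values[] <- NA_real_
  out$values[m] <- rho * z + sqrt(1 - rho^2) * w
  out$unit <- "unitless"
  out
}

#' Generate a complete synthetic case
#'
#' Bundles one patient: pre-wear topography, sampled Ortho-K effect, post-wear
#' topography, eyelid boundary, coverage mask (applied to both records), and
#' the lens design. Deterministic per `(spec$seed, index)`.
#'
#' @param spec a [cohort_spec()]
#' @param index case index
#' @param lid_truncation apply the eyelid coverage footprint (default TRUE)
#' @return list with `patient`, `pre`, `post`, `effect`, `boundary`, `mask`,
#'   `lens`
#' @export
generate_case <- function(spec, index, lid_truncation = TRUE) {
  base <- generate_patient(spec, index)
  effect <- generate_orthok_effect(spec, index)
  pre <- base$topography
  post <- apply_orthok_effect(pre, effect)
  boundary <- with_seed(case_seed(spec$seed, index, salt = 2L), {
    side <- if (base$patient$eye == "right") "right" else "left"
    tab <- eyelid_reference_parabolas(side)
    eyelid_boundary(
      upper = tab$upper + c(rnorm(1, 0, 0.005), rnorm(1, 0, 0.01), rnorm(1, 0, 0.1)),
      lower = tab$lower + c(rnorm(1, 0, 0.005), rnorm(1, 0, 0.01), rnorm(1, 0, 0.1))
    )
  })
  mask <- NULL
  if (lid_truncation) {
    mask <- generate_coverage_mask(boundary, spec$grid,
      seed = case_seed(spec$seed, index, salt = 3L)
    )
    pre$coverage <- pre$coverage & mask
    pre$elevation[!pre$coverage] <- NA_real_
    post$coverage <- post$coverage & mask
    post$elevation[!post$coverage] <- NA_real_
  }
  list(
    patient = base$patient, pre = pre, post = post, effect = effect,
    boundary = boundary, mask = mask, lens = base$lens
  )
}

#' Write a cohort manifest
#'
#' @param spec a [cohort_spec()]
#' @param path CSV output path
#' @return tibble manifest (id, metadata, lens parameters, true decentration)
#' @export
cohort_manifest <- function(spec, path = NULL) {
  rows <- lapply(seq_len(spec$n), function(i) {
    p <- generate_patient(spec, i)
    e <- generate_orthok_effect(spec, i)
    cbind(p$patient, tibble(
      lens_base_curve = p$lens$back$radius[1],
      lens_diameter = p$lens$diameter,
      true_dx = e$decentration[1], true_dy = e$decentration[2],
      central_flattening = e$central_flattening,
      annulus_steepening = e$annulus_steepening,
      annulus_radius = e$annulus_radius
    ))
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
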