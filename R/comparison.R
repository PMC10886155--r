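# Per-case comparison of barometer fields against the clinical RPC map, and
# cohort-level statistics.

#' Compare a barometer map against the RPC template
#'
#' Both maps are normalised to \[-1, 1\]; the NCC coefficient map is the
#' zero-displacement-aligned central window of the full correlation surface,
#' and the SSIM map is computed after affine rescaling to \[0, 1\]. Both
#' coefficient maps are classified into weak/moderate/strong band areas over
#' the analysis mask.
#'
#' @param rpc normalised RPC `grid_map` (template)
#' @param field normalised barometer `grid_map`
#' @param ssim_pars a [ssim_params()]
#' @return object of class `map_comparison`: `ncc` (correlation_map),
#'   `ncc_map` (central window as matrix), `ssim` (matrix), `bands`
#'   (tibble with metric, band, area_pct)
#' @export
compare_maps <- function(rpc, field, ssim_pars = ssim_params()) {
  stopifnot(inherits(rpc, "grid_map"), inherits(field, "grid_map"))
  ncc <- ncc_map(rpc, field)
  d <- dim(rpc$values)
  # central template-aligned window: displacement (0, 0)
  full <- ncc$surface
  # corneal map interpretation: windowed local NCC about the zero lag is not
  # defined pointwise; report the zero-lag-aligned surface restricted to the
  # template extent centred on the zero displacement
  ctr <- d # zero-lag index
  half1 <- (d[1] - 1L) %/% 2L
  half2 <- (d[2] - 1L) %/% 2L
  win <- full[(ctr[1] - half1):(ctr[1] + half1), (ctr[2] - half2):(ctr[2] + half2)]
  mask <- rpc$mask & field$mask
  x01 <- (rpc$values + 1) / 2
  y01 <- (field$values + 1) / 2
  x01[!mask] <- 0
  y01[!mask] <- 0
  ss <- ssim_map(x01, y01, ssim_pars)
  bands <- dplyr::bind_rows(
    dplyr::mutate(classify_areas(win, mask), metric = "ncc"),
    dplyr::mutate(classify_areas(ss, mask), metric = "ssim")
  )
  structure(
    list(
      ncc = ncc, ncc_window = win, ssim = ss, mask = mask,
      bands = bands[, c("metric", "band", "area_pct")],
      component = field$component
    ),
    class = "map_comparison"
  )
}

#' @exportS3Method base::print
print.map_comparison <- function(x, ...) {
  cat(sprintf("<map_comparison> %s vs RPC\n", x$component))
  print(x$bands)
  invisible(x)
}

#' Band-area table of a comparison
#'
#' @param x a `map_comparison` or `case_report`
#' @param ... unused
#' @return tibble of band areas
#' @export
tidy_comparison <- function(x, ...) {
  if (inherits(x, "map_comparison")) {
    return(dplyr::mutate(x$bands, component = x$component))
  }
  stop("no tidy method for ", class(x)[1])
}

#' Cohort summary of comparison results
#'
#' Per barometer, metric and band: mean and SD of the area percentages, a
#' Kolmogorov-Smirnov normality check of the per-eye values, and pairwise
#' two-sample t-tests between barometers at the 95% confidence level.
#'
#' @param results list of per-case band tibbles (metric, band, area_pct,
#'   component), e.g. from [run_case()] reports
#' @return object of class `cohort_summary`: `table` (mean +/- SD per
#'   barometer/metric/band), `normality`, `pairwise`
#' @export
cohort_summary <- function(results) {
  if (length(results) < 1) stop("cohort summary needs at least one result")
  all_bands <- dplyr::bind_rows(
    lapply(seq_along(results), function(i) {
      dplyr::mutate(results[[i]], case = i)
    })
  )
  comp_sets <- lapply(
    split(all_bands$component, all_bands$case),
    function(x) sort(unique(x))
  )
  if (length(unique(comp_sets)) != 1) {
    stop("mismatched barometer sets across cases")
  }
  tab <- dplyr::summarise(
    dplyr::group_by(all_bands, .data$component, .data$metric, .data$band),
    mean_pct = mean(.data$area_pct),
    sd_pct = if (dplyr::n() > 1) sd(.data$area_pct) else NA_real_,
    n = dplyr::n(),
    .groups = "drop"
  )
  ks <- dplyr::summarise(
    dplyr::group_by(all_bands, .data$component, .data$metric, .data$band),
    ks_p = tryCatch(
      {
        v <- .data$area_pct
        if (sd(v) < 1e-12) NA_real_ else {
          suppressWarnings(ks.test((v - mean(v)) / sd(v), "pnorm")$p.value)
        }
      },
      error = function(e) NA_real_
    ),
    .groups = "drop"
  )
  comps <- sort(unique(all_bands$component))
  pairs <- if (length(comps) >= 2) {
    utils::combn(comps, 2, simplify = FALSE)
  } else {
    list()
  }
  pw <- dplyr::bind_rows(lapply(pairs, function(pr) {
    sub <- all_bands[all_bands$component %in% pr, ]
    dplyr::summarise(
      dplyr::group_by(sub, .data$metric, .data$band),
      component_a = pr[1], component_b = pr[2],
      p_value = tryCatch(
        {
          a <- .data$area_pct[.data$component == pr[1]]
          b <- .data$area_pct[.data$component == pr[2]]
          if (sd(a) < 1e-12 && sd(b) < 1e-12) {
            if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
          } else {
            t.test(a, b)$p.value
          }
        },
        error = function(e) NA_real_
      ),
      .groups = "drop"
    )
  }))
  structure(
    list(table = tab, normality = ks, pairwise = pw, n_cases = length(results)),
    class = "cohort_summary"
  )
}

#' @exportS3Method base::print
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d cases\n", x$n_cases))
  print(x$table, n = 30)
  invisible(x)
}
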