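# Topography records and the plain-text grid dialect.
#
# The instrument's native binary formats are proprietary and undocumented, so
# the package defines a text container: a header with the grid dimensions and
# exam metadata, an explicit radial-station line, an elevation block and a
# coverage block. Files are lossless round-trip for all finite fields.

#' Create a corneal topography record
#'
#' A record holds the anterior-surface elevation on a polar grid (apex at
#' z = 0, +Z toward the device, mm), a validity (coverage) mask, and exam
#' metadata including simulated keratometry. The default clinical dialect uses
#' a 300 azimuth x 333 radial-station grid.
#'
#' @param elevation numeric matrix, n_az x n_r, corneal height in mm
#' @param grid a [polar_grid()] matching `elevation`
#' @param coverage logical matrix marking valid samples (default all valid)
#' @param meta named list: `eye` ("right"/"left"), `exam_date`,
#'   `simk_flat`, `simk_steep` (D), `flat_angle`, `steep_angle` (deg)
#' @return object of class `topo_record`
#' @export
topo_record <- function(elevation, grid, coverage = NULL, meta = list()) {
  elevation <- as.matrix(elevation)
  if (nrow(elevation) != length(grid$azimuths) ||
    ncol(elevation) != length(grid$radii)) {
    stop("elevation dimensions do not match the grid (expected ",
      length(grid$azimuths), " x ", length(grid$radii), ")")
  }
  if (is.null(coverage)) coverage <- matrix(TRUE, nrow(elevation), ncol(elevation))
  coverage <- coverage & is.finite(elevation)
  if (any(!is.finite(elevation[coverage]))) {
    stop("elevation must be finite wherever coverage is TRUE")
  }
  meta_def <- list(
    eye = "right", exam_date = NA_character_,
    simk_flat = NA_real_, simk_steep = NA_real_,
    flat_angle = NA_real_, steep_angle = NA_real_
  )
  structure(
    list(
      elevation = elevation, grid = grid, coverage = coverage,
      meta = modifyList(meta_def, meta)
    ),
    class = "topo_record"
  )
}

#' @exportS3Method base::print
print.topo_record <- function(x, ...) {
  cat(sprintf(
    "<topo_record> %d x %d polar grid, r <= %.3g mm, %s eye, %.1f%% covered\n",
    nrow(x$elevation), ncol(x$elevation), max(x$grid$radii),
    x$meta$eye, 100 * mean(x$coverage)
  ))
  if (is.finite(x$meta$simk_flat)) {
    cat(sprintf(
      "  Sim-K %.2f / %.2f D @ %.0f / %.0f deg\n",
      x$meta$simk_flat, x$meta$simk_steep,
      x$meta$flat_angle, x$meta$steep_angle
    ))
  }
  invisible(x)
}

#' Write a topography record to the text dialect
#'
#' @param record a [topo_record()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_topography <- function(record, path) {
  stopifnot(inherits(record, "topo_record"))
  con <- file(path, "w")
  on.exit(close(con))
  m <- record$meta
  hdr <- c(
    "OKFEA-TOPO 1",
    sprintf("n_az: %d", nrow(record$elevation)),
    sprintf("n_r: %d", ncol(record$elevation)),
    sprintf("eye: %s", m$eye),
    sprintf("exam_date: %s", m$exam_date),
    sprintf("simk_flat: %.17g", m$simk_flat),
    sprintf("simk_steep: %.17g", m$simk_steep),
    sprintf("flat_angle: %.17g", m$flat_angle),
    sprintf("steep_angle: %.17g", m$steep_angle)
  )
  writeLines(hdr, con)
  writeLines("RADII", con)
  writeLines(paste(sprintf("%.17g", record$grid$radii), collapse = " "), con)
  writeLines("ELEVATION", con)
  elev <- record$elevation
  elev[!record$coverage] <- NA_real_
  writeLines(apply(elev, 1L, function(row) {
    paste(ifelse(is.na(row), "NA", sprintf("%.17g", row)), collapse = " ")
  }), con)
  writeLines("COVERAGE", con)
  writeLines(apply(record$coverage, 1L, function(row) {
    paste(as.integer(row), collapse = "")
  }), con)
  invisible(path)
}

#' Read a topography record from the text dialect
#'
#' Left-eye records are mirrored (X -> -X, i.e. azimuth -> 180 - azimuth) at
#' ingest so downstream analysis is laterality-agnostic; the original
#' laterality is retained in the metadata.
#'
#' @param path file written by [write_topography()]
#' @param mirror_left mirror left eyes into the right-eye frame (default TRUE)
#' @return a [topo_record()]
#' @export
read_topography <- function(path, mirror_left = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 1L || !startsWith(lines[[1]], "OKFEA-TOPO")) {
    stop("not a topography dialect file (missing OKFEA-TOPO header): ", path)
  }
  sect <- function(name) {
    i <- which(lines == name)
    if (length(i) != 1L) stop("truncated or malformed file: missing ", name, " section")
    i
  }
  hdr_end <- sect("RADII")
  hdr <- lines[2:(hdr_end - 1L)]
  kv <- strsplit(hdr, ": ", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = ": "), "")
  get <- function(k) vals[match(k, keys)]
  n_az <- as.integer(get("n_az"))
  n_r <- as.integer(get("n_r"))
  if (is.na(n_az) || is.na(n_r)) stop("header does not declare grid dimensions")
  radii <- suppressWarnings(as.numeric(strsplit(lines[hdr_end + 1L], " ")[[1]]))
  if (length(radii) != n_r || anyNA(radii)) {
    stop("dimension mismatch: RADII line has ", length(radii),
      " entries, header declares n_r = ", n_r)
  }
  if (any(diff(radii) <= 0)) stop("non-monotone radial positions")
  ie <- sect("ELEVATION")
  ic <- sect("COVERAGE")
  if (ic - ie - 1L != n_az || length(lines) < ic + n_az) {
    stop("dimension mismatch: elevation/coverage blocks do not match n_az = ", n_az)
  }
  elev_rows <- lapply(lines[(ie + 1L):(ic - 1L)], function(l) {
    v <- strsplit(l, " ")[[1]]
    out <- suppressWarnings(as.numeric(ifelse(v == "NA", NA, v)))
    if (length(out) != n_r || any(is.na(out) & v != "NA")) {
      stop("unparseable numbers in elevation block")
    }
    out
  })
  elevation <- do.call(rbind, elev_rows)
  coverage <- do.call(rbind, lapply(lines[(ic + 1L):(ic + n_az)], function(l) {
    as.logical(as.integer(strsplit(l, "")[[1]]))
  }))
  if (ncol(coverage) != n_r) stop("dimension mismatch in coverage block")
  elevation[!coverage] <- NA_real_
  num <- function(k) suppressWarnings(as.numeric(get(k)))
  meta <- list(
    eye = get("eye"), exam_date = get("exam_date"),
    simk_flat = num("simk_flat"), simk_steep = num("simk_steep"),
    flat_angle = num("flat_angle"), steep_angle = num("steep_angle")
  )
  rec <- topo_record(elevation, polar_grid(n_az, n_r, radii = radii), coverage, meta)
  if (mirror_left && identical(meta$eye, "left")) rec <- mirror_record(rec)
  rec
}

# Mirror a record about the vertical (Y) axis: azimuth -> 180 - azimuth.
mirror_record <- function(record) {
  az <- record$grid$azimuths
  target <- (180 - az) %% 360
  idx <- match(round(target, 9), round(az, 9))
  if (anyNA(idx)) stop("azimuth sampling is not mirror-symmetric")
  record$elevation <- record$elevation[idx, , drop = FALSE]
  record$coverage <- record$coverage[idx, , drop = FALSE]
  record$meta$mirrored <- TRUE
  record
}
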