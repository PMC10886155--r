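# Case- and cohort-level orchestration: topography -> RPC/zones -> eyelid ->
# meshing -> seating -> FEA -> field extraction -> comparison.

#' Default pipeline configuration
#'
#' Every modelling constant is a named, defaulted key: refractive indices
#' and smoothing factor, load-program pressures, solver tolerances, band
#' edges, mesh preset and cohort spec parameters. Values can be overridden
#' by a YAML file or a named list.
#'
#' @param ... overrides (named)
#' @param config_file optional YAML file of overrides
#' @return nested configuration list
#' @export
pipeline_config <- function(..., config_file = NULL) {
  cfg <- list(
    seed = 1L,
    n = 3L,
    mesh_preset = "desk",
    skip_fea = FALSE,
    power = list(nh = 1.3375, nair = 1.0, smoothing_factor = 4.5),
    zones = list(edge_margin = 0.5),
    program = list(
      iop_increments = 10L, eyelid_pressure_mmhg = 8.0,
      tear_tension_mpa = 43.6, tol = 5e-3, max_newton = 30L
    ),
    stress_free = list(tol = 1e-4, max_iter = 30L),
    comparison = list(mask_radius = 5.0)
  )
  over <- list(...)
  if (!is.null(config_file)) {
    over <- modifyList(yaml::read_yaml(config_file), over)
  }
  modifyList(cfg, over)
}

#' Run one synthetic case end to end
#'
#' Generates the case, measures the clinical-style RPC and treatment-zone
#' decentration, builds cornea/eyelid/lens meshes, seats the lens at the
#' detected decentration, recovers the stress-free geometry, runs the staged
#' contact simulation, extracts the five barometer fields plus the FEA RPC,
#' and compares every barometer with the clinical RPC map.
#'
#' @param spec a [cohort_spec()]
#' @param index case index
#' @param config a [pipeline_config()]
#' @param outdir optional artefact directory
#' @param verbose print stage progress
#' @return object of class `case_report`
#' @export
run_case <- function(spec, index, config = pipeline_config(), outdir = NULL,
                     verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  say("case %d: generate", index)
  case <- stage("generate", generate_case(spec, index))
  pcfg <- power_map_config(
    nh = config$power$nh, nair = config$power$nair,
    smoothing_factor = config$power$smoothing_factor
  )
  say("case %d: power maps", index)
  p_pre <- stage("power_maps", power_map_pipeline(case$pre, pcfg))
  p_post <- stage("power_maps", power_map_pipeline(case$post, pcfg))
  rpc <- stage("power_maps", rpc_map(p_pre, p_post))
  zones <- stage("zones", detect_zones(rpc, edge_margin = config$zones$edge_margin))
  dec <- if (zones$treatment_zone) zones$decentration else c(0, 0)
  say("case %d: detected decentration (%.3f, %.3f)", index, dec[1], dec[2])
  boundary <- stage("eyelid", tryCatch(
    detect_eyelid_boundary(case$pre$coverage, spec$grid),
    error = function(e) case$boundary
  ))
  say("case %d: surfaces & meshes", index)
  ext <- stage("extend", extend_surface(case$pre))
  preset <- mesh_preset(config$mesh_preset)
  grid <- common_grid(mask_radius = config$comparison$mask_radius)
  rpc_grid <- normalize_map(resample_to_grid(rpc, grid, component = "rpc"))

  report <- list(
    patient = case$patient, effect = case$effect, zones = zones,
    boundary = boundary, rpc = rpc, rpc_grid = rpc_grid,
    schema_version = "1"
  )
  if (!isTRUE(config$skip_fea)) {
    cornea <- stage("meshing", build_cornea_mesh(
      ext,
      cct = case$patient$cct,
      layers = preset$cornea_layers, base = preset$cornea_base,
      rings = preset$cornea_rings
    ))
    lens <- stage("meshing", build_lens_mesh(
      case$lens,
      element_base = preset$lens_base,
      rings = preset$lens_rings, layers = preset$lens_layers
    ))
    say("case %d: seating", index)
    seat <- stage("seating", seat_lens(lens, dec, ext))
    lid_mesh <- stage("eyelid_mesh", build_eyelid_mesh(
      boundary, ext,
      nx = preset$eyelid_nx, ny = preset$eyelid_ny, lens = seat$mesh
    ))
    mats <- list(
      cornea = material_preset("cornea", age = case$patient$age),
      lens = material_preset("lens"),
      eyelid = material_preset("eyelid")
    )
    say("case %d: stress-free + inflation", index)
    sf <- stage("stress_free", find_stress_free_geometry(
      cornea, mats$cornea, case$patient$iop,
      tol = config$stress_free$tol, max_iter = config$stress_free$max_iter
    ))
    infl <- stage("inflation", inflate_mesh(
      sf$mesh, mats$cornea, case$patient$iop,
      increments = config$program$iop_increments
    ))
    cornea_infl <- cornea
    cornea_infl$nodes <- infl$nodes
    say("case %d: contact solve", index)
    asm <- stage("assembly", fea_assembly(
      cornea_infl, seat$mesh, lid_mesh, mats
    ))
    prog <- load_program(
      iop_mmhg = case$patient$iop,
      iop_increments = config$program$iop_increments,
      eyelid_pressure_mmhg = config$program$eyelid_pressure_mmhg,
      tear_tension_mpa = config$program$tear_tension_mpa,
      tol = config$program$tol, max_newton = config$program$max_newton
    )
    result <- stage("fea", run_load_program(asm, prog, prestress = infl$stress,
      verbose = verbose))
    say("case %d: fields + comparison", index)
    comps <- c(
      "contact_pressure", "mises", "pressure", "max_principal_stress",
      "max_principal_log_strain"
    )
    fields <- lapply(comps, function(cn) {
      stage("fields", extract_field(result, cn))
    })
    names(fields) <- comps
    field_grids <- lapply(fields, function(fl) {
      normalize_map(resample_to_grid(
        fl, grid, unit = fl$unit, component = fl$component
      ))
    })
    comparisons <- lapply(field_grids, function(fg) {
      stage("comparison", compare_maps(rpc_grid, fg))
    })
    bands <- dplyr::bind_rows(lapply(comps, function(cn) {
      dplyr::mutate(comparisons[[cn]]$bands, component = cn)
    }))
    frpc <- stage("fea_rpc", fea_rpc(result, pcfg))
    report <- c(report, list(
      seating = seat["report"], transform = seat$transform,
      convergence = result$logs, fields = field_grids,
      comparisons = comparisons, bands = bands, fea_rpc = frpc,
      stress_free_residuals = sf$residuals
    ))
  }
  class(report) <- "case_report"
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(report$bands)) {
      write.csv(report$bands, file.path(outdir, sprintf("case%03d_bands.csv", index)),
        row.names = FALSE)
    }
    jsonlite::write_json(
      list(
        patient = report$patient,
        decentration = as.list(stats::setNames(dec, c("dx", "dy"))),
        schema_version = report$schema_version
      ),
      file.path(outdir, sprintf("case%03d_report.json", index)),
      auto_unbox = TRUE, digits = NA
    )
  }
  report
}

#' @exportS3Method base::print
print.case_report <- function(x, ...) {
  cat(sprintf("<case_report> %s\n", x$patient$id))
  if (!is.null(x$bands)) print(x$bands, n = 30)
  invisible(x)
}

#' Run a synthetic cohort
#'
#' Iterates [run_case()] over the cohort; individual case failures are
#' logged and skipped, and the per-case band tables are aggregated with
#' [cohort_summary()].
#'
#' @param spec a [cohort_spec()]
#' @param config a [pipeline_config()]
#' @param outdir optional artefact directory
#' @param verbose progress messages
#' @return list: `summary` (a [cohort_summary()] or NULL), `reports`,
#'   `failures` (tibble of case/message), `n_skipped`
#' @export
run_cohort <- function(spec, config = pipeline_config(), outdir = NULL,
                       verbose = FALSE) {
  reports <- list()
  failures <- list()
  for (i in seq_len(spec$n)) {
    r <- tryCatch(
      run_case(spec, i, config, outdir = outdir, verbose = verbose),
      error = function(e) e
    )
    if (inherits(r, "error")) {
      failures[[length(failures) + 1L]] <- tibble(
        case = i, message = conditionMessage(r)
      )
      if (verbose) message("case ", i, " skipped: ", conditionMessage(r))
    } else {
      reports[[length(reports) + 1L]] <- r
    }
  }
  band_list <- lapply(reports, `[[`, "bands")
  band_list <- band_list[!vapply(band_list, is.null, TRUE)]
  summary <- if (length(band_list) >= 2) cohort_summary(band_list) else NULL
  out <- list(
    summary = summary, reports = reports,
    failures = if (length(failures)) dplyr::bind_rows(failures) else tibble(case = integer(), message = character()),
    n_skipped = length(failures)
  )
  if (!is.null(outdir) && !is.null(summary)) {
    write.csv(summary$table, file.path(outdir, "cohort_band_table.csv"),
      row.names = FALSE)
  }
  out
}
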