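#' Run the full desk-scale profiling pipeline
#'
#' Chains the stages downstream of image segmentation: synthetic inputs
#' (pressure and flow waveforms, tube surface mesh) are generated, the
#' pulsatile Carreau flow problem is solved flow-driven on the tube, the
#' solver wall shear is mapped onto the surface and endothelial indices are
#' computed alongside an analytic planted-truth WSS series, pressure
#' waveform features and location-to-location differences are extracted,
#' and the mesh-sensitivity analysis is run on a generated study table.
#' All artifacts (CSV/VTK-XML/JSON) are written under `out_dir`, with the
#' seed and a config hash embedded in the report; re-running with the same
#' config reproduces every numeric byte (no timestamps are written).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory; defaults to the config's
#'   `paths$out_dir`.
#' @param quiet Suppress per-stage messages.
#' @return The report list, invisibly (also written to `report.json`).
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(out_dir)) out_dir <- config$paths$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[hemowall] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  cfg_hash <- unname(tools::md5sum(tf)); unlink(tf)

  s <- config$synth
  scfg <- synth_config(seed = config$seed, period_T = s$period_T,
                       sbp = s$sbp, dbp = s$dbp, t_peak = s$t_peak,
                       radius = s$radius, tube_length = s$tube_length,
                       wss_samples = s$wss_samples,
                       mean_velocity = s$mean_velocity)

  say("stage synth: waveforms, mesh, study table (seed ", config$seed, ")")
  synth <- stage("synth", {
    pw <- synth_pressure_waveform(scfg)
    qw <- synth_flow_waveform(scfg, as_flow = TRUE)
    mesh <- synth_tube_mesh(s$radius, s$tube_length, s$element_size_mm)
    study <- synth_mesh_study(scfg, noise = 0.002)
    write_waveform_csv(pw$waveform, file.path(out_dir, "pressure.csv"))
    write_waveform_csv(qw, file.path(out_dir, "flow.csv"))
    write_mesh_study_csv(study, file.path(out_dir, "mesh_study.csv"))
    list(pw = pw, qw = qw, mesh = mesh, study = study)
  })

  say("stage solve: flow-driven Carreau solve")
  sol <- stage("solve", {
    params <- do.call(carreau_params, config$rheology)
    grid <- radial_grid(s$radius, first_layer = config$solver$first_layer,
                        n_layers = config$solver$n_layers,
                        growth = config$solver$growth,
                        n_interior = config$solver$n_interior)
    sol <- solve_flow_driven(params, grid, synth$qw,
                             dt = config$solver$dt,
                             n_cycles = config$solver$n_cycles,
                             picard_tol = config$solver$picard_tol,
                             max_picard = config$solver$max_picard)
    write_flow_solution(sol, file.path(out_dir, "solution"))
    sol
  })

  say("stage indices: planted WSS series and solver-mapped indices")
  idx <- stage("indices", {
    syn <- synth_wss_series(synth$mesh, scfg, mode = "analytic")
    map <- wall_indices(syn$series)
    solver_syn <- synth_wss_series(synth$mesh, scfg, mode = "solver",
                                   solution = sol)
    solver_map <- wall_indices(solver_syn$series)
    write_index_map(map, file.path(out_dir, "indices_analytic"),
                    high_tawss = config$indices$high_tawss,
                    low_tawss = config$indices$low_tawss)
    write_index_map(solver_map, file.path(out_dir, "indices_solver"),
                    high_tawss = config$indices$high_tawss,
                    low_tawss = config$indices$low_tawss)
    list(map = map, solver_map = solver_map, truth = syn$truth)
  })

  say("stage waveform: features and location differences")
  wf <- stage("waveform", {
    feats <- extract_features(synth$pw$waveform,
                              notch_window = config$waveform$notch_window)
    downstream <- synth$pw$waveform
    downstream$values <- downstream$values - 1.5  # planted distal offset
    downstream$location <- "aortic arch"
    dp <- delta_p(synth$pw$waveform, downstream,
                  n = config$waveform$resample_points)
    list(features = feats, dp = dp)
  })

  say("stage sensitivity: mesh-independence report")
  sens <- stage("sensitivity", {
    rep <- mesh_sensitivity(synth$study,
                            threshold_pct = config$sensitivity$threshold_pct)
    sensitivity_report_json(rep, file.path(out_dir, "sensitivity.json"))
    rep
  })

  hi <- threshold_area(idx$map, "tawss", config$indices$high_tawss, "above")
  lo <- threshold_area(idx$map, "tawss", config$indices$low_tawss, "below")
  report <- list(
    config_hash = cfg_hash,
    seed = config$seed,
    solver = list(converged = sol$converged,
                  peak_velocity_mps = max(abs(sol$u)),
                  tau_wall_peak_pa = max(sol$tau_wall),
                  cycle_diffs = sol$cycle_diffs,
                  reynolds_mean = reynolds_number(
                    config$rheology$rho, s$mean_velocity, 2 * s$radius, 0.004)),
    indices = list(
      tawss_range_pa = range(idx$map$tawss),
      osi_range = range(idx$map$osi),
      area_fraction_tawss_above_high = hi$fraction,
      area_fraction_tawss_below_low = lo$fraction,
      solver_mode_max_osi = max(idx$solver_map$osi),
      sentinel_counts = idx$map$counts),
    waveform = list(
      systolic_mmHg = wf$features$systolic_peak$value,
      diastolic_mmHg = wf$features$diastolic_min$value,
      notch_mmHg = if (is.null(wf$features$dicrotic_notch)) NULL
        else wf$features$dicrotic_notch$value,
      mean_dp_mmHg = wf$dp$mean_dp),
    sensitivity = list(selected = as.list(sens$selected),
                       joint = sens$joint,
                       threshold_pct = sens$threshold_pct))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  say("done: ", out_dir)
  invisible(report)
}
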