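default_run_config <- function() {
  list(
    seed = 1L,
    rheology = list(mu_zero = 0.056, mu_inf = 0.0035, lambda_s = 3.313,
                    n_index = 0.568, rho = 1060),
    solver = list(dt = 0.001, n_cycles = 3L, picard_tol = 1e-5,
                  max_picard = 30L, n_interior = 40L, first_layer = 1e-4,
                  n_layers = 5L, growth = 1.2),
    indices = list(high_tawss = 5, low_tawss = 0.4),
    waveform = list(notch_window = 0.4, resample_points = 1000L),
    sensitivity = list(threshold_pct = 3),
    synth = list(period_T = 1.0, sbp = 120, dbp = 80, t_peak = 0.15,
                 radius = 0.01794, tube_length = 0.05,
                 element_size_mm = 3, wss_samples = 200L,
                 mean_velocity = 0.14),
    paths = list(out_dir = "hemowall_out")
  )
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(defaults))
      stop("unknown config key: ", paste0(path, nm), call. = FALSE)
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop("config key ", paste0(path, nm), " must be a mapping",
             call. = FALSE)
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Pipeline run configuration
#'
#' Loads (optionally) a YAML file and merges it over the built-in defaults,
#' which reproduce the reference solver protocol: dt = 0.001 s, 3 cardiac
#' cycles, iteration residual 1e-5, mesh-acceptance threshold 3%, wall-index
#' thresholds 5 Pa (high TAWSS) and 0.4 Pa (low TAWSS). Unknown keys are
#' rejected.
#'
#' @param path Optional YAML file path.
#' @param overrides Optional named list merged over the file values.
#' @return Object of class `"run_config"` (a nested list).
#' @export
run_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  do.call(carreau_params, cfg$rheology)     # validates the rheology block
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("hemowall run configuration\n")
  utils::str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}
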