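#' Mesh-independence study table
#'
#' Per-resolution summary of a grid-refinement family: element size and
#' count plus the parameters of interest (peak velocity `v_max`, peak wall
#' shear `wss_max`) sampled at the systolic peak. Runtimes are carried as
#' metadata only.
#'
#' @param element_size_mm Strictly increasing, unique element sizes, mm.
#' @param element_count Element counts (> 0).
#' @param v_max_mps Peak velocities, m/s (`>= 0`).
#' @param wss_max_pa Peak wall shear stresses, Pa (`>= 0`).
#' @param runtime_min Optional runtimes, minutes (pass-through).
#' @param mesh_family Label, e.g. `"tetrahedral"` or `"polyhedral"`.
#' @return Object of class `"mesh_study_table"` (also a `data.frame`),
#'   sorted by increasing element size.
#' @export
mesh_study_table <- function(element_size_mm, element_count, v_max_mps,
                             wss_max_pa, runtime_min = NULL,
                             mesh_family = "unspecified") {
  n <- length(element_size_mm)
  if (n < 2L) stop("need at least 2 rows", call. = FALSE)
  stopifnot(length(element_count) == n, length(v_max_mps) == n,
            length(wss_max_pa) == n)
  if (any(element_size_mm <= 0)) stop("element sizes must be > 0", call. = FALSE)
  if (anyDuplicated(element_size_mm)) stop("element sizes must be unique",
                                           call. = FALSE)
  if (any(element_count <= 0)) stop("element counts must be > 0", call. = FALSE)
  if (any(v_max_mps < 0) || any(wss_max_pa < 0))
    stop("parameters of interest must be >= 0", call. = FALSE)
  df <- data.frame(element_size_mm = element_size_mm,
                   element_count = as.numeric(element_count),
                   v_max_mps = v_max_mps, wss_max_pa = wss_max_pa)
  if (!is.null(runtime_min)) {
    stopifnot(length(runtime_min) == n)
    df$runtime_min <- runtime_min
  }
  df <- df[order(df$element_size_mm), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "mesh_family") <- mesh_family
  class(df) <- c("mesh_study_table", "data.frame")
  df
}

#' @export
print.mesh_study_table <- function(x, ...) {
  cat(sprintf("Mesh study (%s family), %d resolutions\n",
              attr(x, "mesh_family"), nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

study_param <- function(table, parameter = c("v_max", "wss_max")) {
  parameter <- match.arg(parameter)
  table[[paste0(parameter, if (parameter == "v_max") "_mps" else "_pa")]]
}

#' Consecutive-mesh percentage differences
#'
#' For each row paired with its next-coarser neighbour, the relative change
#' of a parameter of interest, normalized by the larger of the two values:
#' \eqn{100\,|v_i - v_{i+1}| / \max(v_i, v_{i+1})}, rounded half away from
#' zero to an integer percent. This is the convention that reproduces the
#' printed percentage column of a standard mesh-independence table; the raw
#' unrounded values are returned alongside.
#'
#' @param table A [mesh_study_table()].
#' @param parameter `"v_max"` or `"wss_max"`.
#' @return `data.frame` with `element_size_mm` (all rows but the coarsest),
#'   `percent` (integer) and `percent_raw`.
#' @export
consecutive_percent_diff <- function(table, parameter = c("v_max", "wss_max")) {
  stopifnot(inherits(table, "mesh_study_table"))
  if (nrow(table) < 2L) stop("need at least 2 rows", call. = FALSE)
  v <- study_param(table, parameter)
  n <- length(v)
  fine <- v[-n]; coarse <- v[-1]
  raw <- 100 * abs(fine - coarse) / pmax(fine, coarse)
  data.frame(element_size_mm = table$element_size_mm[-n],
             percent = as.integer(round_half_away(raw)),
             percent_raw = raw)
}

#' Coarsest acceptable mesh for a parameter of interest
#'
#' Scans rows from coarsest to finest and returns the first element size
#' whose consecutive percentage difference (versus its next-coarser
#' neighbour, rounded integer percent) does not exceed the threshold — the
#' least-time-consuming mesh that has stopped moving the parameter.
#'
#' @param table A [mesh_study_table()].
#' @param parameter `"v_max"` or `"wss_max"`.
#' @param threshold_pct Acceptance threshold, percent. Default 3.
#' @return Element size in mm, or `NA` if no row qualifies.
#' @export
select_mesh <- function(table, parameter = c("v_max", "wss_max"),
                        threshold_pct = 3) {
  d <- consecutive_percent_diff(table, parameter)
  for (i in rev(seq_len(nrow(d)))) {       # coarsest-with-a-diff first
    if (d$percent[i] <= threshold_pct) return(d$element_size_mm[i])
  }
  NA_real_
}

#' Mesh acceptable for several parameters jointly
#'
#' The finest of the per-parameter selections — i.e. a size acceptable for
#' every parameter of interest; `NA` if any parameter has none.
#'
#' @param table A [mesh_study_table()].
#' @param parameters Character vector of parameters.
#' @param threshold_pct Acceptance threshold, percent.
#' @return Element size in mm, or `NA`.
#' @export
joint_selection <- function(table, parameters = c("v_max", "wss_max"),
                            threshold_pct = 3) {
  if (!length(parameters)) stop("need at least one parameter", call. = FALSE)
  sel <- vapply(parameters, function(p) select_mesh(table, p, threshold_pct),
                numeric(1))
  if (anyNA(sel)) return(NA_real_)
  min(sel)
}

#' Mesh-independence sensitivity report
#'
#' Full sensitivity analysis of a mesh family: consecutive percentage
#' differences for each parameter of interest and the selected
#' (coarsest-acceptable) element size per parameter and jointly.
#'
#' @param table A [mesh_study_table()].
#' @param parameters Parameters of interest. Default both.
#' @param threshold_pct Acceptance threshold, percent. Default 3.
#' @return Object of class `"mesh_sensitivity"` with fields `table`,
#'   `threshold_pct`, `diffs` (per parameter), `selected` (per parameter),
#'   `joint`.
#' @export
#' @examples
#' tab <- mesh_study_table(seq(0.2, 1, 0.2), c(7e6, 1.1e6, 5e5, 4e5, 3.7e5),
#'                         c(0.72, 0.7075, 0.6854, 0.6442, 0.5607),
#'                         c(21.82, 22.37, 23.04, 23.65, 26.74))
#' mesh_sensitivity(tab)
mesh_sensitivity <- function(table, parameters = c("v_max", "wss_max"),
                             threshold_pct = 3) {
  stopifnot(inherits(table, "mesh_study_table"))
  diffs <- lapply(parameters, function(p) consecutive_percent_diff(table, p))
  names(diffs) <- parameters
  selected <- vapply(parameters,
                     function(p) select_mesh(table, p, threshold_pct),
                     numeric(1))
  structure(list(table = table, threshold_pct = threshold_pct,
                 diffs = diffs, selected = selected,
                 joint = joint_selection(table, parameters, threshold_pct)),
            class = "mesh_sensitivity")
}

#' @export
print.mesh_sensitivity <- function(x, ...) {
  cat(sprintf("Mesh independence analysis (%s family), threshold %g%%\n",
              attr(x$table, "mesh_family"), x$threshold_pct))
  print.data.frame(as.data.frame(x), row.names = FALSE)
  for (p in names(x$diffs))
    cat(sprintf("  %s: selected %s mm\n", p,
                ifelse(is.na(x$selected[[p]]), "none",
                       format(x$selected[[p]]))))
  cat(sprintf("  joint: %s mm\n",
              ifelse(is.na(x$joint), "none", format(x$joint))))
  invisible(x)
}

#' Render a sensitivity report as a flat table
#'
#' Mesh-independence-table-shaped output: one row per resolution with the
#' parameters of interest and their integer consecutive percentage
#' differences (blank for the coarsest row), ready for CSV or JSON export.
#'
#' @param x A [mesh_sensitivity()] report.
#' @param ... Unused.
#' @return `data.frame`.
#' @export
as.data.frame.mesh_sensitivity <- function(x, ...) {
  df <- as.data.frame(unclass(x$table), stringsAsFactors = FALSE)
  for (p in names(x$diffs)) {
    col <- rep(NA_integer_, nrow(df))
    col[seq_len(nrow(df) - 1L)] <- x$diffs[[p]]$percent
    df[[paste0(p, "_pct")]] <- col
  }
  df
}

#' Serialize a sensitivity report to JSON
#'
#' @param x A [mesh_sensitivity()] report.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
sensitivity_report_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "mesh_sensitivity"))
  obj <- list(mesh_family = attr(x$table, "mesh_family"),
              threshold_pct = x$threshold_pct,
              rows = as.data.frame(x),
              selected = as.list(x$selected),
              joint = x$joint)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}
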