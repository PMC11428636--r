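## Plain-text file formats: CSV waveforms and mesh-study tables, VTK-XML
## PolyData (ASCII) for surfaces and per-cell fields, a CSV/JSON directory
## container for time-resolved flow solutions, and JSON reports. All writers
## embed units; numbers round-trip at full double precision.

fmt_full <- function(x) sprintf("%.17g", x)

#' Write a waveform to CSV
#'
#' Two-column CSV (`t_s`, value) with a `#`-prefixed metadata line carrying
#' units, period and location. Pressure waveforms use the column name
#' `p_mmHg`; generic series use `value`.
#'
#' @param w A [waveform_series()] or [pressure_waveform()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(w, path) {
  stopifnot(inherits(w, "waveform_series"))
  vcol <- if (inherits(w, "pressure_waveform")) "p_mmHg" else "value"
  meta <- sprintf("# units=%s period_T=%s location=%s", w$units,
                  fmt_full(w$period_T),
                  if (!is.null(w$location)) w$location else "unspecified")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines(paste0("t_s,", vcol), con)
  writeLines(paste(fmt_full(w$times), fmt_full(w$values), sep = ","), con)
  invisible(path)
}

#' Read a waveform from CSV
#'
#' Expects the layout of [write_waveform_csv()]: optional `#` metadata line,
#' a mandatory header (`t_s`, value column), then numeric rows. Parse
#' problems are reported with line numbers; decimal-comma locales are
#' rejected with an actionable message.
#'
#' @param path Input path.
#' @param period_T Period override, s; inferred from metadata (or the last
#'   sample time) when `NULL`.
#' @param location Location override.
#' @return A [pressure_waveform()] when the units are mmHg, otherwise a
#'   [waveform_series()].
#' @export
read_waveform_csv <- function(path, period_T = NULL, location = NULL) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  meta <- character(0)
  skip <- 0L
  while (skip < length(lines) && startsWith(lines[skip + 1L], "#")) {
    meta <- c(meta, lines[skip + 1L])
    skip <- skip + 1L
  }
  if (skip + 1L > length(lines) ||
      !grepl("^t_s\\s*,", lines[skip + 1L]))
    stop("missing header line 't_s,<value>' in ", path, call. = FALSE)
  header <- strsplit(lines[skip + 1L], ",")[[1]]
  body <- lines[-seq_len(skip + 1L)]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, ",")
  bad_cols <- which(lengths(parts) != 2L)
  if (length(bad_cols))
    stop("line ", bad_cols[1] + skip + 1L, ": expected 2 comma-separated ",
         "fields; if the file uses decimal commas, rewrite it with decimal ",
         "points and comma separators", call. = FALSE)
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 2,
              byrow = TRUE)
  bad <- which(rowSums(is.na(m)) > 0)
  if (length(bad))
    stop("line ", bad[1] + skip + 1L, ": non-numeric or NaN value",
         call. = FALSE)
  nonmono <- which(diff(m[, 1]) <= 0)
  if (length(nonmono))
    stop("line ", nonmono[1] + skip + 2L, ": times not strictly increasing",
         call. = FALSE)
  units <- sub(".*units=(\\S+).*", "\\1", meta[1])
  if (!length(meta) || identical(units, meta[1])) units <- ""
  Tmeta <- if (length(meta) && grepl("period_T=", meta[1]))
    as.numeric(sub(".*period_T=(\\S+).*", "\\1", meta[1])) else NA_real_
  loc <- if (length(meta) && grepl("location=", meta[1]))
    sub(".*location=(.*)$", "\\1", meta[1]) else "unspecified"
  T_ <- if (!is.null(period_T)) period_T else if (!is.na(Tmeta)) Tmeta else
    m[nrow(m), 1]
  if (!is.null(location)) loc <- location
  if (identical(units, "mmHg") || identical(header[2], "p_mmHg"))
    pressure_waveform(m[, 1], m[, 2], T_, location = loc)
  else waveform_series(m[, 1], m[, 2], T_, units = units)
}

#' Write a surface mesh (and per-cell fields) as VTK-XML PolyData
#'
#' ASCII `.vtp` file readable by standard visualization tools. Cell arrays
#' may be per-cell vectors (1 component) or `F x 3` matrices (3
#' components). Non-finite values must be encoded by the caller (see
#' [write_index_map()]).
#'
#' @param mesh A [surface_mesh()].
#' @param path Output path (`.vtp`).
#' @param cell_data Named list of per-cell arrays.
#' @param field_data Named list of scalar metadata values stored as field
#'   arrays.
#' @return `path`, invisibly.
#' @export
write_vtp <- function(mesh, path, cell_data = list(), field_data = list()) {
  stopifnot(inherits(mesh, "surface_mesh"))
  V <- nrow(mesh$vertices); F_ <- nrow(mesh$triangles)
  da <- function(parent, name, values, ncomp, type = "Float64") {
    node <- xml2::xml_add_child(parent, "DataArray", type = type,
                                Name = name, format = "ascii",
                                NumberOfComponents = as.character(ncomp))
    txt <- if (type == "Float64") paste(fmt_full(values), collapse = " ")
    else paste(format(values, scientific = FALSE, trim = TRUE), collapse = " ")
    xml2::xml_text(node) <- txt
    node
  }
  doc <- xml2::xml_new_root("VTKFile", type = "PolyData", version = "1.0",
                            byte_order = "LittleEndian")
  pd <- xml2::xml_add_child(doc, "PolyData")
  piece <- xml2::xml_add_child(pd, "Piece",
                               NumberOfPoints = as.character(V),
                               NumberOfVerts = "0", NumberOfLines = "0",
                               NumberOfStrips = "0",
                               NumberOfPolys = as.character(F_))
  pts <- xml2::xml_add_child(piece, "Points")
  da(pts, "Points", as.vector(t(mesh$vertices)), 3)
  polys <- xml2::xml_add_child(piece, "Polys")
  da(polys, "connectivity", as.vector(t(mesh$triangles)) - 1L, 1, "Int64")
  da(polys, "offsets", seq_len(F_) * 3L, 1, "Int64")
  if (length(cell_data)) {
    cd <- xml2::xml_add_child(piece, "CellData")
    for (nm in names(cell_data)) {
      v <- cell_data[[nm]]
      if (is.matrix(v)) {
        stopifnot(nrow(v) == F_, ncol(v) == 3L)
        da(cd, nm, as.vector(t(v)), 3)
      } else {
        stopifnot(length(v) == F_)
        da(cd, nm, as.numeric(v), 1)
      }
    }
  }
  if (length(field_data)) {
    fd <- xml2::xml_add_child(pd, "FieldData")
    for (nm in names(field_data))
      da(fd, nm, as.numeric(field_data[[nm]]), 1)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a VTK-XML PolyData file
#'
#' Counterpart of [write_vtp()] (ASCII format only).
#'
#' @param path A `.vtp` path.
#' @return List with `mesh` (a [surface_mesh()]), `cell_data` (named list)
#'   and `field_data`.
#' @export
read_vtp <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  if (is.na(xml2::xml_name(piece))) stop("no <Piece> in ", path, call. = FALSE)
  get_num <- function(node) as.numeric(strsplit(trimws(xml2::xml_text(node)),
                                                "\\s+")[[1]])
  pts_node <- xml2::xml_find_first(piece, "./Points/DataArray")
  verts <- matrix(get_num(pts_node), ncol = 3, byrow = TRUE)
  conn <- get_num(xml2::xml_find_first(piece,
                                       "./Polys/DataArray[@Name='connectivity']"))
  tris <- matrix(as.integer(conn), ncol = 3, byrow = TRUE) + 1L
  cd_nodes <- xml2::xml_find_all(piece, "./CellData/DataArray")
  cell_data <- list()
  for (nd in cd_nodes) {
    nm <- xml2::xml_attr(nd, "Name")
    ncomp <- as.integer(xml2::xml_attr(nd, "NumberOfComponents"))
    v <- get_num(nd)
    cell_data[[nm]] <- if (!is.na(ncomp) && ncomp == 3L)
      matrix(v, ncol = 3, byrow = TRUE) else v
  }
  fd_nodes <- xml2::xml_find_all(doc, ".//FieldData/DataArray")
  field_data <- list()
  for (nd in fd_nodes)
    field_data[[xml2::xml_attr(nd, "Name")]] <- get_num(nd)
  list(mesh = surface_mesh(verts, tris), cell_data = cell_data,
       field_data = field_data)
}

#' Write a WSS series as a VTK-XML time series with JSON manifest
#'
#' One `.vtp` per time step carrying a 3-component cell array `"WSS"`, plus
#' a manifest `<basename>_series.json` recording the period, times and
#' files.
#'
#' @param series A [wss_series()].
#' @param dir Output directory (created if needed).
#' @param basename File stem. Default `"wss"`.
#' @return Manifest path, invisibly.
#' @export
write_wss_series <- function(series, dir, basename = "wss") {
  stopifnot(inherits(series, "wss_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nt <- length(series$times)
  files <- sprintf("%s_%04d.vtp", basename, seq_len(nt) - 1L)
  for (j in seq_len(nt)) {
    wssj <- cbind(series$wss[j, , 1], series$wss[j, , 2], series$wss[j, , 3])
    write_vtp(series$mesh, file.path(dir, files[j]),
              cell_data = list(WSS = wssj))
  }
  manifest <- file.path(dir, paste0(basename, "_series.json"))
  # times as %.17g strings: JSON numeric printing is not ulp-exact
  jsonlite::write_json(list(period_T = fmt_full(series$period_T),
                            times = fmt_full(series$times), files = files),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a WSS series from a VTK-XML time series manifest
#'
#' @param manifest Path to the `*_series.json` manifest of
#'   [write_wss_series()].
#' @return A [wss_series()].
#' @export
read_wss_series <- function(manifest) {
  man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  man$times <- as.numeric(man$times)
  man$period_T <- as.numeric(man$period_T)
  dir <- dirname(manifest)
  nt <- length(man$files)
  if (nt != length(man$times)) stop("manifest times/files mismatch",
                                    call. = FALSE)
  mesh <- NULL
  wss <- NULL
  for (j in seq_len(nt)) {
    v <- read_vtp(file.path(dir, man$files[j]))
    if (is.null(v$cell_data$WSS))
      stop("step ", j, " (", man$files[j], "): missing cell array 'WSS'",
           call. = FALSE)
    wj <- v$cell_data$WSS
    if (!is.matrix(wj) || ncol(wj) != 3L)
      stop("step ", j, " (", man$files[j], "): 'WSS' must have 3 components",
           call. = FALSE)
    if (is.null(mesh)) {
      mesh <- v$mesh
      wss <- array(0, dim = c(nt, nrow(wj), 3))
    } else if (nrow(wj) != dim(wss)[2]) {
      stop("step ", j, " (", man$files[j], "): inconsistent cell count",
           call. = FALSE)
    }
    wss[j, , ] <- wj
  }
  wss_series(mesh, man$times, wss, man$period_T)
}

#' Write a wall-index map to VTK-XML, CSV and JSON
#'
#' Emits `<prefix>.vtp` with cell arrays `TAWSS`, `OSI`, `RRT`, `ECAP` plus
#' threshold masks, `<prefix>.csv` (cell id, area, indices) and
#' `<prefix>.json` (threshold area fractions and sentinel counts). Infinite
#' RRT/ECAP values are encoded in the VTK file as the finite sentinel 1e30
#' with companion mask arrays `RRT_singular` / `ECAP_singular`, because
#' XML readers handle literal infinities inconsistently.
#'
#' @param map A [wall_indices()].
#' @param prefix Output path prefix (no extension).
#' @param high_tawss High-shear threshold, Pa. Default 5.
#' @param low_tawss Proatherogenic low-shear threshold, Pa. Default 0.4.
#' @return Named vector of written paths, invisibly.
#' @export
write_index_map <- function(map, prefix, high_tawss = 5, low_tawss = 0.4) {
  stopifnot(inherits(map, "wall_index_map"))
  if (!length(map$tawss)) stop("empty index map", call. = FALSE)
  enc <- function(v) ifelse(is.finite(v), v, 1e30)
  hi <- threshold_area(map, "tawss", high_tawss, "above")
  lo <- threshold_area(map, "tawss", low_tawss, "below")
  vtp <- paste0(prefix, ".vtp")
  write_vtp(map$mesh, vtp,
            cell_data = list(
              TAWSS = map$tawss, OSI = map$osi,
              RRT = enc(map$rrt), ECAP = enc(map$ecap),
              RRT_singular = as.numeric(!is.finite(map$rrt)),
              ECAP_singular = as.numeric(!is.finite(map$ecap)),
              TAWSS_above_high = as.numeric(hi$cell_mask),
              TAWSS_below_low = as.numeric(lo$cell_mask)))
  csv <- paste0(prefix, ".csv")
  df <- data.frame(cell_id = seq_along(map$tawss),
                   area_m2 = map$mesh$cell_areas,
                   tawss_pa = map$tawss, osi = map$osi,
                   rrt_per_pa = map$rrt, ecap_per_pa = map$ecap)
  utils::write.csv(df, csv, row.names = FALSE)
  js <- paste0(prefix, ".json")
  jsonlite::write_json(list(
    n_cells = length(map$tawss),
    total_area_m2 = sum(map$mesh$cell_areas),
    thresholds = list(high_tawss_pa = high_tawss, low_tawss_pa = low_tawss),
    area_fraction_tawss_above_high = hi$fraction,
    area_fraction_tawss_below_low = lo$fraction,
    sentinel_counts = map$counts), js, auto_unbox = TRUE, digits = NA)
  invisible(c(vtp = vtp, csv = csv, json = js))
}

#' Read a wall-index map written by [write_index_map()]
#'
#' Decodes the 1e30 sentinels back to `+Inf` using the mask arrays.
#'
#' @param prefix The path prefix used when writing.
#' @return A [wall_indices()].
#' @export
read_index_map <- function(prefix) {
  v <- read_vtp(paste0(prefix, ".vtp"))
  cd <- v$cell_data
  dec <- function(vals, mask) ifelse(mask > 0, Inf, vals)
  rrt <- dec(cd$RRT, cd$RRT_singular)
  ecap <- dec(cd$ECAP, cd$ECAP_singular)
  structure(list(mesh = v$mesh, tawss = cd$TAWSS, osi = cd$OSI,
                 rrt = rrt, ecap = ecap,
                 counts = list(degenerate_cells = sum(cd$TAWSS == 0),
                               rrt_sentinels = sum(cd$RRT_singular > 0),
                               ecap_sentinels = sum(cd$ECAP_singular > 0))),
            class = "wall_index_map")
}

#' Write/read a mesh-study table as CSV
#'
#' Header: `element_size_mm, element_count, v_max_mps, wss_max_pa[,
#' runtime_min]`.
#'
#' @param table A [mesh_study_table()].
#' @param path CSV path.
#' @return `path` invisibly / the table.
#' @export
write_mesh_study_csv <- function(table, path) {
  stopifnot(inherits(table, "mesh_study_table"))
  utils::write.csv(as.data.frame(unclass(table)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mesh_study_csv
#' @param mesh_family Family label applied on read.
#' @export
read_mesh_study_csv <- function(path, mesh_family = "unspecified") {
  df <- utils::read.csv(path)
  need <- c("element_size_mm", "element_count", "v_max_mps", "wss_max_pa")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "),
         call. = FALSE)
  mesh_study_table(df$element_size_mm, df$element_count, df$v_max_mps,
                   df$wss_max_pa, runtime_min = df$runtime_min,
                   mesh_family = mesh_family)
}

#' Persist a flow solution as a plain-text container
#'
#' Directory holding CSV matrices (`times`, `radii`, `u`, `tau_wall`, `Q`,
#' `dpdx`) and a JSON metadata file with the rheological parameters and
#' solver settings.
#'
#' @param sol A `"flow_solution"`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_flow_solution <- function(sol, dir) {
  stopifnot(inherits(sol, "flow_solution"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wv <- function(x, f) writeLines(fmt_full(x), file.path(dir, f))
  wv(sol$times, "times.csv"); wv(sol$grid$radii, "radii.csv")
  wv(sol$tau_wall, "tau_wall.csv"); wv(sol$tau_wall_signed, "tau_wall_signed.csv")
  wv(sol$Q, "Q.csv"); wv(sol$dpdx, "dpdx.csv")
  utils::write.table(sol$u, file.path(dir, "u.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(
    params = unclass(sol$params), dt = sol$dt, period_T = sol$period_T,
    n_cycles_run = sol$n_cycles_run, converged = sol$converged,
    cycle_diffs = sol$cycle_diffs,
    layer_spec = sol$grid$layer_spec, R = sol$grid$R,
    units = list(u = "m/s", tau_wall = "Pa", Q = "m3/s", dpdx = "Pa/m",
                 radii = "m", times = "s")),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_flow_solution
#' @export
read_flow_solution <- function(dir) {
  rd <- function(f) as.numeric(readLines(file.path(dir, f)))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  radii <- rd("radii.csv")
  grid <- structure(list(radii = radii, R = meta$R, n_nodes = length(radii),
                         layer_spec = as.list(meta$layer_spec)),
                    class = "radial_grid")
  params <- do.call(carreau_params, meta$params)
  u <- as.matrix(utils::read.csv(file.path(dir, "u.csv"), header = FALSE))
  dimnames(u) <- NULL
  structure(list(grid = grid, times = rd("times.csv"), u = u,
                 tau_wall = rd("tau_wall.csv"),
                 tau_wall_signed = rd("tau_wall_signed.csv"),
                 Q = rd("Q.csv"), dpdx = rd("dpdx.csv"), params = params,
                 dt = meta$dt, period_T = meta$period_T,
                 n_cycles_run = meta$n_cycles_run,
                 converged = meta$converged,
                 cycle_diffs = as.numeric(meta$cycle_diffs),
                 picard_max_iters = NA_integer_),
            class = "flow_solution")
}
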