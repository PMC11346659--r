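#' Write a grid as an ESRI ASCII raster
#'
#' Canonical plain-text raster dialect: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by the grid
#' rows, first data line = northernmost row (matrix row 1).
#'
#' @param mat numeric or integer matrix (row 1 = north).
#' @param file output path.
#' @param cellsize cell edge length (m).
#' @param xll,yll lower-left corner coordinates.
#' @param nodata NODATA sentinel written for `NA` cells.
#' @return `file`, invisibly.
#' @export
write_ascii_grid <- function(mat, file, cellsize = 4, xll = 0, yll = 0,
                             nodata = -9999) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(mat)),
               paste("nrows", nrow(mat)),
               paste("xllcorner", xll),
               paste("yllcorner", yll),
               paste("cellsize", cellsize),
               paste("NODATA_value", nodata)), con)
  m <- mat
  m[is.na(m)] <- nodata
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' Read an ESRI ASCII raster
#'
#' @param file path to a raster written in the ESRI ASCII dialect.
#' @return matrix with attributes `cellsize`, `xllcorner`, `yllcorner`;
#'   NODATA cells become `NA`.
#' @export
read_ascii_grid <- function(file) {
  hdr <- readLines(file, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, character(1), 1))
  vals <- as.numeric(vapply(kv, `[`, character(1), 2))
  names(vals) <- keys
  stopifnot(all(c("ncols", "nrows", "cellsize") %in% keys))
  dat <- utils::read.table(file, skip = 6)
  m <- as.matrix(dat)
  dimnames(m) <- NULL
  stopifnot(nrow(m) == vals["nrows"], ncol(m) == vals["ncols"])
  if ("nodata_value" %in% keys) m[m == vals["nodata_value"]] <- NA
  attr(m, "cellsize") <- unname(vals["cellsize"])
  attr(m, "xllcorner") <- unname(vals["xllcorner"])
  attr(m, "yllcorner") <- unname(vals["yllcorner"])
  m
}

#' Write an island state as a set of rasters
#'
#' Writes `H.asc` (slab counts) and `P1.asc` ... `P4.asc` (covers) into a
#' directory, plus a small `state.yml` with the scalar fields.
#'
#' @param state an `island_state`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_state <- function(state, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  L <- state$grid$L
  write_ascii_grid(state$H, file.path(dir, "H.asc"), cellsize = L)
  for (k in 1:4)
    write_ascii_grid(state$P[[k]], file.path(dir, paste0("P", k, ".asc")),
                     cellsize = L)
  yaml::write_yaml(list(delta = state$grid$delta, L = L,
                        sea_level_offset = state$sea_level_offset,
                        t = state$t),
                   file.path(dir, "state.yml"))
  invisible(dir)
}

#' Read an island state written by [write_state()]
#'
#' @param dir directory holding `H.asc`, `P1.asc`..`P4.asc`, `state.yml`.
#' @return an `island_state`.
#' @export
read_state <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "state.yml"))
  H <- read_ascii_grid(file.path(dir, "H.asc"))
  g <- grid_spec(nrow(H), ncol(H), L = meta$L, delta = meta$delta)
  P <- lapply(1:4, function(k) {
    m <- read_ascii_grid(file.path(dir, paste0("P", k, ".asc")))
    attributes(m) <- list(dim = dim(m))
    m
  })
  attributes(H) <- list(dim = dim(H))
  storage.mode(H) <- "integer"
  island_state(g, H = H, P = P,
               sea_level_offset = meta$sea_level_offset, t = meta$t)
}

#' Read a wind table
#'
#' Delimited text with columns `speed_mps` (or `speed`) and `direction`
#' (compass labels) or `direction_deg8` (degrees snapped to the eight points,
#' 0 = N, 45 = NE, ...). Extra columns such as `timestamp` are ignored.
#'
#' @param file path to the table (whitespace- or comma-delimited, header
#'   required).
#' @return data frame with columns `speed` and `direction` usable as a
#'   [simulation_config()] wind source.
#' @export
read_wind_table <- function(file) {
  first <- readLines(file, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  d <- utils::read.table(file, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  speed <- if ("speed_mps" %in% names(d)) d$speed_mps else d$speed
  if (is.null(speed)) stop("wind table needs a speed_mps or speed column")
  if ("direction_deg8" %in% names(d)) {
    idx <- (round(d$direction_deg8 / 45) %% 8) + 1
    direction <- COMPASS[idx]
  } else if ("direction" %in% names(d)) {
    direction <- toupper(d$direction)
  } else stop("wind table needs a direction or direction_deg8 column")
  stopifnot(all(direction %in% COMPASS), all(speed >= 0))
  data.frame(speed = speed, direction = direction, stringsAsFactors = FALSE)
}

#' Write a wind table
#'
#' @param wind data frame with columns `speed` and `direction`.
#' @param file output path (comma-delimited, with a `timestamp` step index).
#' @return `file`, invisibly.
#' @export
write_wind_table <- function(wind, file) {
  utils::write.csv(data.frame(timestamp = seq_len(nrow(wind)),
                              speed_mps = wind$speed,
                              direction = wind$direction),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a simulation configuration from YAML
#'
#' Keys mirror [simulation_config()] argument names; `scenario` may be a name
#' or a mapping with `a`, `b`, `c`; `species` entries override fields of the
#' default set by position. Unknown keys are rejected.
#'
#' @param file path to a YAML config.
#' @return a [simulation_config()].
#' @export
read_config <- function(file) {
  raw <- yaml::read_yaml(file)
  args <- list()
  known <- setdiff(names(formals(simulation_config)), c("wind", "repose"))
  bad <- setdiff(names(raw), c(known, "wind", "repose", "theta_o", "max_passes"))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$scenario)) {
    args$scenario <- if (is.character(raw$scenario)) slr_scenario(raw$scenario)
    else do.call(slr_scenario, c(list(name = "custom"), raw$scenario))
  }
  if (!is.null(raw$species)) {
    sp <- default_species()
    for (k in seq_along(raw$species))
      sp[[k]] <- do.call(species_params, utils::modifyList(
        unclass(sp[[k]]), raw$species[[k]]))
    args$species <- sp
  }
  if (!is.null(raw$wind)) {
    args$wind <- if (is.character(raw$wind)) read_wind_table(raw$wind)
    else do.call(wind_climate, raw$wind)
  }
  if (!is.null(raw$theta_o) || !is.null(raw$max_passes)) {
    args$repose <- repose_params(
      theta_o = if (is.null(raw$theta_o)) pi / 6 else raw$theta_o,
      max_passes = if (is.null(raw$max_passes)) 100L else raw$max_passes)
  }
  scalars <- intersect(names(raw), setdiff(known, c("scenario", "species")))
  args[scalars] <- raw[scalars]
  do.call(simulation_config, args)
}
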