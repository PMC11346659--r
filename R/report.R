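#' Ocean-side shoreline position per transect
#'
#' For each alongshore row (transect), the easting of the easternmost
#' subaerial cell times the cell size; rows with no subaerial cells are `NA`
#' and are excluded from regression averages.
#'
#' @param state an `island_state`.
#' @param rows rows to evaluate (default all).
#' @return numeric vector of positions in meters (`NA` where absent).
#' @export
shoreline_position <- function(state, rows = NULL) {
  sub <- subaerial_mask(state)
  if (is.null(rows)) rows <- seq_len(nrow(sub))
  vapply(rows, function(i) {
    w <- which(sub[i, ])
    if (length(w)) max(w) * state$grid$L else NA_real_
  }, numeric(1))
}

#' Split transects into upper and lower island halves
#'
#' The northernmost and southernmost rows containing subaerial cells are the
#' island tips; the midpoint row between them divides the halves, with the
#' midpoint itself assigned to the upper half.
#'
#' @param state an `island_state`.
#' @return `list(upper = row indices, lower = row indices)`.
#' @export
split_rows <- function(state) {
  present <- which(rowSums(subaerial_mask(state)) > 0)
  if (!length(present)) stop("empty island: no subaerial cells")
  first <- min(present); last <- max(present)
  mid <- (first + last) %/% 2L
  list(upper = first:mid,
       lower = if (mid < last) (mid + 1L):last else integer(0))
}

#' Mean annual shoreline regression
#'
#' Average over the included transects of
#' `(position(t0) - position(t1)) / (t1 - t0)`; westward (landward) movement
#' is positive. Only transects subaerial at both epochs enter the average.
#'
#' @param pos0,pos1 per-row shoreline positions (m) at `t0` and `t1`.
#' @param t0,t1 epoch years, `t1 > t0`.
#' @param rows optional subset of rows to average over.
#' @return mean regression rate in m/yr.
#' @export
mean_annual_regression <- function(pos0, pos1, t0, t1, rows = NULL) {
  stopifnot(t1 > t0)
  if (!is.null(rows)) { pos0 <- pos0[rows]; pos1 <- pos1[rows] }
  ok <- is.finite(pos0) & is.finite(pos1)
  if (!any(ok)) stop("no transects subaerial at both epochs")
  mean((pos0[ok] - pos1[ok]) / (t1 - t0))
}

#' Shoreline regression report
#'
#' Summarises a matrix of per-transect shoreline positions over time into
#' mean annual regression rates for the whole island and the upper and lower
#' halves, over the full span and its two halves (the 0-15 / 15-30 year
#' reporting grid for a 30-year run).
#'
#' @param positions matrix, rows = transects, columns = recorded years.
#' @param years the recorded calendar years (column labels).
#' @param split a [split_rows()] result fixing the half assignment.
#' @param grid_L cell size in meters (cosmetic, kept for printing).
#' @return an object of class `migration_report`: a data frame with columns
#'   `rows` (All / Upper / Lower), `from`, `to`, and `regression_m_per_yr`.
#' @export
migration_report <- function(positions, years, split, grid_L = 4) {
  stopifnot(ncol(positions) == length(years))
  t0 <- years[1]; t1 <- years[length(years)]
  epochs <- list(c(t0, t1))
  if (length(years) > 2) {
    mid <- years[which.min(abs(years - (t0 + t1) / 2))]
    if (mid > t0 && mid < t1) epochs <- list(c(t0, mid), c(mid, t1), c(t0, t1))
  }
  subsets <- list(All = NULL, Upper = split$upper, Lower = split$lower)
  out <- do.call(rbind, lapply(names(subsets), function(lab) {
    do.call(rbind, lapply(epochs, function(ep) {
      p0 <- positions[, match(ep[1], years)]
      p1 <- positions[, match(ep[2], years)]
      r <- tryCatch(
        mean_annual_regression(p0, p1, ep[1], ep[2], subsets[[lab]]),
        error = function(e) NA_real_)
      data.frame(rows = lab, from = ep[1], to = ep[2],
                 regression_m_per_yr = r)
    }))
  }))
  structure(out, class = c("migration_report", "data.frame"), grid_L = grid_L)
}

#' @export
print.migration_report <- function(x, ...) {
  cat("Mean annual shoreline regression (m/yr, westward positive)\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Export shoreline contours from snapshots
#'
#' Extracts iso-elevation polylines (default the 0-m shoreline) from each
#' snapshot's effective-elevation surface. Coordinates are in meters:
#' `x` is the cross-shore easting, `y` the alongshore northing (row 1 is the
#' northern edge). Optionally writes the vertices as a delimited file and
#' overlays the outlines on the current graphics device.
#'
#' @param snapshots named list of `island_state` objects (names = years).
#' @param levels contour elevations in meters; the default (`NULL`) traces the
#'   shoreline at half a slab thickness, which separates land from water
#'   without degenerating on cells at exactly sea level.
#' @param file optional path for a CSV of vertices.
#' @param plot draw an overlay figure.
#' @return data frame with columns `snapshot`, `level`, `line`, `x`, `y`
#'   (invisibly when `file` or `plot` is used).
#' @export
export_contours <- function(snapshots, levels = NULL, file = NULL,
                            plot = FALSE) {
  if (is.null(levels) && length(snapshots))
    levels <- snapshots[[1]]$grid$delta / 2
  out <- data.frame(snapshot = character(), level = numeric(),
                    line = integer(), x = numeric(), y = numeric())
  for (nm in names(snapshots)) {
    st <- snapshots[[nm]]
    g <- st$grid
    ee <- effective_elevation(st)
    if (all(ee <= min(levels))) next
    xs <- (seq_len(g$n_rows) - 0.5) * g$L         # along rows, southward
    ys <- (seq_len(g$n_cols) - 0.5) * g$L         # along cols, eastward
    cl <- grDevices::contourLines(xs, ys, ee, levels = levels)
    for (li in seq_along(cl)) {
      northing <- g$n_rows * g$L - cl[[li]]$x
      out <- rbind(out, data.frame(snapshot = nm, level = cl[[li]]$level,
                                   line = li, x = cl[[li]]$y, y = northing))
    }
  }
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  if (plot && nrow(out)) {
    cols <- grDevices::hcl.colors(max(length(snapshots), 2), "Zissou 1")
    graphics::plot(NA, xlim = range(out$x), ylim = range(out$y),
                   xlab = "easting (m)", ylab = "northing (m)", asp = 1,
                   main = "shoreline contours")
    for (si in seq_along(names(snapshots))) {
      d <- out[out$snapshot == names(snapshots)[si], ]
      for (li in unique(d$line))
        graphics::lines(d$x[d$line == li], d$y[d$line == li], col = cols[si])
    }
    graphics::legend("topright", legend = names(snapshots),
                     col = cols[seq_along(snapshots)], lty = 1, bty = "n")
  }
  if (is.null(file) && !plot) out else invisible(out)
}
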