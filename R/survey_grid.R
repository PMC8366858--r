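# Transect gridding: divide each flown transect into fixed-length strip
# cells and aggregate flock sightings into per-cell, per-year counts.

#' Segment a transect into grid cells
#'
#' Divides the along-track extent `[0, L)` of a transect into consecutive
#' half-open intervals of `cell_length_m` (nominally 1,000 m cells spanning a
#' 550 m strip, 275 m each side of the line, which includes a 25 m GPS-error
#' allowance beyond the 250 m observation band). A trailing remainder shorter
#' than a full cell is kept as a flagged partial cell by default; it can also
#' be dropped or merged into the last full cell.
#'
#' @param tr a [transect()] whose `path` is in projected meters.
#' @param cell_length_m nominal along-track cell length (m), default 1000.
#' @param half_width_m strip half-width (m), default 275.
#' @param partial policy for the trailing remainder: `"keep"` (default,
#'   flagged partial), `"drop"`, or `"merge"` into the last full cell.
#' @return data.frame with one row per cell: `cell_id, transect_id, year,
#'   along_start_m, along_end_m, length_m, half_width_m, center_x, center_y,
#'   partial, count` (count initialised to 0).
#' @export
segment_transect <- function(tr, cell_length_m = 1000, half_width_m = 275,
                             partial = c("keep", "drop", "merge")) {
  partial <- match.arg(partial)
  stopifnot(inherits(tr, "transect"), cell_length_m > 0, half_width_m > 0)
  L <- path_length(tr$path)
  if (L <= 0)
    stop("transect '", tr$transect_id, "': zero-length path, cannot segment")
  n_full <- floor(L / cell_length_m)
  rem <- L - n_full * cell_length_m
  has_rem <- rem > 1e-6
  starts <- seq(0, by = cell_length_m, length.out = n_full)
  ends <- starts + cell_length_m
  flags <- rep(FALSE, n_full)
  if (has_rem) {
    if (partial == "keep") {
      starts <- c(starts, n_full * cell_length_m)
      ends <- c(ends, L)
      flags <- c(flags, TRUE)
    } else if (partial == "merge") {
      if (n_full == 0) {
        starts <- 0; ends <- L; flags <- TRUE
      } else {
        ends[n_full] <- L
      }
    }  # "drop": nothing to add
  }
  if (length(starts) == 0)
    stop("transect '", tr$transect_id, "': shorter than one cell and partial = 'drop'")
  centers <- path_point_at(tr$path, (starts + ends) / 2)
  data.frame(
    cell_id = sprintf("%s_%d_%03d", tr$transect_id, tr$year, seq_along(starts)),
    transect_id = tr$transect_id,
    year = tr$year,
    along_start_m = starts,
    along_end_m = ends,
    length_m = ends - starts,
    half_width_m = half_width_m,
    center_x = centers[, 1],
    center_y = centers[, 2],
    partial = flags,
    count = 0L,
    stringsAsFactors = FALSE
  )
}

#' Segment a list of transects
#'
#' @param transects list of [transect()] objects (projected paths).
#' @inheritParams segment_transect
#' @return Row-bound cell table over all transects.
#' @export
segment_transects <- function(transects, cell_length_m = 1000,
                              half_width_m = 275,
                              partial = c("keep", "drop", "merge")) {
  partial <- match.arg(partial)
  do.call(rbind, lapply(transects, segment_transect,
                        cell_length_m = cell_length_m,
                        half_width_m = half_width_m, partial = partial))
}

#' Assign sightings to grid cells
#'
#' Projects each sighting of the target species onto its transect line and
#' maps the along-track position to a cell using the half-open interval
#' convention (a sighting exactly on an interior boundary belongs to the
#' later cell). Sightings farther than the strip half-width from the line, or
#' at/past the transect end, are dropped and counted. Cell counts are the
#' sums of assigned group sizes.
#'
#' @param sightings data.frame with columns `transect_id, year, x, y,
#'   species, count` (`x`, `y` projected meters).
#' @param cells cell table from [segment_transects()].
#' @param transects the same projected transects used to build `cells`.
#' @param species code of the species entering the analysis (default
#'   `"BLSC"`, Black Scoter); other species are ignored.
#' @return `cells` with `count` populated; attribute `dropped` holds the
#'   number of target-species sightings outside the surveyed strip.
#' @export
assign_sightings <- function(sightings, cells, transects, species = "BLSC") {
  stopifnot(all(c("transect_id", "year", "x", "y", "species", "count") %in%
                  names(sightings)))
  if (any(sightings$count < 0)) stop("negative group size in sightings")
  sightings <- sightings[sightings$species == species, , drop = FALSE]
  cells$count <- 0L
  dropped <- 0L
  key <- function(id, yr) paste(id, yr, sep = "\r")
  tr_map <- stats::setNames(transects,
                            vapply(transects, function(t) key(t$transect_id, t$year), ""))
  for (k in unique(key(sightings$transect_id, sightings$year))) {
    sub <- sightings[key(sightings$transect_id, sightings$year) == k, , drop = FALSE]
    tr <- tr_map[[k]]
    if (is.null(tr)) {
      dropped <- dropped + nrow(sub)
      next
    }
    ci <- which(cells$transect_id == tr$transect_id & cells$year == tr$year)
    csub <- cells[ci, , drop = FALSE]
    ord <- order(csub$along_start_m)
    csub <- csub[ord, , drop = FALSE]
    pr <- project_onto_path(cbind(sub$x, sub$y), tr$path)
    hw <- csub$half_width_m[1]
    last_end <- max(csub$along_end_m)
    ok <- pr$offset <= hw & pr$along_raw >= 0 & pr$along_raw < last_end &
      pr$along < last_end
    dropped <- dropped + sum(!ok)
    if (!any(ok)) next
    idx <- findInterval(pr$along[ok], csub$along_start_m)
    # a position inside a dropped trailing remainder falls past the last end
    in_cell <- pr$along[ok] < csub$along_end_m[idx]
    dropped <- dropped + sum(!in_cell)
    add <- tapply(sub$count[ok][in_cell], idx[in_cell], sum)
    csub$count[as.integer(names(add))] <- csub$count[as.integer(names(add))] +
      as.integer(add)
    cells$count[ci[ord]] <- csub$count
  }
  if (dropped > 0)
    message(dropped, " sighting(s) outside the surveyed strip were dropped")
  attr(cells, "dropped") <- dropped
  cells
}

#' Summarize per-cell counts
#'
#' Reports the cell total, the number of occupied cells, and count summary
#' statistics. Quantiles are lower-nearest order statistics (type 1), so all
#' reported quantiles of an integer count vector are integers.
#'
#' @param cells cell table with `count` populated.
#' @return A list of class `count_summary`: `n_cells`, `n_occupied`, `mean`,
#'   `median`, `q025`, `q50`, `q975`, `max`.
#' @export
summarize_counts <- function(cells) {
  if (NROW(cells) == 0) stop("empty cell table")
  y <- cells$count
  if (any(is.na(y))) stop("cell counts contain NA; assign sightings first")
  q <- stats::quantile(y, c(0.025, 0.5, 0.975), type = 1, names = FALSE)
  structure(list(n_cells = length(y),
                 n_occupied = sum(y > 0),
                 mean = mean(y),
                 median = stats::median(y),
                 q025 = q[1], q50 = q[2], q975 = q[3],
                 max = max(y)),
            class = "count_summary")
}

#' @export
print.count_summary <- function(x, ...) {
  cat("Grid-cell count summary\n")
  cat(sprintf("  cells sampled : %d\n", x$n_cells))
  cat(sprintf("  occupied      : %d (%.1f%%)\n", x$n_occupied,
              100 * x$n_occupied / x$n_cells))
  cat(sprintf("  mean          : %.2f\n", x$mean))
  cat(sprintf("  quantiles     : 2.5%% = %g, 50%% = %g, 97.5%% = %g\n",
              x$q025, x$q50, x$q975))
  cat(sprintf("  max           : %g\n", x$max))
  invisible(x)
}
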