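#' Integrated density of a cell's fluorescence signal
#'
#' Total signal of a cell in one frame: mean per-pixel intensity times the
#' number of pixels of the cell mask. Additive over disjoint pixel sets, so
#' it is conserved when a cell splits.
#'
#' @param mean_fluor mean intensity, AU per pixel.
#' @param pixel_count number of pixels (> 0).
#' @return integrated density in AU (vectorized).
#' @export
integrated_density <- function(mean_fluor, pixel_count) {
  if (any(is.na(mean_fluor)) || any(is.na(pixel_count))) {
    poleage_error("poleage_measurement_error",
                  "mean_fluor and pixel_count must both be present")
  }
  if (any(pixel_count <= 0)) {
    poleage_error("poleage_measurement_error", "pixel_count must be positive")
  }
  mean_fluor * pixel_count
}

#' Cylinder-approximation concentration
#'
#' Converts a cell's integrated density to a concentration by approximating
#' the cell volume as a cylinder whose height is the cell length and whose
#' diameter is the (microfluidic channel) width.
#'
#' @param integrated integrated density, AU.
#' @param length_um cell length in micrometers (> 0).
#' @param channel_width_um cylinder diameter; default 1.2 um.
#' @return concentration in AU per cubic micrometer (vectorized).
#' @examples
#' concentration(1000, 4)  # ~221.05 AU/um^3
#' @export
concentration <- function(integrated, length_um, channel_width_um = 1.2) {
  if (any(length_um <= 0)) {
    poleage_error("poleage_domain_error", "cell length must be positive")
  }
  integrated / (pi * (channel_width_um / 2)^2 * length_um)
}

#' Quarter-cell shares of a long-axis intensity profile
#'
#' Splits a per-column intensity profile (ordered old pole to new pole) into
#' four segments of equal length. When the number of columns is not divisible
#' by four, the remainder columns are assigned by the largest-remainder rule,
#' ties broken toward the old pole (the first quarters get the extra column).
#' Each segment's summed intensity is divided by the profile total, so the
#' four shares sum to one.
#'
#' @param profile numeric vector of per-column summed intensities (length >= 4).
#' @param orientation_known must be `TRUE`; profiles of unknown polarity
#'   cannot be quartered meaningfully.
#' @return numeric vector of 4 relative intensities, old pole first.
#' @examples
#' quarter_profile(rep(1, 8))            # 0.25 0.25 0.25 0.25
#' quarter_profile(c(4, 0, 0, 0))        # 1 0 0 0
#' @export
quarter_profile <- function(profile, orientation_known = TRUE) {
  if (!isTRUE(orientation_known)) {
    poleage_error("poleage_orientation_error",
                  "profile orientation (old pole first) must be known")
  }
  n <- length(profile)
  if (n < 4L) {
    poleage_error("poleage_measurement_error", "profile needs at least 4 columns")
  }
  total <- sum(profile)
  if (!is.finite(total) || total <= 0) {
    poleage_error("poleage_measurement_error", "profile total must be positive")
  }
  sizes <- rep(n %/% 4L, 4L) + (seq_len(4L) <= n %% 4L)
  grp <- rep(seq_len(4L), sizes)
  as.numeric(tapply(profile, grp, sum)) / total
}

#' Median quarter-share trajectories over the normalized lifetime
#'
#' For each stopped individual, quarter shares are computed frame by frame,
#' the time axis is normalized to \[0, 1\] from birth to the end of
#' observation, and the shares are linearly interpolated onto a common
#' 101-point grid. Per grid point the median and the 25th/75th percentiles
#' across individuals are reported, per quarter. In an old-pole-aggregate
#' strain the old-pole quarter's share rises first, then spills into the
#' neighboring quarters.
#'
#' @param profiles data.frame with columns `individual_id`, `time_min` and
#'   `profile` (";"-separated per-column intensities, old pole first), e.g.
#'   the frames of each stopped individual's terminal cell.
#' @param grid_points number of normalized-lifetime grid points (default 101).
#' @return data.frame with `tau` (normalized lifetime), `quarter` (1..4, old
#'   pole first), `median`, `p25`, `p75`, `n`.
#' @export
lifetime_profile_summary <- function(profiles, grid_points = 101L) {
  ids <- unique(profiles$individual_id)
  if (!length(ids)) {
    poleage_error("poleage_insufficient_data", "no individuals with profiles")
  }
  grid <- seq(0, 1, length.out = grid_points)
  per_ind <- list()
  for (id in ids) {
    d <- profiles[profiles$individual_id == id, , drop = FALSE]
    d <- d[order(d$time_min), ]
    if (nrow(d) < 4L) {
      poleage_warn("poleage_short_series",
                   sprintf("individual %s has < 4 frames and was skipped", id))
      next
    }
    q <- t(vapply(split_semi(d$profile), quarter_profile, numeric(4)))
    tau <- (d$time_min - d$time_min[1]) / (d$time_min[nrow(d)] - d$time_min[1])
    per_ind[[id]] <- vapply(1:4, function(k) {
      stats::approx(tau, q[, k], xout = grid, rule = 2)$y
    }, numeric(grid_points))
  }
  if (!length(per_ind)) {
    poleage_error("poleage_insufficient_data", "no usable individuals (all too short)")
  }
  arr <- simplify2array(per_ind)               # grid x quarter x individual
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  out <- expand.grid(tau = grid, quarter = 1:4)
  qs <- apply(arr, c(1, 2), stats::quantile, probs = c(0.25, 0.5, 0.75),
              names = FALSE)
  out$median <- as.vector(qs[2, , ])
  out$p25 <- as.vector(qs[1, , ])
  out$p75 <- as.vector(qs[3, , ])
  out$n <- dim(arr)[3]
  out
}

#' Collect per-individual lifetime profile frames
#'
#' Assembles, for each included stopped individual, the long-axis profiles of
#' all frames of its successive cell cycles (birth as a new-pole cell through
#' the end of observation), in the shape expected by
#' [lifetime_profile_summary()].
#'
#' @param assigned a [assign_pole_ages()] result whose tracking table carries
#'   a `profile` column.
#' @param fates the individuals data.frame after [assign_fates()].
#' @details The lifetime spans the individual's dividing life: frames from its
#'   birth as a new-pole cell up to (and including the first frame after) its
#'   last division; the arrested terminal plateau is not part of the
#'   normalized lifetime.
#' @return data.frame with `individual_id`, `time_min`, `profile`.
#' @export
individual_profiles <- function(assigned, fates) {
  stopifnot(inherits(assigned, "pole_assignment"))
  tab <- assigned$table
  if (!"profile" %in% names(tab)) {
    poleage_error("poleage_io_error", "tracking table has no profile column")
  }
  stopped <- fates$individual_id[fates$fate %in% "stopped" & fates$included]
  cells <- assigned$cells
  out <- lapply(stopped, function(id) {
    chain_cells <- cells[cells$individual_id %in% id, , drop = FALSE]
    chain <- chain_cells$cell_id
    t_end <- max(chain_cells$first_time)   # terminal cycle starts at last division
    d <- tab[tab$cell_id %in% chain, c("time_min", "profile")]
    d <- d[order(d$time_min), ]
    d <- d[d$time_min <= t_end + 1e-9, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    data.frame(individual_id = id, time_min = d$time_min, profile = d$profile,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    poleage_error("poleage_insufficient_data", "no stopped individuals with profiles")
  }
  rownames(res) <- NULL
  res
}

#' Mother/daughter signal panel at the first, second-last and last division
#'
#' For every included focal individual with at least three divisions, extracts
#' a signal for the mother (the old-pole product) and its new-pole daughter
#' just after the individual's first, second-last and last division, and
#' summarizes each division class as mean +/- SE. Two qualitative pattern
#' flags are reported: `aggregate_like` (mother signal rising with division
#' class — at least 1.5-fold from first to last and strictly increasing —
#' while daughters stay within 25% of each other) and `chromosome_like`
#' (mother and daughter comparable at the first and second-last division, the
#' mother dropping below half its second-last value at the last division).
#'
#' @param assigned a [assign_pole_ages()] result from a tracking table that
#'   carries the signal column.
#' @param fates the individuals data.frame after [assign_fates()].
#' @param signal_col column of the tracking table holding the per-frame signal
#'   total (e.g. `"agg_au"`, `"chrom_au"`), or `"integrated_density"` to use
#'   `mean_fluor * pixel_count`.
#' @param min_divisions minimum divisions for a focal individual (default 3).
#' @return list with `panel` (data.frame: `division_class`, `role`, `mean`,
#'   `se`, `n`), `aggregate_like`, `chromosome_like`.
#' @export
mother_daughter_division_panel <- function(assigned, fates,
                                           signal_col = "integrated_density",
                                           min_divisions = 3L) {
  stopifnot(inherits(assigned, "pole_assignment"))
  tab <- assigned$table
  cells <- assigned$cells
  get_signal <- function(cell_id) {
    d <- tab[tab$cell_id == cell_id, , drop = FALSE]
    d <- d[order(d$time_min), ][1, , drop = FALSE]   # first frame after division
    if (signal_col == "integrated_density") {
      integrated_density(d$mean_fluor, d$pixel_count)
    } else d[[signal_col]]
  }
  foc <- fates[fates$included & fates$n_divisions >= min_divisions, , drop = FALSE]
  if (!nrow(foc)) {
    poleage_error("poleage_insufficient_data",
                  sprintf("no included individual has >= %d divisions", min_divisions))
  }
  rows <- list()
  for (i in seq_len(nrow(foc))) {
    ii <- foc$individual_id[i]
    chain <- cells[cells$individual_id %in% ii, , drop = FALSE]
    chain <- chain[order(chain$pole_age), ]
    k <- foc$n_divisions[i]
    classes <- c(first = 1L, second_last = k - 1L, last = k)
    for (cl in names(classes)) {
      j <- classes[[cl]]
      parent_cell <- chain$cell_id[j]           # the cycle ending in division j
      ch <- cells[!is.na(cells$parent_id) & cells$parent_id == parent_cell, ]
      if (nrow(ch) != 2L) next
      mother_cell <- ch$cell_id[ch$old_pole_child == 1]
      daughter_cell <- ch$cell_id[ch$old_pole_child != 1]
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = ii, division_class = cl,
        mother = get_signal(mother_cell), daughter = get_signal(daughter_cell))
    }
  }
  d <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(d, d$division_class), function(g) {
    data.frame(division_class = g$division_class[1],
               role = c("mother", "daughter"),
               mean = c(mean(g$mother), mean(g$daughter)),
               se = c(stats::sd(g$mother), stats::sd(g$daughter)) /
                 sqrt(nrow(g)),
               n = nrow(g))
  }))
  rownames(agg) <- NULL
  ord <- c("first", "second_last", "last")
  m <- vapply(ord, function(cl) agg$mean[agg$division_class == cl &
                                           agg$role == "mother"], 1)
  dg <- vapply(ord, function(cl) agg$mean[agg$division_class == cl &
                                            agg$role == "daughter"], 1)
  aggregate_like <- all(diff(m) > 0) && m[3] >= 1.5 * m[1] &&
    (max(dg) <= 1.25 * max(min(dg), .Machine$double.eps))
  chromosome_like <- m[3] < 0.5 * m[2] &&
    abs(m[1] - dg[1]) <= 0.33 * max(dg[1], .Machine$double.eps) &&
    abs(m[2] - dg[2]) <= 0.33 * max(dg[2], .Machine$double.eps)
  list(panel = agg, aggregate_like = unname(aggregate_like),
       chromosome_like = unname(chromosome_like))
}
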