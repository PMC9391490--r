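# Increment-transect statistics: from measured von Ebner line boundaries to
# mean daily width, line counts, and tooth age in days.

#' Section planes
#'
#' Valid histological thin-section planes: `"TR"` (transverse), `"LL"`
#' (longitudinal labiolingual), `"AP"` (longitudinal anteroposterior).
#'
#' @format Character vector of length 3.
#' @export
SECTION_PLANES <- c("TR", "LL", "AP")

#' Plausibility band for daily increment widths (micrometres)
#'
#' Incremental lines of von Ebner are identified partly by width: single
#' daily increments fall between 1 and 30 micrometres in amniote dentine.
#' Widths outside this band are flagged (never dropped) by
#' [count_total_increments()].
#'
#' @format Numeric vector `c(lower, upper)` in micrometres.
#' @export
WIDTH_PLAUSIBILITY_UM <- c(1, 30)

#' Construct an increment transect
#'
#' An increment transect is one measured path across a thin section: the
#' ordered positions (micrometres) of successive von Ebner line boundaries,
#' measured from the pulp-cavity side outward, together with any unreadable
#' stretches (`gaps`) where lines could not be traced (a common consequence
#' of fossilization or non-uniform grinding).
#'
#' @param tooth_id Identifier for the sectioned tooth.
#' @param plane Section plane, one of [SECTION_PLANES].
#' @param boundary_positions Strictly increasing numeric vector of boundary
#'   positions in micrometres, 0-based at the pulp-cavity edge.
#' @param gaps Optional two-column matrix or data frame (`start_um`,
#'   `end_um`) of unreadable intervals. Gaps must be non-overlapping, lie
#'   within the span of the boundary positions, and contain no boundary
#'   position.
#'
#' @return An object of class `increment_transect`.
#' @examples
#' tr <- increment_transect("t1", "TR", seq(0, 120, by = 12))
#' mean_increment_width(tr)
#' @export
increment_transect <- function(tooth_id, plane, boundary_positions, gaps = NULL) {
  if (!is.character(tooth_id) || length(tooth_id) != 1L || is.na(tooth_id)) {
    tc_stop("invalid_transect", "tooth_id must be a single string")
  }
  if (!plane %in% SECTION_PLANES) {
    tc_stop("invalid_transect", sprintf(
      "plane must be one of %s", paste(SECTION_PLANES, collapse = ", ")))
  }
  pos <- as.numeric(boundary_positions)
  if (length(pos) < 1L || anyNA(pos)) {
    tc_stop("invalid_transect", "boundary_positions must be non-empty and finite")
  }
  if (any(diff(pos) <= 0)) {
    tc_stop("invalid_transect", "boundary_positions must be strictly increasing")
  }
  g <- normalise_gaps(gaps)
  if (nrow(g) > 0L) {
    if (any(g$start_um < pos[1L]) || any(g$end_um > pos[length(pos)])) {
      tc_stop("invalid_transect", "gaps must lie within the span of boundary_positions")
    }
    o <- order(g$start_um)
    g <- g[o, , drop = FALSE]
    if (nrow(g) > 1L && any(g$start_um[-1L] < g$end_um[-nrow(g)])) {
      tc_stop("invalid_transect", "gaps must be non-overlapping")
    }
    for (i in seq_len(nrow(g))) {
      if (any(pos > g$start_um[i] & pos < g$end_um[i])) {
        tc_stop("invalid_transect", "a gap may not contain a boundary position")
      }
    }
  }
  structure(
    list(tooth_id = tooth_id, plane = plane,
         boundary_positions = pos, gaps = g),
    class = "increment_transect"
  )
}

normalise_gaps <- function(gaps) {
  if (is.null(gaps) || (is.data.frame(gaps) && nrow(gaps) == 0L)) {
    return(data.frame(start_um = numeric(0), end_um = numeric(0)))
  }
  if (is.matrix(gaps)) gaps <- as.data.frame(gaps)
  if (is.numeric(gaps) && length(gaps) == 2L) {
    gaps <- data.frame(start_um = gaps[1L], end_um = gaps[2L])
  }
  if (!is.data.frame(gaps) || ncol(gaps) < 2L) {
    tc_stop("invalid_transect", "gaps must be a 2-column matrix/data frame")
  }
  g <- data.frame(start_um = as.numeric(gaps[[1L]]), end_um = as.numeric(gaps[[2L]]))
  if (anyNA(g) || any(g$end_um <= g$start_um)) {
    tc_stop("invalid_transect", "each gap needs finite start < end")
  }
  g
}

#' @export
print.increment_transect <- function(x, ...) {
  cat(sprintf("<increment_transect> %s [%s]: %d boundaries, %d gap(s), span %.1f um\n",
              x$tooth_id, x$plane, length(x$boundary_positions), nrow(x$gaps),
              diff(range(x$boundary_positions))))
  invisible(x)
}

# Split boundary indices into maximal gap-free runs. A run breaks wherever the
# interval between two successive boundaries intersects a gap.
gap_free_runs <- function(transect) {
  pos <- transect$boundary_positions
  n <- length(pos)
  if (n == 1L) return(list(1L))
  crosses <- vapply(seq_len(n - 1L), function(i) {
    interval_hits_gap(pos[i], pos[i + 1L], transect$gaps)
  }, logical(1))
  runs <- list()
  start <- 1L
  for (i in seq_along(crosses)) {
    if (crosses[i]) {
      runs[[length(runs) + 1L]] <- start:i
      start <- i + 1L
    }
  }
  runs[[length(runs) + 1L]] <- start:n
  runs
}

interval_hits_gap <- function(a, b, gaps) {
  if (nrow(gaps) == 0L) return(FALSE)
  any(gaps$start_um < b & gaps$end_um > a)
}

#' Mean increment width of a transect
#'
#' The unreadable stretches make a naive total-span/total-count ratio
#' unreliable, so the mean daily width is taken from the longest continuously
#' readable sequence: the span of the gap-free run with the most increments,
#' divided by that number of increments. Ties between equally long runs are
#' broken toward the pulp cavity.
#'
#' This quantity is the daily dentine apposition rate (DDAR) of the tooth,
#' in micrometres per day.
#'
#' @param transect An [increment_transect()].
#' @return Mean width in micrometres (per day).
#' @export
mean_increment_width <- function(transect) {
  stopifnot(inherits(transect, "increment_transect"))
  runs <- gap_free_runs(transect)
  lens <- vapply(runs, length, integer(1))
  if (max(lens) < 2L) {
    tc_stop("measurement_insufficient",
            "no gap-free run with at least 2 boundaries; cannot measure a width")
  }
  best <- runs[[which.max(lens)]]  # which.max returns the first (pulp-proximal) tie
  pos <- transect$boundary_positions[best]
  (pos[length(pos)] - pos[1L]) / (length(pos) - 1L)
}

#' Count total increments along a transect
#'
#' Counts increments from the pulp cavity to the tooth exterior. Intervals
#' between successive boundaries that do not touch a gap are observed
#' increments; each unreadable gap contributes `round(gap_length /
#' mean_increment_width)` extrapolated increments (round half up). Observed
#' widths are checked against the 1--30 micrometre plausibility band and the
#' out-of-band fraction is reported; out-of-band widths are flagged, never
#' dropped.
#'
#' @param transect An [increment_transect()].
#' @return An object of class `increment_stats` with fields
#'   `n_lines_observed`, `n_lines_extrapolated`, `mean_width`, `width_min`,
#'   `width_max`, `out_of_range_fraction`, and `observed_widths`.
#' @examples
#' tr <- increment_transect("t1", "TR", c(seq(0, 120, by = 12), 156),
#'                          gaps = c(120, 156))
#' st <- count_total_increments(tr)
#' tooth_age_days(st)  # 10 observed + 3 extrapolated
#' @export
count_total_increments <- function(transect) {
  stopifnot(inherits(transect, "increment_transect"))
  mw <- mean_increment_width(transect)  # propagates measurement_insufficient
  pos <- transect$boundary_positions
  n <- length(pos)
  widths <- diff(pos)
  clear <- !vapply(seq_len(n - 1L), function(i) {
    interval_hits_gap(pos[i], pos[i + 1L], transect$gaps)
  }, logical(1))
  observed_widths <- widths[clear]
  n_obs <- length(observed_widths)
  n_ext <- 0L
  if (nrow(transect$gaps) > 0L) {
    n_ext <- sum(vapply(seq_len(nrow(transect$gaps)), function(i) {
      as.integer(round_half_up(
        (transect$gaps$end_um[i] - transect$gaps$start_um[i]) / mw))
    }, integer(1)))
  }
  band <- WIDTH_PLAUSIBILITY_UM
  oor <- if (n_obs > 0L) {
    mean(observed_widths < band[1L] | observed_widths > band[2L])
  } else 0
  structure(
    list(
      tooth_id = transect$tooth_id,
      n_lines_observed = n_obs,
      n_lines_extrapolated = as.integer(n_ext),
      mean_width = mw,
      width_min = if (n_obs > 0L) min(observed_widths) else NA_real_,
      width_max = if (n_obs > 0L) max(observed_widths) else NA_real_,
      out_of_range_fraction = oor,
      observed_widths = observed_widths
    ),
    class = "increment_stats"
  )
}

#' @export
print.increment_stats <- function(x, ...) {
  cat(sprintf(
    "<increment_stats> %s: %d observed + %d extrapolated lines, mean width %.2f um/day\n",
    x$tooth_id, x$n_lines_observed, x$n_lines_extrapolated, x$mean_width))
  if (x$out_of_range_fraction > 0) {
    cat(sprintf("  warning: %.1f%% of widths outside [%g, %g] um\n",
                100 * x$out_of_range_fraction,
                WIDTH_PLAUSIBILITY_UM[1L], WIDTH_PLAUSIBILITY_UM[2L]))
  }
  invisible(x)
}

#' Tooth age in days
#'
#' One von Ebner increment records one day of dentine deposition, so a
#' tooth's age since the start of dentine mineralization equals its total
#' line count: observed lines plus lines extrapolated across unreadable
#' stretches.
#'
#' @param stats An `increment_stats` object from [count_total_increments()].
#' @return Integer age in days.
#' @export
tooth_age_days <- function(stats) {
  stopifnot(inherits(stats, "increment_stats"))
  as.integer(stats$n_lines_observed + stats$n_lines_extrapolated)
}

#' Correct an apparent width for sectioning obliquity
#'
#' A section cut at an angle to the true transverse plane inflates apparent
#' increment widths by `1/cos(angle)`; this undoes that inflation.
#'
#' @param apparent_width Apparent width in micrometres.
#' @param obliquity_angle Angle in degrees between the cut and the true
#'   transverse plane; must satisfy `0 <= angle < 90`.
#' @return True width in micrometres.
#' @examples
#' deoblique_width(20, 60)  # 10
#' @export
deoblique_width <- function(apparent_width, obliquity_angle) {
  if (!is_scalar_number(obliquity_angle) || obliquity_angle < 0 ||
      obliquity_angle >= 90) {
    tc_stop("invalid_geometry", "obliquity_angle must be in [0, 90) degrees")
  }
  if (!is.numeric(apparent_width) || anyNA(apparent_width)) {
    tc_stop("invalid_measurement", "apparent_width must be numeric")
  }
  apparent_width * cos(obliquity_angle * pi / 180)
}
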