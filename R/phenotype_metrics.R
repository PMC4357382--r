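# Interval bookkeeping: record i holds on [t_i, t_{i+1}); the last record
# holds to the end of the simulated window.
.record_durations <- function(traj) {
  t_end <- traj$config$t_end
  c(diff(traj$times), t_end - traj$times[length(traj$times)])
}

#' Choose a CAP state-call threshold from a trajectory
#'
#' The two phenotype states appear as two widely separated levels of the
#' time-weighted CAP distribution. The rule locates the two level centres by
#' an exact time-weighted two-cluster split of the CAP values (all candidate
#' split points are scanned for minimal within-cluster weighted variance).
#' The trajectory is called bimodal when the centres are at least
#' `min_separation` molecules apart and the minor cluster holds at least
#' `min_weight` of the window; the threshold is then the midpoint of the two
#' centres. Otherwise the rule falls back to `fallback` molecules, well
#' below the high-expression extreme of order 100 molecules.
#'
#' @param traj A `cap_trajectory` containing the `CA` species.
#' @param fallback Threshold used when the distribution is unimodal
#'   (default 20).
#' @param min_separation Minimum centre separation in molecules (default 30).
#' @param min_weight Minimum time fraction of the minor cluster (default 0.02).
#' @return A single numeric threshold (molecules).
#' @export
choose_cap_threshold <- function(traj, fallback = 20, min_separation = 30,
                                 min_weight = 0.02) {
  ca <- traj$counts[, "CA"]
  dur <- .record_durations(traj)
  vmax <- max(ca)
  if (vmax < min_separation) return(fallback)
  vals <- 0:vmax
  w <- vapply(vals, function(v) sum(dur[ca == v]), 0)
  keep <- w > 0
  vals <- vals[keep]; w <- w[keep]
  if (length(vals) < 2L) return(fallback)
  # exact 1-D weighted 2-means: scan every split point
  cw <- cumsum(w); cwx <- cumsum(w * vals)
  tot_w <- cw[length(cw)]; tot_wx <- cwx[length(cwx)]
  n <- length(vals)
  i <- seq_len(n - 1L)
  m1 <- cwx[i] / cw[i]
  m2 <- (tot_wx - cwx[i]) / (tot_w - cw[i])
  # within-cluster weighted SS is minimised where between-cluster SS peaks
  between <- cw[i] * (m1 - tot_wx / tot_w)^2 +
    (tot_w - cw[i]) * (m2 - tot_wx / tot_w)^2
  k <- which.max(between)
  sep <- m2[k] - m1[k]
  minor <- min(cw[k], tot_w - cw[k]) / tot_w
  if (sep < min_separation || minor < min_weight) return(fallback)
  (m1[k] + m2[k]) / 2
}

#' Call Cap-/Cap+ phenotype segments from a CAP trajectory
#'
#' CAP above the threshold is called `CAP_HIGH` (Cap+), otherwise `CAP_LOW`
#' (Cap-). Adjacent records with the same call are merged, so segments tile
#' the post-burn-in window exactly and adjacent segments always differ.
#'
#' @param traj A `cap_trajectory` containing the `CA` species.
#' @param threshold State-call threshold in CAP molecules; `NULL` (default)
#'   uses [choose_cap_threshold()].
#' @return An object of class `cap_segments`: a data frame with `start`,
#'   `end` (seconds) and `state`, plus the threshold used and the source
#'   trajectory id as attributes.
#' @export
classify_states <- function(traj, threshold = NULL) {
  if (!"CA" %in% colnames(traj$counts)) stop("trajectory does not contain CA")
  if (is.null(threshold)) threshold <- choose_cap_threshold(traj)
  if (!is.finite(threshold) || threshold < 0) stop("threshold must be >= 0")
  hi <- traj$counts[, "CA"] > threshold
  dur <- .record_durations(traj)
  keep <- dur > 0
  hi <- hi[keep]
  t <- traj$times[keep]
  runs <- rle(hi)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  seg <- data.frame(
    start = t[starts],
    end = c(t[starts[-1L]], traj$config$t_end),
    state = ifelse(runs$values, "CAP_HIGH", "CAP_LOW"),
    stringsAsFactors = FALSE)
  structure(seg, threshold = threshold, traj_id = traj$id,
            class = c("cap_segments", "data.frame"))
}

#' Time-weighted occupancy summary of phenotype segments
#'
#' @param segs A `cap_segments` object from [classify_states()].
#' @param traj The trajectory the segments were derived from (checked by id);
#'   used for per-state mean CAP levels.
#' @return A list of class `cap_occupancy`: `fraction_cap_low`,
#'   `fraction_cap_high`, `mean_dwell` (named seconds per state),
#'   `switch_events`, `mean_cap` (named molecules per state), `threshold`,
#'   `window` (seconds).
#' @export
occupancy_summary <- function(segs, traj = NULL) {
  if (!nrow(segs)) stop("no segments")
  dur <- segs$end - segs$start
  window <- sum(dur)
  frac_low <- sum(dur[segs$state == "CAP_LOW"]) / window
  mean_dwell <- tapply(dur, segs$state, mean)
  mean_cap <- NULL
  if (!is.null(traj)) {
    if (!identical(attr(segs, "traj_id"), traj$id))
      stop("segments were not derived from this trajectory")
    ca <- traj$counts[, "CA"]
    d <- .record_durations(traj)
    state_of <- segs$state[findInterval(traj$times, segs$start)]
    mean_cap <- tapply(seq_along(ca), state_of,
                       function(ix) sum(ca[ix] * d[ix]) / sum(d[ix]))
  }
  structure(list(fraction_cap_low = frac_low,
                 fraction_cap_high = 1 - frac_low,
                 mean_dwell = mean_dwell,
                 switch_events = nrow(segs) - 1L,
                 mean_cap = mean_cap,
                 threshold = attr(segs, "threshold"),
                 window = window),
            class = "cap_occupancy")
}

#' @export
print.cap_occupancy <- function(x, ...) {
  cat(sprintf("occupancy: Cap- %.3f / Cap+ %.3f of %.0f s; %d switch events\n",
              x$fraction_cap_low, x$fraction_cap_high, x$window, x$switch_events))
  invisible(x)
}

#' Cumulative occupancy curve of CAP expression
#'
#' For each level, the total time the trajectory spent at that CAP level or
#' less. A bistable trajectory yields a two-humped curve: a jump near zero
#' (the Cap- state) and a second rise at the high-expression level.
#'
#' @param traj A `cap_trajectory`.
#' @param levels Ascending non-negative CAP levels.
#' @return Data frame with `level` and `cumulative_seconds`; the curve is
#'   monotone non-decreasing and reaches the window duration at the maximum
#'   observed level.
#' @export
cumulative_occupancy_curve <- function(traj, levels) {
  if (is.unsorted(levels, strictly = FALSE) || any(levels < 0))
    stop("levels must be ascending and non-negative")
  ca <- traj$counts[, "CA"]
  dur <- .record_durations(traj)
  cum <- vapply(levels, function(l) sum(dur[ca <= l]), 0)
  data.frame(level = levels, cumulative_seconds = cum)
}

#' Mean dwell time expressed in cell divisions
#'
#' Epigenetic heritability requires dwell times spanning several cell
#' divisions; this converts mean per-state dwell times to division
#' equivalents using the observed ~60-minute division time.
#'
#' @param segs A `cap_segments` object.
#' @param division_time Division time in seconds (default 3600).
#' @return Named numeric vector: mean dwell per state in divisions.
#' @export
heritability_proxy <- function(segs, division_time = 3600) {
  if (!is.finite(division_time) || division_time <= 0)
    stop("division_time must be positive")
  if (!nrow(segs)) stop("no segments")
  dur <- segs$end - segs$start
  tapply(dur, segs$state, mean) / division_time
}

#' Write phenotype segments as TSV
#'
#' @param segs A `cap_segments` object.
#' @param path Output file.
#' @export
write_segments <- function(segs, path) {
  df <- as.data.frame(segs)
  df$threshold <- attr(segs, "threshold")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
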