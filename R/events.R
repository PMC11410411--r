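# Coordinate-based gait event detection (Zeni-style): foot contact at the
# peak anterior excursion of the heel relative to the sacrum, toe-off at the
# peak posterior excursion of the toe. Relative coordinates make detection
# invariant to lab-frame translation and to uniform walking speed.

# Principal direction of progression from the sacrum's horizontal path; the
# returned 2x2 rotation maps lab XY onto (forward, lateral). Imported trials
# therefore need not be axis-aligned.
progression_rotation <- function(rec) {
  sac <- rec$markers[["sacrum"]]
  if (is.null(sac)) gd_format_error("required marker absent: sacrum")
  xy <- sac[, 1:2, drop = FALSE]
  net <- xy[nrow(xy), ] - xy[1, ]
  if (sqrt(sum(net^2)) < 0.2) {
    # effectively static: fall back to +X so callers can fail on event count
    return(diag(2))
  }
  pc <- prcomp(xy, center = TRUE, scale. = FALSE)$rotation[, 1]
  if (sum(pc * net) < 0) pc <- -pc
  matrix(c(pc[1], pc[2], -pc[2], pc[1]), 2, 2)   # columns: forward, lateral
}

# Rotate a marker's XY into the progression frame; returns cbind(fwd, lat, Z).
rotate_marker <- function(m, R) cbind(m[, 1:2, drop = FALSE] %*% R, m[, 3])

# Dominant stride period (frames) from the autocorrelation of a relative
# excursion signal; NA when no credible periodicity is found.
.dominant_period <- function(x, rate) {
  n <- length(x)
  lag_max <- min(n - 2L, round(3 * rate))
  if (lag_max < round(0.4 * rate)) return(NA_real_)
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[-1]
  lo <- round(0.4 * rate)
  idx <- lo:lag_max
  best <- idx[which.max(ac[idx])]
  if (ac[best] < 0.2) NA_real_ else best
}

.find_extrema <- function(x, rate, min_separation) {
  if (diff(range(x)) < 1e-9) return(integer(0))
  # impaired gait can plateau near an extremum and split it; requiring a
  # separation of at least half the dominant stride period keeps one event
  # per cycle without assuming a cadence
  period <- .dominant_period(x, rate)
  sep <- max(round(min_separation * rate),
             if (is.na(period)) 0L else round(0.55 * period))
  pk <- pracma::findpeaks(x, minpeakdistance = max(1L, sep),
                          minpeakheight = mean(range(x)), zero = "-")
  if (is.null(pk)) integer(0) else sort(pk[, 2])
}

#' Detect foot contacts and toe-offs
#'
#' Foot contact = local maximum of the heel marker's anterior position
#' relative to the sacrum; toe-off = local minimum of the toe marker's
#' anterior position relative to the sacrum. Signals are low-pass filtered
#' before peak picking, peaks must be at least `min_separation` apart and
#' above the signal's midrange. Cycles are the half-open intervals between
#' consecutive same-side contacts.
#'
#' @param recording A [trial_recording] with the full marker set.
#' @param min_separation Minimum event spacing, seconds.
#' @param filter_cutoff Low-pass cutoff in Hz (`NULL` to skip filtering).
#' @param min_cycle,max_cycle Plausible cycle-duration bounds in seconds;
#'   out-of-range cycles are flagged, not dropped.
#' @return Object of class `gait_cycle_set`: per side `contacts`, `toeoffs`
#'   (increasing 1-based frame indices) and `cycles` (two-column matrix of
#'   half-open `[start, end)` intervals), plus `sample_rate` and any `flags`.
#' @export
detect_events <- function(recording, min_separation = 0.4, filter_cutoff = 6,
                          min_cycle = 0.4, max_cycle = 3) {
  check_required_markers(recording)
  rate <- recording$sample_rate
  R <- progression_rotation(recording)
  sac_f <- rotate_marker(recording$markers[["sacrum"]], R)[, 1]
  flags <- character(0)
  out <- list()
  for (side in c("left", "right")) {
    sfx <- if (side == "left") "_L" else "_R"
    rel_heel <- rotate_marker(recording$markers[[paste0("heel", sfx)]], R)[, 1] - sac_f
    rel_toe  <- rotate_marker(recording$markers[[paste0("toe", sfx)]], R)[, 1] - sac_f
    rel_heel <- lowpass(rel_heel, rate, filter_cutoff)
    rel_toe <- lowpass(rel_toe, rate, filter_cutoff)
    contacts <- .find_extrema(rel_heel, rate, min_separation)
    toeoffs <- .find_extrema(-rel_toe, rate, min_separation)
    if (side == recording$paretic_side && length(contacts) < 2)
      gd_data_error(sprintf(
        "trial too short: %d foot contact(s) detected on the %s (paretic) side",
        length(contacts), side))
    # keep exactly one toe-off per cycle (deepest if several)
    kept <- integer(0)
    if (length(contacts) >= 2) {
      for (i in seq_len(length(contacts) - 1)) {
        inside <- toeoffs[toeoffs > contacts[i] & toeoffs < contacts[i + 1]]
        if (length(inside) == 0) {
          flags <- c(flags, sprintf("%s: no toe-off between contacts %d and %d",
                                    side, contacts[i], contacts[i + 1]))
        } else {
          kept <- c(kept, inside[which.min(rel_toe[inside])])
        }
        dur <- (contacts[i + 1] - contacts[i]) / rate
        if (dur < min_cycle || dur > max_cycle)
          flags <- c(flags, sprintf("%s: cycle at frame %d has implausible duration %.2f s",
                                    side, contacts[i], dur))
      }
    }
    cycles <- if (length(contacts) >= 2)
      cbind(start = contacts[-length(contacts)], end = contacts[-1])
    else matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end")))
    out[[side]] <- list(contacts = contacts, toeoffs = kept, cycles = cycles)
  }
  structure(c(out, list(sample_rate = rate, flags = flags)),
            class = "gait_cycle_set")
}

#' @export
print.gait_cycle_set <- function(x, ...) {
  cat(sprintf("<gait_cycle_set> left: %d contacts / %d cycles; right: %d contacts / %d cycles\n",
              length(x$left$contacts), nrow(x$left$cycles),
              length(x$right$contacts), nrow(x$right$cycles)))
  if (length(x$flags)) cat("  flags:", length(x$flags), "\n")
  invisible(x)
}

#' Segment a side's gait cycles
#'
#' `k` same-side contacts yield `k - 1` half-open cycles; partial data
#' before the first and after the last contact is excluded.
#'
#' @param events A `gait_cycle_set` from [detect_events()].
#' @param side `"left"` or `"right"`.
#' @return Two-column integer matrix of `[start, end)` frame intervals.
#' @export
segment_cycles <- function(events, side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(inherits(events, "gait_cycle_set"))
  contacts <- events[[side]]$contacts
  if (length(contacts) < 2)
    gd_data_error(sprintf("need at least 2 contacts on the %s side to segment cycles", side))
  cbind(start = contacts[-length(contacts)], end = contacts[-1])
}
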