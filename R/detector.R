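# Orientation angles and buffered two-threshold scrambling event detection.
#
# A lipid's orientation is measured as the angle between its tail-to-head
# direction and the +z axis: ~0 deg in the upper leaflet, ~180 deg in the
# lower. Crossings are only counted when the angle passes strictly beyond the
# far threshold of a buffer band (default 55-125 deg); samples inside the
# buffer never change leaflet state, which suppresses noise-driven double
# counting (hysteresis).

#' Per-lipid orientation angles for one coordinate set
#'
#' Two tail-to-head vectors are formed (tail1 -> head, tail2 -> head). With
#' `method = "vector_mean"` (default) the lipid direction is the mean of the
#' two unit vectors; with `"angle_mean"` the two per-vector angles are
#' averaged instead.
#'
#' @param coords atoms x 3 coordinate matrix (nm).
#' @param selection a [select_lipids()] result.
#' @param method `"vector_mean"` or `"angle_mean"`.
#' @return numeric vector of angles in degrees, in `[0, 180]`, one per lipid.
#' @export
lipid_angles <- function(coords, selection,
                         method = c("vector_mean", "angle_mean")) {
  method <- match.arg(method)
  h <- coords[selection$head, , drop = FALSE]
  v1 <- h - coords[selection$tail1, , drop = FALSE]
  v2 <- h - coords[selection$tail2, , drop = FALSE]
  n1 <- sqrt(rowSums(v1 * v1))
  n2 <- sqrt(rowSums(v2 * v2))
  bad <- which(n1 == 0 | n2 == 0)
  if (length(bad))
    stopf("zero-length orientation vector for lipid_id %s (coincident beads)",
          paste(selection$lipid_id[bad], collapse = ", "))
  u1 <- v1 / n1
  u2 <- v2 / n2
  if (method == "vector_mean") {
    u <- (u1 + u2) / 2
    nu <- sqrt(rowSums(u * u))
    bad <- which(nu == 0)
    if (length(bad))
      stopf("degenerate orientation (anti-parallel tail vectors) for lipid_id %s",
            paste(selection$lipid_id[bad], collapse = ", "))
    acos(pmin(1, pmax(-1, u[, 3] / nu))) * 180 / pi
  } else {
    a1 <- acos(pmin(1, pmax(-1, u1[, 3]))) * 180 / pi
    a2 <- acos(pmin(1, pmax(-1, u2[, 3]))) * 180 / pi
    (a1 + a2) / 2
  }
}

#' Orientation angle of a single lipid in a frame
#'
#' @param frame a `cg_frame`.
#' @param lipid one row of a [select_lipids()] result.
#' @param method see [lipid_angles()].
#' @return angle in degrees in `[0, 180]`.
#' @export
lipid_angle <- function(frame, lipid, method = "vector_mean") {
  lipid_angles(frame$coords, lipid, method = method)
}

#' Build per-lipid orientation traces at a fixed stride
#'
#' Angles are evaluated on the time grid `t0, t0 + stride, ...` covering the
#' trajectory. When the trajectory's own sampling does not land exactly on
#' the grid, the nearest frame is used and a warning is emitted.
#'
#' @param traj a [cg_trajectory()].
#' @param selection a [select_lipids()] result.
#' @param stride_ns sampling stride in ns (default 1).
#' @param method see [lipid_angles()].
#' @return object of class `orientation_traces`: list with `angles`
#'   (lipids x timepoints matrix, degrees), `times` (ns), `lipid_ids`,
#'   `replica`, `stride_ns`.
#' @export
build_traces <- function(traj, selection, stride_ns = 1,
                         method = "vector_mean") {
  nf <- n_frames(traj)
  if (nf == 0L) stopf("empty trajectory")
  tt <- traj$times
  grid <- seq(tt[1], tt[nf], by = stride_ns)
  idx <- findInterval(grid, tt)
  # nearest frame: compare with the next frame where one exists
  nxt <- pmin(idx + 1L, nf)
  use_next <- (tt[nxt] - grid) < (grid - tt[idx])
  idx[use_next] <- nxt[use_next]
  miss <- max(abs(tt[idx] - grid))
  if (miss > 1e-6)
    warnf("trajectory sampling does not match the %g ns stride; nearest-frame resampling applied (max offset %.3g ns)",
          stride_ns, miss)
  nlip <- nrow(selection)
  ang <- matrix(NA_real_, nrow = nlip, ncol = length(grid))
  for (j in seq_along(idx))
    ang[, j] <- lipid_angles(traj$coords[, , idx[j], drop = TRUE], selection,
                             method = method)
  orientation_traces(ang, grid, selection$lipid_id, traj$replica, stride_ns)
}

#' Construct an orientation-trace set
#'
#' @param angles lipids x timepoints matrix of angles (degrees, `[0, 180]`).
#' @param times time grid in ns.
#' @param lipid_ids integer lipid ids (rows of `angles`).
#' @param replica replica id.
#' @param stride_ns sampling stride.
#' @export
orientation_traces <- function(angles, times, lipid_ids, replica = 0L,
                               stride_ns = NULL) {
  angles <- as.matrix(angles)
  stopifnot(ncol(angles) == length(times), nrow(angles) == length(lipid_ids))
  if (any(angles < -1e-9 | angles > 180 + 1e-9, na.rm = TRUE))
    stopf("orientation angles must lie in [0, 180] degrees")
  if (is.null(stride_ns))
    stride_ns <- if (length(times) > 1L) times[2] - times[1] else NA_real_
  structure(list(angles = angles, times = as.numeric(times),
                 lipid_ids = as.integer(lipid_ids),
                 replica = as.integer(replica), stride_ns = stride_ns),
            class = "orientation_traces")
}

#' @export
print.orientation_traces <- function(x, ...) {
  cat(sprintf("orientation_traces: replica %d, %d lipids x %d timepoints (stride %g ns)\n",
              x$replica, nrow(x$angles), ncol(x$angles), x$stride_ns))
  invisible(x)
}

# Core single-trace state machine, vectorised: only samples strictly outside
# the buffer can carry or change state; consecutive distinct out-of-buffer
# labels mark events.
detect_one_trace <- function(a, times, s0, lower, upper, lipid_id = 1L,
                             replica = 0L, correct_initial = TRUE) {
  n <- length(a)
  out <- which(a < lower | a > upper)
  empty <- data.frame(lipid_id = integer(), replica = integer(),
                      event_time_ns = numeric(), direction = character(),
                      buffer_entry_ns = numeric())
  if (length(out) == 0L)
    return(list(events = empty, states = rep(s0, n), final_state = s0))
  lab <- ifelse(a[out] > upper, "LOWER", "UPPER")
  if (correct_initial && out[1] == 1L && lab[1] != s0) {
    warnf("lipid %d (replica %d): initial angle %.1f contradicts declared %s leaflet; state corrected without counting an event",
          lipid_id, replica, a[1], s0)
    s0 <- lab[1]
  }
  prev <- c(s0, lab[-length(lab)])
  ev <- which(lab != prev)
  states <- rep(s0, n)
  if (length(ev)) {
    k <- out[ev]
    prev_out <- c(0L, out)[ev]          # previous out-of-buffer sample (0 if none)
    entry <- pmin(prev_out + 1L, k)
    for (i in seq_along(ev)) states[k[i]:n] <- lab[ev[i]]
    events <- data.frame(
      lipid_id = lipid_id, replica = replica,
      event_time_ns = times[k],
      direction = paste0(prev[ev], "->", lab[ev]),
      buffer_entry_ns = times[entry])
  } else events <- empty
  list(events = events, states = states, final_state = lab[length(lab)])
}

#' Detect scrambling events with the buffered two-threshold rule
#'
#' State machine semantics: a lipid in state `UPPER` flips to `LOWER`
#' (emitting one event) at the first sample with angle strictly greater than
#' `upper_threshold`; a lipid in state `LOWER` flips to `UPPER` at the first
#' sample strictly below `lower_threshold`. Samples inside
#' `[lower_threshold, upper_threshold]` (the buffer) never change state nor
#' emit events. An initial angle already beyond the threshold opposite to the
#' declared initial leaflet corrects the state with a warning instead of
#' emitting a phantom event; set `correct_initial = FALSE` for raw
#' state-machine semantics (appropriate when a trace continues from a known
#' prior state rather than starting a trajectory).
#'
#' @param traces an [orientation_traces()] object, or a bare numeric angle
#'   vector for a single lipid.
#' @param initial_leaflets a [assign_initial_leaflets()] result (or any
#'   data.frame with `lipid_id`, `leaflet`), or a single `"UPPER"`/`"LOWER"`
#'   string when `traces` is a numeric vector.
#' @param lower_threshold,upper_threshold buffer bounds in degrees
#'   (defaults 55 and 125).
#' @param correct_initial correct (with a warning) an initial state that
#'   contradicts the first sample, instead of counting an event.
#' @return list of class `scrambling_events` with `events` (data.frame:
#'   `lipid_id`, `replica`, `event_time_ns`, `direction`,
#'   `buffer_entry_ns`, ordered by replica, time, lipid) and `states`
#'   (lipids x timepoints leaflet-state matrix).
#' @export
detect_events <- function(traces, initial_leaflets,
                          lower_threshold = 55, upper_threshold = 125,
                          correct_initial = TRUE) {
  if (!(lower_threshold < upper_threshold) ||
      lower_threshold <= 0 || upper_threshold >= 180)
    stopf("thresholds must satisfy 0 < lower < upper < 180")
  if (is.numeric(traces)) {
    traces <- orientation_traces(matrix(traces, nrow = 1),
                                 seq_along(traces) - 1, 1L)
    initial_leaflets <- data.frame(lipid_id = 1L, leaflet = initial_leaflets)
  }
  states0 <- initial_leaflets$leaflet[match(traces$lipid_ids,
                                            initial_leaflets$lipid_id)]
  if (anyNA(states0) || !all(states0 %in% c("UPPER", "LOWER")))
    stopf("initial leaflet missing or invalid for some lipids")
  nlip <- nrow(traces$angles)
  st <- matrix(NA_character_, nlip, ncol(traces$angles))
  evs <- vector("list", nlip)
  for (i in seq_len(nlip)) {
    r <- detect_one_trace(traces$angles[i, ], traces$times, states0[i],
                          lower_threshold, upper_threshold,
                          lipid_id = traces$lipid_ids[i],
                          replica = traces$replica,
                          correct_initial = correct_initial)
    st[i, ] <- r$states
    evs[[i]] <- r$events
  }
  events <- do.call(rbind, evs)
  events <- events[order(events$replica, events$event_time_ns,
                         events$lipid_id), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, states = st,
                 times = traces$times, lipid_ids = traces$lipid_ids,
                 thresholds = c(lower_threshold, upper_threshold)),
            class = "scrambling_events")
}

#' @export
print.scrambling_events <- function(x, ...) {
  cat(sprintf("scrambling_events: %d events over %d lipids, buffer [%g, %g] deg\n",
              nrow(x$events), length(x$lipid_ids), x$thresholds[1],
              x$thresholds[2]))
  invisible(x)
}

#' Detect events across all replicas of a system
#'
#' Convenience wrapper: builds traces and runs [detect_events()] per replica,
#' concatenating the event tables.
#'
#' @param trajectories list of [cg_trajectory()] objects.
#' @param selection a [select_lipids()] result.
#' @param initial_leaflets per-replica list or single assignment reused for
#'   all replicas.
#' @inheritParams build_traces
#' @inheritParams detect_events
#' @return data.frame of pooled events (columns as in [detect_events()]).
#' @export
detect_events_all <- function(trajectories, selection, initial_leaflets,
                              stride_ns = 1, method = "vector_mean",
                              lower_threshold = 55, upper_threshold = 125) {
  per_rep <- !is.data.frame(initial_leaflets)
  evs <- lapply(seq_along(trajectories), function(i) {
    tr <- build_traces(trajectories[[i]], selection, stride_ns = stride_ns,
                       method = method)
    la <- if (per_rep) initial_leaflets[[i]] else initial_leaflets
    detect_events(tr, la, lower_threshold, upper_threshold)$events
  })
  out <- do.call(rbind, evs)
  rownames(out) <- NULL
  out
}

#' Write a scrambling event table as TSV
#'
#' Columns: replica, lipid_id, event_time_ns, direction, buffer_entry_ns;
#' rows ordered by (replica, time, lipid_id).
#'
#' @param events event data.frame from [detect_events()].
#' @param path output file.
#' @export
write_event_table <- function(events, path) {
  ev <- events[order(events$replica, events$event_time_ns, events$lipid_id),
               c("replica", "lipid_id", "event_time_ns", "direction",
                 "buffer_entry_ns")]
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
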