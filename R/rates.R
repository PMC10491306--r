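# Event-rate statistics: equilibration discard, per-microsecond binning,
# boxplot summary and scrambler classification.
#
# Protocol defaults: discard the first 2 us of each replica, count events in
# 1 us bins, pool bins over replicates (two replicates of 10 us give 16 data
# points) and classify against a cut-off of 1 event/us.

#' Bin scrambling events into fixed windows per replica
#'
#' Events before `equilibration_ns` are excluded. Bins are half-open
#' `[start, end)` and tile `[equilibration, T_end]`; an incomplete trailing
#' window is dropped (and reported via a message).
#'
#' @param events event data.frame (needs `replica`, `event_time_ns`).
#' @param t_end_ns trajectory end time per replica: a single value recycled
#'   to all replicas, or a vector named by replica id.
#' @param replicas integer vector of replica ids to bin; defaults to the
#'   names of `t_end_ns` or the replicas present in `events`.
#' @param equilibration_ns equilibration discard (default 2000 ns).
#' @param bin_width_ns bin width (default 1000 ns = 1 us).
#' @return data.frame of class `binned_events` with columns `replica`,
#'   `bin_start_ns`, `bin_end_ns`, `count`; attributes `equilibration_ns`,
#'   `bin_width_ns`.
#' @export
bin_events <- function(events, t_end_ns, replicas = NULL,
                       equilibration_ns = 2000, bin_width_ns = 1000) {
  if (is.null(replicas)) {
    replicas <- if (!is.null(names(t_end_ns))) as.integer(names(t_end_ns))
                else sort(unique(events$replica))
    if (length(replicas) == 0L) replicas <- 0L
  }
  if (is.null(names(t_end_ns))) {
    t_end_ns <- rep_len(t_end_ns, length(replicas))
    names(t_end_ns) <- replicas
  }
  rows <- lapply(replicas, function(r) {
    tend <- t_end_ns[[as.character(r)]]
    nb <- floor((tend - equilibration_ns) / bin_width_ns)
    if (nb < 1)
      stopf("replica %d: trajectory of %g ns is shorter than equilibration (%g ns) + one bin (%g ns); at least %g ns required",
            r, tend, equilibration_ns, bin_width_ns,
            equilibration_ns + bin_width_ns)
    if (tend - equilibration_ns - nb * bin_width_ns > 0)
      message(sprintf("replica %d: dropping incomplete trailing bin (%g ns)",
                      r, tend - equilibration_ns - nb * bin_width_ns))
    starts <- equilibration_ns + (seq_len(nb) - 1) * bin_width_ns
    tt <- events$event_time_ns[events$replica == r]
    tt <- tt[tt >= equilibration_ns & tt < equilibration_ns + nb * bin_width_ns]
    cnt <- tabulate(floor((tt - equilibration_ns) / bin_width_ns) + 1L, nb)
    data.frame(replica = r, bin_start_ns = starts,
               bin_end_ns = starts + bin_width_ns, count = cnt)
  })
  out <- do.call(rbind, rows)
  attr(out, "equilibration_ns") <- equilibration_ns
  attr(out, "bin_width_ns") <- bin_width_ns
  class(out) <- c("binned_events", "data.frame")
  out
}

#' Summarise binned event counts and classify the system
#'
#' Bin counts are pooled over replicas and expressed as events/us. Boxplot
#' statistics use linear interpolation between order statistics for the
#' quartiles; whiskers are reported both as Tukey 1.5 x IQR (clamped to the
#' data range) and as the plain min/max. Classification is `SCRAMBLER` iff
#' the pooled mean rate is at least `cutoff`.
#'
#' @param binned a [bin_events()] result.
#' @param cutoff classification cut-off in events/us (default 1).
#' @return list of class `rate_summary`: `data_points` (per-bin rates,
#'   events/us), `n_points`, `mean`, `median`, `q1`, `q3`,
#'   `whisker_low`/`whisker_high` (Tukey), `min`, `max`, `classification`,
#'   `cutoff`.
#' @export
summarize_rates <- function(binned, cutoff = 1) {
  if (nrow(binned) == 0L) stopf("no bins present")
  w_us <- attr(binned, "bin_width_ns") / 1000
  x <- binned$count / w_us
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  wl <- min(x[x >= q[1] - 1.5 * iqr])
  wh <- max(x[x <= q[3] + 1.5 * iqr])
  m <- mean(x)
  structure(list(
    data_points = x, n_points = length(x), mean = m,
    median = q[2], q1 = q[1], q3 = q[3],
    whisker_low = wl, whisker_high = wh, min = min(x), max = max(x),
    classification = if (m >= cutoff) "SCRAMBLER" else "NON_SCRAMBLER",
    cutoff = cutoff), class = "rate_summary")
}

#' @export
print.rate_summary <- function(x, ...) {
  cat(sprintf("rate_summary: %s (mean %.3g events/us over %d points, cutoff %g)\n",
              x$classification, x$mean, x$n_points, x$cutoff))
  cat(sprintf("  median %.3g  q1 %.3g  q3 %.3g  whiskers [%.3g, %.3g]  range [%.3g, %.3g]\n",
              x$median, x$q1, x$q3, x$whisker_low, x$whisker_high,
              x$min, x$max))
  invisible(x)
}

#' Rank systems by scrambling rate
#'
#' @param summaries named list of [summarize_rates()] results.
#' @return data.frame sorted by mean rate (descending; ties broken by system
#'   name) with columns `system`, `mean`, `median`, `n_points`,
#'   `classification`.
#' @export
compare_systems <- function(summaries) {
  stopifnot(length(summaries) >= 1L, !is.null(names(summaries)))
  tab <- data.frame(
    system = names(summaries),
    mean = vapply(summaries, `[[`, numeric(1), "mean"),
    median = vapply(summaries, `[[`, numeric(1), "median"),
    n_points = vapply(summaries, `[[`, numeric(1), "n_points"),
    classification = vapply(summaries, `[[`, character(1), "classification"))
  tab <- tab[order(-tab$mean, tab$system), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Write a rate summary as JSON and the raw bin counts as TSV
#'
#' @param summary a [summarize_rates()] result.
#' @param binned the matching [bin_events()] result.
#' @param json_path,tsv_path output paths (either may be `NULL` to skip).
#' @export
write_rate_summary <- function(summary, binned, json_path = NULL,
                               tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      summary[c("n_points", "mean", "median", "q1", "q3", "whisker_low",
                "whisker_high", "min", "max", "classification", "cutoff")],
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv_path))
    utils::write.table(as.data.frame(binned), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(summary)
}
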