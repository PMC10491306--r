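# Scrambling-pathway mapping: headgroup positions during the transit window
# of each event, projected onto nearby protein residues.

#' Headgroup positions during an event's transit window
#'
#' Returns the head-bead coordinates at every trace stride point from the
#' buffer entry to the completing crossing, inclusive.
#'
#' @param event one row of an event table (needs `lipid_id`,
#'   `buffer_entry_ns`, `event_time_ns`).
#' @param traj the [cg_trajectory()] the event was detected in.
#' @param selection a [select_lipids()] result.
#' @param stride_ns trace stride used during detection (default 1 ns).
#' @return matrix with columns `time_ns`, `x`, `y`, `z` (nm), one row per
#'   stride point, in time order.
#' @export
transit_positions <- function(event, traj, selection, stride_ns = 1) {
  t0 <- event$buffer_entry_ns
  t1 <- event$event_time_ns
  tt <- traj$times
  if (t0 < tt[1] - stride_ns / 2 || t1 > tt[length(tt)] + stride_ns / 2)
    stopf("transit window [%g, %g] ns lies outside the stored frames [%g, %g] ns",
          t0, t1, tt[1], tt[length(tt)])
  grid <- seq(t0, t1, by = stride_ns)
  fidx <- vapply(grid, function(g) which.min(abs(tt - g)), integer(1))
  head_idx <- selection$head[selection$lipid_id == event$lipid_id]
  if (length(head_idx) != 1L)
    stopf("lipid_id %s not found in selection", event$lipid_id)
  pos <- t(vapply(fidx, function(f) traj$coords[head_idx, , f], numeric(3)))
  cbind(time_ns = tt[fidx], x = pos[, 1], y = pos[, 2], z = pos[, 3])
}

#' Map transiting headgroups onto protein residues
#'
#' For every post-equilibration event, the headgroup positions over the
#' transit window are collected; each (event, stride-point) pair within
#' `contact_cutoff_nm` of any bead of a protein residue increments that
#' residue's contact count. The pooled 3D point cloud is attached for
#' visualisation.
#'
#' @param events event data.frame from [detect_events()] (one replica's
#'   events matching `traj`).
#' @param traj the [cg_trajectory()] the events belong to.
#' @param topology a [cg_topology()] with a protein group.
#' @param selection a [select_lipids()] result.
#' @param contact_cutoff_nm residue contact cutoff (default 0.6 nm).
#' @param equilibration_ns events before this time are excluded (default
#'   2000 ns, matching the rate statistics).
#' @param stride_ns trace stride used during detection.
#' @return data.frame of class `pathway_map` with columns `resid`,
#'   `resname`, `contact_count`, `normalized_frequency` (count / total
#'   transit samples); attribute `points` holds the pooled point cloud
#'   (`event`, `time_ns`, `x`, `y`, `z`).
#' @export
residue_contact_map <- function(events, traj, topology, selection,
                                contact_cutoff_nm = 0.6,
                                equilibration_ns = 2000, stride_ns = 1) {
  prot <- topology$groups$protein
  if (is.null(prot) || !length(prot)) stopf("protein group is empty")
  prot_resid <- topology$atoms$resid[prot]
  res_ids <- unique(prot_resid)
  res_names <- topology$atoms$resname[prot][match(res_ids, prot_resid)]
  counts <- setNames(numeric(length(res_ids)), res_ids)

  keep <- events[events$event_time_ns >= equilibration_ns, , drop = FALSE]
  if (nrow(keep) == 0L) {
    warnf("no post-equilibration events; pathway map is empty")
    out <- data.frame(resid = res_ids, resname = res_names,
                      contact_count = 0, normalized_frequency = 0)
    attr(out, "points") <- matrix(numeric(), ncol = 5,
                                  dimnames = list(NULL,
                                    c("event", "time_ns", "x", "y", "z")))
    class(out) <- c("pathway_map", "data.frame")
    return(out)
  }

  clouds <- vector("list", nrow(keep))
  total_samples <- 0L
  for (e in seq_len(nrow(keep))) {
    pos <- transit_positions(keep[e, ], traj, selection, stride_ns)
    clouds[[e]] <- cbind(event = e, pos)
    total_samples <- total_samples + nrow(pos)
    if (contact_cutoff_nm <= 0) next
    for (p in seq_len(nrow(pos))) {
      f <- which.min(abs(traj$times - pos[p, "time_ns"]))
      pc <- traj$coords[prot, , f, drop = TRUE]
      d <- min_dist_to_set(matrix(pos[p, c("x", "y", "z")], nrow = 1),
                           pc, traj$box[f, 1:2])
      # per-residue minimum distance
      dxyz <- sweep(pc, 2, pos[p, c("x", "y", "z")])
      dxyz[, 1:2] <- min_image_xy(dxyz[, 1:2, drop = FALSE],
                                  traj$box[f, 1:2])
      dd <- sqrt(rowSums(dxyz^2))
      hitres <- unique(prot_resid[dd <= contact_cutoff_nm])
      counts[as.character(hitres)] <- counts[as.character(hitres)] + 1
    }
  }
  out <- data.frame(resid = res_ids, resname = res_names,
                    contact_count = as.numeric(counts),
                    normalized_frequency =
                      as.numeric(counts) / max(total_samples, 1L))
  attr(out, "points") <- do.call(rbind, clouds)
  class(out) <- c("pathway_map", "data.frame")
  out
}

#' Write the transit point cloud as a PDB of pseudo-atoms
#'
#' One `HETATM` pseudo-atom per transit sample (coordinates converted to
#' Angstrom) so the scrambling pathway can be inspected in any molecular
#' viewer.
#'
#' @param map a [residue_contact_map()] result (its `points` attribute is
#'   written), or a points matrix directly.
#' @param path output PDB path.
#' @export
write_pathway_pdb <- function(map, path) {
  pts <- if (is.matrix(map)) map else attr(map, "points")
  n <- nrow(pts)
  lines <- character(n + 1L)
  for (i in seq_len(n)) {
    lines[i] <- sprintf(
      "HETATM%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      i %% 100000L, "HD", "PTH", "P", as.integer(pts[i, "event"]) %% 10000L,
      pts[i, "x"] * 10, pts[i, "y"] * 10, pts[i, "z"] * 10, 1, 0)
  }
  lines[n + 1L] <- "END"
  writeLines(lines, path)
  invisible(path)
}

#' Write the residue contact table as TSV
#' @param map a [residue_contact_map()] result.
#' @param path output file.
#' @export
write_contact_table <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
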