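# Lipid bead selection and initial leaflet assignment.

#' Select lipids by residue and bead names
#'
#' Resolves, for every residue matching `residue_name`, one headgroup bead and
#' exactly two tail-terminal beads. Defaults follow Martini 3 DOPC naming:
#' headgroup `NC3`, terminal tail beads `C4A` and `C4B`.
#'
#' @param topology a [cg_topology()].
#' @param residue_name lipid residue name (e.g. `"DOPC"`).
#' @param head_bead_name headgroup bead name.
#' @param tail_bead_names exactly two tail-terminal bead names.
#' @return data.frame of class `lipid_selection` with columns `lipid_id`,
#'   `resid`, `head`, `tail1`, `tail2` (atom indices).
#' @export
select_lipids <- function(topology, residue_name = "DOPC",
                          head_bead_name = "NC3",
                          tail_bead_names = c("C4A", "C4B")) {
  if (length(tail_bead_names) != 2L)
    stopf("exactly two tail-terminal bead names are required")
  at <- topology$atoms
  hit <- at[at$resname == residue_name, , drop = FALSE]
  if (nrow(hit) == 0L)
    stopf("no residues named '%s' in topology", residue_name)
  resids <- unique(hit$resid)
  pick <- function(sub, nm, resid) {
    i <- sub$index[sub$name == nm]
    if (length(i) != 1L)
      stopf("residue %d ('%s') lacks a unique bead named '%s'",
            resid, residue_name, nm)
    i
  }
  rows <- lapply(resids, function(r) {
    sub <- hit[hit$resid == r, , drop = FALSE]
    data.frame(resid = r,
               head  = pick(sub, head_bead_name, r),
               tail1 = pick(sub, tail_bead_names[1], r),
               tail2 = pick(sub, tail_bead_names[2], r))
  })
  sel <- do.call(rbind, rows)
  sel <- cbind(lipid_id = seq_len(nrow(sel)), sel)
  attr(sel, "residue_name") <- residue_name
  attr(sel, "head_bead") <- head_bead_name
  attr(sel, "tail_beads") <- tail_bead_names
  class(sel) <- c("lipid_selection", "data.frame")
  sel
}

#' Assign lipids to leaflets at a reference frame
#'
#' The bilayer midplane is the mean z of all tail-terminal beads; a lipid is
#' `UPPER` iff its headgroup bead sits above the midplane. The assignment is
#' cross-checked against the initial orientation angle (an `UPPER` lipid
#' should point along +z, i.e. have an angle below 90 degrees); lipids whose
#' angle contradicts their geometric leaflet are flagged, not reassigned.
#'
#' @param frame a `cg_frame` (see [get_frame()]).
#' @param selection a [select_lipids()] result.
#' @param angle_method angle convention passed to the angle calculation.
#' @return data.frame of class `leaflet_assignment` with columns `lipid_id`,
#'   `leaflet` (`"UPPER"`/`"LOWER"`), `consistent`; attributes `midplane_z`
#'   and `reference_frame_time`.
#' @export
assign_initial_leaflets <- function(frame, selection,
                                    angle_method = "vector_mean") {
  co <- frame$coords
  need <- c(selection$head, selection$tail1, selection$tail2)
  if (max(need) > nrow(co))
    stopf("frame does not contain all selected beads")
  zs <- co[need, 3]
  if (diff(range(zs)) > 0.9 * frame$box[3])
    stopf(paste("bilayer appears wrapped across the z boundary",
                "(z extent > 90%% of the box); re-image the trajectory",
                "so the bilayer is whole along z"))
  midplane <- mean(co[c(selection$tail1, selection$tail2), 3])
  upper <- co[selection$head, 3] > midplane
  if (all(upper) || all(!upper))
    stopf(paste("degenerate bilayer: all headgroups on one side of the",
                "midplane (z = %.3f nm)"), midplane)
  leaflet <- ifelse(upper, "UPPER", "LOWER")
  ang <- lipid_angles(co, selection, method = angle_method)
  consistent <- (leaflet == "UPPER") == (ang < 90)
  if (!all(consistent))
    warnf("%d lipid(s) have an initial orientation angle inconsistent with their geometric leaflet (flagged)",
          sum(!consistent))
  out <- data.frame(lipid_id = selection$lipid_id, leaflet = leaflet,
                    consistent = consistent)
  attr(out, "midplane_z") <- midplane
  attr(out, "reference_frame_time") <- frame$time
  class(out) <- c("leaflet_assignment", "data.frame")
  out
}
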