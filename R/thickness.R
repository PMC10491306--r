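# Hydrophobic membrane thickness from z-density profiles, and local thinning
# near an embedded protein.
#
# The hydrophobic body is the set of lipid beads excluding the headgroup and
# phosphate beads (Martini 3 DOPC defaults: exclude NC3, PO4). Densities are
# histogrammed along z relative to the per-frame bilayer midplane (mean z of
# the tail-terminal beads), sampled every 5 ns after a 2 us equilibration
# discard; thickness is read off as the full width at half maximum (FWHM) of
# the profile with linear interpolation at the half-maximum crossings.

#' Hydrophobic bead indices of the lipid group
#'
#' @param topology a [cg_topology()] with groups defined (see
#'   [define_groups()]).
#' @param exclude_beads bead names excluded from the hydrophobic body.
#' @return integer atom indices.
#' @export
hydrophobic_beads <- function(topology, exclude_beads = c("NC3", "PO4")) {
  lip <- topology$groups$lipids
  if (is.null(lip) || !length(lip))
    stopf("topology has no lipid group; call define_groups() first")
  lip[!(topology$atoms$name[lip] %in% exclude_beads)]
}

#' Hydrophobic beads of protein-proximal lipids in one frame
#'
#' A lipid is proximal when any of its beads lies within `cutoff_nm` of any
#' protein bead (3D distance, xy minimum image). Selection is lipid-level:
#' all hydrophobic beads of a proximal lipid are returned.
#'
#' @param frame a `cg_frame`.
#' @param topology a [cg_topology()] with protein and lipid groups.
#' @param cutoff_nm proximity cutoff (default 1.0 nm).
#' @param exclude_beads see [hydrophobic_beads()].
#' @return integer atom indices of hydrophobic beads of proximal lipids.
#' @export
proximal_lipid_beads <- function(frame, topology, cutoff_nm = 1.0,
                                 exclude_beads = c("NC3", "PO4")) {
  prot <- topology$groups$protein
  if (is.null(prot) || !length(prot))
    stopf("protein group is empty; request a bulk profile explicitly instead of a proximal one")
  lip <- topology$groups$lipids
  if (!length(lip)) stopf("lipid group is empty")
  if (cutoff_nm <= 0) return(integer())
  co <- frame$coords
  dmin <- min_dist_to_set(co[lip, , drop = FALSE],
                          co[prot, , drop = FALSE], frame$box[1:2])
  near_resid <- unique(topology$atoms$resid[lip[dmin <= cutoff_nm]])
  hb <- hydrophobic_beads(topology, exclude_beads)
  hb[topology$atoms$resid[hb] %in% near_resid]
}

#' z-density profile of a bead selection
#'
#' Frames are taken every `stride_ns` after discarding the first
#' `equilibration_ns`. For each frame, the z coordinates of the selected
#' beads, referenced to that frame's bilayer midplane, are histogrammed; the
#' profile is the per-frame average bead count per nm, so that
#' `sum(density) * bin_nm` equals the mean number of selected beads per
#' frame.
#'
#' @param traj a [cg_trajectory()].
#' @param topology a [cg_topology()] with groups defined.
#' @param selection a [select_lipids()] result (supplies the tail-terminal
#'   beads that define the midplane).
#' @param mode `"bulk"` (all lipids) or `"proximal"` (protein-proximal
#'   lipids, re-selected every frame).
#' @param cutoff_nm proximity cutoff for `mode = "proximal"`.
#' @param exclude_beads bead names excluded from the hydrophobic body.
#' @param stride_ns sampling stride (default 5 ns).
#' @param equilibration_ns equilibration discard (default 2000 ns).
#' @param bin_nm histogram bin width (default 0.1 nm).
#' @return data.frame of class `density_profile` with columns `z_nm` (bin
#'   centres) and `density` (beads per nm per frame); attributes `n_frames`,
#'   `bin_nm`, `selection_descriptor`, `stride_ns`.
#' @export
density_profile <- function(traj, topology, selection,
                            mode = c("bulk", "proximal"), cutoff_nm = 1.0,
                            exclude_beads = c("NC3", "PO4"), stride_ns = 5,
                            equilibration_ns = 2000, bin_nm = 0.1) {
  mode <- match.arg(mode)
  tt <- traj$times
  grid <- seq(equilibration_ns, tt[length(tt)], by = stride_ns)
  grid <- grid[grid >= tt[1]]
  if (!length(grid))
    stopf("no post-equilibration frames at the %g ns stride", stride_ns)
  fidx <- vapply(grid, function(g) which.min(abs(tt - g)), integer(1))
  fidx <- unique(fidx)

  zmax <- max(traj$box[, 3]) / 2
  edges <- seq(-zmax, zmax, by = bin_nm)
  counts <- numeric(length(edges) - 1L)
  tails <- c(selection$tail1, selection$tail2)
  static_beads <- if (mode == "bulk") hydrophobic_beads(topology,
                                                        exclude_beads)
                  else NULL
  n_used <- 0L
  tot_beads <- 0L
  for (f in fidx) {
    fr <- get_frame(traj, f)
    beads <- if (mode == "bulk") static_beads
             else proximal_lipid_beads(fr, topology, cutoff_nm, exclude_beads)
    if (!length(beads)) next
    z <- fr$coords[beads, 3] - mean(fr$coords[tails, 3])
    z <- z[z > edges[1] & z <= edges[length(edges)]]
    counts <- counts + tabulate(findInterval(z, edges, left.open = TRUE),
                                length(counts))
    n_used <- n_used + 1L
    tot_beads <- tot_beads + length(beads)
  }
  if (n_used == 0L)
    stopf("selection empty in all analysed frames (mode '%s')", mode)
  out <- data.frame(z_nm = (edges[-1] + edges[-length(edges)]) / 2,
                    density = counts / (n_used * bin_nm))
  attr(out, "n_frames") <- n_used
  attr(out, "bin_nm") <- bin_nm
  attr(out, "stride_ns") <- stride_ns
  attr(out, "selection_descriptor") <-
    sprintf("%s hydrophobic beads (excluding %s)%s", mode,
            paste(exclude_beads, collapse = ","),
            if (mode == "proximal") sprintf(", lipid within %.2f nm of protein",
                                            cutoff_nm) else "")
  attr(out, "mean_beads_per_frame") <- tot_beads / n_used
  class(out) <- c("density_profile", "data.frame")
  out
}

#' Membrane thickness as the FWHM of a density profile
#'
#' The half-maximum level is half the profile's maximum; crossings of that
#' level are located on the piecewise-linear interpolant of the profile. A
#' valid single-slab profile has exactly two crossings; more indicate a
#' multimodal profile and raise an error.
#'
#' @param profile a [density_profile()] (or any data.frame with `z_nm`,
#'   `density`).
#' @return thickness in nm.
#' @export
thickness_from_profile <- function(profile) {
  z <- profile$z_nm
  d <- profile$density
  half <- max(d) / 2
  s <- d - half
  cross <- which(s[-1] * s[-length(s)] < 0)
  at_zero <- which(s == 0)
  xs <- c(z[at_zero],
          z[cross] + (z[cross + 1] - z[cross]) * (-s[cross]) /
            (s[cross + 1] - s[cross]))
  xs <- sort(unique(xs))
  if (length(xs) != 2L)
    stopf("ambiguous density profile: %d half-maximum crossings (expected 2); profile is multimodal or too noisy",
          length(xs))
  xs[2] - xs[1]
}

#' Local thinning of the membrane near the protein
#'
#' Computes the hydrophobic thickness from a protein-proximal density profile
#' and from the bulk profile over all lipids; thinning is bulk minus local
#' (negative values mean local thickening).
#'
#' @inheritParams density_profile
#' @return list of class `thickness_result`: `local_nm`, `bulk_nm`,
#'   `thinning_nm`, `cutoff_nm`, plus both profiles.
#' @export
thinning_analysis <- function(traj, topology, selection, cutoff_nm = 1.0,
                              exclude_beads = c("NC3", "PO4"), stride_ns = 5,
                              equilibration_ns = 2000, bin_nm = 0.1) {
  loc <- density_profile(traj, topology, selection, mode = "proximal",
                         cutoff_nm = cutoff_nm, exclude_beads = exclude_beads,
                         stride_ns = stride_ns,
                         equilibration_ns = equilibration_ns, bin_nm = bin_nm)
  blk <- density_profile(traj, topology, selection, mode = "bulk",
                         exclude_beads = exclude_beads, stride_ns = stride_ns,
                         equilibration_ns = equilibration_ns, bin_nm = bin_nm)
  lt <- thickness_from_profile(loc)
  bt <- thickness_from_profile(blk)
  structure(list(local_nm = lt, bulk_nm = bt, thinning_nm = bt - lt,
                 cutoff_nm = cutoff_nm, local_profile = loc,
                 bulk_profile = blk),
            class = "thickness_result")
}

#' @export
print.thickness_result <- function(x, ...) {
  cat(sprintf("thickness_result: bulk %.3f nm, local %.3f nm (R = %.2f nm) -> thinning %.3f nm\n",
              x$bulk_nm, x$local_nm, x$cutoff_nm, x$thinning_nm))
  invisible(x)
}

#' Correlation between scrambling rate and membrane thinning
#'
#' Pearson correlation over per-system (mean event rate, thinning) pairs, as
#' a cross-system report.
#'
#' @param mean_rates numeric vector of mean event rates (events/us).
#' @param thinnings numeric vector of thinning values (nm), same order.
#' @return list with `r` (Pearson correlation) and `n`.
#' @export
rate_thinning_correlation <- function(mean_rates, thinnings) {
  stopifnot(length(mean_rates) == length(thinnings),
            length(mean_rates) >= 3L)
  list(r = stats::cor(mean_rates, thinnings), n = length(mean_rates))
}

#' Write a density profile as a two-column TSV
#' @param profile a [density_profile()].
#' @param path output file.
#' @export
write_density_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile)[, c("z_nm", "density")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
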