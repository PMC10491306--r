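# Synthetic coarse-grained bilayer trajectories with a ground-truth event
# ledger.
#
# This is a kinematic fixture generator, not an MD engine: lipids are
# three-bead-chain pseudo-DOPC molecules (12 Martini-3-like beads) placed on
# a lattice, holding leaflet-appropriate orientations (~0 deg upper,
# ~180 deg lower) with clipped-Gaussian angular noise. Flip-flop events
# arrive as a Poisson process at a per-system rate; each flip sweeps the
# orientation angle linearly through the buffer over an exponential dwell.
# An optional cylindrical pseudo-protein supports proximity, thinning and
# pathway analyses; with `pore = TRUE` the headgroups of flipping lipids
# translate along an imposed pathway line adjacent to a known set of
# pore-lining residues. Output is bit-reproducible for a fixed seed.

SYN_LIPID_BEADS <- c("NC3", "PO4", "GL1", "GL2",
                     "C1A", "C2A", "C3A", "C4A",
                     "C1B", "C2B", "C3B", "C4B")
# distance of each bead from the tail-terminal anchor along the lipid
# director (nm); gives ~2.9 nm bulk hydrophobic span and ~4.1 nm head-head
SYN_BEAD_OFFSET <- c(NC3 = 2.05, PO4 = 1.75, GL1 = 1.45, GL2 = 1.45,
                     C1A = 1.20, C2A = 0.80, C3A = 0.40, C4A = 0.00,
                     C1B = 1.20, C2B = 0.80, C3B = 0.40, C4B = 0.00)
# chain splay: +1 for the A chain side, -1 for the B chain side, 0 on axis
SYN_BEAD_SPLAY <- c(NC3 = 0, PO4 = 0, GL1 = 1, GL2 = -1,
                    C1A = 1, C2A = 1, C3A = 1, C4A = 1,
                    C1B = -1, C2B = -1, C3B = -1, C4B = -1)
SYN_HYDROPHOBIC_SPAN <- 2 * SYN_BEAD_OFFSET[["GL1"]]

#' Cylindrical pseudo-protein parameters
#'
#' @param radius_nm cylinder radius.
#' @param height_nm cylinder height (centred on the bilayer midplane).
#' @param n_rings number of bead rings along z.
#' @param beads_per_ring beads (= residues) per ring.
#' @param pore if `TRUE`, flipping headgroups are guided along a pathway
#'   line adjacent to the ring column at azimuth zero, whose residues are
#'   recorded as the pore lining.
#' @return list of class `synthetic_protein`.
#' @export
synthetic_protein <- function(radius_nm = 1.0, height_nm = 4.0,
                              n_rings = 5L, beads_per_ring = 10L,
                              pore = FALSE) {
  stopifnot(radius_nm > 0, height_nm > 0, n_rings >= 1, beads_per_ring >= 3)
  structure(list(radius_nm = radius_nm, height_nm = height_nm,
                 n_rings = as.integer(n_rings),
                 beads_per_ring = as.integer(beads_per_ring),
                 pore = isTRUE(pore)),
            class = "synthetic_protein")
}

#' Specification of a synthetic bilayer simulation
#'
#' Defaults mirror the analysis protocol's study conditions: two replicas of
#' 10 us sampled every 1 ns. `flip_rate` is the expected number of
#' scrambling events per microsecond for the whole system.
#'
#' @param n_lipids_per_leaflet lipids per leaflet.
#' @param duration_ns trajectory length per replica.
#' @param frame_interval_ns frame spacing.
#' @param n_replicas number of replicate trajectories.
#' @param flip_rate expected events per us per system (Poisson).
#' @param transit_dwell_ns mean buffer-transit dwell (exponential, floored
#'   at one frame interval).
#' @param angular_noise_deg sd of the within-leaflet angular noise; the
#'   noise is clipped at 3 sd so excursions are bounded.
#' @param protein optional [synthetic_protein()].
#' @param local_thinning_nm hydrophobic thinning imposed on lipids within
#'   1 nm of the protein surface (0 = none).
#' @param seed root RNG seed; replica streams are derived from it.
#' @param lattice_spacing_nm in-plane lipid lattice spacing.
#' @param box_z_nm box height.
#' @param anchor_z_noise_nm sd of the per-frame rigid z shift of each lipid
#'   (smears the density comb without touching orientation angles).
#' @param bead_jitter_nm sd of independent per-bead positional jitter.
#' @param splay_nm half-distance between the two tail chains.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_lipids_per_leaflet = 64L, duration_ns = 10000,
                           frame_interval_ns = 1, n_replicas = 2L,
                           flip_rate = 2, transit_dwell_ns = 25,
                           angular_noise_deg = 15, protein = NULL,
                           local_thinning_nm = 0, seed = 1L,
                           lattice_spacing_nm = 0.8, box_z_nm = 10,
                           anchor_z_noise_nm = 0.25, bead_jitter_nm = 0.02,
                           splay_nm = 0.12) {
  if (flip_rate < 0) stopf("flip_rate must be >= 0")
  if (transit_dwell_ns < frame_interval_ns)
    stopf("transit_dwell_ns must be at least one frame interval")
  if (3 * angular_noise_deg >= 125)
    stopf("angular_noise_deg too large: 3 sd excursions would cross the buffer")
  if (3 * angular_noise_deg > 55)
    warnf("angular noise 3 sd exceeds 55 deg: excursions will enter the buffer region")
  if (duration_ns < frame_interval_ns) stopf("duration too short")
  if (local_thinning_nm < 0 || local_thinning_nm >= SYN_HYDROPHOBIC_SPAN)
    stopf("local_thinning_nm must be in [0, %.2f)", SYN_HYDROPHOBIC_SPAN)
  if (local_thinning_nm > 0 && is.null(protein))
    stopf("local thinning requires a protein")
  structure(list(
    n_lipids_per_leaflet = as.integer(n_lipids_per_leaflet),
    duration_ns = duration_ns, frame_interval_ns = frame_interval_ns,
    n_replicas = as.integer(n_replicas), flip_rate = flip_rate,
    transit_dwell_ns = transit_dwell_ns,
    angular_noise_deg = angular_noise_deg, protein = protein,
    local_thinning_nm = local_thinning_nm, seed = as.integer(seed),
    lattice_spacing_nm = lattice_spacing_nm, box_z_nm = box_z_nm,
    anchor_z_noise_nm = anchor_z_noise_nm,
    bead_jitter_nm = bead_jitter_nm, splay_nm = splay_nm),
    class = "synthetic_spec")
}

# Static system layout: lattice sites, leaflets, azimuths, thinning scales,
# protein coordinates and the topology. Consumes RNG (azimuths).
syn_layout <- function(spec) {
  n <- spec$n_lipids_per_leaflet
  sp <- spec$lattice_spacing_nm
  prot <- spec$protein
  m <- ceiling(sqrt(n))
  repeat {
    L <- m * sp
    cx <- L / 2
    gx <- ((seq_len(m) - 0.5) * sp)
    sites <- expand.grid(x = gx, y = gx)
    if (!is.null(prot)) {
      rd <- sqrt((sites$x - cx)^2 + (sites$y - cx)^2)
      sites <- sites[rd > prot$radius_nm + 0.45, , drop = FALSE]
    }
    if (nrow(sites) >= n) break
    m <- m + 1L
  }
  sites <- sites[seq_len(n), , drop = FALSE]
  box <- c(m * sp, m * sp, spec$box_z_nm)
  z_mid <- box[3] / 2
  nlip <- 2L * n
  leaflet <- rep(c("UPPER", "LOWER"), each = n)
  x0 <- rep(sites$x, 2L)
  y0 <- rep(sites$y, 2L)
  phi <- stats::runif(nlip, 0, 2 * pi)

  scale <- rep(1, nlip)
  pore_xy <- NULL
  prot_xyz <- NULL
  pore_residues <- integer()
  nprot <- 0L
  if (!is.null(prot)) {
    cx <- box[1] / 2
    thin_r <- prot$radius_nm + 1.0
    rd <- sqrt((x0 - cx)^2 + (y0 - cx)^2)
    if (spec$local_thinning_nm > 0)
      scale[rd <= thin_r] <- 1 - spec$local_thinning_nm / SYN_HYDROPHOBIC_SPAN
    ang <- (seq_len(prot$beads_per_ring) - 1L) * 2 * pi / prot$beads_per_ring
    zl <- if (prot$n_rings == 1L) z_mid else
      z_mid + seq(-prot$height_nm / 2, prot$height_nm / 2,
                  length.out = prot$n_rings)
    prot_xyz <- cbind(
      x = cx + prot$radius_nm * cos(rep(ang, times = prot$n_rings)),
      y = cx + prot$radius_nm * sin(rep(ang, times = prot$n_rings)),
      z = rep(zl, each = prot$beads_per_ring))
    nprot <- nrow(prot_xyz)
    # residue ids continue after the lipids; azimuth-zero column lines the pore
    pore_residues <- nlip + which(rep(ang, times = prot$n_rings) == 0)
    if (prot$pore) pore_xy <- c(cx + prot$radius_nm + 0.35, cx)
  }

  nb <- length(SYN_LIPID_BEADS)
  atoms <- data.frame(
    index = seq_len(nlip * nb + nprot),
    name = c(rep(SYN_LIPID_BEADS, nlip), rep("BB", nprot)),
    resname = c(rep("DOPC", nlip * nb), rep("PRT", nprot)),
    resid = c(rep(seq_len(nlip), each = nb), nlip + seq_len(nprot)))
  topology <- define_groups(cg_topology(atoms, box, source = "synthetic"),
                            lipid_residues = "DOPC")
  list(box = box, z_mid = z_mid, nlip = nlip, leaflet = leaflet,
       x0 = x0, y0 = y0, phi = phi, scale = scale, prot_xyz = prot_xyz,
       pore_xy = pore_xy, pore_residues = pore_residues,
       topology = topology, n_beads = nb)
}

# One replica: event schedule, angle traces and (optionally) coordinates.
syn_replica <- function(spec, layout, rep_seed, replica, mode) {
  set.seed(rep_seed)
  fi <- spec$frame_interval_ns
  times <- seq(0, spec$duration_ns, by = fi)
  nt <- length(times)
  nlip <- layout$nlip
  sigma <- spec$angular_noise_deg

  # --- Poisson flip schedule -------------------------------------------------
  n_ev <- stats::rpois(1, spec$flip_rate * spec$duration_ns / 1000)
  t0s <- sort(stats::runif(n_ev, 0, spec$duration_ns))
  state <- layout$leaflet
  busy_until <- rep(-Inf, nlip)
  sched <- vector("list", n_ev)
  ledger_rows <- vector("list", n_ev)
  frac <- 125 / 180  # ramp fraction at which the far threshold is passed
  for (e in seq_len(n_ev)) {
    t0 <- t0s[e]
    free <- which(busy_until < t0)
    if (!length(free)) next  # all lipids mid-transit; drop this arrival
    l <- free[sample.int(length(free), 1L)]
    dwell <- max(stats::rexp(1, 1 / spec$transit_dwell_ns), fi)
    from <- state[l]
    to <- if (from == "UPPER") "LOWER" else "UPPER"
    t_cross_grid <- fi * (floor((t0 + dwell * frac) / fi) + 1L)
    sched[[e]] <- list(l = l, t0 = t0, dwell = dwell, from = from, to = to)
    if (t_cross_grid <= spec$duration_ns)
      ledger_rows[[e]] <- data.frame(
        lipid_id = l, replica = replica, start_ns = t0,
        completion_ns = t0 + dwell, crossing_ns = t_cross_grid,
        direction = paste0(from, "->", to))
    state[l] <- to
    busy_until[l] <- t0 + dwell
  }
  sched <- Filter(Negate(is.null), sched)
  ledger <- do.call(rbind, Filter(Negate(is.null), ledger_rows))
  if (is.null(ledger))
    ledger <- data.frame(lipid_id = integer(), replica = integer(),
                         start_ns = numeric(), completion_ns = numeric(),
                         crossing_ns = numeric(), direction = character())

  # --- angle traces ----------------------------------------------------------
  base0 <- ifelse(layout$leaflet == "UPPER", 0, 180)
  noise <- matrix(stats::rnorm(nlip * nt, 0, sigma), nlip, nt)
  if (sigma > 0) noise <- pmin(pmax(noise, -3 * sigma), 3 * sigma)
  theta <- base0 + noise
  theta <- abs(theta)
  theta[theta > 180] <- 360 - theta[theta > 180]
  for (s in sched) {
    b0 <- if (s$from == "UPPER") 0 else 180
    b1 <- 180 - b0
    in_ramp <- which(times >= s$t0 & times <= s$t0 + s$dwell)
    theta[s$l, in_ramp] <- b0 + (b1 - b0) * (times[in_ramp] - s$t0) / s$dwell
    after <- which(times > s$t0 + s$dwell)
    if (length(after)) {
      v <- b1 + noise[s$l, after]
      v <- abs(v)
      v[v > 180] <- 360 - v[v > 180]
      theta[s$l, after] <- v
    }
  }
  traces <- orientation_traces(theta, times, seq_len(nlip), replica, fi)
  if (mode == "angles")
    return(list(traces = traces, ledger = ledger))

  # --- coordinates -----------------------------------------------------------
  th <- theta * pi / 180
  sth <- sin(th); cth <- cos(th)
  cphi <- cos(layout$phi); sphi <- sin(layout$phi)
  ux <- sth * cphi; uy <- sth * sphi; uz <- cth
  jn <- function(sd) matrix(stats::rnorm(nlip * nt, 0, sd), nlip, nt)
  ax <- layout$x0 + jn(spec$bead_jitter_nm)
  ay <- layout$y0 + jn(spec$bead_jitter_nm)
  az <- layout$z_mid + jn(spec$anchor_z_noise_nm)
  if (!is.null(layout$pore_xy)) {
    # place the lipid so its headgroup bead tracks the pathway line
    d_head <- SYN_BEAD_OFFSET[["NC3"]] * layout$scale
    for (s in sched) {
      in_ramp <- which(times >= s$t0 & times <= s$t0 + s$dwell)
      ax[s$l, in_ramp] <- layout$pore_xy[1] -
        d_head[s$l] * ux[s$l, in_ramp] +
        stats::rnorm(length(in_ramp), 0, spec$bead_jitter_nm)
      ay[s$l, in_ramp] <- layout$pore_xy[2] -
        d_head[s$l] * uy[s$l, in_ramp] +
        stats::rnorm(length(in_ramp), 0, spec$bead_jitter_nm)
    }
  }
  nb <- layout$n_beads
  nprot <- if (is.null(layout$prot_xyz)) 0L else nrow(layout$prot_xyz)
  coords <- array(0, dim = c(nlip * nb + nprot, 3L, nt))
  px <- -sphi; py <- cphi  # in-plane direction perpendicular to the azimuth
  for (b in seq_len(nb)) {
    d <- SYN_BEAD_OFFSET[b] * layout$scale
    sgn <- SYN_BEAD_SPLAY[b] * spec$splay_nm
    rows <- (seq_len(nlip) - 1L) * nb + b
    coords[rows, 1L, ] <- ax + d * ux + sgn * px + jn(spec$bead_jitter_nm)
    coords[rows, 2L, ] <- ay + d * uy + sgn * py + jn(spec$bead_jitter_nm)
    coords[rows, 3L, ] <- az + d * uz + jn(spec$bead_jitter_nm)
  }
  if (nprot) {
    prow <- nlip * nb + seq_len(nprot)
    for (dim3 in 1:3) coords[prow, dim3, ] <- layout$prot_xyz[, dim3]
  }
  traj <- cg_trajectory(coords, times, layout$box, replica = replica)
  list(traces = traces, ledger = ledger, trajectory = traj)
}

#' Simulate a synthetic bilayer with ground-truth flip-flop events
#'
#' @param spec a [synthetic_spec()].
#' @param mode `"coordinates"` produces full bead trajectories;
#'   `"angles"` produces orientation traces only (fast path for rate
#'   statistics, identical flip schedule and angle noise).
#' @return list of class `synthetic_bilayer`: `topology` (with groups
#'   defined), `trajectories` (coordinate mode) or `NULL`, `traces` (list of
#'   [orientation_traces()], one per replica), and `ledger` (class
#'   `synthetic_ledger`: `events` with `lipid_id`, `replica`, `start_ns`,
#'   `completion_ns`, `crossing_ns` (first sampled time strictly past the
#'   far threshold), `direction`; `leaflets`; `pore_residues`;
#'   `imposed_thinning_nm`).
#' @export
simulate_bilayer <- function(spec, mode = c("coordinates", "angles")) {
  mode <- match.arg(mode)
  set.seed(spec$seed)
  layout <- syn_layout(spec)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_replicas)
  reps <- lapply(seq_len(spec$n_replicas), function(i)
    syn_replica(spec, layout, rep_seeds[i], i - 1L, mode))
  events <- do.call(rbind, lapply(reps, `[[`, "ledger"))
  rownames(events) <- NULL
  ledger <- structure(list(
    events = events,
    leaflets = data.frame(lipid_id = seq_len(layout$nlip),
                          leaflet = layout$leaflet),
    pore_residues = layout$pore_residues,
    imposed_thinning_nm = spec$local_thinning_nm), class = "synthetic_ledger")
  structure(list(
    topology = layout$topology,
    trajectories = if (mode == "coordinates")
      lapply(reps, `[[`, "trajectory") else NULL,
    traces = lapply(reps, `[[`, "traces"),
    ledger = ledger, spec = spec), class = "synthetic_bilayer")
}

#' @export
print.synthetic_bilayer <- function(x, ...) {
  cat(sprintf("synthetic_bilayer: %d lipids, %d replicas x %g ns, %d true events\n",
              nrow(x$ledger$leaflets), x$spec$n_replicas, x$spec$duration_ns,
              nrow(x$ledger$events)))
  invisible(x)
}

#' Write a whole trajectory as a multi-frame GRO file
#'
#' @param traj a [cg_trajectory()].
#' @param topology the matching [cg_topology()].
#' @param path output path.
#' @export
write_trajectory_gro <- function(traj, topology, path) {
  at <- topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    co <- traj$coords[, , f, drop = TRUE]
    lines <- c(
      sprintf("synthetic CG bilayer t= %.4f", traj$times[f]),
      sprintf("%5d", nrow(at)),
      sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
              at$resid %% 100000L, at$resname, substr(at$name, 1L, 5L),
              at$index %% 100000L, co[, 1], co[, 2], co[, 3]),
      sprintf("%10.5f%10.5f%10.5f", traj$box[f, 1], traj$box[f, 2],
              traj$box[f, 3]))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write a synthetic simulation in standard formats
#'
#' Writes `topology.gro` (first frame), one multi-frame GRO trajectory per
#' replica (`traj_rep<k>.gro`) and the ground-truth ledger as
#' `ledger.json`.
#'
#' @param sim a [simulate_bilayer()] result (coordinate mode).
#' @param dir output directory (created if needed).
#' @return named list of written paths.
#' @export
write_synthetic_system <- function(sim, dir) {
  if (is.null(sim$trajectories))
    stopf("simulation was run in angle mode; rerun with mode = 'coordinates'")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  top_path <- file.path(dir, "topology.gro")
  write_gro(sim$topology, sim$trajectories[[1]]$coords[, , 1, drop = TRUE],
            top_path, time_ns = sim$trajectories[[1]]$times[1])
  traj_paths <- vapply(seq_along(sim$trajectories), function(i) {
    p <- file.path(dir, sprintf("traj_rep%d.gro", i - 1L))
    write_trajectory_gro(sim$trajectories[[i]], sim$topology, p)
    p
  }, character(1))
  ledger_path <- file.path(dir, "ledger.json")
  jsonlite::write_json(list(
    events = sim$ledger$events, leaflets = sim$ledger$leaflets,
    pore_residues = sim$ledger$pore_residues,
    imposed_thinning_nm = sim$ledger$imposed_thinning_nm),
    ledger_path, digits = NA)
  list(topology = top_path, trajectories = traj_paths, ledger = ledger_path)
}

#' Match detected events against a ground-truth ledger
#'
#' A detected event matches a ledger event when lipid and direction agree
#' and the detected time is within `tolerance_ns` of the ledger's grid
#' crossing time. Matching is one-to-one and greedy in time order.
#'
#' @param ledger a `synthetic_ledger` (or its `events` data.frame).
#' @param detected detected event data.frame (from [detect_events()]).
#' @param tolerance_ns time tolerance (default: one frame interval's worth,
#'   1 ns).
#' @return list with `n_true`, `n_detected`, `n_matched`, `recall`,
#'   `precision`.
#' @export
match_events <- function(ledger, detected, tolerance_ns = 1) {
  truth <- if (is.data.frame(ledger)) ledger else ledger$events
  used <- rep(FALSE, nrow(detected))
  matched <- 0L
  for (i in seq_len(nrow(truth))) {
    cand <- which(!used &
                    detected$replica == truth$replica[i] &
                    detected$lipid_id == truth$lipid_id[i] &
                    detected$direction == truth$direction[i] &
                    abs(detected$event_time_ns - truth$crossing_ns[i]) <=
                      tolerance_ns + 1e-9)
    if (length(cand)) {
      used[cand[1]] <- TRUE
      matched <- matched + 1L
    }
  }
  list(n_true = nrow(truth), n_detected = nrow(detected),
       n_matched = matched,
       recall = if (nrow(truth)) matched / nrow(truth) else 1,
       precision = if (nrow(detected)) matched / nrow(detected) else 1)
}
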