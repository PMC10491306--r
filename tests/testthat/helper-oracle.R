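# Independent brute-force two-threshold state machine: walks the trace
# sample by sample, keeping leaflet state explicitly. Used as the oracle for
# the vectorised detector.
brute_detect <- function(a, s0, lo = 55, hi = 125) {
  state <- s0
  if (a[1] > hi && state == "UPPER") state <- "LOWER"
  if (a[1] < lo && state == "LOWER") state <- "UPPER"
  idx <- integer()
  dir <- character()
  for (i in seq_along(a)) {
    if (state == "UPPER" && a[i] > hi) {
      idx <- c(idx, i); dir <- c(dir, "UPPER->LOWER"); state <- "LOWER"
    } else if (state == "LOWER" && a[i] < lo) {
      idx <- c(idx, i); dir <- c(dir, "LOWER->UPPER"); state <- "UPPER"
    }
  }
  data.frame(idx = idx, direction = dir)
}

# A minimal flat system: nlip lipids with NC3/C4A/C4B beads at caller-chosen
# z positions, optional extra protein beads. Returns topology, selection and
# a one-frame trajectory.
make_flat_system <- function(head_z, tail_z, head_xy = NULL,
                             protein_xyz = NULL, box = c(10, 10, 10)) {
  nlip <- length(head_z)
  beads <- c("NC3", "C4A", "C4B")
  nprot <- if (is.null(protein_xyz)) 0L else nrow(protein_xyz)
  atoms <- data.frame(
    index = seq_len(3L * nlip + nprot),
    name = c(rep(beads, nlip), rep("BB", nprot)),
    resname = c(rep("DOPC", 3L * nlip), rep("PRT", nprot)),
    resid = c(rep(seq_len(nlip), each = 3L), nlip + seq_len(nprot)))
  topo <- define_groups(cg_topology(atoms, box), lipid_residues = "DOPC")
  if (is.null(head_xy)) head_xy <- cbind(seq_len(nlip), seq_len(nlip))
  co <- matrix(0, nrow(atoms), 3L)
  for (i in seq_len(nlip)) {
    r <- (i - 1L) * 3L
    co[r + 1L, ] <- c(head_xy[i, 1], head_xy[i, 2], head_z[i])
    co[r + 2L, ] <- c(head_xy[i, 1] - 0.1, head_xy[i, 2], tail_z[i])
    co[r + 3L, ] <- c(head_xy[i, 1] + 0.1, head_xy[i, 2], tail_z[i])
  }
  if (nprot) co[3L * nlip + seq_len(nprot), ] <- protein_xyz
  traj <- cg_trajectory(array(co, dim = c(nrow(co), 3L, 1L)),
                        times = 0, box = box)
  sel <- select_lipids(topo)
  list(topology = topo, selection = sel, trajectory = traj,
       frame = get_frame(traj, 1L))
}

# Write a tiny hand-rolled GRO file (optionally multi-frame) and return its
# path; used for reader edge cases.
write_toy_gro <- function(path, natoms = 3L, nframes = 1L, dt = 1) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nframes)) {
    writeLines(sprintf("toy t= %.4f", (f - 1) * dt), con)
    writeLines(sprintf("%5d", natoms), con)
    for (i in seq_len(natoms))
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         i, "DOPC", "NC3", i, i * 0.1, f * 0.1, 0.5), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", 5, 5, 5), con)
  }
  path
}

# Fast rate-protocol run on an angle-mode synthetic simulation.
rate_from_sim <- function(sim, equilibration_ns = 2000, bin_width_ns = 1000,
                          cutoff = 1) {
  ev <- do.call(rbind, lapply(sim$traces, function(tr)
    detect_events(tr, sim$ledger$leaflets)$events))
  t_end <- vapply(sim$traces, function(tr) max(tr$times), numeric(1))
  names(t_end) <- vapply(sim$traces, `[[`, integer(1), "replica")
  b <- bin_events(ev, t_end, equilibration_ns = equilibration_ns,
                  bin_width_ns = bin_width_ns)
  list(events = ev, binned = b,
       summary = summarize_rates(b, cutoff = cutoff))
}
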