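# System topology, file readers and the frame model.
#
# Internal units are nm and ns throughout (GROMACS-native). PDB coordinates
# (Angstrom) are converted on read; DCD frames are assumed to be in Angstrom
# as written by CHARMM/NAMD-lineage codes and are converted as well.

#' Construct a coarse-grained system topology
#'
#' @param atoms data.frame with columns `index`, `name`, `resname`, `resid`.
#' @param box numeric length-3 box vector in nm.
#' @param source optional path the topology was read from.
#' @return An object of class `cg_topology`.
#' @export
cg_topology <- function(atoms, box, source = NA_character_) {
  stopifnot(is.data.frame(atoms),
            all(c("index", "name", "resname", "resid") %in% names(atoms)))
  if (anyDuplicated(atoms$index))
    stopf("topology atom indices must be unique")
  if (!identical(atoms$index, seq_len(nrow(atoms))))
    stopf("topology atom indices must be contiguous in file order")
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stopf("box lengths must be three positive numbers (nm)")
  structure(list(atoms = atoms, box = as.numeric(box),
                 groups = list(), source = source),
            class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf("cg_topology: %d atoms, %d residues, box %.3f x %.3f x %.3f nm\n",
              nrow(x$atoms), length(unique(x$atoms$resid)),
              x$box[1], x$box[2], x$box[3]))
  if (length(x$groups))
    cat("groups:", paste(sprintf("%s (%d)", names(x$groups),
                                 lengths(x$groups)), collapse = ", "), "\n")
  invisible(x)
}

#' Define protein and lipid atom groups on a topology
#'
#' Lipid atoms are those whose residue name is in `lipid_residues`; protein
#' atoms default to every atom that is neither lipid nor solvent/ion.
#'
#' @param topology a [cg_topology()].
#' @param lipid_residues character vector of lipid residue names.
#' @param protein_residues optional character vector of protein residue names;
#'   if `NULL`, the complement of lipids and `solvent_residues` is used.
#' @param solvent_residues residue names treated as solvent/ions.
#' @return The topology with `groups$lipids` and `groups$protein` index sets.
#' @export
define_groups <- function(topology, lipid_residues,
                          protein_residues = NULL,
                          solvent_residues = c("W", "WN", "NA", "CL", "ION")) {
  at <- topology$atoms
  lip <- which(at$resname %in% lipid_residues)
  if (is.null(protein_residues)) {
    prot <- which(!(at$resname %in% c(lipid_residues, solvent_residues)))
  } else {
    prot <- which(at$resname %in% protein_residues)
  }
  if (length(intersect(lip, prot)))
    stopf("protein and lipid groups overlap; check residue names")
  topology$groups <- list(protein = prot, lipids = lip)
  topology
}

# ---- GRO format ------------------------------------------------------------

parse_gro_time <- function(title) {
  m <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1]]
  if (length(m) == 2L) as.numeric(m[2]) else NA_real_
}

#' Read a GRO file (single- or multi-frame)
#'
#' GRO is parsed as fixed-width text with positions in nm. Multi-frame GRO
#' files (concatenated frames, as written by `gmx trjconv` or by
#' [write_trajectory_gro()]) are read as a trajectory; frame times are taken
#' from `t=` annotations in the title lines when present, otherwise from
#' `dt_ns` times the frame index.
#'
#' @param path GRO file path.
#' @param dt_ns fallback frame spacing in ns when titles carry no time.
#' @return list with `topology` ([cg_topology()]), `coords`
#'   (atoms x 3 x frames array, nm), `times` (ns) and `box` (frames x 3, nm).
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) stopf("cannot read GRO file: %s", path)
  lines <- readLines(path)
  if (length(lines) < 3L) stopf("GRO file too short: %s", path)
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms) || natoms < 1L)
    stopf("malformed GRO atom count in %s", path)
  flen <- natoms + 3L
  if (length(lines) %% flen != 0L)
    stopf("GRO file %s: %d lines is not a whole number of %d-line frames",
          path, length(lines), flen)
  nframes <- length(lines) %/% flen
  frame0 <- (seq_len(nframes) - 1L) * flen

  atom_lines1 <- lines[frame0[1] + 2L + seq_len(natoms)]
  atoms <- data.frame(
    index   = seq_len(natoms),
    name    = trimws(substr(atom_lines1, 11L, 15L)),
    resname = trimws(substr(atom_lines1, 6L, 10L)),
    resid   = as.integer(substr(atom_lines1, 1L, 5L))
  )

  all_atom_idx <- as.vector(outer(2L + seq_len(natoms), frame0, "+"))
  al <- lines[all_atom_idx]
  x <- as.numeric(substr(al, 21L, 28L))
  y <- as.numeric(substr(al, 29L, 36L))
  z <- as.numeric(substr(al, 37L, 44L))
  coords <- array(0, dim = c(natoms, 3L, nframes))
  coords[, 1L, ] <- x
  coords[, 2L, ] <- y
  coords[, 3L, ] <- z

  box_lines <- lines[frame0 + flen]
  box <- t(vapply(strsplit(trimws(box_lines), "\\s+"),
                  function(v) as.numeric(v[1:3]), numeric(3)))
  times <- vapply(lines[frame0 + 1L], parse_gro_time, numeric(1),
                  USE.NAMES = FALSE)

  list(topology = cg_topology(atoms, box[1, ], source = path),
       coords = coords, times = times, box = box)
}

#' Write one GRO frame
#'
#' @param topology a [cg_topology()].
#' @param coords atoms x 3 coordinate matrix in nm.
#' @param path output path.
#' @param time_ns frame time written into the title as `t= <ns>`.
#' @param append append to an existing file (multi-frame GRO).
#' @export
write_gro <- function(topology, coords, path, time_ns = 0, append = FALSE) {
  at <- topology$atoms
  n <- nrow(at)
  stopifnot(nrow(coords) == n, ncol(coords) == 3L)
  lines <- c(
    sprintf("synthetic CG bilayer t= %.4f", time_ns),
    sprintf("%5d", n),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            at$resid %% 100000L, at$resname, substr(at$name, 1L, 5L),
            at$index %% 100000L, coords[, 1], coords[, 2], coords[, 3]),
    sprintf("%10.5f%10.5f%10.5f", topology$box[1], topology$box[2],
            topology$box[3])
  )
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# ---- trajectory object -----------------------------------------------------

#' Construct an in-memory trajectory
#'
#' @param coords atoms x 3 x frames array (nm).
#' @param times frame times in ns, strictly increasing.
#' @param box frames x 3 matrix of box lengths (nm) or length-3 vector.
#' @param replica integer replica id (0-based, input file order).
#' @return object of class `cg_trajectory`.
#' @export
cg_trajectory <- function(coords, times, box, replica = 0L) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  nf <- dim(coords)[3]
  if (length(times) != nf) stopf("times length must equal frame count")
  if (nf > 1L && any(diff(times) <= 0))
    stopf("frame times must be strictly increasing within a replica")
  if (any(times < 0)) stopf("frame times must be non-negative")
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3L, byrow = TRUE)
  structure(list(coords = coords, times = as.numeric(times), box = box,
                 replica = as.integer(replica), natoms = dim(coords)[1]),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("cg_trajectory: replica %d, %d atoms, %d frames, t = %.1f..%.1f ns\n",
              x$replica, x$natoms, n_frames(x), x$times[1],
              x$times[n_frames(x)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `cg_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame from a trajectory
#'
#' @param traj a `cg_trajectory`.
#' @param i frame number (1-based).
#' @return list with `time` (ns), `coords` (atoms x 3, nm), `box` (nm),
#'   `replica`; class `cg_frame`.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  structure(list(time = traj$times[i],
                 coords = traj$coords[, , i, drop = TRUE],
                 box = traj$box[i, ], replica = traj$replica),
            class = "cg_frame")
}

# ---- system loader ---------------------------------------------------------

read_pdb_system <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stopf("reading PDB requires the 'bio3d' package")
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  sel <- pdb$atom
  atoms <- data.frame(index = seq_len(nrow(sel)),
                      name = sel$elety, resname = sel$resid,
                      resid = sel$resno)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nf <- nrow(xyz)
  coords <- array(0, dim = c(nrow(atoms), 3L, nf))
  for (f in seq_len(nf)) {
    m <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE) / 10  # A -> nm
    coords[, , f] <- m
  }
  box <- if (!is.null(pdb$cryst1) && length(pdb$cryst1$abc) == 3L &&
             all(pdb$cryst1$abc > 0)) pdb$cryst1$abc / 10 else
    apply(coords[, , 1, drop = FALSE], 2, function(v) diff(range(v)) + 2)
  list(topology = cg_topology(atoms, box, source = path),
       coords = coords, times = rep(NA_real_, nf),
       box = matrix(box, nf, 3L, byrow = TRUE))
}

read_traj_file <- function(path, topology, dt_ns) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "gro") {
    g <- read_gro(path)
    list(coords = g$coords, times = g$times, box = g$box,
         natoms = dim(g$coords)[1])
  } else if (ext == "pdb") {
    p <- read_pdb_system(path)
    list(coords = p$coords, times = p$times, box = p$box,
         natoms = dim(p$coords)[1])
  } else if (ext == "dcd") {
    if (!requireNamespace("bio3d", quietly = TRUE))
      stopf("reading DCD requires the 'bio3d' package")
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    nf <- nrow(xyz)
    na <- ncol(xyz) %/% 3L
    coords <- array(0, dim = c(na, 3L, nf))
    for (f in seq_len(nf))
      coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE) / 10
    list(coords = coords, times = rep(NA_real_, nf),
         box = matrix(topology$box, nf, 3L, byrow = TRUE), natoms = na)
  } else {
    stopf("unsupported trajectory format '.%s' (supported: gro, pdb, dcd): %s",
          ext, path)
  }
}

#' Load a topology plus trajectory files
#'
#' Reads a GRO or PDB topology and one or more trajectory files (GRO, PDB or
#' DCD). Replicates keep their input file order: the i-th trajectory file is
#' tagged replica `i - 1` and the tag is carried through all downstream
#' records. Frames missing time stamps (PDB/DCD) are assigned
#' `dt_ns * (frame - 1)`.
#'
#' @param topology_path GRO or PDB file defining the system.
#' @param trajectory_paths character vector of trajectory files, one replica
#'   each.
#' @param dt_ns frame spacing used when the format stores no times.
#' @return list of class `cg_system` with `topology`, `trajectories` (list of
#'   [cg_trajectory()]) and `reference` (first frame of the topology file).
#' @export
load_system <- function(topology_path, trajectory_paths = character(),
                        dt_ns = 1) {
  ext <- tolower(tools::file_ext(topology_path))
  top <- switch(ext,
    gro = read_gro(topology_path),
    pdb = read_pdb_system(topology_path),
    stopf("unsupported topology format '.%s' (supported: gro, pdb): %s",
          ext, topology_path))
  topo <- top$topology
  trajs <- vector("list", length(trajectory_paths))
  for (i in seq_along(trajectory_paths)) {
    tr <- read_traj_file(trajectory_paths[i], topo, dt_ns)
    if (tr$natoms != nrow(topo$atoms))
      stopf("atom count mismatch: topology %s has %d atoms, trajectory %s has %d",
            topology_path, nrow(topo$atoms), trajectory_paths[i], tr$natoms)
    times <- tr$times
    if (anyNA(times)) times <- (seq_along(times) - 1) * dt_ns
    trajs[[i]] <- cg_trajectory(tr$coords, times, tr$box, replica = i - 1L)
  }
  reference <- structure(list(time = if (anyNA(top$times[1])) 0 else top$times[1],
                              coords = top$coords[, , 1, drop = TRUE],
                              box = topo$box, replica = NA_integer_),
                         class = "cg_frame")
  structure(list(topology = topo, trajectories = trajs,
                 reference = reference), class = "cg_system")
}
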