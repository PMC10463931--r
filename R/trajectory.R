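# Trajectory container, file I/O (PDB topology + DCD coordinates) and the
# RMSD/RMSF analyses. Internal length unit is nanometres; PDB and DCD store
# Angstrom and are converted on read/write.

#' Construct a trajectory
#'
#' @param coords Numeric array frames x atoms x 3, in nanometres.
#' @param topology The bound `ddpd_topology`; atom count must match.
#' @param time_step Optional frame spacing metadata (ps).
#' @return A `ddpd_trajectory`.
#' @export
trajectory <- function(coords, topology, time_step = NULL) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3, dim(coords)[1] >= 1)
  if (dim(coords)[2] != n_atoms(topology)) {
    stop("atom-count mismatch between topology and coordinates")
  }
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  structure(list(coords = coords, topology = topology, time_step = time_step),
            class = "ddpd_trajectory")
}

#' @export
print.ddpd_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat("ddpd_trajectory:", d[1], "frames x", d[2], "atoms (nm)\n")
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]

# frames x 3A matrix in (x1,y1,z1,x2,...) order, Angstrom or nm
flat_xyz <- function(coords) {
  d <- dim(coords)
  m <- aperm(coords, c(1, 3, 2))
  dim(m) <- c(d[1], 3L * d[2])
  m
}

#' Write a topology (+ reference frame) as PDB
#'
#' Emits standard ATOM records through bio3d plus CONECT records for the
#' bond graph, so that a round trip through [load_trajectory()] recovers
#' both coordinates and bonds.
#'
#' @param topology A `ddpd_topology`.
#' @param coords Atoms x 3 matrix (nm) for the single stored frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_topology_pdb <- function(topology, coords, path) {
  a <- topology$atoms
  xyz <- as.vector(t(coords * 10)) # nm -> Angstrom
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno, resid = a$resname,
                   eleno = a$index + 1L, elety = a$name, elesy = a$element)
  if (nrow(topology$bonds)) {
    con <- sprintf("CONECT%5d%5d", topology$bonds$i + 1L, topology$bonds$j + 1L)
    # preserve bond orders in a trailing REMARK (PDB has no order field)
    ord <- sprintf("REMARK 300 BONDORDER %d %d %d",
                   topology$bonds$i + 1L, topology$bonds$j + 1L,
                   topology$bonds$order)
    txt <- readLines(path)
    end <- grep("^END", txt)
    body <- if (length(end)) txt[-end] else txt
    writeLines(c(body, con, ord, "END"), path)
  }
  invisible(path)
}

#' Write trajectory coordinates as CHARMM-format DCD
#'
#' @param traj A `ddpd_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_dcd <- function(traj, path) {
  coords <- traj$coords * 10 # nm -> Angstrom
  F <- dim(coords)[1]; A <- dim(coords)[2]
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(writer) {
    # Fortran unformatted record: payload length before and after
    raw <- writer()
    writeBin(length(raw), con, size = 4L, endian = "little")
    writeBin(raw, con)
    writeBin(length(raw), con, size = 4L, endian = "little")
  }
  # header: CORD + 20 control ints (slot 10 is the float timestep,
  # slot 20 the CHARMM version flag)
  icntrl <- integer(20)
  icntrl[1] <- F; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- F
  icntrl[20] <- 24L
  rec(function() {
    c(charToRaw("CORD"),
      writeBin(icntrl[1:9], raw(), size = 4L, endian = "little"),
      writeBin(1.0, raw(), size = 4L, endian = "little"), # delta, float32
      writeBin(icntrl[11:20], raw(), size = 4L, endian = "little"))
  })
  title <- formatC("Synthetic trajectory written by ddpd3", width = -80)
  title <- substr(paste0(title, strrep(" ", 80)), 1, 80)
  rec(function() c(writeBin(1L, raw(), size = 4L, endian = "little"),
                   charToRaw(title)))
  rec(function() writeBin(as.integer(A), raw(), size = 4L, endian = "little"))
  for (t in seq_len(F)) {
    for (ax in 1:3) {
      rec(function() writeBin(as.numeric(coords[t, , ax]), raw(),
                              size = 4L, endian = "little"))
    }
  }
  invisible(path)
}

#' Read a topology/trajectory pair
#'
#' Reads a PDB topology (ATOM records, elements, CONECT bonds and the
#' bond-order REMARK written by [write_topology_pdb()]) and a DCD coordinate
#' file, converting Angstrom to the internal nanometre unit.
#'
#' @param topology_path PDB file path.
#' @param coords_path DCD file path (XTC/TRR are not supported and error as
#'   unreadable).
#' @return A `ddpd_trajectory`.
#' @export
load_trajectory <- function(topology_path, coords_path) {
  if (!file.exists(topology_path)) stop("topology file not found")
  if (!file.exists(coords_path)) stop("coordinate file not found")
  if (!grepl("\\.dcd$", coords_path, ignore.case = TRUE)) {
    stop("unreadable trajectory format (only DCD is supported)")
  }
  pdb <- bio3d::read.pdb(topology_path)
  at <- pdb$atom
  resfac <- factor(paste(at$chain, at$resno), levels = unique(paste(at$chain, at$resno)))
  elesy <- at$elesy
  if (any(is.na(elesy) | elesy == "")) elesy <- substr(trimws(at$elety), 1, 1)
  atoms <- data.frame(
    index = seq_len(nrow(at)) - 1L,
    element = trimws(elesy),
    name = trimws(at$elety),
    resindex = as.integer(resfac) - 1L,
    resname = at$resid,
    resno = at$resno,
    stringsAsFactors = FALSE
  )
  bonds <- parse_pdb_bonds(topology_path, nrow(at))
  topo <- structure(list(atoms = atoms, bonds = bonds), class = "ddpd_topology")
  dcd <- bio3d::read.dcd(coords_path, verbose = FALSE)
  if (ncol(dcd) != 3L * nrow(at)) {
    stop("atom-count mismatch between topology and trajectory")
  }
  F <- nrow(dcd)
  coords <- array(dcd, dim = c(F, 3L, nrow(at)))
  coords <- aperm(coords, c(1, 3, 2)) / 10 # Angstrom -> nm
  trajectory(coords, topo)
}

# CONECT + bond-order REMARK extraction (bio3d does not expose CONECT)
parse_pdb_bonds <- function(path, natoms) {
  txt <- readLines(path)
  cn <- txt[startsWith(txt, "CONECT")]
  if (!length(cn)) {
    return(data.frame(i = integer(), j = integer(), order = integer()))
  }
  ij <- do.call(rbind, lapply(cn, function(l) {
    as.integer(c(substr(l, 7, 11), substr(l, 12, 16)))
  }))
  bonds <- data.frame(i = ij[, 1] - 1L, j = ij[, 2] - 1L, order = 1L)
  rem <- txt[startsWith(txt, "REMARK 300 BONDORDER")]
  if (length(rem)) {
    parts <- do.call(rbind, lapply(strsplit(rem, "\\s+"), function(p) {
      as.integer(p[4:6])
    }))
    key <- paste(bonds$i, bonds$j)
    ord <- stats::setNames(parts[, 3], paste(parts[, 1] - 1L, parts[, 2] - 1L))
    hit <- key %in% names(ord)
    bonds$order[hit] <- ord[key[hit]]
  }
  validate_bonds(bonds, natoms)
  bonds
}

#' Select atoms by element class
#'
#' @param topology A `ddpd_topology`.
#' @param mode `"all-heavy"` (every non-hydrogen atom) or `"non-carbon"`
#'   (non-hydrogen, non-carbon).
#' @return A `ddpd_atomsel`: list with 0-based `indices` (strictly
#'   increasing) and the `mode` tag.
#' @export
select_atoms <- function(topology, mode = c("all-heavy", "non-carbon")) {
  mode <- match.arg(mode)
  el <- topology$atoms$element
  keep <- if (mode == "all-heavy") el != "H" else !(el %in% c("H", "C"))
  idx <- topology$atoms$index[keep]
  if (!length(idx)) stop("empty atom selection under mode ", mode)
  structure(list(indices = idx, mode = mode), class = "ddpd_atomsel")
}

#' Select residues (full sequence or an MSA-defined pocket)
#'
#' @param topology A `ddpd_topology`.
#' @param level `"full"` or a pocket level tag (`"class"`, `"family"`,
#'   `"subfamily"`, `"target"`); any non-full level requires
#'   `pocket_columns`, `msa` and `target_id`.
#' @param pocket_columns Integer set of 1-based MSA columns defining the
#'   pocket.
#' @param msa A `ddpd_msa` containing `target_id`.
#' @param target_id Target identifier.
#' @return A `ddpd_ressel`: list with 0-based `residues`, `level`,
#'   `pocket_columns`.
#' @export
select_residues <- function(topology, level = "full", pocket_columns = NULL,
                            msa = NULL, target_id = NULL) {
  nr <- n_residues(topology)
  if (level == "full") {
    res <- seq_len(nr) - 1L
  } else {
    stopifnot(!is.null(pocket_columns), !is.null(msa), !is.null(target_id))
    map <- msa_map_of(msa, target_id)
    if (length(map) != nr) stop("MSA row length does not match topology")
    res <- which(map %in% pocket_columns) - 1L
    if (!length(res)) stop("empty residue selection: pocket columns fall in gaps")
  }
  structure(list(residues = res, level = level,
                 pocket_columns = pocket_columns), class = "ddpd_ressel")
}

#' Per-frame RMSD relative to the first frame
#'
#' Each frame is rigid-body superposed onto frame 1 over all atoms before
#' the deviation is computed, so the series is invariant under rigid
#' motions of whole frames; frame 1 maps to 0 by construction.
#'
#' @param traj A `ddpd_trajectory`.
#' @param fit Superpose frames onto the reference first (default). With
#'   `fit = FALSE` the raw deviation of stored coordinates is returned.
#' @return Numeric vector of length F (nm).
#' @export
compute_rmsd <- function(traj, fit = TRUE) {
  xyz <- flat_xyz(traj$coords)
  if (fit) {
    inds <- seq_len(ncol(xyz))
    as.numeric(bio3d::rmsd(a = xyz[1, ], b = xyz, a.inds = inds,
                           b.inds = inds, fit = TRUE))
  } else {
    dev <- sweep(xyz, 2, xyz[1, ])
    sqrt(rowSums(dev^2) / dim(traj$coords)[2])
  }
}

#' Per-residue RMSF over the C-alpha atoms
#'
#' Every frame is superposed onto the mean structure over the C-alpha atoms
#' (the mean is obtained from a first pass fitted to frame 1, then used as
#' the reference for a second fit), and the fluctuation of residue r is
#' sqrt(mean_t |x_r(t) - mean x_r|^2).
#'
#' @param traj A `ddpd_trajectory`; every residue must have exactly one CA.
#' @return Numeric vector, one value per residue (nm).
#' @export
compute_rmsf <- function(traj) {
  ca <- ca_indices(traj$topology) + 1L
  coords <- traj$coords[, ca, , drop = FALSE]
  xyz <- flat_xyz(coords)
  inds <- seq_len(ncol(xyz))
  fit1 <- bio3d::fit.xyz(fixed = xyz[1, ], mobile = xyz,
                         fixed.inds = inds, mobile.inds = inds)
  mean1 <- colMeans(fit1)
  fit2 <- bio3d::fit.xyz(fixed = mean1, mobile = fit1,
                         fixed.inds = inds, mobile.inds = inds)
  mu <- colMeans(fit2)
  dev2 <- sweep(fit2, 2, mu)^2
  # per-atom: squared deviation summed over x,y,z, averaged over frames
  sqrt(colSums(matrix(colMeans(dev2), nrow = 3)))
}

#' Align a per-residue RMSF series to MSA columns
#'
#' @param rmsf Numeric vector, one value per residue of `target_id`.
#' @param msa A `ddpd_msa`.
#' @param target_id Target identifier present in the MSA.
#' @return Numeric vector of length L with the residue values at their
#'   alignment columns and `NA` at the target's gap columns.
#' @export
map_rmsf_to_msa <- function(rmsf, msa, target_id) {
  map <- msa_map_of(msa, target_id)
  if (length(rmsf) != length(map)) {
    stop("RMSF length does not match the target's ungapped MSA length")
  }
  out <- rep(NA_real_, msa$L)
  out[map] <- rmsf
  out
}
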