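# The dynamic-descriptor engine: sub-trajectory coordinate statistics plus a
# partial-charge channel, min-max standardization, and a two-stage PCA that
# condenses atoms to residues (rs3DDPD) or atoms to whole targets (ps3DDPD).

#' Descriptor generation configuration
#'
#' Defaults are the optimized settings: residue-specific descriptors use
#' rigidity mode (per-axis coordinate SD only) over 100-frame splits, keep
#' 95% of atom-stage variance and 5 residue-stage PCs on all heavy atoms of
#' the full sequence; protein-specific descriptors use coordinate mode
#' (mean, median and SD) with the same frame split, variance rule and atom
#' selection.
#'
#' @param kind `"rs"` (residue-specific) or `"ps"` (protein-specific).
#' @param mode `"coordinate"` (mean + median + SD) or `"rigidity"` (SD only).
#' @param frame_split Frames per sub-trajectory f (>= 2).
#' @param atom_variance Fraction of variance retained by the atom-stage PCA
#'   (0 < v <= 1).
#' @param residue_pcs Residue-stage PCs n (rs only, >= 1).
#' @param atom_selection `"all-heavy"` or `"non-carbon"`.
#' @param residue_selection `"full"` or a pocket level tag.
#' @param pocket_columns Optional 1-based MSA columns defining the pocket.
#' @return A `ddpd_config` list.
#' @export
ddpd_config <- function(kind = c("rs", "ps"), mode = NULL, frame_split = 100,
                        atom_variance = 0.95, residue_pcs = 5,
                        atom_selection = "all-heavy",
                        residue_selection = "full", pocket_columns = NULL) {
  kind <- match.arg(kind)
  if (is.null(mode)) mode <- if (kind == "rs") "rigidity" else "coordinate"
  mode <- match.arg(mode, c("coordinate", "rigidity"))
  stopifnot(frame_split >= 2, atom_variance > 0, atom_variance <= 1,
            residue_pcs >= 1)
  structure(list(kind = kind, mode = mode, frame_split = frame_split,
                 atom_variance = atom_variance, residue_pcs = residue_pcs,
                 atom_selection = atom_selection,
                 residue_selection = residue_selection,
                 pocket_columns = pocket_columns), class = "ddpd_config")
}

config_fingerprint <- function(config) {
  paste(config$kind, config$mode, config$frame_split, config$atom_variance,
        if (config$kind == "rs") config$residue_pcs else "-",
        config$atom_selection, config$residue_selection, sep = "|")
}

#' Split a trajectory into equal sub-trajectories
#'
#' @param n_frames Total frame count F.
#' @param frame_split Frames per sub-trajectory f (2 <= f <= F).
#' @return List of S = floor(F/f) integer ranges (1-based, contiguous,
#'   non-overlapping); trailing remainder frames are dropped.
#' @export
split_subtrajectories <- function(n_frames, frame_split) {
  if (frame_split < 2) stop("frame_split must be >= 2")
  if (n_frames < frame_split) stop("trajectory shorter than one split")
  S <- n_frames %/% frame_split
  lapply(seq_len(S), function(s) ((s - 1L) * frame_split + 1L):(s * frame_split))
}

pop_sd <- function(x) sqrt(mean(x^2) - mean(x)^2)

#' Per-atom sub-trajectory coordinate statistics
#'
#' For each selected atom, sub-trajectory and axis, computes the mean,
#' median and population SD of the coordinate (coordinate mode) or the SD
#' only (rigidity mode). Columns are ordered sub-trajectory-major, axis
#' next, statistic innermost.
#'
#' @param traj A `ddpd_trajectory`.
#' @param ranges Frame ranges from [split_subtrajectories()].
#' @param mode `"coordinate"` or `"rigidity"`.
#' @param selection A `ddpd_atomsel`.
#' @return Numeric matrix, selected atoms x (9S or 3S) named columns.
#' @export
subtrajectory_statistics <- function(traj, ranges, mode, selection) {
  idx <- selection$indices + 1L
  if (!length(idx)) stop("empty atom selection")
  stats_set <- if (mode == "coordinate") c("mean", "median", "sd") else "sd"
  axes <- c("x", "y", "z")
  cols <- list()
  for (s in seq_along(ranges)) {
    sub <- traj$coords[ranges[[s]], idx, , drop = FALSE]
    for (ax in 1:3) {
      m <- sub[, , ax, drop = FALSE]
      dim(m) <- dim(sub)[1:2]
      for (st in stats_set) {
        v <- switch(st,
                    mean = colMeans(m),
                    median = apply(m, 2, stats::median),
                    sd = sqrt(pmax(0, colMeans(m^2) - colMeans(m)^2)))
        cols[[sprintf("s%d_%s_%s", s, axes[ax], st)]] <- v
      }
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- selection$indices
  out
}

#' Append the partial-charge column to an atom statistics matrix
#'
#' @param stats Matrix from [subtrajectory_statistics()].
#' @param charges Per-atom charge vector covering the whole topology.
#' @param selection The `ddpd_atomsel` used for `stats`.
#' @return Matrix with one extra `charge` column.
#' @export
assemble_feature_matrix <- function(stats, charges, selection) {
  if (nrow(stats) != length(selection$indices)) {
    stop("selection/statistics row mismatch")
  }
  if (length(charges) <= max(selection$indices)) {
    stop("charge series does not cover all topology atoms")
  }
  cbind(stats, charge = charges[selection$indices + 1L])
}

#' Min-max standardize a matrix column-wise to [0, 1]
#'
#' Constant columns map to all zeros, keeping gap and constant channels
#' inert.
#'
#' @param x Numeric matrix without non-finite entries.
#' @return Matrix of the same shape.
#' @export
minmax_standardize <- function(x) {
  stopifnot(all(is.finite(x)))
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  rng <- hi - lo
  out <- sweep(sweep(x, 2, lo), 2, ifelse(rng == 0, 1, rng), "/")
  out[, rng == 0] <- 0
  out
}

#' PCA projection with a deterministic sign convention
#'
#' Columns are mean-centred, principal axes are computed by singular value
#' decomposition, and each axis is oriented so its largest-magnitude
#' loading is positive. The number of retained components is either a fixed
#' count or the smallest k whose cumulative explained variance reaches a
#' fraction.
#'
#' @param x Numeric matrix (rows >= 2).
#' @param k Fixed component count, or `NULL` to use `var_frac`.
#' @param var_frac Explained-variance threshold in (0, 1].
#' @return List with `scores` (rows x k), `k`, `explained` (all component
#'   variance fractions) and `rotation`.
#' @export
pca_project <- function(x, k = NULL, var_frac = NULL) {
  stopifnot(nrow(x) >= 2, !is.null(k) || !is.null(var_frac))
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  vars <- p$sdev^2
  if (sum(vars) == 0) stop("matrix has rank 0: no variance to project")
  expl <- vars / sum(vars)
  nz <- sum(vars > max(vars) * 1e-12)
  if (is.null(k)) {
    k <- which(cumsum(expl) >= var_frac - 1e-12)[1]
  } else if (k > nz) {
    stop("requested ", k, " components but rank is ", nz)
  }
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  scores <- p$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, k = k, explained = expl, rotation = rot)
}

new_descriptor <- function(values, kind, target, config, m = NULL) {
  structure(values, class = "ddpd_descriptor", kind = kind, target = target,
            config = config_fingerprint(config), m = m)
}

#' @export
print.ddpd_descriptor <- function(x, ...) {
  cat(sprintf("%s3DDPD for %s: %d features\n", attr(x, "kind"),
              attr(x, "target"), length(x)))
  invisible(x)
}

# shared front half of both descriptor flavours: selection -> statistics ->
# charge channel
atom_feature_matrix <- function(traj, config, msa = NULL, target_id = NULL) {
  topo <- traj$topology
  asel <- select_atoms(topo, config$atom_selection)
  rsel <- select_residues(topo, config$residue_selection,
                          config$pocket_columns, msa, target_id)
  keep <- topo$atoms$resindex[asel$indices + 1L] %in% rsel$residues
  asel$indices <- asel$indices[keep]
  if (!length(asel$indices)) stop("empty atom selection after residue filter")
  ranges <- split_subtrajectories(n_frames(traj), config$frame_split)
  stats <- subtrajectory_statistics(traj, ranges, config$mode, asel)
  charges <- gasteiger_charges(topo)
  list(matrix = assemble_feature_matrix(stats, charges, asel),
       selection = asel, residues = rsel$residues, S = length(ranges))
}

#' Residue-specific dynamic descriptor (rs3DDPD)
#'
#' Pipeline: per-atom sub-trajectory statistics plus the charge channel are
#' min-max standardized per target and reduced by an atom-stage PCA at the
#' configured variance threshold; atom-PC scores are grouped per residue as
#' mean and population SD; the residue matrix is standardized again and
#' reduced to exactly `residue_pcs` components; residue scores are placed
#' at the target's alignment columns, position-major, with zeros at gap
#' columns. The result has length `residue_pcs * L` and feature names
#' `AA{column}_PC{c}`.
#'
#' @param traj A `ddpd_trajectory`.
#' @param msa A `ddpd_msa` containing `target_id`; the target's ungapped
#'   length must equal the topology residue count.
#' @param target_id Target identifier.
#' @param config A `ddpd_config` (kind "rs").
#' @return A named `ddpd_descriptor` vector of length `residue_pcs * L`.
#' @export
compute_rs3ddpd <- function(traj, msa, target_id, config = ddpd_config("rs")) {
  map <- msa_map_of(msa, target_id)
  topo <- traj$topology
  if (length(map) != n_residues(topo)) {
    stop("topology residue count does not match the target's MSA row")
  }
  afm <- atom_feature_matrix(traj, config, msa, target_id)
  std <- minmax_standardize(afm$matrix)
  atom_pca <- pca_project(std, var_frac = config$atom_variance)
  res_of_atom <- topo$atoms$resindex[afm$selection$indices + 1L]
  res_levels <- sort(unique(afm$residues))
  k <- atom_pca$k
  res_mat <- matrix(0, length(res_levels), 2L * k)
  for (r in seq_along(res_levels)) {
    rows <- atom_pca$scores[res_of_atom == res_levels[r], , drop = FALSE]
    res_mat[r, ] <- as.vector(rbind(colMeans(rows),
                                    apply(rows, 2, pop_sd)))
  }
  n <- config$residue_pcs
  if (length(res_levels) <= n) {
    stop("fewer residues than residue PCs: residue PCA is rank deficient")
  }
  res_pca <- pca_project(minmax_standardize(res_mat), k = n)
  L <- msa$L
  values <- numeric(n * L)
  names(values) <- paste0("AA", rep(seq_len(L), each = n), "_PC",
                          rep(seq_len(n), L))
  cols <- map[res_levels + 1L]
  for (r in seq_along(res_levels)) {
    values[(cols[r] - 1L) * n + seq_len(n)] <- res_pca$scores[r, ]
  }
  new_descriptor(values, "rs", target_id, config)
}

#' Protein-specific dynamic descriptors (ps3DDPD)
#'
#' Per-target atom feature matrices (same statistics mode) are truncated to
#' the minimum shared sub-trajectory count, stacked across targets, min-max
#' standardized globally and reduced by one atom-stage PCA at the
#' configured variance threshold (retaining m components). Each target's
#' descriptor aggregates every component's scores over that target's atoms
#' as average, median and population SD, PC-major, giving length `3 m`.
#'
#' @param per_target_data Named list (>= 2 targets) of `ddpd_trajectory`.
#' @param config A `ddpd_config` (kind "ps").
#' @return Named list of `ddpd_descriptor` vectors, all of length `3 m`.
#' @export
compute_ps3ddpd <- function(per_target_data, config = ddpd_config("ps")) {
  ids <- names(per_target_data)
  if (length(ids) < 2) stop("ps3DDPD requires at least two targets")
  afms <- lapply(per_target_data, atom_feature_matrix, config = config)
  n_stats <- if (config$mode == "coordinate") 9L else 3L
  S_min <- min(vapply(afms, `[[`, integer(1), "S"))
  trunc <- lapply(afms, function(a) {
    keep <- seq_len(n_stats * S_min)
    cbind(a$matrix[, keep, drop = FALSE],
          charge = a$matrix[, ncol(a$matrix)])
  })
  stacked <- do.call(rbind, trunc)
  group <- rep(ids, vapply(trunc, nrow, integer(1)))
  std <- minmax_standardize(stacked)
  pca <- pca_project(std, var_frac = config$atom_variance)
  m <- pca$k
  nms <- paste0("PC", rep(seq_len(m), each = 3), "_",
                rep(c("avg", "median", "sd"), m))
  out <- lapply(ids, function(id) {
    sc <- pca$scores[group == id, , drop = FALSE]
    v <- as.vector(rbind(colMeans(sc),
                         apply(sc, 2, stats::median),
                         apply(sc, 2, pop_sd)))
    names(v) <- nms
    new_descriptor(v, "ps", id, config, m = m)
  })
  stats::setNames(out, ids)
}

#' Write descriptor vectors as CSV
#'
#' One row per target, header of feature names; re-runs are bit-exact
#' because descriptor generation contains no randomness.
#'
#' @param descriptors A single `ddpd_descriptor` or a named list of them
#'   with identical feature names.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_descriptor_csv <- function(descriptors, path) {
  if (inherits(descriptors, "ddpd_descriptor")) {
    descriptors <- stats::setNames(list(descriptors),
                                   attr(descriptors, "target"))
  }
  mat <- do.call(rbind, lapply(descriptors, as.numeric))
  colnames(mat) <- names(descriptors[[1]])
  df <- data.frame(target_id = names(descriptors), mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read descriptor vectors from CSV
#'
#' @param path CSV written by [write_descriptor_csv()].
#' @return Named list of numeric feature vectors.
#' @export
read_descriptor_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    v <- as.numeric(df[i, -1])
    names(v) <- colnames(df)[-1]
    v
  })
  stats::setNames(out, df$target_id)
}
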