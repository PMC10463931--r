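# Synthetic fixture generators: topologies come from synth_topology(); here
# live the trajectory, alignment and bioactivity generators. All are
# bit-reproducible under a fixed seed.

#' Coarse helical reference coordinates
#'
#' Places each residue's atoms around an ideal alpha-helix path (CA radius
#' 0.23 nm, rise 0.15 nm, 100 degree turn per residue) with small fixed
#' per-atom offsets, so that superposition-based analyses are non-degenerate.
#'
#' @param topology A `ddpd_topology`.
#' @return Numeric matrix (atoms x 3), in nanometres.
#' @export
helix_reference <- function(topology) {
  a <- topology$atoms
  n <- nrow(a)
  ref <- matrix(0, n, 3)
  turn <- 100 * pi / 180
  within <- stats::ave(seq_len(n), a$resindex, FUN = seq_along)
  for (i in seq_len(n)) {
    r <- a$resindex[i]
    th <- r * turn
    ca <- c(0.23 * cos(th), 0.23 * sin(th), 0.15 * r)
    # deterministic small offset per within-residue atom position
    k <- within[i] - 1L
    off <- 0.05 * c(cos(1.7 * k + th), sin(1.7 * k + th), (k %% 3 - 1) / 3)
    ref[i, ] <- ca + if (a$name[i] == "CA") 0 else off
  }
  ref
}

#' Per-residue fluctuation profile
#'
#' Bundles the parameters of the isotropic Gaussian fluctuation model used by
#' [synth_trajectory()]: frame `t` coordinates are the reference plus an
#' independent per-axis Gaussian displacement whose SD is the residue's
#' `sigma`. Displacements are i.i.d. across frames, atoms and axes, so the
#' expected RMSF of a residue with per-axis SD sigma is sigma * sqrt(3).
#'
#' @param topology A `ddpd_topology`.
#' @param sigma Per-residue displacement SD (nm); scalar or one per residue.
#' @param n_frames Number of frames F (>= 2).
#' @param seed Integer seed; identical seed and parameters give bit-identical
#'   trajectories.
#' @param reference Optional atoms x 3 reference matrix (nm); defaults to
#'   [helix_reference()].
#' @return A `ddpd_profile` list.
#' @export
fluctuation_profile <- function(topology, sigma, n_frames = 2500, seed = 1,
                                reference = NULL) {
  nr <- n_residues(topology)
  sigma <- rep_len(sigma, nr)
  stopifnot(all(sigma >= 0), n_frames >= 2)
  if (is.null(reference)) reference <- helix_reference(topology)
  stopifnot(nrow(reference) == n_atoms(topology), ncol(reference) == 3)
  structure(list(topology = topology, sigma = sigma, n_frames = n_frames,
                 seed = as.integer(seed), reference = reference),
            class = "ddpd_profile")
}

#' Simulate an isotropic Gaussian-fluctuation trajectory
#'
#' @param topology A `ddpd_topology`; must match the profile's topology.
#' @param profile A [fluctuation_profile()].
#' @return A `ddpd_trajectory` (see [trajectory()]).
#' @export
synth_trajectory <- function(topology, profile) {
  if (length(profile$sigma) != n_residues(topology)) {
    stop("profile length does not match residue count")
  }
  A <- n_atoms(topology)
  F <- profile$n_frames
  sd_at <- profile$sigma[topology$atoms$resindex + 1L]
  coords <- withr_seed(profile$seed, {
    noise <- array(stats::rnorm(F * A * 3L, sd = rep(sd_at, each = F)),
                   dim = c(F, A, 3L))
    ref <- array(rep(profile$reference, each = F), dim = c(F, A, 3L))
    ref + noise
  })
  trajectory(coords, topology)
}

#' Simulate a trajectory with low-rank sub-trajectory drift
#'
#' Generates coordinates whose sub-trajectory structure follows a
#' `k`-dimensional latent factor model: within each block of `frame_split`
#' frames the mean position of every atom is the reference plus a linear
#' combination of `k` random factor patterns, and the within-block noise SD
#' is modulated log-linearly by the same factors. The resulting per-atom
#' sub-trajectory statistics matrix therefore has (up to estimation noise)
#' exactly `k` dominant variance directions -- the knob used to exercise the
#' explained-variance rule of the atom-stage PCA at a chosen rank.
#'
#' @param topology A `ddpd_topology`.
#' @param n_frames Total frames F.
#' @param frame_split Frames per sub-trajectory block f.
#' @param k Number of latent factors.
#' @param loadings Optional atoms x k loading matrix; drawn N(0,1) by default.
#' @param drift_scale SD (nm) of the factor-driven block-mean displacement.
#' @param noise_sd Baseline within-block noise SD (nm).
#' @param noise_mod Relative modulation of the noise SD by the factors
#'   (0 = constant noise; the modulated SD is clipped at 10% of
#'   `noise_sd`, so keep `noise_mod` below ~0.6 for near-linearity).
#' @param include_reference Add the helical reference to the block means
#'   (default). With `FALSE` the block means are pure factor mixtures, so
#'   the statistics matrix has exactly `k` dominant variance directions --
#'   the configuration used to exercise the explained-variance rule at a
#'   chosen rank.
#' @param seed Integer seed for the factor structure (loadings and
#'   patterns).
#' @param noise_seed Optional separate seed for the within-block noise;
#'   targets generated with a shared `seed` but distinct `noise_seed`s are
#'   replicates of one factor structure (so a stack of them keeps exactly
#'   `k` dominant directions) while differing in their noise realizations.
#' @return A `ddpd_trajectory`.
#' @export
synth_factor_trajectory <- function(topology, n_frames = 2500,
                                    frame_split = 100, k = 10,
                                    loadings = NULL, drift_scale = 0.3,
                                    noise_sd = 0.02, noise_mod = 0.4,
                                    include_reference = TRUE, seed = 1,
                                    noise_seed = NULL) {
  A <- n_atoms(topology)
  S <- n_frames %/% frame_split
  stopifnot(S >= 2, k >= 1)
  ref <- if (include_reference) helix_reference(topology) else
    matrix(0, A, 3)
  # loadings and patterns are orthonormalized (then rescaled to unit entry
  # variance) so the k latent directions carry equal energy: the dominant
  # variance shares of the resulting statistics matrix are nearly equal
  orth <- function(n, k) {
    q <- qr.Q(qr(matrix(stats::rnorm(n * k), n, k)))
    q * sqrt(n)
  }
  str <- withr_seed(seed, {
    W <- if (is.null(loadings)) orth(A, k) else loadings
    stopifnot(nrow(W) == A, ncol(W) == k)
    B3 <- t(orth(3L * S, k))
    list(W = W,
         B = array(B3, dim = c(k, S, 3L)),
         bs = t(orth(S, min(k, S)))[rep_len(seq_len(min(k, S)), k), ,
                                    drop = FALSE])
  })
  W <- str$W; B <- str$B; bs <- str$bs
  withr_seed(if (is.null(noise_seed)) seed + 1L else noise_seed, {
    coords <- array(0, dim = c(n_frames, A, 3L))
    for (s in seq_len(S)) {
      rows <- ((s - 1L) * frame_split + 1L):(s * frame_split)
      sd_at <- noise_sd *
        pmax(0.1, 1 + noise_mod * drop(W %*% bs[, s]) / sqrt(k))
      for (ax in 1:3) {
        mu <- ref[, ax] + drift_scale * drop(W %*% B[, s, ax]) / sqrt(k)
        coords[rows, , ax] <-
          matrix(mu, length(rows), A, byrow = TRUE) +
          matrix(stats::rnorm(length(rows) * A, sd = rep(sd_at, each = length(rows))),
                 length(rows), A)
      }
    }
    # frames beyond S*frame_split stay at the reference (they are dropped by
    # the frame-split rule anyway)
    if (S * frame_split < n_frames) {
      extra <- (S * frame_split + 1L):n_frames
      for (ax in 1:3) coords[extra, , ax] <-
          matrix(ref[, ax], length(extra), A, byrow = TRUE)
    }
    trajectory(coords, topology)
  })
}

#' Build a synthetic aligned-FASTA MSA
#'
#' Each sequence is laid into an alignment of exactly `pad_to` columns:
#' columns listed in `gap_plan` for that id are gaps, residues fill the
#' remaining columns left to right, and trailing columns are padded with
#' gaps.
#'
#' @param sequences Named character vector of one-letter residue strings.
#' @param gap_plan Named list: id -> integer vector of 1-based gap columns.
#' @param pad_to Total alignment columns L; must leave room for every
#'   sequence's residues.
#' @return A `ddpd_msa` (see [parse_msa()]).
#' @export
synth_msa <- function(sequences, gap_plan = list(), pad_to = NULL) {
  stopifnot(length(sequences) >= 1, !is.null(names(sequences)))
  if (is.null(pad_to)) {
    pad_to <- max(vapply(names(sequences), function(id) {
      nchar(sequences[[id]]) + length(gap_plan[[id]])
    }, numeric(1)))
  }
  rows <- vapply(names(sequences), function(id) {
    seq <- strsplit(sequences[[id]], "")[[1]]
    gaps <- gap_plan[[id]]
    free <- setdiff(seq_len(pad_to), gaps)
    if (length(free) < length(seq)) stop("pad_to too small for ", id)
    row <- rep("-", pad_to)
    row[free[seq_along(seq)]] <- seq
    paste(row, collapse = "")
  }, character(1))
  new_msa(names(sequences), unname(rows))
}

#' Fixed pool of valid drug-like SMILES
#'
#' Fifty neutral organic molecules (analgesics-like scaffolds, substituted
#' benzenes, heterocycles and short chains) embedded so compound
#' fingerprints vary without external files.
#'
#' @return Character vector of SMILES strings.
#' @export
ddpd_smiles_pool <- function() {
  c(
    "CC(=O)Oc1ccccc1C(=O)O",          # aspirin
    "CC(=O)Nc1ccc(O)cc1",             # paracetamol
    "CC(C)Cc1ccc(cc1)C(C)C(=O)O",     # ibuprofen
    "Cn1cnc2c1c(=O)n(C)c(=O)n2C",     # caffeine
    "c1ccc2[nH]ccc2c1",               # indole
    "c1ccc2ncccc2c1",                 # quinoline
    "c1cncnc1",                       # pyrimidine
    "c1ccsc1", "c1ccoc1", "c1cc[nH]c1",
    "c1ccncc1", "c1ccc(cc1)O", "c1ccc(cc1)N",
    "c1ccc(cc1)C(=O)O", "c1ccc(cc1)C=O", "c1ccc(cc1)C#N",
    "c1ccc(cc1)S(=O)(=O)N", "c1ccc(cc1)Cl", "c1ccc(cc1)F",
    "c1ccc(cc1)Br", "Cc1ccccc1", "CCc1ccccc1",
    "COc1ccccc1", "CSc1ccccc1", "CNc1ccccc1",
    "Cc1ccccc1C", "Cc1ccc(C)cc1", "Oc1ccc(Cl)cc1",
    "Nc1ccc(O)cc1", "OC(=O)c1ccccc1O",
    "CCO", "CCCO", "CCCCO", "CC(C)O", "CC(C)(C)O",
    "CCN", "CCCN", "CC(=O)C", "CC(=O)CC", "CCOC(=O)C",
    "CC(=O)OC", "NCCO", "OCCO", "CC#N", "CC(=O)N",
    "C1CCCCC1", "C1CCNCC1", "C1CCOC1", "C1CCSC1",
    "CC1CCCCC1"
  )
}

#' Generate an additive-effect synthetic bioactivity table
#'
#' pChEMBL = `global_mean` + target effect + compound effect + Gaussian
#' noise; target and compound effects are drawn once from centred normals
#' with the given scales, compounds are sampled per target without
#' replacement from the SMILES pool (so compounds are shared across targets,
#' as in a proteochemometric set), and years are uniform over `year_range`.
#'
#' @param n_targets Number of targets T (>= 1).
#' @param compounds_per_target Compounds sampled for each target (<= pool
#'   size).
#' @param target_scale,compound_scale SDs of the additive effects (>= 0).
#' @param noise_sd Residual noise SD (>= 0).
#' @param year_range Integer vector c(first, last) publication year.
#' @param global_mean Grand mean pChEMBL.
#' @param seed Integer seed.
#' @param smiles_pool Pool of valid SMILES; defaults to [ddpd_smiles_pool()].
#' @return data.frame with columns `target_id`, `SMILES`, `pchembl_value`,
#'   `year`; attributes `target_effects` and `compound_effects` expose the
#'   injected effects for oracle checks.
#' @export
synth_bioactivity <- function(n_targets, compounds_per_target,
                              target_scale = 1, compound_scale = 1,
                              noise_sd = 0.3, year_range = c(2005, 2020),
                              global_mean = 6.5, seed = 1,
                              smiles_pool = ddpd_smiles_pool()) {
  stopifnot(n_targets >= 1, target_scale >= 0, compound_scale >= 0,
            noise_sd >= 0)
  if (length(smiles_pool) == 0) stop("empty SMILES pool")
  if (compounds_per_target > length(smiles_pool)) {
    stop("compounds_per_target exceeds SMILES pool size")
  }
  withr_seed(seed, {
    tid <- sprintf("T%03d", seq_len(n_targets))
    te <- stats::rnorm(n_targets, 0, target_scale)
    ce <- stats::rnorm(length(smiles_pool), 0, compound_scale)
    names(te) <- tid
    names(ce) <- smiles_pool
    rec <- do.call(rbind, lapply(seq_len(n_targets), function(t) {
      cpd <- sample(smiles_pool, compounds_per_target)
      data.frame(target_id = tid[t], SMILES = cpd,
                 pchembl_value = global_mean + te[t] + ce[cpd] +
                   stats::rnorm(compounds_per_target, 0, noise_sd),
                 year = sample(seq(year_range[1], year_range[2]),
                               compounds_per_target, replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    rownames(rec) <- NULL
    attr(rec, "target_effects") <- te
    attr(rec, "compound_effects") <- ce
    rec
  })
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
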