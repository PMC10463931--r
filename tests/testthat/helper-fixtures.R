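# Shared builders and independent oracles. Expensive fixtures are cached per
# test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# an all-alanine MSA row for a target of n residues, padded to L columns
one_target_msa <- function(n, L = NULL, id = "TGT", gap_plan = list()) {
  synth_msa(stats::setNames(paste(rep("A", n), collapse = ""), id),
            gap_plan = gap_plan, pad_to = L)
}

# 40-residue backbone topology + factor trajectory: the standard rich fixture
# able to sustain the default descriptor configuration (5 residue PCs)
rich_fixture <- function() {
  cached("rich", function() {
    topo <- synth_topology(40)
    traj <- synth_factor_trajectory(topo, n_frames = 2500, k = 8,
                                    noise_sd = 0.05, noise_mod = 0.5,
                                    seed = 11)
    list(topology = topo, traj = traj)
  })
}

# brute-force covariance-eigendecomposition PCA oracle with the same sign
# convention as pca_project
oracle_pca_scores <- function(x, k) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  eg <- eigen(stats::cov(xc), symmetric = TRUE)
  v <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  xc %*% v
}

# O(n^3) agglomerative oracle: merge heights under average linkage computed
# as the mean of all inter-cluster original distances (UPGMA)
oracle_agglom_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < best[1]) best <- c(dd, j, i)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# small hand-built molecules for the charge tests
ethanol_topology <- function() {
  structure(list(
    atoms = data.frame(
      index = 0:8,
      element = c("C", "C", "O", "H", "H", "H", "H", "H", "H"),
      name = c("C1", "C2", "O1", paste0("H", 1:6)),
      resindex = 0L, resname = "ETH", resno = 1L, stringsAsFactors = FALSE),
    bonds = data.frame(i = c(0, 1, 0, 0, 0, 1, 1, 2),
                       j = c(1, 2, 3, 4, 5, 6, 7, 8), order = 1L)
  ), class = "ddpd_topology")
}

methane_topology <- function() {
  structure(list(
    atoms = data.frame(
      index = 0:4, element = c("C", "H", "H", "H", "H"),
      name = c("C", paste0("H", 1:4)),
      resindex = 0L, resname = "MET", resno = 1L, stringsAsFactors = FALSE),
    bonds = data.frame(i = 0L, j = 1:4, order = 1L)
  ), class = "ddpd_topology")
}
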