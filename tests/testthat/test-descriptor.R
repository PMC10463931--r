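test_that("frame splitting follows the floor rule", {
  expect_length(split_subtrajectories(2500, 100), 25)
  r <- split_subtrajectories(1250, 100)
  expect_length(r, 12)
  expect_equal(r[[12]][100], 1200) # last 50 frames unused
  expect_equal(r[[1]], 1:100)
  expect_error(split_subtrajectories(99, 100), "shorter")
  expect_error(split_subtrajectories(100, 1), ">= 2")
})

test_that("sub-trajectory statistics match hand-computed values", {
  # one atom, one range of two frames, x = (0, 2), y and z constant
  topo <- synth_topology(1, template = carbon_template())
  cc <- array(0, c(2, 1, 3))
  cc[, 1, 1] <- c(0, 2)
  cc[, 1, 2] <- 5
  traj <- trajectory(cc, topo)
  sel <- select_atoms(topo, "all-heavy")
  st <- subtrajectory_statistics(traj, list(1:2), "coordinate", sel)
  expect_equal(st[1, "s1_x_mean"], 1, ignore_attr = TRUE)
  expect_equal(st[1, "s1_x_median"], 1, ignore_attr = TRUE)
  expect_equal(st[1, "s1_x_sd"], 1, ignore_attr = TRUE) # population SD
  expect_equal(st[1, "s1_y_sd"], 0, ignore_attr = TRUE)
  expect_equal(st[1, "s1_y_mean"], 5, ignore_attr = TRUE)
})

test_that("feature-matrix widths follow the 9S+1 / 3S+1 law", {
  topo <- synth_topology(1)
  traj <- synth_trajectory(topo, fluctuation_profile(topo, 0.1,
                                                     n_frames = 2500,
                                                     seed = 1))
  sel <- select_atoms(topo, "all-heavy") # 4 atoms
  ranges <- split_subtrajectories(2500, 100) # S = 25
  ch <- gasteiger_charges(topo)
  rig <- subtrajectory_statistics(traj, ranges, "rigidity", sel)
  expect_equal(dim(rig), c(4, 75))
  expect_equal(dim(assemble_feature_matrix(rig, ch, sel)), c(4, 76))
  coo <- subtrajectory_statistics(traj, ranges, "coordinate", sel)
  expect_equal(dim(coo), c(4, 225))
  expect_equal(dim(assemble_feature_matrix(coo, ch, sel)), c(4, 226))
  expect_error(assemble_feature_matrix(coo, ch[1:2], sel), "cover")
})

test_that("constant coordinates give zero SD and mean = median = value", {
  topo <- synth_topology(2)
  ref <- helix_reference(topo)
  cc <- array(rep(ref, each = 10), c(10, nrow(ref), 3))
  traj <- trajectory(cc, topo)
  sel <- select_atoms(topo, "all-heavy")
  st <- subtrajectory_statistics(traj, split_subtrajectories(10, 5),
                                 "coordinate", sel)
  sd_cols <- grepl("_sd$", colnames(st))
  expect_true(all(st[, sd_cols] == 0))
  expect_equal(st[, "s1_x_mean"], st[, "s1_x_median"])
  expect_equal(unname(st[, "s1_x_mean"]), ref[sel$indices + 1L, 1])
})

test_that("min-max standardization maps to [0,1] with inert constant columns", {
  expect_equal(minmax_standardize(cbind(c(1, 3, 5)))[, 1], c(0, 0.5, 1))
  expect_equal(minmax_standardize(cbind(c(7, 7)))[, 1], c(0, 0))
  set.seed(4)
  x <- matrix(rnorm(60), 12, 5)
  s <- minmax_standardize(x)
  expect_equal(unname(apply(s, 2, min)), rep(0, 5))
  expect_equal(unname(apply(s, 2, max)), rep(1, 5))
  expect_error(minmax_standardize(cbind(c(1, NA))), "finite")
})

test_that("PCA projection matches the eigendecomposition oracle", {
  set.seed(21)
  for (dims in list(c(20, 6), c(50, 10))) {
    x <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    k <- dims[2] - 2
    p <- pca_project(x, k = k)
    expect_lt(max(abs(p$scores - oracle_pca_scores(x, k))), 1e-8)
    # scores have diagonal covariance with non-increasing variance
    cv <- stats::cov(p$scores)
    expect_lt(max(abs(cv[upper.tri(cv)])), 1e-10)
    expect_true(all(diff(diag(cv)) < 1e-10))
  }
  # rank-1 data: one component explains everything
  y <- cbind(1:8, 2 * (1:8))
  p1 <- pca_project(y, var_frac = 0.95)
  expect_equal(p1$k, 1)
  expect_equal(p1$explained[1], 1)
  expect_error(pca_project(y, k = 2), "rank")
})

test_that("rs3DDPD has length n*L with zero blocks exactly at gap columns", {
  topo <- synth_topology(12)
  traj <- synth_factor_trajectory(topo, n_frames = 600, k = 6,
                                  noise_sd = 0.05, noise_mod = 0.5, seed = 4)
  gaps <- c(2L, 7L, 19L)
  msa <- synth_msa(c(TGT = paste(rep("A", 12), collapse = "")),
                   gap_plan = list(TGT = gaps), pad_to = 20)
  cfg <- ddpd_config("rs", residue_pcs = 3)
  d <- compute_rs3ddpd(traj, msa, "TGT", cfg)
  expect_length(d, 3 * 20)
  expect_equal(names(d)[1:3], c("AA1_PC1", "AA1_PC2", "AA1_PC3"))
  zero_cols <- which(vapply(seq_len(20), function(col) {
    all(d[(col - 1L) * 3L + 1:3] == 0)
  }, logical(1)))
  # 12 residues fill the first 12 non-gap columns (1..14 minus {2,7});
  # the rest of the alignment is padding
  expect_equal(zero_cols, sort(unique(c(gaps, 15:20))))
})

test_that("descriptor generation is deterministic and charge-sensitive", {
  fx <- rich_fixture()
  msa <- one_target_msa(40, L = 60)
  d1 <- compute_rs3ddpd(fx$traj, msa, "TGT")
  d2 <- compute_rs3ddpd(fx$traj, msa, "TGT")
  expect_identical(as.numeric(d1), as.numeric(d2))
  # identical topology+trajectory under another id gives the same values
  msa2 <- synth_msa(stats::setNames(rep(paste(rep("A", 40), collapse = ""), 2),
                                    c("TGT", "COPY")), pad_to = 60)
  expect_equal(as.numeric(compute_rs3ddpd(fx$traj, msa2, "COPY")),
               as.numeric(compute_rs3ddpd(fx$traj, msa2, "TGT")))
  # swapping one atom's element at fixed geometry changes the descriptor
  swapped <- fx$traj
  swapped$topology$atoms$element[1] <- "O"
  d3 <- compute_rs3ddpd(swapped, msa, "TGT")
  expect_false(identical(as.numeric(d1), as.numeric(d3)))
})

test_that("rs3DDPD validates residue counts against the MSA and config", {
  topo <- synth_topology(4)
  traj <- synth_factor_trajectory(topo, n_frames = 300, k = 3, seed = 2)
  msa <- one_target_msa(4, L = 8)
  expect_error(compute_rs3ddpd(traj, msa, "TGT", ddpd_config("rs")),
               "fewer residues")
  expect_error(compute_rs3ddpd(traj, one_target_msa(5, L = 8), "TGT",
                               ddpd_config("rs", residue_pcs = 2)),
               "does not match")
})

test_that("ps3DDPD respects the m*3 length law and permutation equivariance", {
  topo <- synth_topology(30, template = carbon_template(), cyclic = TRUE)
  trs <- lapply(1:3, function(i) {
    synth_factor_trajectory(topo, n_frames = 600, k = 4,
                            include_reference = FALSE, seed = 5,
                            noise_seed = 50 + i)
  })
  names(trs) <- c("A", "B", "C")
  ps <- compute_ps3ddpd(trs)
  m <- attr(ps[[1]], "m")
  expect_true(all(vapply(ps, length, integer(1)) == 3 * m))
  expect_equal(names(ps[[1]])[1:3], c("PC1_avg", "PC1_median", "PC1_sd"))
  perm <- compute_ps3ddpd(trs[c("C", "A", "B")])
  for (id in names(trs)) {
    expect_equal(as.numeric(perm[[id]]), as.numeric(ps[[id]]))
  }
  expect_error(compute_ps3ddpd(trs["A"]), "two targets")
})

test_that("ps3DDPD truncates to the minimum shared sub-trajectory count", {
  topo <- synth_topology(20, template = carbon_template(), cyclic = TRUE)
  long <- synth_factor_trajectory(topo, n_frames = 1000, k = 2,
                                  include_reference = FALSE, seed = 9,
                                  noise_seed = 1)
  short <- synth_factor_trajectory(topo, n_frames = 500, k = 2,
                                   include_reference = FALSE, seed = 9,
                                   noise_seed = 2)
  ps <- compute_ps3ddpd(list(A = long, B = short))
  expect_equal(length(ps$A), length(ps$B))
  # rank-1 stack: a single shared variance direction
  r1 <- lapply(1:2, function(i) {
    synth_factor_trajectory(topo, n_frames = 500, k = 1, noise_sd = 0,
                            noise_mod = 0, include_reference = FALSE,
                            seed = 3, noise_seed = i)
  })
  names(r1) <- c("A", "B")
  ps1 <- compute_ps3ddpd(r1)
  expect_equal(attr(ps1$A, "m"), 1)
  expect_length(ps1$A, 3)
})

test_that("descriptor CSV round trip is exact", {
  topo <- synth_topology(30, template = carbon_template(), cyclic = TRUE)
  trs <- lapply(1:2, function(i) {
    synth_factor_trajectory(topo, n_frames = 400, k = 2,
                            include_reference = FALSE, seed = 6,
                            noise_seed = i)
  })
  names(trs) <- c("A", "B")
  ps <- compute_ps3ddpd(trs)
  f <- withr::local_tempfile(fileext = ".csv")
  write_descriptor_csv(ps, f)
  back <- read_descriptor_csv(f)
  expect_equal(back$A, stats::setNames(as.numeric(ps$A), names(ps$A)))
  expect_equal(back$B, stats::setNames(as.numeric(ps$B), names(ps$B)))
})
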