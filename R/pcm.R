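# PCM/QSAR benchmarking harness: dataset splits, random-forest models over
# fixed seed replicates, MCC / Pearson r / RMSE metrics, the AVE
# chemical-bias statistic and pairwise significance testing.

#' The ten fixed benchmark seeds
#'
#' @return Integer vector of the ten seeds used for model replicates.
#' @export
ddpd_seeds <- function() {
  c(1234L, 2345L, 3456L, 4567L, 5678L, 6879L, 7890L, 8901L, 9012L, 9999L)
}

#' Read / write a bioactivity table
#'
#' CSV with columns `target_id`, `SMILES`, `pchembl_value`, `year`.
#'
#' @param path CSV file path.
#' @return data.frame of records.
#' @export
read_bioactivity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("target_id", "SMILES", "pchembl_value", "year")
  if (!all(need %in% names(df))) {
    stop("bioactivity CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df[, c("target_id", "SMILES")])) {
    stop("duplicate (target, compound) pairs")
  }
  df
}

#' @rdname read_bioactivity_csv
#' @param data data.frame of records.
#' @export
write_bioactivity_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Binary activity label from pChEMBL
#'
#' @param pchembl Numeric pChEMBL value(s); must be finite.
#' @param cutoff Activity cutoff (default 6.5); values at the cutoff count
#'   as active.
#' @return Logical vector: `TRUE` = active.
#' @export
label_activity <- function(pchembl, cutoff = 6.5) {
  if (any(!is.finite(pchembl))) stop("missing or non-finite pChEMBL value")
  pchembl >= cutoff
}

#' Random 80:20 split
#'
#' @param data Record data.frame (>= 5 rows).
#' @param seed Integer seed driving the shuffle.
#' @param train_fraction Training fraction (default 0.8).
#' @return List with integer row indices `train` and `test` (an exact
#'   partition).
#' @export
split_random <- function(data, seed, train_fraction = 0.8) {
  n <- nrow(data)
  if (n < 5) stop("too few records to split")
  idx <- withr_seed(seed, sample.int(n))
  n_train <- round(train_fraction * n)
  list(train = sort(idx[seq_len(n_train)]), test = sort(idx[-seq_len(n_train)]))
}

#' Temporal split at a cutoff year
#'
#' Records first published before the cutoff train; records from the cutoff
#' year onward test.
#'
#' @param data Record data.frame with a `year` column.
#' @param cutoff_year Cutoff (default 2013).
#' @return List with integer row indices `train` and `test`.
#' @export
split_temporal <- function(data, cutoff_year = 2013) {
  train <- which(data$year < cutoff_year)
  test <- which(data$year >= cutoff_year)
  if (!length(train) || !length(test)) {
    stop("temporal split leaves an empty side at cutoff ", cutoff_year)
  }
  list(train = train, test = test)
}

#' Assemble the model matrix for PCM
#'
#' Each record's row is the concatenation of its compound fingerprint and
#' its protein descriptor block(s); combination mode (several protein
#' descriptor sets) concatenates the blocks in order. Column names are
#' preserved for feature-importance traceback.
#'
#' @param data Record data.frame.
#' @param protein_desc Named list: target id -> named numeric vector, or a
#'   list of such lists for combinations. `NULL` gives compound-only
#'   (QSAR-style) rows.
#' @param compound_desc Matrix with SMILES rownames (e.g. from
#'   [ecfp6_matrix()]).
#' @return Numeric matrix, one row per record.
#' @export
build_feature_table <- function(data, protein_desc, compound_desc) {
  miss <- setdiff(unique(data$SMILES), rownames(compound_desc))
  if (length(miss)) stop("missing compound descriptor for ", miss[1])
  blocks <- list(compound_desc[data$SMILES, , drop = FALSE])
  if (!is.null(protein_desc)) {
    sets <- if (is.list(protein_desc[[1]]) && !is.numeric(protein_desc[[1]])) {
      protein_desc
    } else list(protein_desc)
    for (s in seq_along(sets)) {
      set <- sets[[s]]
      miss <- setdiff(unique(data$target_id), names(set))
      if (length(miss)) stop("missing protein descriptor for ", miss[1])
      pm <- do.call(rbind, lapply(set, as.numeric))
      colnames(pm) <- names(set[[1]])
      if (length(sets) > 1) colnames(pm) <- paste0("set", s, "_", colnames(pm))
      blocks[[length(blocks) + 1L]] <- pm[data$target_id, , drop = FALSE]
    }
  }
  out <- do.call(cbind, blocks)
  rownames(out) <- NULL
  out
}

#' Matthews correlation coefficient from confusion counts
#'
#' @param tp,tn,fp,fn Non-negative counts.
#' @return MCC in [-1, 1]; 0 when any denominator factor is zero.
#' @export
metric_mcc <- function(tp, tn, fp, fn) {
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

mcc_from_pred <- function(truth, pred) {
  metric_mcc(sum(pred & truth), sum(!pred & !truth),
             sum(pred & !truth), sum(!pred & truth))
}

eval_metrics <- function(task, truth, pred) {
  if (task == "classification") {
    c(mcc = mcc_from_pred(truth, pred))
  } else {
    c(pearson_r = if (stats::sd(pred) == 0 || stats::sd(truth) == 0) 0 else
        stats::cor(truth, pred),
      rmse = sqrt(mean((truth - pred)^2)))
  }
}

#' Train and evaluate one random-forest model
#'
#' Random forest (ranger backend, library default hyperparameters, no
#' tuning) with k-fold cross-validation on the training side and final
#' evaluation on the held-out side. The seed drives fold shuffling and
#' forest initialization; runs are bit-reproducible (single-threaded).
#'
#' @param x Model matrix (records x features).
#' @param y Response: numeric pChEMBL (regression) or logical/binary
#'   activity (classification).
#' @param task `"regression"` or `"classification"`.
#' @param seed Integer seed.
#' @param split List with `train`/`test` row indices.
#' @param num_trees Forest size (ranger default 500).
#' @param cv_folds Cross-validation folds (default 5).
#' @return A `ddpd_run`: list with `task`, `seed`, `metrics` (test-set),
#'   `cv` (per-fold metrics), `importance` (impurity-based, named).
#' @export
train_eval_rf <- function(x, y, task = c("regression", "classification"),
                          seed, split, num_trees = 500, cv_folds = 5) {
  task <- match.arg(task)
  stopifnot(length(split$train) > 0, length(split$test) > 0)
  if (task == "classification") {
    y <- factor(as.logical(y), levels = c(FALSE, TRUE))
    if (length(unique(y[split$train])) < 2) {
      stop("training set contains a single class")
    }
  }
  fit_one <- function(tr_idx, ev_idx) {
    m <- ranger::ranger(x = x[tr_idx, , drop = FALSE], y = y[tr_idx],
                        num.trees = num_trees, seed = seed,
                        num.threads = 1, importance = "impurity")
    pred <- stats::predict(m, data = x[ev_idx, , drop = FALSE],
                           num.threads = 1)$predictions
    list(model = m,
         metrics = if (task == "classification") {
           eval_metrics(task, y[ev_idx] == "TRUE", pred == "TRUE")
         } else eval_metrics(task, y[ev_idx], pred))
  }
  folds <- withr_seed(seed, {
    sh <- sample(split$train)
    split(sh, rep_len(seq_len(cv_folds), length(sh)))
  })
  cv <- do.call(rbind, lapply(seq_len(cv_folds), function(f) {
    r <- tryCatch(fit_one(setdiff(split$train, folds[[f]]), folds[[f]]),
                  error = function(e) NULL)
    if (is.null(r)) return(NULL)
    data.frame(fold = f, t(r$metrics))
  }))
  final <- fit_one(split$train, split$test)
  structure(list(task = task, seed = seed, metrics = final$metrics, cv = cv,
                 importance = final$model$variable.importance),
            class = "ddpd_run")
}

#' @export
print.ddpd_run <- function(x, ...) {
  cat("ddpd_run:", x$task, "seed", x$seed, "|",
      paste(names(x$metrics), round(x$metrics, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Per-target QSAR baseline
#'
#' One compound-only random forest per target under the same split rule and
#' options as the PCM models; reports the unweighted mean of the per-target
#' test metrics.
#'
#' @param data Record data.frame.
#' @param compound_desc SMILES-rowname fingerprint matrix.
#' @param task `"regression"` or `"classification"`.
#' @param seed Integer seed.
#' @param split_rule `"random"` or `"temporal"`.
#' @param cutoff_year Temporal cutoff (when `split_rule = "temporal"`).
#' @param num_trees Forest size.
#' @return List with `mean` (named averaged metric vector) and
#'   `per_target` (data.frame).
#' @export
qsar_baseline <- function(data, compound_desc,
                          task = c("regression", "classification"), seed,
                          split_rule = c("random", "temporal"),
                          cutoff_year = 2013, num_trees = 500) {
  task <- match.arg(task)
  split_rule <- match.arg(split_rule)
  per <- lapply(split(seq_len(nrow(data)), data$target_id), function(idx) {
    sub <- data[idx, , drop = FALSE]
    sp <- if (split_rule == "random") split_random(sub, seed) else
      split_temporal(sub, cutoff_year)
    x <- build_feature_table(sub, NULL, compound_desc)
    y <- if (task == "classification") label_activity(sub$pchembl_value) else
      sub$pchembl_value
    run <- train_eval_rf(x, y, task, seed, sp, num_trees = num_trees)
    run$metrics
  })
  per_target <- data.frame(target_id = names(per),
                           do.call(rbind, per), row.names = NULL)
  list(mean = colMeans(do.call(rbind, per)), per_target = per_target)
}

tanimoto_dist <- function(a, b) {
  # a: n x bits, b: m x bits binary matrices -> n x m distance matrix
  inter <- a %*% t(b)
  ca <- rowSums(a); cb <- rowSums(b)
  un <- outer(ca, cb, "+") - inter
  d <- 1 - ifelse(un == 0, 1, inter / un)
  d
}

nearness <- function(v_fp, t_fp, thresholds) {
  if (!nrow(v_fp) || !nrow(t_fp)) stop("empty fingerprint set")
  dmin <- apply(tanimoto_dist(v_fp, t_fp), 1, min)
  mean(vapply(dmin, function(d) mean(d < thresholds), numeric(1)))
}

#' AVE chemical-bias statistic for a train/test split
#'
#' Asymmetric validation embedding bias: the nearness of test actives to
#' training actives minus to training inactives, plus the same contrast for
#' inactives. Nearness of a set V to a set T is the mean over v in V of the
#' fraction of the distance-threshold grid exceeded by v's nearest-neighbour
#' Tanimoto distance to T. Positive values indicate a clustered (biased)
#' split; i.i.d. splits of distinct compounds give values near 0.
#'
#' @param train_fp,test_fp Binary fingerprint matrices.
#' @param train_active,test_active Logical activity labels (both classes
#'   must be present on both sides).
#' @param thresholds Distance threshold grid (default 51 points on [0, 1]).
#' @return Scalar AVE bias.
#' @export
ave_bias <- function(train_fp, train_active, test_fp, test_active,
                     thresholds = seq(0, 1, length.out = 51)) {
  stopifnot(any(train_active), any(!train_active),
            any(test_active), any(!test_active))
  VA <- test_fp[test_active, , drop = FALSE]
  VI <- test_fp[!test_active, , drop = FALSE]
  TA <- train_fp[train_active, , drop = FALSE]
  TI <- train_fp[!train_active, , drop = FALSE]
  (nearness(VA, TA, thresholds) - nearness(VA, TI, thresholds)) +
    (nearness(VI, TI, thresholds) - nearness(VI, TA, thresholds))
}

#' Compare two descriptors' seed-replicate metrics
#'
#' Two-sided independent Student's t-test on the per-seed metric values,
#' with the conventional significance stars (* < 0.05, ** < 0.01,
#' *** < 0.001, else "ns").
#'
#' @param metrics_a,metrics_b Numeric vectors (>= 2 values each).
#' @return List with `mean_a`, `sd_a`, `mean_b`, `sd_b`, `p_value`,
#'   `stars`.
#' @export
compare_descriptors <- function(metrics_a, metrics_b) {
  if (length(metrics_a) < 2 || length(metrics_b) < 2) {
    stop("need at least 2 values per side")
  }
  if (stats::sd(metrics_a) == 0 && stats::sd(metrics_b) == 0) {
    p <- if (mean(metrics_a) == mean(metrics_b)) 1 else 0
  } else {
    p <- stats::t.test(metrics_a, metrics_b, var.equal = TRUE)$p.value
  }
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else "ns"
  list(mean_a = mean(metrics_a), sd_a = stats::sd(metrics_a),
       mean_b = mean(metrics_b), sd_b = stats::sd(metrics_b),
       p_value = p, stars = stars)
}

#' Rank features by seed-mean importance
#'
#' @param runs List of `ddpd_run` objects (one per seed) with identical
#'   feature-name sets.
#' @param k Number of top features to return (default 25; the full ranking
#'   if fewer features exist).
#' @return data.frame `feature`, `mean_importance`, `sd_importance`, ranked
#'   by decreasing mean with lexicographic name tie-break.
#' @export
top_features <- function(runs, k = 25) {
  imps <- lapply(runs, `[[`, "importance")
  nm <- names(imps[[1]])
  for (im in imps) {
    if (!identical(sort(names(im)), sort(nm))) {
      stop("mismatched feature name sets across seeds")
    }
  }
  m <- do.call(rbind, lapply(imps, function(im) im[nm]))
  mean_imp <- colMeans(m)
  sd_imp <- apply(m, 2, stats::sd)
  ord <- order(-mean_imp, nm)
  out <- data.frame(feature = nm[ord], mean_importance = mean_imp[ord],
                    sd_importance = sd_imp[ord], row.names = NULL)
  utils::head(out, k)
}

#' Run a multi-seed PCM benchmark
#'
#' Trains one model per seed for each named protein-descriptor set and
#' returns the tidy long-format results table.
#'
#' @param data Record data.frame.
#' @param protein_desc_sets Named list of protein descriptor sets (each a
#'   named list target -> vector), or `NULL` entries for QSAR-style rows.
#' @param compound_desc Fingerprint matrix.
#' @param task `"regression"` or `"classification"`.
#' @param split_rule `"random"` or `"temporal"`.
#' @param seeds Integer seeds (default the ten fixed benchmark seeds).
#' @param cutoff_year Temporal cutoff.
#' @param num_trees Forest size.
#' @return List with `results` (data.frame: task, split, descriptor, seed,
#'   metric, value) and `runs` (nested list of `ddpd_run`).
#' @export
benchmark_pcm <- function(data, protein_desc_sets, compound_desc,
                          task = "regression", split_rule = "random",
                          seeds = ddpd_seeds(), cutoff_year = 2013,
                          num_trees = 500) {
  y <- if (task == "classification") label_activity(data$pchembl_value) else
    data$pchembl_value
  rows <- list(); runs <- list()
  for (dn in names(protein_desc_sets)) {
    x <- build_feature_table(data, protein_desc_sets[[dn]], compound_desc)
    runs[[dn]] <- lapply(seeds, function(s) {
      sp <- if (split_rule == "random") split_random(data, s) else
        split_temporal(data, cutoff_year)
      train_eval_rf(x, y, task, s, sp, num_trees = num_trees)
    })
    for (i in seq_along(seeds)) {
      met <- runs[[dn]][[i]]$metrics
      rows[[length(rows) + 1L]] <- data.frame(
        task = task, split = split_rule, descriptor = dn,
        seed = seeds[i], metric = names(met), value = unname(met))
    }
  }
  list(results = do.call(rbind, rows), runs = runs)
}
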