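# Phonemic decoding: windowed high-gamma features, mRMR feature selection,
# shrinkage-regularized LDA with stratified cross-validation, per-electrode
# encoding strength, cluster-specific analysis windows, single-electrode
# decoding, and the bootstrap phonemic preference index.

#' Windowed high-gamma features for classification
#'
#' Divides each electrode's epoch into moving averages (50 ms windows,
#' 25 ms stride by default) over a decoding window around voice onset.
#' A 2000 ms window yields 79 features per electrode.
#'
#' @param epochs an `hg_epochs` object.
#' @param window length-2 ms decoding window, half-open (default
#'   `c(-1000, 1000)`).
#' @param width_ms,stride_ms feature window and stride (ms).
#' @return object of class `feature_matrix`: list with `X` (trials x
#'   features), `map` (data.frame: `electrode`, `start_ms`, `end_ms`),
#'   `labels` (data.frame of trial labels), `n_per_electrode`.
#' @export
extract_features <- function(epochs, window = c(-1000, 1000),
                             width_ms = 50, stride_ms = 25) {
  stopifnot(inherits(epochs, "hg_epochs"))
  if (diff(window) < width_ms) stop("window shorter than one feature width")
  if (window[1] < min(epochs$time_ms) - 1e-9 ||
      window[2] > max(epochs$time_ms) + 1000 / epochs$sampling_rate + 1e-9) {
    stop("decoding window outside the epoch span")
  }
  starts <- seq(window[1], window[2] - width_ms, by = stride_ms)
  n_feat <- length(starts)
  n_elec <- dim(epochs$power)[1]
  n_tr <- dim(epochs$power)[2]
  X <- matrix(NA_real_, n_tr, n_elec * n_feat)
  map <- data.frame(
    electrode = rep(epochs$electrode_meta$id, each = n_feat),
    start_ms = rep(starts, n_elec),
    end_ms = rep(starts + width_ms, n_elec)
  )
  for (e in seq_len(n_elec)) {
    for (j in seq_len(n_feat)) {
      sel <- epochs$time_ms >= starts[j] & epochs$time_ms < starts[j] + width_ms
      X[, (e - 1L) * n_feat + j] <-
        rowMeans(epochs$power[e, , sel, drop = FALSE][1, , , drop = TRUE],
                 na.rm = TRUE)
    }
  }
  if (any(!is.finite(X))) stop("non-finite features (invalid electrode-trials?)")
  lab_cols <- intersect(c("syllable", "consonant_pair", "vowel"),
                        names(epochs$trials))
  structure(list(X = X, map = map,
                 labels = epochs$trials[, lab_cols, drop = FALSE],
                 n_per_electrode = n_feat),
            class = "feature_matrix")
}

# equal-frequency discretization into n_bins integer codes
discretize_ef <- function(x, n_bins = 8L) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                               names = FALSE, type = 7))
  if (length(br) < 2L) return(rep(1L, length(x)))
  findInterval(x, br[-c(1L, length(br))]) + 1L
}

# mutual information (nats) between two integer-coded vectors
mi_disc <- function(a, b, na, nb) {
  joint <- tabulate(a + na * (b - 1L), nbins = na * nb) / length(a)
  pa <- tabulate(a, nbins = na) / length(a)
  pb <- tabulate(b, nbins = nb) / length(b)
  outer_p <- as.numeric(outer(pa, pb))
  nz <- joint > 0 & outer_p > 0
  sum(joint[nz] * log(joint[nz] / outer_p[nz]))
}

#' Greedy mRMR feature selection
#'
#' Minimum-redundancy-maximum-relevance ranking in the mutual-information
#' difference (MID) form: features are discretized into equal-frequency
#' bins, the first feature maximizes I(f; y), and each subsequent pick
#' maximizes I(f; y) - mean_{s in selected} I(f; s). Deterministic for a
#' fixed input (ties broken by column index).
#'
#' @param X trials x features numeric matrix.
#' @param y categorical labels (factor or character).
#' @param k number of features to select (capped at ncol(X)).
#' @param n_bins equal-frequency bins for discretization (default 8).
#' @return integer vector of selected column indices in selection order.
#' @export
mrmr_select <- function(X, y, k, n_bins = 8L) {
  y <- as.integer(factor(y))
  ny <- max(y)
  if (ny < 2L) stop("labels have a single class")
  stopifnot(k >= 1L)
  p <- ncol(X)
  k <- min(k, p)
  D <- matrix(0L, nrow(X), p)
  for (j in seq_len(p)) D[, j] <- discretize_ef(X[, j], n_bins)
  nb <- max(D)
  relevance <- vapply(seq_len(p), function(j) mi_disc(D[, j], y, nb, ny),
                      numeric(1))
  selected <- integer(0)
  red_sum <- numeric(p)
  candidates <- seq_len(p)
  for (step in seq_len(k)) {
    score <- if (length(selected) == 0L) relevance[candidates] else
      relevance[candidates] - red_sum[candidates] / length(selected)
    pick <- candidates[which.max(score)]
    selected <- c(selected, pick)
    candidates <- setdiff(candidates, pick)
    if (length(candidates) && step < k) {
      red_sum[candidates] <- red_sum[candidates] +
        vapply(candidates, function(j) mi_disc(D[, j], D[, pick], nb, nb),
               numeric(1))
    }
  }
  selected
}

# --- shrinkage-regularized LDA -------------------------------------------
# Pooled within-class covariance shrunk toward a scaled identity with an
# analytically estimated (Ledoit-Wolf-type) intensity; survives the
# many-features / few-trials regime where the plain pooled covariance is
# singular.

lda_shrink_fit <- function(X, y) {
  y <- factor(y)
  classes <- levels(y)
  n <- nrow(X); p <- ncol(X)
  means <- t(vapply(classes, function(cl) colMeans(X[y == cl, , drop = FALSE]),
                    numeric(p)))
  Z <- X - means[as.integer(y), , drop = FALSE]
  S <- crossprod(Z) / n
  mu <- mean(diag(S))
  d2 <- sum((S - diag(mu, p))^2)
  if (d2 < 1e-300) {
    gamma <- 1
  } else {
    q <- rowSums(Z^2)
    b2 <- (sum(q^2) - 2 * sum((Z %*% S) * Z) + n * sum(S^2)) / n^2
    gamma <- max(0, min(1, b2 / d2))
  }
  Sr <- (1 - gamma) * S + gamma * diag(mu, p)
  Ri <- chol(Sr)
  W <- backsolve(Ri, forwardsolve(t(Ri), t(means)))   # p x g = S^-1 mu_k
  const <- -0.5 * colSums(t(means) * W) +
    log(as.numeric(table(y)) / n)
  list(W = W, const = const, classes = classes, gamma = gamma)
}

lda_shrink_predict <- function(fit, X) {
  scores <- X %*% fit$W + matrix(fit$const, nrow(X), length(fit$const),
                                 byrow = TRUE)
  fit$classes[max.col(scores, ties.method = "first")]
}

# deterministic stratified fold assignment given the current RNG state;
# n_folds >= n degenerates to leave-one-out
make_folds <- function(strata, n_folds) {
  if (n_folds >= length(strata)) return(seq_along(strata))
  strata <- as.factor(strata)
  fold <- integer(length(strata))
  for (s in levels(strata)) {
    idx <- sample(which(strata == s))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Cross-validated LDA decoding
#'
#' Splits trials into `n_folds` disjoint folds (stratified by
#' `stratify_by`, defaulting to the labels themselves), performs mRMR
#' selection on the training folds only, fits the shrinkage LDA on the
#' training folds, and scores the held-out fold; feature selection never
#' sees test data. Per-trial correctness is retained.
#'
#' @param X trials x features matrix (or a `feature_matrix`, whose `X` is
#'   used).
#' @param y labels.
#' @param n_folds number of folds (default 5).
#' @param n_features mRMR budget (default 150); `NULL` or >= ncol uses all
#'   features without selection.
#' @param stratify_by stratification labels (default `y`; pass the syllable
#'   labels to balance all phonemic units across folds).
#' @param folds optional precomputed fold vector (overrides the split).
#' @return object of class `classification_result`: list with `accuracy`
#'   (pooled %), `fold_accuracy` (%), `correct` (0/1 per trial), `folds`,
#'   `n_features`.
#' @export
crossval_lda <- function(X, y, n_folds = 5L, n_features = 150L,
                         stratify_by = NULL, folds = NULL) {
  if (inherits(X, "feature_matrix")) X <- X$X
  y <- factor(y)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (is.null(folds)) {
    folds <- make_folds(stratify_by %||% y, n_folds)
  }
  correct <- integer(n)
  fold_acc <- numeric(max(folds))
  for (f in sort(unique(folds))) {
    tr <- folds != f; te <- !tr
    y_tr <- droplevels(y[tr])
    if (nlevels(y_tr) < nlevels(y)) {
      warning("fold ", f, ": class absent from training data; ",
              "those test trials scored against the remaining classes")
    }
    keep <- seq_len(ncol(X))
    if (!is.null(n_features) && n_features < ncol(X)) {
      keep <- mrmr_select(X[tr, , drop = FALSE], y_tr, n_features)
    }
    fit <- lda_shrink_fit(X[tr, keep, drop = FALSE], y_tr)
    pred <- lda_shrink_predict(fit, X[te, keep, drop = FALSE])
    correct[te] <- as.integer(pred == as.character(y[te]))
    fold_acc[f] <- 100 * mean(pred == as.character(y[te]))
  }
  structure(list(accuracy = 100 * mean(correct),
                 fold_accuracy = fold_acc,
                 correct = correct, folds = folds,
                 n_features = if (is.null(n_features)) ncol(X)
                              else min(n_features, ncol(X))),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("LDA decoding: %.1f%% pooled accuracy over %d trials (%d folds)\n",
              x$accuracy, length(x$correct), length(x$fold_accuracy)))
  invisible(x)
}

#' Leave-one-electrode-out encoding strength
#'
#' The classification strength of an electrode is the pooled accuracy with
#' all electrodes minus the pooled accuracy when that electrode's features
#' are excluded (mRMR re-run without them), holding the fold split fixed
#' across runs.
#'
#' @param features a `feature_matrix` (needs the electrode map).
#' @param y labels.
#' @param n_folds,n_features as in [crossval_lda()].
#' @param stratify_by stratification labels.
#' @return object of class `encoding_result`: data.frame with `electrode`,
#'   `strength` (percentage points), `rank`; the full-model
#'   `classification_result` is attached as attribute `full`.
#' @export
electrode_encoding_strength <- function(features, y, n_folds = 5L,
                                        n_features = 150L, stratify_by = NULL) {
  stopifnot(inherits(features, "feature_matrix"))
  elec <- unique(features$map$electrode)
  if (length(elec) < 2L) stop("leave-one-electrode-out needs >= 2 electrodes")
  folds <- make_folds(stratify_by %||% y, n_folds)
  full <- crossval_lda(features$X, y, n_folds, n_features, folds = folds)
  strength <- vapply(elec, function(e) {
    keep <- features$map$electrode != e
    part <- crossval_lda(features$X[, keep, drop = FALSE], y, n_folds,
                         n_features, folds = folds)
    full$accuracy - part$accuracy
  }, numeric(1))
  out <- data.frame(electrode = elec, strength = unname(strength))
  out$rank <- rank(-out$strength, ties.method = "first")
  attr(out, "full") <- full
  class(out) <- c("encoding_result", "data.frame")
  out
}

#' Flag the top fraction of encoders
#'
#' Flags the ceiling(fraction * N) electrodes with the highest strength,
#' pooled across however many participants are represented in `strengths`.
#' Ties at the boundary are broken by position (and a warning is emitted).
#'
#' @param strengths named numeric vector, or an `encoding_result`.
#' @param fraction top fraction (default 0.30).
#' @return logical vector of top flags, aligned with `strengths`.
#' @export
select_top_encoders <- function(strengths, fraction = 0.30) {
  if (inherits(strengths, "encoding_result")) {
    s <- stats::setNames(strengths$strength, strengths$electrode)
  } else s <- strengths
  n_top <- ceiling(fraction * length(s))
  ord <- order(-s)
  flags <- rep(FALSE, length(s))
  flags[ord[seq_len(n_top)]] <- TRUE
  if (n_top < length(s) && s[ord[n_top]] == s[ord[n_top + 1L]]) {
    warning("tied strengths at the selection boundary; broken by position")
  }
  stats::setNames(flags, names(s))
}

#' Decoding with cluster-specific analysis windows
#'
#' For each cluster, the decoding window is the interval between the
#' cluster's start and end landmarks (right-censored ends are closed at the
#' epoch end), divided into 79 features of equal duration with a stride of
#' half the feature duration (so a window of length L gets width L/40).
#' The same mRMR + LDA cross-validation is then run per cluster.
#'
#' @param epochs an `hg_epochs` object.
#' @param y labels.
#' @param assignment a [assign_clusters()] result for these electrodes.
#' @param n_windows number of features per electrode (default 79).
#' @param n_folds,n_features,stratify_by as in [crossval_lda()].
#' @return list of `classification_result`, one per cluster, with the
#'   window used attached as attribute `window` on each.
#' @export
classify_cluster_windows <- function(epochs, y, assignment, n_windows = 79L,
                                     n_folds = 5L, n_features = 150L,
                                     stratify_by = NULL) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  fs <- epochs$sampling_rate
  out <- list()
  for (cl in seq_along(assignment$landmarks)) {
    lm <- assignment$landmarks[[cl]]
    if (is.null(lm)) next
    w0 <- lm$start_ms
    w1 <- if (is.finite(lm$end_ms)) lm$end_ms else max(epochs$time_ms)
    L <- w1 - w0
    width <- 2 * L / (n_windows + 1L)
    if (width < 1000 / fs) stop("cluster ", cl, " window too short to tile")
    stride <- width / 2
    starts <- w0 + stride * (seq_len(n_windows) - 1L)
    n_elec <- dim(epochs$power)[1]
    X <- matrix(NA_real_, dim(epochs$power)[2], n_elec * n_windows)
    for (e in seq_len(n_elec)) {
      for (j in seq_len(n_windows)) {
        sel <- epochs$time_ms >= starts[j] & epochs$time_ms < starts[j] + width
        X[, (e - 1L) * n_windows + j] <-
          rowMeans(epochs$power[e, , sel, drop = FALSE][1, , , drop = TRUE],
                   na.rm = TRUE)
      }
    }
    res <- crossval_lda(X, y, n_folds, n_features, stratify_by = stratify_by)
    attr(res, "window") <- c(w0, w1)
    out[[cl]] <- res
  }
  out
}

#' Paired comparison of fixed versus cluster-specific windows
#'
#' @param fixed_acc,cluster_acc per-subject pooled accuracies (%) under the
#'   fixed 2-s window and the cluster-specific windows.
#' @return htest from a paired two-sided t test.
#' @export
compare_windows <- function(fixed_acc, cluster_acc) {
  stopifnot(length(fixed_acc) == length(cluster_acc))
  stats::t.test(fixed_acc, cluster_acc, paired = TRUE)
}

#' Single-electrode decoding
#'
#' Runs the decoding separately on each electrode's own features: mRMR
#' selects the top `n_features` (10 by default) of that electrode's 79
#' windowed features, followed by the stratified 5-fold LDA. Per-trial
#' correctness vectors are retained for the bootstrap preference analysis.
#'
#' @param features a `feature_matrix`.
#' @param y labels.
#' @param n_folds folds (default 5).
#' @param n_features per-electrode mRMR budget (default 10).
#' @param stratify_by stratification labels.
#' @param folds optional fixed fold vector shared across electrodes.
#' @return trials x electrodes 0/1 matrix of per-trial correctness.
#' @export
single_electrode_classify <- function(features, y, n_folds = 5L,
                                      n_features = 10L, stratify_by = NULL,
                                      folds = NULL) {
  stopifnot(inherits(features, "feature_matrix"))
  elec <- unique(features$map$electrode)
  if (is.null(folds)) folds <- make_folds(stratify_by %||% y, n_folds)
  out <- matrix(NA_integer_, nrow(features$X), length(elec),
                dimnames = list(NULL, elec))
  for (e in elec) {
    cols <- features$map$electrode == e
    res <- crossval_lda(features$X[, cols, drop = FALSE], y, n_folds,
                        n_features, folds = folds)
    out[, e] <- res$correct
  }
  out
}

#' Bootstrap phonemic preference index (PPI)
#'
#' For each of `n_boot` resampled trial sets (drawn with replacement within
#' subject and shared across that subject's electrodes), every electrode's
#' mean single-electrode accuracy is computed per phonemic unit and ranked
#' across electrodes within the unit (rank 1 = least accurate, N = most).
#' The PPI of a unit is the larger of its rank minus each other unit's
#' rank. An electrode preferentially encodes a unit when the 5th percentile
#' of its PPI distribution is above zero; if two units are significant the
#' one with the higher mean PPI is preferred.
#'
#' @param correct trials x electrodes x units 0/1 array (units named), as
#'   assembled from [single_electrode_classify()] runs.
#' @param n_boot bootstrap resamples (default 10000).
#' @return object of class `ppi_result`: list with `table` (data.frame:
#'   `electrode`, `unit`, `mean_ppi`, `p5`, `significant`) and `preferred`
#'   (named character vector per electrode, NA when no preference).
#' @export
compute_ppi <- function(correct, n_boot = 10000L) {
  stopifnot(length(dim(correct)) == 3L)
  if (n_boot < 100L) warning("n_boot < 100 gives unstable percentiles")
  n_tr <- dim(correct)[1]; n_el <- dim(correct)[2]; n_un <- dim(correct)[3]
  if (n_un < 2L) stop("need at least two phonemic units")
  units <- dimnames(correct)[[3]] %||% paste0("unit", seq_len(n_un))
  elecs <- dimnames(correct)[[2]] %||% paste0("e", seq_len(n_el))
  flat <- matrix(correct, n_tr, n_el * n_un)      # columns: elec within unit
  ppi <- array(NA_real_, c(n_boot, n_el, n_un))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n_tr, n_tr, replace = TRUE)
    acc <- matrix(colMeans(flat[idx, , drop = FALSE]), n_el, n_un)
    rk <- apply(acc, 2, rank, ties.method = "average")  # 1 = least accurate
    if (n_el == 1L) rk <- matrix(rk, 1L, n_un)
    for (u in seq_len(n_un)) {
      others <- rk[, -u, drop = FALSE]
      ppi[b, , u] <- apply(rk[, u] - others, 1, max)
    }
  }
  tab <- expand.grid(electrode = elecs, unit = units,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$mean_ppi <- as.numeric(apply(ppi, c(2, 3), mean))
  tab$p5 <- as.numeric(apply(ppi, c(2, 3), stats::quantile, probs = 0.05))
  tab$significant <- tab$p5 > 0
  preferred <- vapply(elecs, function(e) {
    rows <- tab[tab$electrode == e & tab$significant, ]
    if (!nrow(rows)) NA_character_ else rows$unit[which.max(rows$mean_ppi)]
  }, character(1))
  structure(list(table = tab, preferred = preferred, n_boot = n_boot),
            class = "ppi_result")
}

#' Above-chance decoding decision from correctness vectors
#'
#' Concatenates per-subject correctness vectors and compares the pooled
#' count of correct trials to the exact cumulative-binomial chance level
#' (see [chance_level()]); also decides significance per subject with that
#' subject's trial count.
#'
#' @param correct_by_subject named list of 0/1 correctness vectors.
#' @param n_classes number of classes c.
#' @param p significance level (default 0.05).
#' @return list with `pooled` and `per_subject` data.frames (`n`,
#'   `n_correct`, `accuracy`, `chance_percent`, `p_value`, `significant`).
#' @export
chance_significance <- function(correct_by_subject, n_classes, p = 0.05) {
  one <- function(v) {
    n <- length(v); zc <- sum(v)
    cl <- chance_level(n_classes, n, p)
    data.frame(n = n, n_correct = zc, accuracy = 100 * zc / n,
               chance_percent = cl$chance_percent,
               p_value = stats::pbinom(zc - 1, n, 1 / n_classes,
                                       lower.tail = FALSE),
               significant = zc >= cl$min_significant_count)
  }
  per <- do.call(rbind, lapply(correct_by_subject, one))
  per$subject <- names(correct_by_subject) %||% seq_along(correct_by_subject)
  list(pooled = one(unlist(correct_by_subject, use.names = FALSE)),
       per_subject = per)
}
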