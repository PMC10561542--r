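# Hybrid partitioning/hierarchical clustering of ERSP time-courses under an
# exponential distance that up-weights activity far from baseline.

#' Rescale each profile to the unit interval
#'
#' @param profiles electrodes x timepoints matrix of ERSP traces.
#' @return matrix of the same shape with every non-constant row rescaled to
#'   min 0 / max 1 (constant rows become all zeros, with a warning); the
#'   original `(min, max)` per row is kept in attribute `scale`.
#' @export
normalize_profiles <- function(profiles) {
  stopifnot(is.matrix(profiles))
  rng <- t(apply(profiles, 1, range))
  flat <- rng[, 2] - rng[, 1] == 0
  if (any(flat)) warning(sum(flat), " constant profile(s) mapped to zero")
  out <- (profiles - rng[, 1]) / ifelse(rng[, 2] - rng[, 1] == 0, 1,
                                        rng[, 2] - rng[, 1])
  attr(out, "scale") <- rng
  out
}

#' Exponential profile distance
#'
#' DIST(p, q) = sum_i (exp(p_i) - exp(q_i))^2 on \[0,1\]-normalized traces.
#' Exponentiation stretches differences at high-activity time points
#' (peaks, plateaus) relative to near-baseline points, so the measure
#' weights the task-active parts of the time-course more than a plain
#' squared difference would. It is a semi-metric: non-negative, symmetric,
#' zero iff the traces are identical; the triangle inequality is not
#' guaranteed.
#'
#' @param p,q numeric traces of equal length with values in \[0, 1\].
#' @param method "exponential" (default) or "squared" for the plain squared
#'   difference (sensitivity checks).
#' @return scalar distance.
#' @export
profile_distance <- function(p, q, method = c("exponential", "squared")) {
  method <- match.arg(method)
  if (length(p) != length(q)) stop("traces must have the same length")
  if (method == "exponential") sum((exp(p) - exp(q))^2) else sum((p - q)^2)
}

# full pairwise DIST matrix; rows of `x` are traces
profile_distance_matrix <- function(x, method = "exponential") {
  z <- if (method == "exponential") exp(x) else x
  as.matrix(stats::dist(z))^2
}

#' Hybrid partitioning/hierarchical clustering
#'
#' Starts with every electrode in its own cluster and repeatedly merges the
#' closest pair under [profile_distance()] between cluster centroids (the
#' member means of the normalized profiles). After each merge, a
#' partitioning refinement keeps the tree monotone: any cluster lying closer
#' to the new centroid than the just-merged distance triggers a k-means-like
#' reallocation of electrodes among the merged cluster and the violating
#' clusters (electrode-to-centroid distances), iterated to convergence with
#' an iteration cap. Ties in the closest pair are broken by the lowest
#' cluster index pair, so the result is deterministic given input order.
#'
#' @param profiles electrodes x timepoints matrix, rows normalized to \[0,1\]
#'   (see [normalize_profiles()]).
#' @param method distance variant, as in [profile_distance()].
#' @param max_refine cap on refinement sweeps per merge.
#' @return object of class `cluster_tree`: list with `merges` (data.frame:
#'   `step`, `k`, `height`), `assignments` (list of membership vectors
#'   indexed by as.character(k) for k = n..1), `profiles`, `method`.
#' @export
hybrid_cluster <- function(profiles, method = c("exponential", "squared"),
                           max_refine = 100L) {
  method <- match.arg(method)
  n <- nrow(profiles)
  if (is.null(n) || n < 2L) stop("need at least 2 profiles")
  member <- seq_len(n)                 # cluster id per electrode
  active <- seq_len(n)                 # live cluster ids
  centroid <- profiles                 # row i = centroid of cluster i
  cdist <- function(a, b) profile_distance(centroid[a, ], centroid[b, ], method)
  edist <- function(e, a) profile_distance(profiles[e, ], centroid[a, ], method)
  D <- profile_distance_matrix(profiles, method)
  diag(D) <- Inf
  assignments <- list()
  assignments[[as.character(n)]] <- member
  merges <- data.frame(step = integer(0), k = integer(0), height = numeric(0))
  last_height <- 0
  step <- 0L
  while (length(active) > 1L) {
    sub <- D[active, active, drop = FALSE]
    ij <- which(sub == min(sub), arr.ind = TRUE)
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE][1, ]
    a <- active[min(ij)]; b <- active[max(ij)]
    h <- sub[ij[1], ij[2]]
    member[member == b] <- a
    active <- setdiff(active, b)
    centroid[a, ] <- colMeans(profiles[member == a, , drop = FALSE])
    D[a, active] <- D[active, a] <-
      vapply(active, function(x) if (x == a) Inf else cdist(a, x), numeric(1))
    # partitioning refinement: clusters closer to the new centroid than the
    # merge height break monotonicity; reallocate among them
    for (iter in seq_len(max_refine)) {
      viol <- active[active != a & D[a, active] < h]
      if (!length(viol)) break
      pool_clusters <- c(a, viol)
      pool_elec <- which(member %in% pool_clusters)
      moved <- FALSE
      for (e in pool_elec) {
        cur <- member[e]
        if (sum(member == cur) == 1L) next     # never empty a cluster
        d_e <- vapply(pool_clusters, function(cl) edist(e, cl), numeric(1))
        best <- pool_clusters[which.min(d_e)]
        if (best != cur) { member[e] <- best; moved <- TRUE }
      }
      for (cl in pool_clusters) {
        centroid[cl, ] <- colMeans(profiles[member == cl, , drop = FALSE])
        D[cl, active] <- D[active, cl] <-
          vapply(active, function(x) if (x == cl) Inf else cdist(cl, x), numeric(1))
      }
      if (!moved) break
    }
    h <- max(h, last_height)           # enforce a monotone recorded tree
    last_height <- h
    step <- step + 1L
    merges <- rbind(merges, data.frame(step = step, k = length(active), height = h))
    assignments[[as.character(length(active))]] <- member
  }
  structure(list(merges = merges, assignments = assignments,
                 profiles = profiles, method = method),
            class = "cluster_tree")
}

#' Select the number of clusters
#'
#' Combines two criteria computed from the tree. The elbow candidate is the
#' cluster count with the largest second difference of the log
#' merge-distance versus cluster-count curve — the point where the *rate*
#' of distance reduction from adding clusters slows most sharply; the log
#' form keys on relative slowing, which is what a visual elbow on a curve
#' spanning orders of magnitude reflects, and is insensitive to large but
#' proportionally mild gaps higher in the tree. The variance candidate is
#' the smallest k whose explained
#' variance (1 - SS_within / SS_total on the normalized profiles) gains less
#' than `ev_gain` from moving to k + 1. When the two agree that value is
#' returned; otherwise both are reported and the variance candidate is used.
#'
#' @param tree a [hybrid_cluster()] result.
#' @param max_k largest cluster count considered.
#' @param ev_gain marginal explained-variance gain threshold (default 0.05).
#' @return list with `k`, `elbow_k`, `variance_k`, `agreement`,
#'   `explained_variance` (named vector over k), `heights`.
#' @export
select_cluster_count <- function(tree, max_k = 15L, ev_gain = 0.05) {
  stopifnot(inherits(tree, "cluster_tree"))
  if (nrow(tree$merges) < 3L) stop("tree too small to locate an elbow")
  profiles <- tree$profiles
  n <- nrow(profiles)
  kmax <- min(max_k, n - 1L)
  # d(k): merge height paid to go below k+1 clusters, i.e. height of the
  # merge that produced k clusters
  hk <- tree$merges$height[match(seq_len(kmax), tree$merges$k)]
  lh <- log(pmax(hk, 1e-12))
  d2 <- c(NA, diff(diff(lh)), NA)      # second difference over k = 1..kmax
  elbow_k <- which.max(replace(d2, is.na(d2), -Inf))
  ev <- vapply(seq_len(kmax), function(k) explained_variance(tree, k), numeric(1))
  gains <- c(diff(ev), 0)
  variance_k <- which(gains < ev_gain)[1]
  if (is.na(variance_k)) variance_k <- kmax
  agreement <- elbow_k == variance_k
  list(k = if (agreement) elbow_k else variance_k,
       elbow_k = elbow_k, variance_k = variance_k, agreement = agreement,
       explained_variance = stats::setNames(ev, seq_len(kmax)),
       heights = stats::setNames(hk, seq_len(kmax)))
}

# 1 - SS_within / SS_total at a k-cluster cut
explained_variance <- function(tree, k) {
  member <- cut_tree(tree, k)
  profiles <- tree$profiles
  gm <- colMeans(profiles)
  ss_tot <- sum(sweep(profiles, 2, gm)^2)
  if (ss_tot == 0) return(1)
  ss_w <- 0
  for (cl in unique(member)) {
    rows <- profiles[member == cl, , drop = FALSE]
    ss_w <- ss_w + sum(sweep(rows, 2, colMeans(rows))^2)
  }
  1 - ss_w / ss_tot
}

# membership vector (1..k, renumbered in first-appearance order) at a cut
cut_tree <- function(tree, k) {
  m <- tree$assignments[[as.character(k)]]
  if (is.null(m)) stop("no cut with k = ", k, " recorded in the tree")
  match(m, unique(m))
}

#' Cut the tree and label clusters by response onset
#'
#' Cuts the tree at `k` clusters, computes each cluster's centroid trace,
#' derives timing landmarks for every centroid with the trend analysis, and
#' renumbers clusters C1..Ck by ascending start landmark (response onset
#' time). If the trend analysis declares a centroid non-responsive its
#' onset falls back to the time the centroid first crosses half its range,
#' with a warning.
#'
#' @param tree a [hybrid_cluster()] result.
#' @param k number of clusters (1..n).
#' @param time_ms time axis of the profiles (ms relative to voice onset).
#' @param baseline_window length-2 ms baseline window for the trend
#'   analysis of centroids (default the first 500 ms of the axis).
#' @param threshold change threshold applied to the \[0,1\]-normalized
#'   centroids (default 0.2).
#' @param config a [trend_config_default()].
#' @return object of class `cluster_assignment`: list with `membership`
#'   (integer vector, 1..k by onset order), `centroids` (k x T), `landmarks`
#'   (list per cluster or NULL), `share` (percent of electrodes per
#'   cluster), `time_ms`.
#' @export
assign_clusters <- function(tree, k, time_ms = NULL,
                            baseline_window = NULL, threshold = 0.2,
                            config = trend_config_default()) {
  stopifnot(inherits(tree, "cluster_tree"))
  n <- nrow(tree$profiles)
  if (k < 1L || k > n) stop("k out of range")
  member <- if (k == n) seq_len(n) else cut_tree(tree, k)
  if (is.null(time_ms)) time_ms <- seq_len(ncol(tree$profiles))
  if (is.null(baseline_window)) {
    baseline_window <- c(min(time_ms), min(time_ms) + 500)
  }
  ids <- sort(unique(member))
  centroids <- t(vapply(ids, function(cl) {
    colMeans(tree$profiles[member == cl, , drop = FALSE])
  }, numeric(ncol(tree$profiles))))
  onset <- numeric(length(ids))
  landmarks <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    tr <- centroids[j, ]
    res <- tryCatch({
      cps <- detect_change_points(tr, time_ms, baseline_window, threshold, config)
      lm <- extract_landmarks(tr, time_ms, cps)
      landmarks[[j]] <- lm
      lm$start_ms
    }, error = function(e) NA_real_)
    if (is.na(res)) {
      warning("centroid ", j, " not responsive under the trend analysis; ",
              "using half-range crossing for ordering")
      res <- time_ms[which(tr >= min(tr) + 0.5 * (max(tr) - min(tr)))[1]]
    }
    onset[j] <- res
  }
  ord <- order(onset, ids)
  relabel <- match(member, ids[ord])
  structure(list(
    membership = relabel,
    centroids = centroids[ord, , drop = FALSE],
    landmarks = landmarks[ord],
    share = 100 * as.numeric(table(factor(relabel, levels = seq_along(ids)))) / n,
    time_ms = time_ms
  ), class = "cluster_assignment")
}
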