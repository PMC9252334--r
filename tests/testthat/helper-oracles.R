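# Independent oracles used by the unit and acceptance tests.

# Brute-force ST-DBSCAN: full pairwise neighbourhood graph, core points by
# degree, clusters as connected components of the core subgraph (igraph),
# borders assigned to the earliest-discovered adjacent cluster.
oracle_stdbscan <- function(times, coords, eps_s, eps_t, min_pts) {
  n <- length(times)
  coords <- as.matrix(coords)
  if (n == 0L) return(integer(0))
  D <- as.matrix(stats::dist(coords))
  Tm <- abs(outer(times, times, "-"))
  adj <- D <= eps_s & Tm <= eps_t
  core <- rowSums(adj) >= min_pts  # self included
  labels <- rep(-1L, n)
  if (!any(core)) return(labels)
  core_idx <- which(core)
  g <- igraph::graph_from_adjacency_matrix(
    adj[core_idx, core_idx, drop = FALSE], mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  first_idx <- tapply(core_idx, comp, min)
  ordered <- integer(max(comp))
  ordered[order(first_idx)] <- seq_along(first_idx)
  labels[core_idx] <- ordered[comp]
  for (i in which(!core)) {
    nbc <- core_idx[adj[i, core_idx]]
    if (length(nbc)) labels[i] <- min(labels[nbc])
  }
  labels
}

# All permutations of a vector (independent of the package's internal one).
perms_of <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1L))
  do.call(rbind, lapply(seq_len(n), function(i) cbind(v[i], perms_of(v[-i]))))
}

# Exact right-tailed Spearman p by direct enumeration with cor().
oracle_spearman_right <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  obs <- stats::cor(rx, ry)
  P <- perms_of(seq_along(y))
  rhos <- apply(P, 1, function(p) stats::cor(rx, ry[p]))
  mean(rhos >= obs - 1e-12)
}

# Exact two-sided Wilcoxon signed-rank p by sign enumeration.
oracle_wilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wd <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(Wd >= W - 1e-9), mean(Wd <= W + 1e-9)))
}

# A tiny hand-built pose sequence: static hips plus caller-supplied ankle
# tracks (matrices frames x 2 or 3).
toy_sequence <- function(left_ankle, right_ankle = NULL, fps = 30,
                         hip_sep = 20) {
  nf <- nrow(left_ankle)
  d <- ncol(left_ankle)
  if (is.null(right_ankle)) {
    right_ankle <- left_ankle
    right_ankle[, 1] <- right_ankle[, 1] + hip_sep
  }
  jn <- c("left_hip", "right_hip", "left_ankle", "right_ankle")
  coords <- array(NA_real_, c(nf, 4, d), dimnames = list(NULL, jn, NULL))
  coords[, "left_hip", ] <- matrix(rep(c(100, 50, 3)[seq_len(d)], each = nf),
                                   nf)
  coords[, "right_hip", ] <- matrix(rep(c(100 + hip_sep, 50, 3)[seq_len(d)],
                                        each = nf), nf)
  coords[, "left_ankle", ] <- left_ankle
  coords[, "right_ankle", ] <- right_ankle
  pose_sequence(coords, fps = fps,
                confidence = matrix(1, nf, 4, dimnames = list(NULL, jn)),
                missing = matrix(FALSE, nf, 4, dimnames = list(NULL, jn)))
}

# Ankle track with flat plateaus separated by linear transitions.
plateau_track <- function(levels, plateau_frames = 12, trans_frames = 9,
                          y = 400) {
  xs <- numeric(0)
  for (i in seq_along(levels)) {
    xs <- c(xs, rep(levels[i], plateau_frames))
    if (i < length(levels)) {
      xs <- c(xs, levels[i] + seq_len(trans_frames) / (trans_frames + 1) *
                (levels[i + 1] - levels[i]))
    }
  }
  cbind(xs, rep(y, length(xs)))
}
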