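# Two-step cluster analysis on the N x 15 composite score matrix.
#
# Step 1 compresses subjects into pre-clusters with a CF (clustering
# feature) tree: each entry keeps the sufficient statistics (n, linear sum,
# square sum), points are absorbed into the closest entry when the centroid
# distance is within the current threshold, and the tree is rebuilt with a
# raised threshold when it outgrows its capacity. At study scale (N in the
# hundreds) the tree is bypassed by default and every subject is its own
# pre-cluster, which makes the procedure deterministic and
# insertion-order-free.
#
# Step 2 merges pre-clusters by centroid-linkage agglomeration (Euclidean),
# records the BIC of every partition along the way, and selects the number
# of clusters with a two-stage rule: a coarse estimate from the flattening
# of successive BIC improvements, then refinement by the ratio of merge
# distances.

# ---- pre-cluster sufficient statistics ------------------------------------

new_precluster_set <- function(n, ls, ss, members) {
  stopifnot(nrow(ls) == length(n), nrow(ss) == length(n), length(members) == length(n))
  structure(list(n = as.numeric(n), ls = ls, ss = ss, members = members),
            class = "precluster_set")
}

#' @export
print.precluster_set <- function(x, ...) {
  cat("<precluster_set> ", length(x$n), " pre-cluster(s), ",
      sum(x$n), " point(s), d=", ncol(x$ls), "\n", sep = "")
  invisible(x)
}

precluster_centroids <- function(pc) pc$ls / pc$n

#' CF-tree parameters
#'
#' @param branching_factor Maximum child entries per internal node.
#' @param max_leaf_entries Maximum entries per leaf node.
#' @param max_depth Maximum tree depth before a rebuild is triggered.
#' @param initial_threshold Starting absorption threshold (Euclidean
#'   distance between a point and an entry centroid); 0 absorbs only exact
#'   duplicates.
#' @param bypass_tree If `TRUE`, skip the tree entirely and return one
#'   singleton pre-cluster per point.
#' @return A list of class `cf_tree_params`.
#' @export
cf_tree_params <- function(branching_factor = 8, max_leaf_entries = 8,
                           max_depth = 3, initial_threshold = 0,
                           bypass_tree = FALSE) {
  stopifnot(branching_factor >= 2, max_leaf_entries >= 2, max_depth >= 1,
            initial_threshold >= 0)
  structure(list(branching_factor = branching_factor,
                 max_leaf_entries = max_leaf_entries,
                 max_depth = max_depth,
                 initial_threshold = initial_threshold,
                 bypass_tree = isTRUE(bypass_tree)),
            class = "cf_tree_params")
}

# Entries are lists (n, ls, ss, members); nodes are lists with $leaf and
# either $entries (leaf) or $children + $cf (internal, one CF per child).
.entry_centroid <- function(e) e$ls / e$n

.merge_entries <- function(a, b) {
  list(n = a$n + b$n, ls = a$ls + b$ls, ss = a$ss + b$ss,
       members = c(a$members, b$members))
}

.split_entries <- function(entries) {
  cents <- do.call(rbind, lapply(entries, .entry_centroid))
  dmat <- as.matrix(stats::dist(cents))
  far <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
  s1 <- min(far); s2 <- max(far)
  g1 <- list(); g2 <- list()
  for (i in seq_along(entries)) {
    if (i == s1) g1[[length(g1) + 1]] <- entries[[i]]
    else if (i == s2) g2[[length(g2) + 1]] <- entries[[i]]
    else if (dmat[i, s1] <= dmat[i, s2]) g1[[length(g1) + 1]] <- entries[[i]]
    else g2[[length(g2) + 1]] <- entries[[i]]
  }
  list(g1, g2)
}

.node_cf <- function(node) {
  ents <- if (node$leaf) node$entries else node$cf
  n <- sum(vapply(ents, `[[`, numeric(1), "n"))
  ls <- Reduce(`+`, lapply(ents, `[[`, "ls"))
  ss <- Reduce(`+`, lapply(ents, `[[`, "ss"))
  list(n = n, ls = ls, ss = ss, members = integer(0))
}

# Insert an entry; returns list(node=, split=NULL | list(nodeA, nodeB)).
.insert_entry <- function(node, entry, threshold, params) {
  if (node$leaf) {
    if (length(node$entries)) {
      cents <- do.call(rbind, lapply(node$entries, .entry_centroid))
      d <- sqrt(colSums((t(cents) - .entry_centroid(entry))^2))
      j <- which.min(d)
      if (d[j] <= threshold) {
        node$entries[[j]] <- .merge_entries(node$entries[[j]], entry)
        return(list(node = node, split = NULL))
      }
    }
    node$entries[[length(node$entries) + 1]] <- entry
    if (length(node$entries) > params$max_leaf_entries) {
      halves <- .split_entries(node$entries)
      return(list(node = NULL, split = list(
        list(leaf = TRUE, entries = halves[[1]]),
        list(leaf = TRUE, entries = halves[[2]])
      )))
    }
    return(list(node = node, split = NULL))
  }
  cents <- do.call(rbind, lapply(node$cf, .entry_centroid))
  d <- sqrt(colSums((t(cents) - .entry_centroid(entry))^2))
  j <- which.min(d)
  res <- .insert_entry(node$children[[j]], entry, threshold, params)
  if (is.null(res$split)) {
    node$children[[j]] <- res$node
    node$cf[[j]] <- .node_cf(res$node)
    return(list(node = node, split = NULL))
  }
  node$children[[j]] <- res$split[[1]]
  node$cf[[j]] <- .node_cf(res$split[[1]])
  node$children[[length(node$children) + 1]] <- res$split[[2]]
  node$cf[[length(node$cf) + 1]] <- .node_cf(res$split[[2]])
  if (length(node$children) > params$branching_factor) {
    grouped <- .split_entries(node$cf)
    idx_of <- function(cf_list, pool) match(
      vapply(cf_list, function(e) paste(e$ls, collapse = ","), character(1)),
      vapply(pool, function(e) paste(e$ls, collapse = ","), character(1)))
    # regroup children by the same farthest-pair split applied to their CFs
    cents2 <- do.call(rbind, lapply(node$cf, .entry_centroid))
    dmat <- as.matrix(stats::dist(cents2))
    far <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
    s1 <- min(far); s2 <- max(far)
    g1 <- s1; g2 <- s2
    for (i in seq_along(node$cf)) {
      if (i %in% c(s1, s2)) next
      if (dmat[i, s1] <= dmat[i, s2]) g1 <- c(g1, i) else g2 <- c(g2, i)
    }
    mk <- function(idx) list(leaf = FALSE, children = node$children[idx],
                             cf = node$cf[idx])
    return(list(node = NULL, split = list(mk(g1), mk(g2))))
  }
  list(node = node, split = NULL)
}

.tree_depth <- function(node) {
  if (node$leaf) return(1L)
  1L + max(vapply(node$children, .tree_depth, integer(1)))
}

.leaf_count <- function(node) {
  if (node$leaf) return(1L)
  sum(vapply(node$children, .leaf_count, integer(1)))
}

.collect_entries <- function(node) {
  if (node$leaf) return(node$entries)
  do.call(c, lapply(node$children, .collect_entries))
}

#' Build the CF-tree pre-clustering
#'
#' Sequentially inserts subjects into a CF-tree: each point descends to the
#' leaf entry with the closest centroid and is absorbed when within the
#' threshold, otherwise it opens a new entry. Overflowing leaves split; when
#' the tree exceeds its depth or leaf capacity it is rebuilt from its
#' entries with the threshold raised to the smallest inter-entry centroid
#' distance observed. Insertion order is the row order of `scores` (a
#' deterministic choice; shuffle beforehand for a sensitivity analysis).
#'
#' @param scores An `als_scores` tibble or a numeric matrix (subjects x
#'   variables), no missing values.
#' @param params A [cf_tree_params()] list. With `bypass_tree = TRUE` every
#'   subject becomes its own pre-cluster and the tree is never built.
#' @return A `precluster_set`: parallel sufficient statistics (`n`, linear
#'   sums `ls`, square sums `ss`) and the member row indices of each
#'   pre-cluster.
#' @export
build_cf_tree <- function(scores, params = cf_tree_params()) {
  x <- if (is.matrix(scores)) scores else score_matrix(scores)
  if (nrow(x) < 1) stop("empty input", call. = FALSE)
  if (anyNA(x)) stop("missing values in score matrix", call. = FALSE)
  n <- nrow(x)
  if (params$bypass_tree) {
    return(new_precluster_set(rep(1, n), x, x^2,
                              members = as.list(seq_len(n))))
  }
  threshold <- params$initial_threshold
  max_leaves <- params$branching_factor^params$max_depth
  root <- list(leaf = TRUE, entries = list())
  point_entry <- function(i) list(n = 1, ls = x[i, ], ss = x[i, ]^2, members = i)

  insert_top <- function(root, entry, threshold) {
    res <- .insert_entry(root, entry, threshold, params)
    if (!is.null(res$split)) {
      root <- list(leaf = FALSE, children = res$split,
                   cf = lapply(res$split, .node_cf))
    } else {
      root <- res$node
    }
    root
  }
  rebuild <- function(root, threshold) {
    entries <- .collect_entries(root)
    cents <- do.call(rbind, lapply(entries, .entry_centroid))
    new_thr <- threshold
    if (nrow(cents) >= 2) {
      dd <- stats::dist(cents)
      pos <- dd[dd > 0]
      if (length(pos)) new_thr <- max(new_thr, min(pos))
    }
    if (new_thr <= threshold) new_thr <- if (threshold > 0) 2 * threshold else 1e-8
    root <- list(leaf = TRUE, entries = list())
    for (e in entries) root <- insert_top(root, e, new_thr)
    list(root = root, threshold = new_thr)
  }
  for (i in seq_len(n)) {
    root <- insert_top(root, point_entry(i), threshold)
    while (.tree_depth(root) > params$max_depth || .leaf_count(root) > max_leaves) {
      rb <- rebuild(root, threshold)
      root <- rb$root; threshold <- rb$threshold
    }
  }
  entries <- .collect_entries(root)
  new_precluster_set(
    n = vapply(entries, `[[`, numeric(1), "n"),
    ls = do.call(rbind, lapply(entries, `[[`, "ls")),
    ss = do.call(rbind, lapply(entries, `[[`, "ss")),
    members = lapply(entries, `[[`, "members")
  )
}

# ---- BIC ------------------------------------------------------------------

# Per-cluster log-likelihood term xi_j = -N_j * sum_v 0.5*log(sigma_v^2 +
# sigma_jv^2), with maximum-likelihood (1/N) variances and a relative floor
# on the within-cluster variance to guard log(0) in degenerate clusters.
.xi_term <- function(n_j, ls_j, ss_j, cohort_var, floor_frac = 1e-9) {
  centroid <- ls_j / n_j
  var_j <- pmax(ss_j / n_j - centroid^2, 0)
  var_j <- pmax(var_j, floor_frac * cohort_var)
  -n_j * sum(0.5 * log(cohort_var + var_j))
}

#' BIC of a partition of pre-clusters
#'
#' `BIC(J) = -2 * sum_j xi_j + m_J * log(N)` with `m_J = 2 * d * J`
#' parameters (a mean and a variance per variable per cluster) and
#' `xi_j = -N_j * sum_v 0.5 * log(sigma_v^2 + sigma_jv^2)`, where
#' `sigma_v^2` is the cohort (maximum-likelihood) variance of variable `v`
#' and `sigma_jv^2` the within-cluster variance. Lower is better; the
#' penalty grows linearly in the number of clusters.
#'
#' @param preclusters A `precluster_set`.
#' @param partition Integer vector assigning each pre-cluster to a cluster.
#' @return The BIC value (scalar).
#' @export
twostep_bic <- function(preclusters, partition) {
  stopifnot(length(partition) == length(preclusters$n))
  N <- sum(preclusters$n)
  d <- ncol(preclusters$ls)
  tot_ls <- colSums(preclusters$ls)
  tot_ss <- colSums(preclusters$ss)
  cohort_var <- pmax(tot_ss / N - (tot_ls / N)^2, .Machine$double.eps)
  labels <- unique(partition)
  xi <- 0
  for (lab in labels) {
    idx <- which(partition == lab)
    n_j <- sum(preclusters$n[idx])
    if (n_j == 0) stop("empty cluster in partition", call. = FALSE)
    ls_j <- colSums(preclusters$ls[idx, , drop = FALSE])
    ss_j <- colSums(preclusters$ss[idx, , drop = FALSE])
    xi <- xi + .xi_term(n_j, ls_j, ss_j, cohort_var)
  }
  -2 * xi + 2 * d * length(labels) * log(N)
}

# ---- agglomeration --------------------------------------------------------

#' Centroid-linkage agglomeration of pre-clusters
#'
#' Repeatedly merges the pair of clusters whose centroids are closest in
#' Euclidean distance, summing their sufficient statistics exactly, until a
#' single cluster remains. Records the merge sequence, the partition at
#' every intermediate cluster count, and the BIC trace. Ties in the minimum
#' distance are broken by the lexicographically lowest cluster-index pair.
#'
#' @param preclusters A `precluster_set` with at least 2 pre-clusters.
#' @return A `twostep_dendrogram`: list with `k0` (starting cluster count),
#'   `merges` (tibble `step`, `cluster_a`, `cluster_b`, `distance`,
#'   `k_after`), `partitions` (pre-cluster membership vector for every k),
#'   `bic` (tibble `k`, `bic`) and the `preclusters` themselves.
#' @export
agglomerate_preclusters <- function(preclusters) {
  K0 <- length(preclusters$n)
  if (K0 < 2) stop("need at least 2 pre-clusters to agglomerate", call. = FALSE)
  n <- preclusters$n
  ls <- preclusters$ls
  ss <- preclusters$ss
  active <- rep(TRUE, K0)
  membership <- seq_len(K0)
  cent <- ls / n
  D <- as.matrix(stats::dist(cent))
  diag(D) <- Inf

  partitions <- vector("list", K0)   # partitions[[k]] = membership at k clusters
  partitions[[K0]] <- membership
  bic <- rep(NA_real_, K0)
  bic[K0] <- twostep_bic(preclusters, membership)
  merges <- vector("list", K0 - 1)

  for (k in K0:2) {
    act <- which(active)
    sub <- D[act, act, drop = FALSE]
    mn <- min(sub)
    hits <- which(sub == mn, arr.ind = TRUE)
    pairs <- cbind(act[hits[, 1]], act[hits[, 2]])
    pairs <- t(apply(pairs, 1, sort))
    pairs <- unique(pairs)
    ord <- order(pairs[, 1], pairs[, 2])
    i <- pairs[ord[1], 1]; j <- pairs[ord[1], 2]

    n[i] <- n[i] + n[j]
    ls[i, ] <- ls[i, ] + ls[j, ]
    ss[i, ] <- ss[i, ] + ss[j, ]
    active[j] <- FALSE
    membership[membership == j] <- i
    cent_i <- ls[i, ] / n[i]
    others <- which(active)
    D[i, others] <- D[others, i] <-
      sqrt(colSums((t(ls[others, , drop = FALSE] / n[others]) - cent_i)^2))
    D[i, i] <- Inf
    D[j, ] <- D[, j] <- Inf

    merges[[K0 - k + 1]] <- tibble::tibble(
      step = K0 - k + 1L, cluster_a = i, cluster_b = j,
      distance = mn, k_after = k - 1L)
    partitions[[k - 1]] <- membership
    bic[k - 1] <- twostep_bic(preclusters, membership)
  }
  structure(list(
    k0 = K0,
    merges = dplyr::bind_rows(merges),
    partitions = partitions,
    bic = tibble::tibble(k = seq_len(K0), bic = bic),
    preclusters = preclusters
  ), class = "twostep_dendrogram")
}

#' @export
print.twostep_dendrogram <- function(x, ...) {
  cat("<twostep_dendrogram> ", x$k0, " pre-clusters agglomerated; BIC traced for k=1..",
      x$k0, "\n", sep = "")
  invisible(x)
}

#' Pre-cluster partition at a given cluster count
#'
#' @param dendrogram A `twostep_dendrogram`.
#' @param k Number of clusters.
#' @return Integer vector of contiguous labels `1..k`, one per pre-cluster.
#' @export
partition_at <- function(dendrogram, k) {
  stopifnot(k >= 1, k <= dendrogram$k0)
  raw <- dendrogram$partitions[[k]]
  match(raw, unique(raw))
}

# ---- automatic selection of the number of clusters ------------------------

#' Select the number of clusters from the BIC trace
#'
#' Two-stage rule. Stage 1 (coarse): with `dBIC(k) = BIC(k) - BIC(k+1)` (the
#' improvement gained by allowing a (k+1)-th cluster), the coarse estimate
#' is the smallest `k` whose relative improvement `dBIC(k)/dBIC(1)` falls
#' below `c1`; if `dBIC(1) <= 0` a single cluster is selected outright.
#' Stage 2 (refinement): among `k` up to the coarse estimate, compute the
#' merge-distance ratios `R(k) = d(k)/d(k+1)` where `d(k)` is the centroid
#' distance of the merge reducing `k` clusters to `k-1`. If the largest
#' ratio exceeds the second largest by more than `c2`, its `k` is selected;
#' otherwise the larger of the two candidate `k` wins.
#'
#' @param dendrogram A `twostep_dendrogram`.
#' @param c1 Stage-1 BIC-change ratio threshold.
#' @param c2 Stage-2 distance-ratio dominance threshold.
#' @param k_max Largest cluster count considered.
#' @return A list with `k` and a `diagnostics` list (`bic_change_ratios`,
#'   `distance_ratios`, `coarse_k`).
#' @export
select_cluster_count <- function(dendrogram, c1 = 0.04, c2 = 1.15, k_max = 15) {
  if (k_max < 2) stop("k_max must be at least 2", call. = FALSE)
  k_max <- min(k_max, dendrogram$k0)
  bic <- dendrogram$bic$bic
  dbic <- bic[seq_len(k_max - 1)] - bic[seq_len(k_max - 1) + 1]  # dBIC(k), k=1..k_max-1
  ratios <- dbic / dbic[1]
  diagnostics <- list(bic_change_ratios = ratios, distance_ratios = NULL,
                      coarse_k = NA_integer_)
  if (dbic[1] <= 0) {
    diagnostics$coarse_k <- 1L
    return(list(k = 1L, diagnostics = diagnostics))
  }
  below <- which(ratios < c1)
  coarse <- if (length(below)) below[1] else k_max
  diagnostics$coarse_k <- as.integer(coarse)
  if (coarse == 1L) return(list(k = 1L, diagnostics = diagnostics))

  merge_dist <- function(k) {
    # distance of the merge that reduces k clusters to k-1
    dendrogram$merges$distance[dendrogram$merges$k_after == k - 1L]
  }
  ks <- 2:coarse
  R <- vapply(ks, function(k) merge_dist(k) / merge_dist(k + 1), numeric(1))
  names(R) <- ks
  diagnostics$distance_ratios <- R
  if (length(R) == 1) return(list(k = ks[1], diagnostics = diagnostics))
  ord <- order(R, decreasing = TRUE)
  top <- ord[1]; second <- ord[2]
  k_sel <- if (R[top] / R[second] > c2) ks[top] else max(ks[top], ks[second])
  list(k = as.integer(k_sel), diagnostics = diagnostics)
}

# ---- assignment and silhouette --------------------------------------------

#' Subject-level cluster assignments for a chosen partition
#'
#' Maps every subject to the cluster of its pre-cluster at `k` clusters and
#' relabels clusters by increasing size, so cluster 1 is the smallest (for
#' the two-cluster solution this mirrors the convention that cluster 1 is
#' the minority subtype). An optional refinement pass reassigns each subject
#' to the nearest final centroid (off by default).
#'
#' @param scores `als_scores` tibble or numeric matrix used for clustering.
#' @param dendrogram A `twostep_dendrogram`.
#' @param k Number of clusters.
#' @param refine If `TRUE`, one pass of nearest-centroid reassignment.
#' @return A list with `cluster` (integer vector per subject), `centroids`
#'   (k x d matrix) and `sizes`.
#' @export
assign_clusters <- function(scores, dendrogram, k, refine = FALSE) {
  x <- if (is.matrix(scores)) scores else score_matrix(scores)
  part <- partition_at(dendrogram, k)
  cluster <- integer(nrow(x))
  for (p in seq_along(part)) {
    cluster[dendrogram$preclusters$members[[p]]] <- part[p]
  }
  if (refine && k >= 2) {
    cent <- centroids_of(x, cluster)
    d2 <- sapply(seq_len(nrow(cent)), function(j) colSums((t(x) - cent[j, ])^2))
    cluster <- max.col(-d2, ties.method = "first")
  }
  # relabel by increasing cluster size; ties by first subject index
  sizes <- tabulate(cluster, nbins = max(cluster))
  first_seen <- vapply(seq_along(sizes), function(lab) {
    w <- which(cluster == lab)
    if (length(w)) w[1] else Inf
  }, numeric(1))
  keep <- sizes > 0
  ord <- order(sizes[keep], first_seen[keep])
  relabel <- integer(length(sizes))
  relabel[which(keep)[ord]] <- seq_len(sum(keep))
  cluster <- relabel[cluster]
  list(cluster = cluster,
       centroids = centroids_of(x, cluster),
       sizes = tabulate(cluster))
}

centroids_of <- function(x, cluster) {
  labs <- sort(unique(cluster))
  cent <- t(vapply(labs, function(lab) colMeans(x[cluster == lab, , drop = FALSE]),
                   numeric(ncol(x))))
  rownames(cent) <- labs
  cent
}

#' Mean silhouette coefficient
#'
#' Standard silhouette with Euclidean distance: for subject `i`,
#' `s(i) = (b - a) / max(a, b)` where `a` is the mean distance to the other
#' members of its cluster and `b` the mean distance to the nearest other
#' cluster; `s(i) = 0` for members of singleton clusters. Values of 0.5-0.7
#' are conventionally read as a reasonable cluster structure.
#'
#' @param scores `als_scores` tibble or numeric matrix.
#' @param cluster Integer vector of cluster labels (at least 2 clusters).
#' @return Mean silhouette over subjects, in \[-1, 1\].
#' @export
mean_silhouette <- function(scores, cluster) {
  mean(silhouette_widths(scores, cluster))
}

#' Per-subject silhouette widths
#'
#' @inheritParams mean_silhouette
#' @return Numeric vector of silhouette widths, one per subject.
#' @export
silhouette_widths <- function(scores, cluster) {
  x <- if (is.matrix(scores)) scores else score_matrix(scores)
  labs <- unique(cluster)
  if (length(labs) < 2) stop("silhouette requires at least 2 clusters", call. = FALSE)
  D <- as.matrix(stats::dist(x))
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cluster == cluster[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- sum(D[i, own]) / (sum(own) - 1)
    b <- min(vapply(setdiff(labs, cluster[i]),
                    function(lab) mean(D[i, cluster == lab]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# ---- top-level fit --------------------------------------------------------

#' Two-step cluster analysis of composite scores
#'
#' Runs the full procedure on the N x 15 score matrix: CF-tree
#' pre-clustering (bypassed by default at study scale, making every subject
#' a pre-cluster), centroid-linkage agglomeration with a BIC trace,
#' automatic selection of the number of clusters, subject assignment and
#' silhouette evaluation.
#'
#' @param scores An `als_scores` tibble from [composite_scores()] (or a
#'   numeric matrix with subject row names).
#' @param k Fix the number of clusters instead of selecting it by BIC.
#' @param bypass_tree If `TRUE` (default), skip the CF-tree: deterministic
#'   and insertion-order-free, appropriate for cohorts of a few hundred.
#' @param cf_params CF-tree parameters for `bypass_tree = FALSE`.
#' @param k_max,c1,c2 Auto-selection controls, see [select_cluster_count()].
#' @param refine One nearest-centroid reassignment pass after cutting the
#'   dendrogram (default off).
#' @param shuffle_seed If non-`NULL`, shuffle subject insertion order with
#'   this seed before building the CF-tree (sensitivity analysis only).
#' @return A `twostep_fit`: list with `k`, `assignments` (tibble
#'   `subject_id`, `cluster`), `centroids`, `cluster_sizes`, `silhouette`
#'   (`NA` when k = 1), `bic` trace tibble, `diagnostics` and
#'   `n_preclusters`.
#' @examples
#' coh <- simulate_cohort(n_subjects = 60, seed = 7)$cohort
#' scores <- composite_scores(reduce_bilateral(normalize_volumes(coh)))
#' fit <- cluster_twostep(scores)
#' glance(fit)
#' @export
cluster_twostep <- function(scores, k = NULL, bypass_tree = TRUE,
                            cf_params = cf_tree_params(), k_max = 15,
                            c1 = 0.04, c2 = 1.15, refine = FALSE,
                            shuffle_seed = NULL) {
  x <- if (is.matrix(scores)) scores else score_matrix(scores)
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  perm <- seq_len(nrow(x))
  if (!is.null(shuffle_seed) && !bypass_tree) {
    perm <- withr::with_seed(shuffle_seed, sample.int(nrow(x)))
  }
  cf_params$bypass_tree <- bypass_tree
  pcs <- build_cf_tree(x[perm, , drop = FALSE], cf_params)
  # map pre-cluster members back to original row indices
  pcs$members <- lapply(pcs$members, function(m) perm[m])
  dend <- agglomerate_preclusters(pcs)
  if (is.null(k)) {
    sel <- select_cluster_count(dend, c1 = c1, c2 = c2,
                                k_max = min(k_max, dend$k0))
    k <- sel$k
    diagnostics <- sel$diagnostics
  } else {
    diagnostics <- list(fixed_k = k)
  }
  asg <- assign_clusters(x, dend, k, refine = refine)
  sil <- if (k >= 2) mean_silhouette(x, asg$cluster) else NA_real_
  structure(list(
    k = k,
    assignments = tibble::tibble(subject_id = ids, cluster = asg$cluster),
    centroids = asg$centroids,
    cluster_sizes = asg$sizes,
    silhouette = sil,
    bic = dend$bic,
    diagnostics = diagnostics,
    dendrogram = dend,
    scores_matrix = x,
    n_preclusters = dend$k0,
    n = nrow(x)
  ), class = "twostep_fit")
}

#' @export
print.twostep_fit <- function(x, ...) {
  cat("<twostep_fit> ", x$n, " subjects -> k=", x$k, " cluster(s), sizes [",
      paste(x$cluster_sizes, collapse = ", "), "]", sep = "")
  if (!is.na(x$silhouette)) cat(", mean silhouette ", round(x$silhouette, 3), sep = "")
  cat("\n")
  invisible(x)
}
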