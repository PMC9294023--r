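# Independent oracles and small fixture builders used across the suite.

# Greedy centroid-linkage agglomeration on raw points, written naively
# (recomputes all centroids and all pairwise distances at every step) so it
# shares no code with the package implementation.
naive_agglomerate <- function(x) {
  membership <- seq_len(nrow(x))
  parts <- vector("list", nrow(x))
  parts[[nrow(x)]] <- membership
  dists <- numeric(0)
  while (length(unique(membership)) > 1) {
    labs <- sort(unique(membership))
    cents <- t(sapply(labs, function(l) colMeans(x[membership == l, , drop = FALSE])))
    D <- as.matrix(dist(cents)); diag(D) <- Inf
    mn <- min(D)
    hit <- which(D == mn, arr.ind = TRUE)
    hit <- unique(t(apply(hit, 1, sort)))
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    a <- labs[hit[1, 1]]; b <- labs[hit[1, 2]]
    membership[membership == b] <- a
    dists <- c(dists, mn)
    parts[[length(unique(membership))]] <- membership
  }
  list(distances = dists, partitions = parts)
}

# Brute-force silhouette: explicit double loop over subjects and clusters.
brute_silhouette <- function(x, cl) {
  n <- nrow(x)
  s <- numeric(n)
  edist <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  for (i in seq_len(n)) {
    same <- setdiff(which(cl == cl[i]), i)
    if (length(same) == 0) { s[i] <- 0; next }
    a <- mean(sapply(same, function(j) edist(i, j)))
    b <- Inf
    for (lab in setdiff(unique(cl), cl[i])) {
      others <- which(cl == lab)
      b <- min(b, mean(sapply(others, function(j) edist(i, j))))
    }
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# Same-partition check up to label names.
same_partition <- function(a, b) {
  length(unique(a)) == length(unique(b)) &&
    all(tapply(a, b, function(v) length(unique(v))) == 1)
}

# Spreadsheet-style recomputation of composite scores: plain loops and
# inline (x - min)/(max - min), independent of the package scoring path.
spreadsheet_scores <- function(features, rois) {
  n <- nrow(features)
  out <- matrix(NA_real_, n, nrow(rois), dimnames = list(NULL, rois$roi))
  for (i in seq_len(nrow(rois))) {
    gm <- rois$gm_members[[i]]; wm <- rois$wm_members[[i]]
    idx_list <- list()
    if (length(gm)) {
      v <- rep(0, n); for (col in gm) v <- v + features[[col]]
      idx_list <- c(idx_list, list(v))
    }
    if (rois$wm_mode[[i]] == "pooled") {
      v <- rep(0, n); for (col in wm) v <- v + features[[col]]
      idx_list <- c(idx_list, list(v))
    } else {
      for (col in wm) idx_list <- c(idx_list, list(features[[col]]))
    }
    total <- rep(0, n)
    for (v in idx_list) total <- total + (v - min(v)) / (max(v) - min(v))
    out[, i] <- total
  }
  out
}

# Small simulated cohort scored through the package pipeline.
scored_cohort <- function(n = 60, seed = 1, params = default_cohort_params()) {
  sim <- simulate_cohort(params, seed = seed, n_subjects = n)
  scores <- composite_scores(reduce_bilateral(normalize_volumes(sim$cohort)))
  list(sim = sim, scores = scores)
}

# Metadata + assignments fixture whose cross-tabulations reproduce the
# published per-cluster counts (sizes 76/138; male 54/86; right-handed
# 73/129; ALS-FTD 13/15; carriers 16/6 with 8/45 unscreened; ECAS impaired
# 20/21 with 9/21 unassessed).
paper_counts_fixture <- function() {
  fill <- function(n, counts, levels) {
    # counts named by level; NA_character_ allowed via level "missing"
    out <- rep(NA_character_, n)
    pos <- 1
    for (lev in names(counts)) {
      k <- counts[[lev]]
      if (k > 0) out[pos:(pos + k - 1)] <- if (lev == "missing") NA_character_ else lev
      pos <- pos + k
    }
    out
  }
  n1 <- 76; n2 <- 138
  meta <- tibble::tibble(
    subject_id = sprintf("S%03d", 1:(n1 + n2)),
    sex = c(fill(n1, c(male = 54, female = 22)),
            fill(n2, c(male = 86, female = 52))),
    handedness = c(fill(n1, c(right = 73, left = 3)),
                   fill(n2, c(right = 129, left = 9))),
    als_ftd = c(fill(n1, c(yes = 13, no = 63)),
                fill(n2, c(yes = 15, no = 123))),
    c9orf72 = c(fill(n1, c(carrier = 16, non_carrier = 52, missing = 8)),
                fill(n2, c(carrier = 6, non_carrier = 87, missing = 45))),
    ecas_impaired = c(fill(n1, c(yes = 20, no = 47, missing = 9)),
                      fill(n2, c(yes = 21, no = 96, missing = 21)))
  )
  assignments <- tibble::tibble(subject_id = meta$subject_id,
                                cluster = rep(1:2, c(n1, n2)))
  list(metadata = meta, assignments = assignments)
}
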