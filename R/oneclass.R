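#' Rebin an EFP onto a uniform comparison scheme and vectorize
#'
#' Brings fingerprints fitted under different band schemes into one space:
#' each model band row is replicated onto its member 1 Hz rows, the 1 Hz rows
#' are averaged within each band of the uniform comparison scheme, and the
#' resulting matrix is flattened band-major (delay fastest).
#'
#' @param model An [efp_model()].
#' @param uniform_scheme A [band_scheme()] covering the same frequency range.
#' @return Numeric vector of length `n_bands(uniform) * 48` with `session_id`
#'   and `scheme` attributes.
#' @export
rebin_efp <- function(model, uniform_scheme) {
  e_m <- model$scheme$edges_hz
  e_u <- uniform_scheme$edges_hz
  if (min(e_m) != min(e_u) || max(e_m) != max(e_u)) {
    abort("model and uniform schemes must cover the same frequency range.")
  }
  grid <- seq(min(e_m), max(e_m) - 1)  # 1 Hz rows: [f, f+1)
  src <- findInterval(grid, e_m, rightmost.closed = FALSE)
  expanded <- model$coeffs[src, , drop = FALSE]
  ub <- findInterval(grid, e_u, rightmost.closed = FALSE)
  collapsed <- rowsum(expanded, ub) / as.numeric(table(ub))
  v <- as.numeric(t(collapsed))
  attr(v, "session_id") <- model$fit_meta$session_id %||% ""
  attr(v, "scheme") <- uniform_scheme
  v
}

#' Correlation distance between two EFP vectors
#'
#' `1 - r`, where r is Pearson's correlation; bounded by `[0, 2]`, zero iff
#' the vectors are positively affinely related.
#'
#' @param a,b Equal-length numeric vectors with positive variance.
#' @return Scalar distance.
#' @export
efp_distance <- function(a, b) {
  if (length(a) != length(b)) abort("vectors must have equal length.")
  if (sd(a) == 0 || sd(b) == 0) abort("zero-variance vector; distance undefined.")
  1 - cor(as.numeric(a), as.numeric(b))
}

#' Agglomerative clustering of EFP vectors
#'
#' Iteratively merges the two clusters whose representative vectors are
#' closest in correlation distance; a cluster's representative is the plain
#' mean of all its member leaf vectors (so merge heights are reported as
#' computed and are not guaranteed monotone). Ties are broken toward the
#' lexicographically lowest pair of cluster labels (a cluster is labelled by
#' its smallest member session id). Merging stops when `stop_k` clusters
#' remain.
#'
#' @param vectors Named list of numeric vectors (names = session ids), or a
#'   list of [rebin_efp()] outputs carrying `session_id` attributes.
#' @param stop_k Number of clusters to stop at (default 1 = full tree).
#' @return An object of class `efp_cluster_tree`: `merges` (tibble with step,
#'   cluster labels, distance), `clusters` (list of member id vectors at the
#'   stop level), `leaf_ids`, `leaf_vectors`.
#' @export
cluster_efps <- function(vectors, stop_k = 1L) {
  ids <- names(vectors)
  if (is.null(ids)) {
    ids <- vapply(vectors, function(v) attr(v, "session_id") %||% "", character(1))
  }
  if (any(!nzchar(ids)) || anyDuplicated(ids)) {
    ids <- sprintf("v%03d", seq_along(vectors))
  }
  n <- length(vectors)
  if (n < 2L) abort("need at least two vectors.")
  if (stop_k < 1L || stop_k >= n) abort("`stop_k` must be in [1, n).")
  leaves <- lapply(vectors, as.numeric)
  names(leaves) <- ids
  members <- lapply(ids, identity)   # member leaf ids per active cluster
  reps <- leaves                     # representative = mean of member leaves
  labels <- ids                      # smallest member id per cluster
  merges <- vector("list", n - stop_k)
  for (step in seq_len(n - stop_k)) {
    k <- length(reps)
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        d <- efp_distance(reps[[i]], reps[[j]])
        pair <- sort(c(labels[i], labels[j]))
        if (is.null(best) || d < best$d - 1e-15 ||
            (abs(d - best$d) <= 1e-15 &&
             (pair[1] < best$pair[1] ||
              (pair[1] == best$pair[1] && pair[2] < best$pair[2])))) {
          best <- list(i = i, j = j, d = d, pair = pair)
        }
      }
    }
    new_members <- c(members[[best$i]], members[[best$j]])
    merges[[step]] <- tibble(step = step, a = best$pair[1], b = best$pair[2],
                             distance = best$d, size = length(new_members))
    keep <- setdiff(seq_len(k), c(best$i, best$j))
    members <- c(members[keep], list(new_members))
    reps <- c(reps[keep],
              list(Reduce(`+`, leaves[new_members]) / length(new_members)))
    labels <- c(labels[keep], min(new_members))
  }
  structure(list(merges = dplyr::bind_rows(merges), clusters = members,
                 leaf_ids = ids, leaf_vectors = leaves, stop_k = stop_k),
            class = "efp_cluster_tree")
}

#' @export
print.efp_cluster_tree <- function(x, ...) {
  cat(sprintf("<efp_cluster_tree> %d leaves, stopped at %d clusters (%d merges)\n",
              length(x$leaf_ids), length(x$clusters), nrow(x$merges)))
  invisible(x)
}

#' Cluster membership at an earlier level of a tree
#'
#' Re-derives the partition after only the first `n - k` merges of a tree
#' built with a smaller `stop_k`.
#'
#' @param tree An `efp_cluster_tree`.
#' @param k Number of clusters wanted (>= `tree$stop_k`).
#' @return List of member-id vectors.
#' @export
cut_clusters <- function(tree, k) {
  n <- length(tree$leaf_ids)
  if (k < length(tree$clusters) || k >= n) {
    abort("`k` must be between the tree's stop level and n - 1.")
  }
  members <- lapply(tree$leaf_ids, identity)
  labels <- tree$leaf_ids
  for (step in seq_len(n - k)) {
    m <- tree$merges[step, ]
    ia <- match(m$a, labels)
    ib <- match(m$b, labels)
    new_members <- c(members[[ia]], members[[ib]])
    keep <- setdiff(seq_along(members), c(ia, ib))
    members <- c(members[keep], list(new_members))
    labels <- c(labels[keep], min(new_members))
  }
  members
}

#' Knee-based stopping level for the clustering
#'
#' Finds the merge step at which the merge-distance curve bends (maximum
#' discrete second difference, kneedle-style) and returns the number of
#' clusters remaining just before that merge, with the step index attached as
#' an attribute. A flat (or strictly linear) curve falls back to the
#' configured default, 24 clusters per 39 leaves scaled proportionally.
#'
#' @param merge_distances Per-step merge distances of a full tree.
#' @param n_leaves Number of leaves the tree was built from.
#' @param default_ratio Fallback clusters-per-leaf ratio.
#' @return Integer `stop_k` with attribute `step`.
#' @export
knee_stop <- function(merge_distances, n_leaves, default_ratio = 24 / 39) {
  m <- length(merge_distances)
  if (m < 3L) abort("need at least 3 merge steps.")
  d2 <- diff(diff(merge_distances))
  if (max(abs(d2)) <= 1e-12 * max(1, max(abs(merge_distances)))) {
    k <- max(1L, min(n_leaves - 1L, round(default_ratio * n_leaves)))
    return(structure(as.integer(k), step = NA_integer_))
  }
  step <- which.max(d2) + 1L  # last step before the curve bends upward
  k <- max(1L, n_leaves - step)  # stop after executing merges 1..step
  structure(as.integer(k), step = step)
}

#' Select the positive training sessions from a cluster tree
#'
#' Within the biggest cluster (most leaves; ties by smaller mean internal
#' distance), returns the `n_select` members with the smallest maximum
#' internal pairwise distance, found greedily: start from the closest pair,
#' then repeatedly add the member that minimizes the resulting maximum
#' internal distance (ties by session id).
#'
#' @param tree An `efp_cluster_tree` (stopped at the desired level).
#' @param n_select Number of sessions to select.
#' @return Character vector of selected session ids (sorted).
#' @export
select_positive <- function(tree, n_select = 10L) {
  sizes <- vapply(tree$clusters, length, integer(1))
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1L) {
    mid <- vapply(biggest, function(ci) {
      ids <- tree$clusters[[ci]]
      if (length(ids) < 2L) return(0)
      dm <- pairwise_efp_distances(tree$leaf_vectors[ids])
      mean(dm[upper.tri(dm)])
    }, numeric(1))
    biggest <- biggest[which.min(mid)]
  }
  ids <- sort(tree$clusters[[biggest]])
  if (length(ids) < n_select) {
    abort(sprintf("largest cluster has %d members < n_select = %d (cluster sizes: %s).",
                  length(ids), n_select, paste(sort(sizes, TRUE), collapse = ", ")))
  }
  if (length(ids) == n_select) return(ids)
  dm <- pairwise_efp_distances(tree$leaf_vectors[ids])
  pair <- which(dm == min(dm[upper.tri(dm)]), arr.ind = TRUE)
  pair <- pair[pair[, 1] < pair[, 2], , drop = FALSE][1L, ]
  chosen <- sort(c(pair[[1]], pair[[2]]))
  while (length(chosen) < n_select) {
    rest <- setdiff(seq_along(ids), chosen)
    cost <- vapply(rest, function(c0) max(dm[c(chosen, c0), c(chosen, c0)]), numeric(1))
    chosen <- sort(c(chosen, rest[which.min(cost)]))  # which.min ties -> first = lowest id
  }
  sort(ids[chosen])
}

pairwise_efp_distances <- function(vectors) {
  m <- do.call(cbind, vectors)
  d <- 1 - stats::cor(m)
  dimnames(d) <- NULL
  d
}

#' One-class selection pipeline
#'
#' Rebins a set of individual EFP models onto a uniform comparison scheme,
#' clusters them, picks the stopping level by [knee_stop()] unless given, and
#' selects the positive training set from the biggest cluster.
#'
#' @param models List of [efp_model()]s.
#' @param uniform_scheme Comparison [band_scheme()] (built from the log-mean
#'   spectrum across all sessions).
#' @param n_select Number of positive sessions to select.
#' @param stop_k Optional fixed stopping level; default = knee.
#' @return List with `selected` (session ids), `tree` (full tree), `stop_k`
#'   and `clusters` (membership at the stop level).
#' @export
oneclass_select <- function(models, uniform_scheme, n_select = 10L,
                            stop_k = NULL) {
  vecs <- lapply(models, rebin_efp, uniform_scheme = uniform_scheme)
  names(vecs) <- vapply(models, function(m) m$fit_meta$session_id %||% "",
                        character(1))
  full <- cluster_efps(vecs, stop_k = 1L)
  if (is.null(stop_k)) {
    stop_k <- if (nrow(full$merges) < 3L) 1L else
      as.integer(knee_stop(full$merges$distance, length(vecs)))
  }
  clusters <- cut_clusters(full, stop_k)
  # if the knee level leaves the biggest cluster too small, merge further
  while (max(vapply(clusters, length, integer(1))) < n_select && stop_k > 1L) {
    stop_k <- stop_k - 1L
    clusters <- cut_clusters(full, stop_k)
  }
  pruned <- full
  pruned$clusters <- clusters
  pruned$stop_k <- stop_k
  list(selected = select_positive(pruned, n_select), tree = full,
       stop_k = stop_k, clusters = clusters)
}

#' Newick string of a full cluster tree
#'
#' Branch lengths are parent merge height minus child merge height (heights
#' as computed; may be negative under average-representative linkage).
#'
#' @param tree A full `efp_cluster_tree` (`stop_k = 1`).
#' @return A single Newick string ending in ";".
#' @export
efp_newick <- function(tree) {
  n <- length(tree$leaf_ids)
  if (length(tree$clusters) != 1L) abort("newick export needs a full tree (stop_k = 1).")
  node_str <- as.list(tree$leaf_ids)
  names(node_str) <- tree$leaf_ids
  height <- as.list(setNames(rep(0, n), tree$leaf_ids))
  for (step in seq_len(nrow(tree$merges))) {
    m <- tree$merges[step, ]
    h <- m$distance
    ba <- h - height[[m$a]]
    bb <- h - height[[m$b]]
    lab <- min(m$a, m$b)
    node_str[[lab]] <- sprintf("(%s:%g,%s:%g)", node_str[[m$a]], ba,
                               node_str[[m$b]], bb)
    height[[lab]] <- h
  }
  last <- tree$merges[nrow(tree$merges), ]
  paste0(node_str[[min(last$a, last$b)]], ";")
}
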