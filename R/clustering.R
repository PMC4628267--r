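## ---- cluster partition container -------------------------------------------

## labels: integer vector named by sequence id, arbitrary levels; the cluster
## containing query_id is relabeled 0, the rest by order of first appearance
new_partition <- function(labels, query_id) {
  if (is.null(names(labels)) || !query_id %in% names(labels)) {
    stop("partition labels must be named and include the query sequence")
  }
  target <- labels[[query_id]]
  others <- unique(labels[labels != target])
  relab <- integer(length(labels))
  names(relab) <- names(labels)
  relab[labels == target] <- 0L
  for (i in seq_along(others)) relab[labels == others[i]] <- i
  sizes <- table(relab)
  structure(list(labels = relab, k = length(unique(relab)),
                 target_label = 0L,
                 sizes = as.integer(sizes[order(as.integer(names(sizes)))])),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("cluster_partition: %d clusters over %d sequences (sizes: %s)\n",
              x$k, length(x$labels), paste(x$sizes, collapse = ", ")))
  invisible(x)
}

check_partition <- function(window, partition) {
  ids <- rownames(window$msa$mat)
  if (!setequal(ids, names(partition$labels)) ||
      length(ids) != length(partition$labels)) {
    stop("partition is inconsistent with the window rows")
  }
  partition$labels[ids]
}

## ---- combinatorial entropy --------------------------------------------------

#' Combinatorial entropy of one alignment column
#'
#' The log multinomial coefficient `ln(n! / prod(n_a!))` of the residue counts
#' of a column within one cluster, with gaps counted as a 21st symbol. It is
#' zero exactly when the column is monomorphic within the cluster.
#'
#' @param residue_counts named (or unnamed) nonnegative counts per symbol.
#' @return entropy in nats.
#' @export
column_combinatorial_entropy <- function(residue_counts) {
  counts <- as.numeric(residue_counts)
  if (length(counts) == 0L) stop("empty count map")
  if (any(counts < 0)) stop("counts must be nonnegative")
  n <- sum(counts)
  if (n < 1) stop("total count must be >= 1")
  lgamma(n + 1) - sum(lgamma(counts + 1))
}

## counts array (21 symbols x columns) for a set of encoded rows
count_columns <- function(enc, rows) {
  apply(enc[rows, , drop = FALSE], 2L, tabulate, nbins = 21L)
}

## entropy per column from a 21 x ncol count matrix
entropy_from_counts <- function(counts) {
  lgamma(colSums(counts) + 1) - colSums(lgamma(counts + 1))
}

## Monte-Carlo expected entropy table E[m, col]: mean combinatorial entropy of
## a size-m subsample of each column under `shuffles` seeded permutations of
## the column's residues across rows. Restricting a uniform permutation to its
## first m positions is distribution-identical to restricting it to the rows
## of any fixed size-m cluster.
expected_entropy_table <- function(enc, shuffles, seed) {
  n <- nrow(enc); p <- ncol(enc)
  E <- matrix(0, n, p)
  with_seed(seed, {
    for (s in seq_len(shuffles)) {
      for (cc in seq_len(p)) {
        perm <- enc[sample.int(n), cc]
        counts <- integer(21L)
        ent <- 0
        for (m in seq_len(n)) {
          a <- perm[m]
          counts[a] <- counts[a] + 1L
          ent <- ent + log(m) - log(counts[a])
          E[m, cc] <- E[m, cc] + ent
        }
      }
    }
  })
  E / shuffles
}

#' Combinatorial entropy objective of a partition
#'
#' Sum over clusters and columns of observed minus expected combinatorial
#' entropy, the quantity minimized by [ceo_cluster()]. Expected entropy is
#' estimated from seeded random permutations of each column's residues across
#' rows, at the same cluster sizes.
#'
#' By default only the negative part of each cluster-column term enters the
#' sum (`min(S_obs - E, 0)`): clusters are credited for being more conserved
#' than a random row subset of the same size, but not penalized for
#' diversity at unconstrained sites. The plain two-sided sum is available
#' with `one_sided = FALSE`; it is unsuitable as an optimization target
#' because the log-multinomial entropy is superadditive in cluster size for
#' diverse rows, so it rewards shattering any subfamily with unconstrained
#' columns into singletons.
#'
#' @param window an `msa_window`.
#' @param partition a `cluster_partition` over the window rows.
#' @param shuffles number of Monte-Carlo permutations (default 20).
#' @param seed RNG seed for the permutations.
#' @param one_sided keep only conservation excess (default TRUE).
#' @return objective value (nats); lower means crisper subfamilies.
#' @export
ceo_objective <- function(window, partition, shuffles = 20L, seed = 1L,
                          one_sided = TRUE) {
  if (shuffles < 1L) stop("shuffles must be >= 1")
  labels <- check_partition(window, partition)
  enc <- encode_window(window)
  E <- expected_entropy_table(enc, shuffles, seed)
  obj <- 0
  for (lab in unique(labels)) {
    rows <- which(labels == lab)
    counts <- count_columns(enc, rows)
    term <- entropy_from_counts(counts) - E[length(rows), ]
    if (one_sided) term <- pmin(term, 0)
    obj <- obj + sum(term)
  }
  obj
}

## ---- CEO clustering ---------------------------------------------------------

#' Subfamily detection by combinatorial entropy optimization
#'
#' Starts from the height-0 cut of an average-linkage p-distance tree
#' (identical rows begin in the same cluster, all others as singletons) and
#' greedily merges the pair of clusters whose merge most decreases the
#' observed-minus-expected entropy objective, stopping at a local minimum.
#' The number of clusters is an output, not an input. The best of `restarts`
#' seeded runs (differing in the Monte-Carlo permutations used for the
#' expected entropy) is returned, with the cluster containing the query
#' relabeled 0.
#'
#' @param window an `msa_window` with at least two rows.
#' @param restarts seeded optimization restarts (default 2).
#' @param shuffles Monte-Carlo permutations for the expected entropy.
#' @param seed base RNG seed; restart r uses `seed + r - 1`.
#' @return a `cluster_partition`; attribute `objective` holds the achieved
#'   objective value and `objective_trace` its per-merge path.
#' @export
ceo_cluster <- function(window, restarts = 2L, shuffles = 20L, seed = 1L,
                        one_sided = TRUE) {
  stopifnot(inherits(window, "msa_window"))
  enc <- encode_window(window)
  n <- nrow(enc)
  if (n < 2L) stop("need at least 2 rows to cluster")
  ## fine initial partition: identical rows (p-distance 0) start together,
  ## everything else as singletons (the height-0 cut of the linkage tree)
  d <- p_distance(window$msa$mat)
  init <- seq_len(n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (d[i, j] == 0 && init[i] != init[j]) init[init == init[j]] <- init[i]
    }
  }

  best <- NULL
  for (r in seq_len(restarts)) {
    E <- expected_entropy_table(enc, shuffles, seed + r - 1L)
    run <- ceo_greedy(enc, init, E, one_sided)
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  part <- new_partition(best$labels, query_id(window$msa))
  attr(part, "objective") <- best$objective
  attr(part, "objective_trace") <- best$trace
  part
}

## greedy agglomeration from an initial partition given an expected-entropy table
ceo_greedy <- function(enc, init, E, one_sided = TRUE) {
  part_sum <- if (one_sided) function(x) sum(pmin(x, 0)) else sum
  n <- nrow(enc)
  labs <- as.integer(factor(init))
  k <- max(labs)
  counts <- lapply(seq_len(k), function(g) count_columns(enc, which(labs == g)))
  sizes <- vapply(counts, function(x) sum(x[, 1L]), numeric(1))
  ## per-cluster contribution Sum_col S_obs - E[size, col]
  contrib <- vapply(seq_len(k), function(g) {
    part_sum(entropy_from_counts(counts[[g]]) - E[sizes[g], ])
  }, numeric(1))
  alive <- rep(TRUE, k)
  objective <- sum(contrib)
  trace <- objective
  repeat {
    live <- which(alive)
    if (length(live) < 2L) break
    best_delta <- Inf; best_pair <- NULL; best_contrib <- NA
    for (ai in seq_along(live)[-length(live)]) {
      a <- live[ai]
      for (b in live[(ai + 1L):length(live)]) {
        cab <- counts[[a]] + counts[[b]]
        new_contrib <- part_sum(entropy_from_counts(cab) - E[sizes[a] + sizes[b], ])
        delta <- new_contrib - contrib[a] - contrib[b]
        if (delta < best_delta - 1e-12) {
          best_delta <- delta; best_pair <- c(a, b); best_contrib <- new_contrib
        }
      }
    }
    if (is.null(best_pair) || best_delta >= -1e-9) break
    a <- best_pair[1]; b <- best_pair[2]
    counts[[a]] <- counts[[a]] + counts[[b]]
    sizes[a] <- sizes[a] + sizes[b]
    contrib[a] <- best_contrib
    alive[b] <- FALSE
    labs[labs == b] <- a
    objective <- objective + best_delta
    trace <- c(trace, objective)
  }
  labels <- labs
  names(labels) <- rownames(enc)
  list(labels = labels, objective = objective, trace = trace)
}

## ---- K-means baseline -------------------------------------------------------

#' K-means clustering of window rows
#'
#' Rows are embedded as one-hot indicator vectors over residue-by-column
#' (gap as a 21st symbol) and clustered with Lloyd's algorithm from seeded
#' random initial centers; the best of `restarts` runs by within-cluster sum
#' of squares is returned.
#'
#' @param window an `msa_window`.
#' @param k number of clusters (2 to number of rows).
#' @param restarts random restarts (default 100).
#' @param seed RNG seed.
#' @return a `cluster_partition` with the query's cluster relabeled 0.
#' @export
kmeans_cluster <- function(window, k, restarts = 100L, seed = 1L) {
  stopifnot(inherits(window, "msa_window"))
  enc <- encode_window(window)
  n <- nrow(enc)
  if (k > n) stop("k cannot exceed the number of rows")
  if (k < 1L) stop("k must be >= 1")
  X <- matrix(0, n, 21L * ncol(enc))
  for (cc in seq_len(ncol(enc))) {
    X[cbind(seq_len(n), (cc - 1L) * 21L + enc[, cc])] <- 1
  }
  rownames(X) <- rownames(enc)

  if (k == n) {
    labels <- seq_len(n)
    names(labels) <- rownames(enc)
    return(new_partition(labels, query_id(window$msa)))
  }
  distinct <- !duplicated(as.data.frame(X))
  labels <- with_seed(seed, {
    if (sum(distinct) <= k) {
      ## fewer distinct row patterns than centers: cluster by pattern
      as.integer(factor(apply(enc, 1L, paste, collapse = ",")))
    } else {
      best <- NULL
      for (r in seq_len(restarts)) {
        centers <- X[sample(which(distinct), k), , drop = FALSE]
        km <- suppressWarnings(
          kmeans(X, centers = centers, iter.max = 100L, algorithm = "Lloyd"))
        if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
      }
      best$cluster
    }
  })
  names(labels) <- rownames(enc)
  new_partition(labels, query_id(window$msa))
}

## ---- cluster validity indices ----------------------------------------------

#' Dunn and Davies-Bouldin indices from a distance matrix
#'
#' Dunn index: minimum between-cluster distance divided by the maximum
#' within-cluster diameter. Davies-Bouldin: mean over clusters of the largest
#' pairwise `(scatter_i + scatter_j) / d(medoid_i, medoid_j)`, with scatter
#' the mean distance of members to their cluster medoid.
#'
#' @param d symmetric distance matrix.
#' @param labels cluster labels, one per row of `d`.
#' @return list with `dunn`, `davies_bouldin`, and `degenerate` (TRUE when a
#'   zero diameter or zero medoid separation forces an infinite index).
#' @export
cluster_validity <- function(d, labels) {
  d <- as.matrix(d)
  stopifnot(nrow(d) == length(labels))
  groups <- split(seq_along(labels), labels)
  k <- length(groups)
  if (k < 2L) stop("need at least 2 clusters")
  diam <- vapply(groups, function(g) {
    if (length(g) < 2L) 0 else max(d[g, g])
  }, numeric(1))
  min_between <- Inf
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      min_between <- min(min_between, min(d[groups[[i]], groups[[j]]]))
    }
  }
  degenerate <- max(diam) == 0
  dunn <- if (degenerate) Inf else min_between / max(diam)

  medoid <- vapply(groups, function(g) {
    g[which.min(rowSums(d[g, g, drop = FALSE]))]
  }, integer(1))
  scatter <- vapply(seq_len(k), function(i) {
    mean(d[groups[[i]], medoid[i]])
  }, numeric(1))
  R <- vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      sep <- d[medoid[i], medoid[j]]
      if (sep == 0) Inf else (scatter[i] + scatter[j]) / sep
    }, numeric(1)))
  }, numeric(1))
  if (any(!is.finite(R))) degenerate <- TRUE
  list(dunn = dunn, davies_bouldin = mean(R), degenerate = degenerate)
}

#' Cluster quality of a window partition
#'
#' [cluster_validity()] applied to the p-distance matrix of the window rows
#' (per-column mismatch fraction over columns where both rows are non-gap).
#'
#' @param window an `msa_window`.
#' @param partition a `cluster_partition` over the window rows.
#' @return list with `dunn`, `davies_bouldin`, `degenerate`.
#' @export
cluster_quality <- function(window, partition) {
  labels <- check_partition(window, partition)
  cluster_validity(p_distance(window$msa$mat), labels)
}
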