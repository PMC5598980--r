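# Independent oracles implementing definitions directly, for equivalence
# tests against the package's algorithms.

# DBSCAN by literal density-reachability closure: clusters are connected
# components of the core-core eps graph, labelled in increasing order of
# their smallest core index; a border point joins the earliest-formed
# cluster with a core point within eps.
oracle_dbscan <- function(peaks, eps, min_pts, scaling = peak_scaling()) {
  peaks <- dplyr::arrange(peaks, measurement_id, rt, ik0)
  n <- nrow(peaks)
  D <- peak_dist_matrix(peaks, scaling)
  core <- vapply(seq_len(n), function(i) sum(D[i, ] <= eps) >= min_pts, logical(1))
  membership <- rep(NA_integer_, n)
  cores <- which(core)
  if (length(cores)) {
    reach <- D[cores, cores, drop = FALSE] <= eps
    g <- igraph::graph_from_adjacency_matrix(reach, mode = "undirected")
    comp <- igraph::components(g)$membership
    # label clusters by ascending minimal core index
    min_core <- tapply(cores, comp, min)
    relabel <- rank(min_core)
    membership[cores] <- as.integer(relabel[comp])
    for (i in which(!core)) {
      near <- membership[cores[D[i, cores] <= eps]]
      if (length(near)) membership[i] <- min(near)
    }
  }
  membership
}

# all set partitions of n elements as canonical membership vectors
# (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, k) {
    i <- length(prefix) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- prefix; return(invisible()) }
    for (b in seq_len(k + 1L)) rec(c(prefix, b), max(k, b))
  }
  rec(integer(0), 0L)
  out
}

# cluster-editing cost of a partition, computed pair-by-pair from scratch
oracle_ce_cost <- function(W, membership) {
  n <- nrow(W)
  cost <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    w <- W[i, j]
    if (membership[i] == membership[j]) {
      if (w < 0) cost <- cost - w
    } else if (w > 0) cost <- cost + w
  }
  cost
}

# minimum cluster-editing cost by exhaustive enumeration over all set
# partitions; per-partition cost evaluated over the precomputed pair index
oracle_ce_min_cost <- function(W, partitions = all_partitions(nrow(W))) {
  n <- nrow(W)
  pairs <- which(upper.tri(W), arr.ind = TRUE)
  w <- W[pairs]
  del <- pmax(w, 0); ins <- pmax(-w, 0)
  min(vapply(partitions, function(p) {
    same <- p[pairs[, 1]] == p[pairs[, 2]]
    sum(ins[same]) + sum(del[!same])
  }, numeric(1)))
}

# canonicalise a membership vector (noise NA kept) so partitions can be
# compared independent of label numbering
canonical_partition <- function(membership) {
  lab <- match(membership, unique(membership[!is.na(membership)]))
  ifelse(is.na(membership), NA_integer_, lab)
}
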