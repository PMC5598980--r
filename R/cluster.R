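#' @keywords internal
# cost of a clique partition under a similarity/dissimilarity weight matrix:
# deleted positive edges (between blocks) plus inserted negative edges
# (within blocks) each pay |w|
partition_cost <- function(W, membership) {
  same <- outer(membership, membership, `==`)
  up <- upper.tri(W)
  sum(ifelse(same, pmax(-W, 0), pmax(W, 0))[up])
}

# greedy cluster-editing heuristic: start from singletons and repeatedly
# merge the pair of clusters with the largest positive total inter-cluster
# weight until none remains
ce_greedy <- function(W) {
  n <- nrow(W)
  blocks <- as.list(seq_len(n))
  repeat {
    nb <- length(blocks)
    if (nb < 2) break
    best <- c(0, 0); best_w <- 0
    for (a in seq_len(nb - 1)) for (b in (a + 1):nb) {
      wab <- sum(W[blocks[[a]], blocks[[b]]])
      if (wab > best_w) { best_w <- wab; best <- c(a, b) }
    }
    if (best_w <= 0) break
    blocks[[best[1]]] <- c(blocks[[best[1]]], blocks[[best[2]]])
    blocks[[best[2]]] <- NULL
  }
  membership <- integer(n)
  for (b in seq_along(blocks)) membership[blocks[[b]]] <- b
  membership
}

# exact cluster editing by branch-and-bound over set partitions, seeded with
# the greedy solution for pruning; feasible to ~12 elements
ce_exact <- function(W) {
  n <- nrow(W)
  if (n == 1) return(list(membership = 1L, cost = 0))
  seed <- ce_greedy(W)
  env <- new.env()
  env$best_cost <- partition_cost(W, seed)
  env$best <- seed
  assign_vec <- integer(n)
  rec <- function(i, k, cost) {
    if (cost >= env$best_cost) return(invisible())
    if (i > n) {
      env$best_cost <- cost
      env$best <- assign_vec[seq_len(n)]
      return(invisible())
    }
    prev <- seq_len(i - 1)
    for (b in seq_len(k + 1)) {
      in_b <- prev[assign_vec[prev] == b]
      out_b <- prev[assign_vec[prev] != b]
      add <- sum(pmax(-W[i, in_b], 0)) + sum(pmax(W[i, out_b], 0))
      assign_vec[i] <<- b
      rec(i + 1L, max(k, b), cost + add)
    }
    invisible()
  }
  rec(1L, 0L, 0)
  list(membership = env$best, cost = env$best_cost)
}

# weighted cluster editing on a full weight matrix: split into connected
# components of the positive-weight graph (an optimal solution never joins
# elements from different components), solve small components exactly
ce_partition <- function(W, exact_limit = 12) {
  n <- nrow(W)
  if (n == 0) return(list(membership = integer(0), cost = 0))
  diag(W) <- 0
  adj <- (W > 0)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  membership <- integer(n)
  cost <- 0
  offset <- 0L
  for (cc in split(seq_len(n), comp)) {
    if (length(cc) == 1) {
      membership[cc] <- offset + 1L
      offset <- offset + 1L
      next
    }
    sol <- if (length(cc) <= exact_limit) ce_exact(W[cc, cc, drop = FALSE])
           else {
             mem <- ce_greedy(W[cc, cc, drop = FALSE])
             list(membership = mem, cost = partition_cost(W[cc, cc, drop = FALSE], mem))
           }
    membership[cc] <- offset + sol$membership
    cost <- cost + sol$cost
    offset <- offset + max(sol$membership)
  }
  list(membership = membership, cost = cost)
}

# assemble an ims_clusters object from peaks plus an integer membership
# vector (NA = noise); consensus positions are member centroids
new_cluster_result <- function(peaks, membership, method, params = list(),
                               cost = NULL, means = NULL) {
  peaks <- tibble::as_tibble(peaks)
  keep <- !is.na(membership)
  if (any(keep)) {
    cons <- tibble::tibble(cluster = membership[keep],
                           rt = peaks$rt[keep], ik0 = peaks$ik0[keep]) |>
      dplyr::group_by(.data$cluster) |>
      dplyr::summarise(rt = mean(.data$rt), ik0 = mean(.data$ik0),
                       support = dplyr::n(), .groups = "drop")
    if (!is.null(means)) {   # EM reports component means, not raw centroids
      cons$rt <- means$rt[match(cons$cluster, means$cluster)]
      cons$ik0 <- means$ik0[match(cons$cluster, means$cluster)]
    }
    cons <- dplyr::arrange(cons, .data$rt, .data$ik0)
    cons$feature_id <- sprintf("F%03d", seq_len(nrow(cons)))
    fid <- cons$feature_id[match(membership, cons$cluster)]
    cons$cluster <- NULL
  } else {
    cons <- tibble::tibble(feature_id = character(), rt = double(),
                           ik0 = double(), support = integer())
    fid <- rep(NA_character_, nrow(peaks))
  }
  assignment <- peaks
  assignment$feature_id <- fid
  structure(list(consensus = cons[c("feature_id", "rt", "ik0", "support")],
                 assignment = assignment, method = method, params = params,
                 cost = cost),
            class = "ims_clusters")
}

#' @export
print.ims_clusters <- function(x, ...) {
  cat(sprintf("<ims_clusters> %s: %d consensus peaks from %d peaks (%d noise)\n",
              x$method, nrow(x$consensus), nrow(x$assignment),
              sum(is.na(x$assignment$feature_id))))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ims_clusters <- function(x, ...) x$consensus

#' @exportS3Method generics::glance
glance.ims_clusters <- function(x, ...) {
  tibble::tibble(method = x$method, n_consensus = nrow(x$consensus),
                 n_peaks = nrow(x$assignment),
                 n_noise = sum(is.na(x$assignment$feature_id)),
                 cost = if (is.null(x$cost)) NA_real_ else x$cost)
}

#' @exportS3Method ggplot2::autoplot
autoplot.ims_clusters <- function(object, ...) {
  ggplot2::ggplot(object$assignment,
                  ggplot2::aes(.data$ik0, .data$rt, colour = .data$feature_id)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_point(data = object$consensus, shape = 4, size = 3,
                        colour = "black") +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = "1/K0 [Vs/cm2]", y = "retention time [s]",
                  title = sprintf("%s: %d consensus peaks", object$method,
                                  nrow(object$consensus)))
}

#' Grid-squares (GS) peak clustering
#'
#' Partitions the (1/K0, retention time) plane into disjoint rectangles of
#' size `cell_ik0` x `cell_rt`, anchored at the global minimum position of
#' the peak set. Every rectangle holding at least `min_count` peaks yields a
#' consensus peak at the average member position; peaks in sparser
#' rectangles are noise.
#'
#' @param peaks combined peak-list tibble across measurements.
#' @param cell_ik0 rectangle width in Vs/cm2.
#' @param cell_rt rectangle height in seconds.
#' @param min_count minimum number of member peaks per rectangle.
#' @return An `ims_clusters` object.
#' @export
cluster_grid_squares <- function(peaks, cell_ik0 = 0.006, cell_rt = 6,
                                 min_count = 3) {
  stopifnot(cell_ik0 > 0, cell_rt > 0, min_count >= 1)
  peaks <- validate_peaklist(peaks)
  if (!nrow(peaks)) return(new_cluster_result(peaks, integer(0), "gs"))
  bi <- floor((peaks$ik0 - min(peaks$ik0)) / cell_ik0)
  br <- floor((peaks$rt - min(peaks$rt)) / cell_rt)
  cell <- paste(bi, br)
  counts <- table(cell)
  ok <- cell %in% names(counts)[counts >= min_count]
  membership <- ifelse(ok, match(cell, unique(cell[ok])), NA_integer_)
  new_cluster_result(peaks, membership, "gs",
                     list(cell_ik0 = cell_ik0, cell_rt = cell_rt,
                          min_count = min_count))
}

#' DBSCAN peak clustering
#'
#' Density-based clustering of peak positions in normalised coordinates
#' (see [peak_scaling()]): points with at least `min_pts` neighbours within
#' `eps` (the point itself included) are core points; clusters are the
#' density-reachability closures of core points, and non-reachable peaks are
#' noise. Peaks are processed in sorted order (measurement id, rt, ik0), so
#' border points deterministically join the first core cluster that reaches
#' them. Consensus peaks are cluster centroids.
#'
#' @param peaks combined peak-list tibble.
#' @param eps neighbourhood radius in normalised distance units.
#' @param min_pts core-point threshold (>= 1).
#' @param scaling an [peak_scaling()].
#' @return An `ims_clusters` object.
#' @export
cluster_dbscan <- function(peaks, eps = 1, min_pts = 3,
                           scaling = peak_scaling()) {
  stopifnot(eps > 0, min_pts >= 1)
  peaks <- validate_peaklist(peaks)
  peaks <- dplyr::arrange(peaks, .data$measurement_id, .data$rt, .data$ik0)
  n <- nrow(peaks)
  if (!n) return(new_cluster_result(peaks, integer(0), "dbscan"))
  D <- peak_dist_matrix(peaks, scaling)
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- lengths(nb) >= min_pts
  membership <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(membership[i]) || !core[i]) next
    k <- k + 1L
    queue <- i
    membership[i] <- k
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      for (q in nb[[j]]) {
        if (is.na(membership[q])) {
          membership[q] <- k
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  new_cluster_result(peaks, membership, "dbscan",
                     list(eps = eps, min_pts = min_pts, scaling = scaling))
}

#' Weighted cluster-editing (CE) peak clustering
#'
#' Builds a similarity graph over peak positions with edge weight
#' `sim_threshold - d(u, v)` (normalised distance, see [peak_scaling()]);
#' positive weights mean "similar". The peaks are partitioned into disjoint
#' cliques by inserting/deleting edges at minimum total absolute weight.
#' Connected components of the positive-weight graph are solved
#' independently: components of at most `exact_limit` peaks exactly by
#' branch-and-bound over set partitions, larger ones by a greedy
#' cluster-merging heuristic. Consensus peaks are clique centroids.
#'
#' @param peaks combined peak-list tibble.
#' @param sim_threshold similarity threshold in normalised distance units.
#' @param scaling an [peak_scaling()].
#' @param exact_limit largest component size solved exactly.
#' @return An `ims_clusters` object with the achieved editing `cost`.
#' @export
cluster_editing <- function(peaks, sim_threshold = 1,
                            scaling = peak_scaling(), exact_limit = 12) {
  stopifnot(sim_threshold > 0)
  peaks <- validate_peaklist(peaks)
  peaks <- dplyr::arrange(peaks, .data$measurement_id, .data$rt, .data$ik0)
  if (!nrow(peaks)) return(new_cluster_result(peaks, integer(0), "ce"))
  W <- sim_threshold - peak_dist_matrix(peaks, scaling)
  sol <- ce_partition(W, exact_limit)
  new_cluster_result(peaks, sol$membership, "ce",
                     list(sim_threshold = sim_threshold, scaling = scaling,
                          exact_limit = exact_limit), cost = sol$cost)
}

#' EM peak clustering with component merging
#'
#' Models peak positions as draws from a mixture of axis-aligned Gaussians
#' with known, fixed standard deviations (`sigma_ik0`, `sigma_rt`) — one
#' component per putative consensus peak. The E-step computes
#' responsibilities; the M-step updates only component means and mixture
#' weights. After every iteration, components whose mean separation,
#' normalised by the sigmas, falls below `merge_dist` are merged (weights
#' summed, means weight-averaged), so the number of clusters need not be
#' known a priori. Components are seeded from a coarse grid-squares pass
#' (`min_count` 1, cell size twice the sigma in each dimension), which makes
#' the fit deterministic and independent of peak order.
#'
#' @param peaks combined peak-list tibble.
#' @param sigma_ik0,sigma_rt known component standard deviations (Vs/cm2,
#'   seconds).
#' @param merge_dist merge threshold on the sigma-normalised mean
#'   separation; the default of 4 sigma merges components that known
#'   positional jitter cannot separate while keeping distinct analytes
#'   (typically tens of sigma apart) intact.
#' @param max_iter,tol convergence controls on the log-likelihood.
#' @return An `ims_clusters` object; consensus positions are the final
#'   component means, assignment is by maximum responsibility.
#' @export
cluster_em <- function(peaks, sigma_ik0 = 0.003, sigma_rt = 3,
                       merge_dist = 4, max_iter = 200, tol = 1e-6) {
  stopifnot(sigma_ik0 > 0, sigma_rt > 0, merge_dist >= 0)
  peaks <- validate_peaklist(peaks)
  peaks <- dplyr::arrange(peaks, .data$measurement_id, .data$rt, .data$ik0)
  n <- nrow(peaks)
  if (!n) return(new_cluster_result(peaks, integer(0), "em"))
  x1 <- peaks$ik0; x2 <- peaks$rt

  # deterministic init: grid-squares bin means at 2*sigma cells
  bi <- floor((x1 - min(x1)) / (2 * sigma_ik0))
  br <- floor((x2 - min(x2)) / (2 * sigma_rt))
  cell <- paste(bi, br)
  mu1 <- tapply(x1, cell, mean); mu2 <- tapply(x2, cell, mean)
  mu <- cbind(as.numeric(mu1), as.numeric(mu2[names(mu1)]))
  wgt <- as.numeric(table(cell)[names(mu1)]) / n

  merge_close <- function(mu, wgt) {
    repeat {
      K <- nrow(mu)
      if (K < 2) break
      d <- sqrt(outer(mu[, 1], mu[, 1], `-`)^2 / sigma_ik0^2 +
                  outer(mu[, 2], mu[, 2], `-`)^2 / sigma_rt^2)
      diag(d) <- Inf
      if (min(d) >= merge_dist) break
      ij <- which(d == min(d), arr.ind = TRUE)[1, ]
      i <- min(ij); j <- max(ij)
      wsum <- wgt[i] + wgt[j]
      mu[i, ] <- (wgt[i] * mu[i, ] + wgt[j] * mu[j, ]) / wsum
      wgt[i] <- wsum
      mu <- mu[-j, , drop = FALSE]; wgt <- wgt[-j]
    }
    list(mu = mu, wgt = wgt)
  }
  mg <- merge_close(mu, wgt); mu <- mg$mu; wgt <- mg$wgt

  log_dens <- function(mu) {
    # n x K matrix of log component densities
    outer(x1, mu[, 1], function(a, b) stats::dnorm(a, b, sigma_ik0, log = TRUE)) +
      outer(x2, mu[, 2], function(a, b) stats::dnorm(a, b, sigma_rt, log = TRUE))
  }
  ll_old <- -Inf
  converged <- FALSE
  trace <- list()
  for (iter in seq_len(max_iter)) {
    ld <- sweep(log_dens(mu), 2, log(wgt), `+`)
    mx <- apply(ld, 1, max)
    lse <- mx + log(rowSums(exp(ld - mx)))
    r <- exp(ld - lse)
    ll <- sum(lse)
    wgt <- colMeans(r)
    mu <- cbind(colSums(r * x1), colSums(r * x2)) / colSums(r)
    K_before <- nrow(mu)
    mg <- merge_close(mu, wgt); mu <- mg$mu; wgt <- mg$wgt
    trace[[iter]] <- tibble::tibble(iter = iter, loglik = ll,
                                    merged = nrow(mu) < K_before)
    if (nrow(mu) == K_before && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  if (!converged) {
    warning(sprintf("EM clustering did not converge in %d iterations", max_iter))
  }
  ld <- sweep(log_dens(mu), 2, log(wgt), `+`)
  membership <- max.col(ld, ties.method = "first")
  used <- sort(unique(membership))
  membership <- match(membership, used)
  means <- tibble::tibble(cluster = seq_along(used),
                          ik0 = mu[used, 1], rt = mu[used, 2])
  new_cluster_result(peaks, membership, "em",
                     list(sigma_ik0 = sigma_ik0, sigma_rt = sigma_rt,
                          merge_dist = merge_dist,
                          trace = dplyr::bind_rows(trace)),
                     means = means)
}

#' Cluster peaks across measurements
#'
#' Dispatch wrapper over the four clustering methods.
#'
#' @param peaks combined peak-list tibble.
#' @param method `"gs"`, `"dbscan"`, `"ce"` or `"em"`.
#' @param ... passed to the method.
#' @return An `ims_clusters` object.
#' @export
cluster_peaks <- function(peaks, method = c("dbscan", "gs", "ce", "em"), ...) {
  method <- match.arg(method)
  switch(method,
         gs = cluster_grid_squares(peaks, ...),
         dbscan = cluster_dbscan(peaks, ...),
         ce = cluster_editing(peaks, ...),
         em = cluster_em(peaks, ...))
}
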