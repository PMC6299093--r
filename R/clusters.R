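# Density-based cluster detection on localization tables, and the
# cluster-set container used by the colocalization statistic.
#
# Clustering is DBSCAN: a point with at least min_pts neighbours within eps
# (itself included) is a core point; clusters are the connected components
# of core points under eps-adjacency, plus border points attached to any
# neighbouring core point; everything else is noise. Neighbour search uses
# an eps-sized grid hash, so runtime is near-linear at SMLM densities.

#' Construct a cluster set
#'
#' @param nucleus_id Nucleus identifier.
#' @param channel Channel label.
#' @param clusters Data frame with columns `cluster_id`, `x`, `y` (centroid
#'   nm), `radius` (effective radius nm), `n_loc` (member localizations).
#' @param members Optional list of per-cluster offset matrices (dx, dy)
#'   relative to the centroid.
#' @param params Optional list of clustering parameters (`eps`, `min_pts`).
#' @return A `cluster_set`.
#' @export
cluster_set <- function(nucleus_id, channel, clusters,
                        members = NULL, params = list()) {
  clusters <- as.data.frame(clusters)
  needed <- c("cluster_id", "x", "y", "radius", "n_loc")
  if (!all(needed %in% names(clusters))) {
    format_error("cluster data frame needs columns: ",
                 paste(needed, collapse = ", "))
  }
  if (anyDuplicated(clusters$cluster_id)) {
    format_error("cluster_ids must be unique")
  }
  if (any(clusters$radius < 0)) {
    format_error("cluster radii must be >= 0")
  }
  structure(
    list(
      nucleus_id = as.character(nucleus_id),
      channel = as.character(channel),
      clusters = clusters,
      members = members,
      params = params
    ),
    class = "cluster_set"
  )
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf(
    "<cluster_set '%s' channel=%s> %d cluster(s)\n",
    x$nucleus_id, x$channel, nrow(x$clusters)
  ))
  invisible(x)
}

# Core DBSCAN labelling. Returns an integer vector: 0 = noise, otherwise
# cluster label.
dbscan_labels <- function(x, y, eps, min_pts) {
  n <- length(x)
  if (n == 0L) {
    return(integer(0))
  }
  cx <- floor(x / eps)
  cy <- floor(y / eps)
  key <- paste(cx, cy)
  cell_of <- split(seq_len(n), key)
  # neighbour list per point: points within eps among the 3x3 cell block
  neigh <- vector("list", n)
  eps2 <- eps^2
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (dx in -1:1) {
      for (dy in -1:1) {
        k <- paste(cx[i] + dx, cy[i] + dy)
        cand <- c(cand, cell_of[[k]])
      }
    }
    d2 <- (x[cand] - x[i])^2 + (y[cand] - y[i])^2
    neigh[[i]] <- cand[d2 <= eps2]
  }
  core <- lengths(neigh) >= min_pts
  labels <- integer(n)
  lab <- 0L
  for (i in which(core)) {
    if (labels[i] != 0L) next
    lab <- lab + 1L
    queue <- i
    labels[i] <- lab
    while (length(queue)) {
      p <- queue[[1L]]
      queue <- queue[-1L]
      for (q in neigh[[p]]) {
        if (labels[q] == 0L) {
          labels[q] <- lab
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

#' Detect clusters in a localization table
#'
#' DBSCAN over the channel's in-ROI localizations. The cluster centroid is
#' the mean of its member coordinates and the effective radius is the
#' maximum member distance to the centroid, so the cluster disc covers all
#' members.
#'
#' @param locs A `localization_table` holding one channel of one nucleus.
#' @param roi Optional `nucleus_roi`; when given, out-of-ROI localizations
#'   are dropped first.
#' @param eps DBSCAN neighbourhood radius in nm (default 75).
#' @param min_pts Minimum neighbours (self included) for a core point
#'   (default 5).
#' @return A `cluster_set`; empty when no cluster reaches `min_pts`.
#' @export
detect_clusters <- function(locs, roi = NULL, eps = 75, min_pts = 5) {
  stopifnot(inherits(locs, "localization_table"), eps > 0, min_pts >= 1)
  if (!is.null(roi)) {
    locs <- filter_in_roi(locs, roi)
  }
  nucleus_id <- if (nrow(locs)) locs$nucleus_id[1L] else "n1"
  channel <- if (nrow(locs)) locs$channel[1L] else "ch1"
  labels <- dbscan_labels(locs$x, locs$y, eps, min_pts)
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids)) {
    empty <- data.frame(
      cluster_id = character(0), x = numeric(0), y = numeric(0),
      radius = numeric(0), n_loc = integer(0), stringsAsFactors = FALSE
    )
    return(cluster_set(nucleus_id, channel, empty,
                       params = list(eps = eps, min_pts = min_pts)))
  }
  rows <- vector("list", length(ids))
  members <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    sel <- labels == ids[k]
    mx <- mean(locs$x[sel])
    my <- mean(locs$y[sel])
    off <- cbind(dx = locs$x[sel] - mx, dy = locs$y[sel] - my)
    rows[[k]] <- data.frame(
      cluster_id = sprintf("c%03d", k), x = mx, y = my,
      radius = max(sqrt(off[, 1L]^2 + off[, 2L]^2)),
      n_loc = sum(sel), stringsAsFactors = FALSE
    )
    members[[k]] <- off
  }
  cluster_set(nucleus_id, channel, do.call(rbind, rows), members = members,
              params = list(eps = eps, min_pts = min_pts))
}
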