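# Independent oracles used to cross-check the package's implementations.
# Each one follows a deliberately different route from the code it checks
# (explicit loops, full enumeration, closed forms).

# O(n^2) brute-force disc-intersection pair count with explicit loops.
brute_overlap_pairs <- function(a, b) {
  ca <- a$clusters; cb <- b$clusters
  n <- 0L
  for (i in seq_len(nrow(ca))) {
    for (j in seq_len(nrow(cb))) {
      d <- sqrt((ca$x[i] - cb$x[j])^2 + (ca$y[i] - cb$y[j])^2)
      if (d <= ca$radius[i] + cb$radius[j]) n <- n + 1L
    }
  }
  n
}

# quadratic interval-intersection oracle for bin -> (site, window)
# assignment, pooling the two sides of the footprint before thresholding.
brute_assign <- function(track, sites, intervals, min_overlap_frac) {
  bw <- attr(track, "bin_width")
  out <- list()
  seg_ov <- function(bs, be, fs, fe) max(0, min(be, fe) - max(bs, fs))
  for (si in seq_len(nrow(sites))) {
    for (ii in seq_len(nrow(intervals))) {
      p <- sites$position[si]
      lo <- intervals$lower[ii]; up <- intervals$upper[ii]
      for (bi in seq_len(nrow(track))) {
        if (track$chrom[bi] != sites$chrom[si]) next
        ov <- seg_ov(track$start[bi], track$end[bi], max(p - up, 0), max(p - lo, 0)) +
          seg_ov(track$start[bi], track$end[bi], p + lo, p + up)
        if (ov >= min_overlap_frac * bw) {
          out[[length(out) + 1L]] <- data.frame(
            site_id = sites$site_id[si], interval = intervals$interval[ii],
            start = track$start[bi], value = track$value[bi],
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(site_id = character(0), interval = character(0),
                      start = numeric(0), value = numeric(0)))
  }
  o <- do.call(rbind, out)
  o[order(o$site_id, o$interval, o$start), ]
}

# exact two-sided signed-rank p by full 2^n enumeration (tie-free input),
# reproducing the standard two-sided doubling rule.
enum_signed_rank_p <- function(x) {
  d <- x[x != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  if (v_obs > mu) {
    p <- 2 * mean(v_all >= v_obs)
  } else if (v_obs < mu) {
    p <- 2 * mean(v_all <= v_obs)
  } else {
    p <- 1
  }
  min(p, 1)
}

# connected components of the eps-neighbourhood graph (BFS on a full
# distance matrix) -- clustering oracle for well-separated dense blobs.
cc_components <- function(x, y, eps) {
  n <- length(x)
  adj <- as.matrix(stats::dist(cbind(x, y))) <= eps
  comp <- integer(n)
  lab <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    lab <- lab + 1L
    queue <- i
    comp[i] <- lab
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[p, ] & comp == 0L)
      comp[nb] <- lab
      queue <- c(queue, nb)
    }
  }
  comp
}

# textbook Welch two-sample statistic and two-sided p.
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# small random cluster set in a box, for overlap-count oracle tests
random_cluster_set <- function(n, channel, box = 1e4, rmax = 300,
                               nucleus_id = "n1") {
  cluster_set(nucleus_id, channel, data.frame(
    cluster_id = sprintf("%s%04d", channel, seq_len(n)),
    x = runif(n, 0, box), y = runif(n, 0, box),
    radius = runif(n, 0, rmax), n_loc = pmax(1L, rpois(n, 20)),
    stringsAsFactors = FALSE
  ))
}
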