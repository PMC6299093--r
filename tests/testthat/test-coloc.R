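# Cluster detection, overlap counting, cluster randomization and the
# normalized overlap ratio.

test_that("density-based detection matches the neighbourhood-graph oracle", {
  # below the density threshold: no clusters
  tiny <- localization_table("n", "A", c(0, 10), c(0, 0))
  expect_equal(nrow(detect_clusters(tiny, eps = 75, min_pts = 3)$clusters), 0L)

  # two dense blobs far apart resolve into exactly their components
  set.seed(21)
  b1 <- cbind(rnorm(20, 500, 30), rnorm(20, 500, 30))
  b2 <- cbind(rnorm(20, 2500, 30), rnorm(20, 2500, 30))
  pts <- rbind(b1, b2)
  locs <- localization_table("n", "A", pts[, 1], pts[, 2])
  cs <- detect_clusters(locs, eps = 100, min_pts = 5)
  comp <- cc_components(pts[, 1], pts[, 2], eps = 100)
  expect_equal(nrow(cs$clusters), length(unique(comp)))
  expect_equal(nrow(cs$clusters), 2L)
  # centroids equal the component means (order-free comparison)
  want <- sort(c(mean(b1[, 1]), mean(b2[, 1])))
  expect_equal(sort(cs$clusters$x), want, tolerance = 1e-9)

  # coincident points: one cluster, zero radius, exact centroid
  co <- localization_table("n", "A", rep(500, 5), rep(500, 5))
  cs2 <- detect_clusters(co, eps = 75, min_pts = 5)
  expect_equal(nrow(cs2$clusters), 1L)
  expect_equal(cs2$clusters$x, 500)
  expect_equal(cs2$clusters$radius, 0)
  expect_equal(cs2$clusters$n_loc, 5L)
})

test_that("overlap counting equals brute force and is symmetric", {
  one_a <- cluster_set("n", "A", data.frame(
    cluster_id = "a", x = 100, y = 100, radius = 50, n_loc = 5
  ))
  one_b <- cluster_set("n", "B", data.frame(
    cluster_id = "b", x = 100, y = 100, radius = 10, n_loc = 5
  ))
  empty_b <- cluster_set("n", "B", data.frame(
    cluster_id = character(0), x = numeric(0), y = numeric(0),
    radius = numeric(0), n_loc = integer(0)
  ))
  expect_equal(count_overlaps(one_a, one_b), 1L)
  expect_equal(count_overlaps(one_a, empty_b), 0L)

  set.seed(31)
  for (i in 1:50) {
    a <- random_cluster_set(sample(1:50, 1), "A")
    b <- random_cluster_set(sample(1:50, 1), "B")
    expect_identical(count_overlaps(a, b), brute_overlap_pairs(a, b))
    expect_identical(count_overlaps(a, b), count_overlaps(b, a))
  }
})

test_that("randomization preserves cluster composition and stays in the ROI", {
  set.seed(41)
  a <- random_cluster_set(30, "A", box = 8000, rmax = 200)
  rois <- list(
    roi_rect(-500, -500, 10500, 10500, "r"),
    roi_polygon(rbind(c(-500, -500), c(10500, -500), c(10500, 10500),
                      c(-500, 10500)), "p"),
    roi_mask(matrix(TRUE, 25, 25), pixel_size = 450, origin = c(-500, -500),
             nucleus_id = "m")
  )
  for (roi in rois) {
    r <- randomize_clusters(a, roi)
    expect_equal(nrow(r$clusters), nrow(a$clusters))
    expect_equal(sort(r$clusters$radius), sort(a$clusters$radius))
    expect_equal(sort(r$clusters$n_loc), sort(a$clusters$n_loc))
    # every disc wholly inside: the four extreme points of each disc
    ok <- roi_contains(roi, r$clusters$x + r$clusters$radius, r$clusters$y) &
      roi_contains(roi, r$clusters$x - r$clusters$radius, r$clusters$y) &
      roi_contains(roi, r$clusters$x, r$clusters$y + r$clusters$radius) &
      roi_contains(roi, r$clusters$x, r$clusters$y - r$clusters$radius)
    expect_true(all(ok))
  }
})

test_that("degenerate geometry forces the unique admissible placement", {
  roi <- roi_disc(1000, 2000, 150, "d")
  cl <- cluster_set("d", "A", data.frame(
    cluster_id = "c", x = 1000, y = 2000, radius = 150, n_loc = 3
  ))
  r <- randomize_clusters(cl, roi)
  expect_equal(c(r$clusters$x, r$clusters$y), c(1000, 2000))

  big <- cluster_set("d", "A", data.frame(
    cluster_id = "huge", x = 1000, y = 2000, radius = 151, n_loc = 3
  ))
  expect_error(randomize_clusters(big, roi), "huge")
})

test_that("normalized ratio handles trivial and forced-geometry cases", {
  roi <- roi_rect(0, 0, 1e4, 1e4, "n")
  a <- cluster_set("n", "A", data.frame(
    cluster_id = "a", x = 100, y = 100, radius = 50, n_loc = 5
  ))
  far_b <- cluster_set("n", "B", data.frame(
    cluster_id = "b", x = 9000, y = 9000, radius = 50, n_loc = 5
  ))
  res <- normalized_overlap_ratio(a, far_b, roi, n_sim = 20, seed = 1)
  expect_equal(res$n_real, 0L)
  expect_true(res$ratio == 0 || res$flag == "both-zero")

  # ROI so tight that every placement overlaps: ratio exactly 1
  tight <- roi_rect(0, 0, 220, 220, "n")
  a2 <- cluster_set("n", "A", data.frame(
    cluster_id = "a", x = 110, y = 110, radius = 100, n_loc = 5
  ))
  b2 <- cluster_set("n", "B", data.frame(
    cluster_id = "b", x = 110, y = 110, radius = 100, n_loc = 5
  ))
  res2 <- normalized_overlap_ratio(a2, b2, tight, n_sim = 20, seed = 2)
  expect_identical(res2$random_counts, rep(1L, 20))
  expect_identical(res2$ratio, 1)
  expect_identical(res2$flag, "ok")
})

test_that("identical seeds reproduce results bit-for-bit", {
  set.seed(51)
  a <- random_cluster_set(25, "A", box = 9000, rmax = 150)
  b <- random_cluster_set(25, "B", box = 9000, rmax = 150)
  roi <- roi_rect(-200, -200, 9500, 9500, "n")
  r1 <- normalized_overlap_ratio(a, b, roi, seed = 77)
  r2 <- normalized_overlap_ratio(a, b, roi, seed = 77)
  expect_identical(r1, r2)
  r3 <- normalized_overlap_ratio(a, b, roi, seed = 78)
  expect_false(identical(r1$random_counts, r3$random_counts))
})

test_that("the statistic is invariant under a global rescaling", {
  set.seed(61)
  a <- random_cluster_set(20, "A", box = 9000, rmax = 150)
  b <- random_cluster_set(20, "B", box = 9000, rmax = 150)
  roi <- roi_rect(-200, -200, 9500, 9500, "n")
  scale_set <- function(s, k) {
    cl <- s$clusters
    cl$x <- cl$x * k; cl$y <- cl$y * k; cl$radius <- cl$radius * k
    cluster_set(s$nucleus_id, s$channel, cl)
  }
  roi10 <- roi_rect(-2000, -2000, 95000, 95000, "n")
  r1 <- normalized_overlap_ratio(a, b, roi, seed = 99)
  r2 <- normalized_overlap_ratio(scale_set(a, 10), scale_set(b, 10), roi10, seed = 99)
  expect_identical(r1$n_real, r2$n_real)
  expect_identical(r1$random_counts, r2$random_counts)
})

test_that("cohort summaries match the closed-form Welch test", {
  # identical groups: t = 0, p = 1
  s0 <- cohort_summary(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(s0$test$t, 0)
  expect_equal(s0$test$p, 1)

  set.seed(71)
  jit <- c(rep(1, 4), rep(2, 4)) + rnorm(8, 0, 1e-6)
  ssep <- cohort_summary(jit, rep(c("a", "b"), each = 4))
  expect_lt(ssep$test$p, 1e-6)

  x <- rnorm(12); y <- rnorm(15, 0.5)
  sw <- cohort_summary(c(x, y), rep(c("x", "y"), c(12, 15)))
  o <- welch_oracle(x, y)
  expect_equal(sw$test$t, o$t, tolerance = 1e-10)
  expect_equal(sw$test$p, o$p, tolerance = 1e-10)
  expect_equal(sw$groups$sem[sw$groups$group == "x"],
               sd(x) / sqrt(12), tolerance = 1e-12)

  expect_warning(
    s1 <- cohort_summary(c(1, 2, 3), c("a", "a", "b")),
    "withheld"
  )
  expect_null(s1$test)
})
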