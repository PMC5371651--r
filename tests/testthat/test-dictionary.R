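test_that("whole-image patch extraction preserves labels bijectively", {
  set.seed(401)
  imgs <- replicate(10, matrix(runif(16), 4, 4), simplify = FALSE)
  labs <- rep(c("a", "b"), each = 5)
  patches <- extract_whole_image_patches(imgs, labs)
  expect_length(patches, 10L)
  expect_equal(vapply(patches, `[[`, "", "label"), labs)
  for (i in 1:10) expect_equal(patches[[i]]$pixels, imgs[[i]])
  expect_equal(extract_whole_image_patches(list(), character(0)), list())
  expect_error(extract_whole_image_patches(list(matrix(1, 2, 2), matrix(1, 3, 3)),
                                           c("a", "b")), "size")
})

test_that("harris_keypoints finds square corners and is threshold-monotone", {
  expect_equal(nrow(harris_keypoints(matrix(0.5, 32, 32))), 0L)

  img <- matrix(0, 32, 32)
  img[10:23, 10:23] <- 1
  kps <- harris_keypoints(img)
  corners <- rbind(c(10, 10), c(10, 23), c(23, 10), c(23, 23))
  for (q in 1:4) {
    d <- sqrt((kps[, 1] - corners[q, 1])^2 + (kps[, 2] - corners[q, 2])^2)
    expect_lte(min(d), 2)
  }

  n_lo <- nrow(harris_keypoints(img, rel_threshold = 0.01))
  n_hi <- nrow(harris_keypoints(img, rel_threshold = 0.5))
  expect_gte(n_lo, n_hi)
})

test_that("keypoint patches have the right size, labels and scale tags", {
  set.seed(402)
  img <- matrix(0, 40, 40)
  img[12:28, 12:28] <- 1
  patches <- extract_keypoint_patches(list(img, img), c("target", "non-target"),
                                      patch_size = 9)
  expect_gt(length(patches), 0L)
  for (p in patches) expect_equal(dim(p$pixels), c(9L, 9L))
  expect_setequal(unique(vapply(patches, `[[`, "", "label")),
                  c("target", "non-target"))
  sc <- extract_keypoint_patches(list(img), "t", patch_size = 9,
                                 scales = c(1, 0.8))
  expect_setequal(unique(vapply(sc, function(p) p$scale_index, 0L)), c(0L, 1L))
  expect_error(extract_keypoint_patches(list(img), "t", patch_size = 8),
               "odd")
  expect_error(extract_keypoint_patches(list(matrix(0, 6, 6)), "t",
                                        patch_size = 9), "smaller")
})

test_that("agglomerative clustering merges, terminates and filters as stated", {
  set.seed(403)
  mk <- function(base, eps = 0.02) {
    base + matrix(rnorm(length(base), 0, eps), nrow(base), ncol(base))
  }
  A <- random_smooth_patch(6); B <- -A + 0.9  # strongly dissimilar

  # two identical patches form one cluster whose mean is the patch
  patches <- lapply(list(A, A), function(p) list(pixels = p, label = "t",
                                                 scale_index = 0L))
  d <- agglomerative_cluster(patches, kappa = 0.9)
  expect_length(d$elements, 1L)
  expect_equal(d$elements[[1]]$pixels, A)
  expect_equal(d$elements[[1]]$member_count, 2L)

  # all pairwise similarities below kappa: every patch its own cluster
  d2 <- agglomerative_cluster(list(
    list(pixels = A, label = "t", scale_index = 0L),
    list(pixels = B, label = "t", scale_index = 0L)), kappa = 0.5)
  expect_length(d2$elements, 2L)

  # cluster sizes {11, 12} with lambda = 12: only the 12-cluster survives
  p11 <- lapply(1:11, function(i) list(pixels = mk(A), label = "t",
                                       scale_index = 0L))
  p12 <- lapply(1:12, function(i) list(pixels = mk(B), label = "t",
                                       scale_index = 0L))
  d3 <- agglomerative_cluster(c(p11, p12), kappa = 0.5, lambda_min = 12L)
  expect_length(d3$elements, 1L)
  expect_equal(d3$elements[[1]]$member_count, 12L)

  # empty input
  expect_length(agglomerative_cluster(list(), 0.5)$elements, 0L)
})

test_that("clustering matches complete-linkage hclust and is order-invariant", {
  set.seed(404)
  for (rep in 1:5) {
    mats <- replicate(8, random_smooth_patch(5), simplify = FALSE)
    patches <- lapply(mats, function(m) list(pixels = m, label = "t",
                                             scale_index = 0L))
    kappa <- 0.5
    d <- agglomerative_cluster(patches, kappa)
    # independent oracle: hclust complete linkage on 1 - ZMNCC distance
    M <- vapply(mats, as.numeric, numeric(25))
    S <- cor(M)
    hc <- stats::hclust(stats::as.dist(1 - S), method = "complete")
    ref <- stats::cutree(hc, h = 1 - kappa)
    # compare partition structure via cluster count and sizes
    expect_equal(length(d$elements), length(unique(ref)))
    expect_setequal(vapply(d$elements, function(e) e$member_count, 0L),
                    as.integer(table(ref)))

    # order invariance (no ties in random similarities)
    perm <- sample(8)
    dp <- agglomerative_cluster(patches[perm], kappa)
    sizes <- sort(vapply(d$elements, function(e) e$member_count, 0L))
    sizes_p <- sort(vapply(dp$elements, function(e) e$member_count, 0L))
    expect_equal(sizes, sizes_p)
    means <- lapply(d$elements, `[[`, "pixels")
    means_p <- lapply(dp$elements, `[[`, "pixels")
    for (m1 in means) {
      expect_true(any(vapply(means_p, function(m2) {
        isTRUE(all.equal(m1, m2, tolerance = 1e-12))
      }, logical(1L))))
    }
  }
})

test_that("raising kappa never decreases the cluster count", {
  set.seed(405)
  patches <- replicate(12, list(pixels = random_smooth_patch(5), label = "t",
                                scale_index = 0L), simplify = FALSE)
  counts <- vapply(c(0.2, 0.4, 0.6, 0.8, 0.95), function(kap) {
    length(agglomerative_cluster(patches, kap)$elements)
  }, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("stage-1 networks are built from preprocessed elements", {
  set.seed(406)
  el <- random_smooth_patch(7)
  dict <- structure(list(elements = list(list(pixels = el, label = "t",
                                              scale_index = 0L,
                                              member_count = 1L)),
                         params = list(kappa = 0.5, lambda_min = 0L)),
                    class = "pcbc_dictionary")
  net <- build_stage1_network(dict, sigma = 2)
  expect_equal(dim(net$W), c(1L, 2L * 49L))
  expect_equal(sum(net$W), 1)

  # constant elements are excluded with a warning
  dict2 <- dict
  dict2$elements <- c(dict2$elements,
                      list(list(pixels = matrix(0.5, 7, 7), label = "t",
                                scale_index = 0L, member_count = 1L)))
  expect_warning(net2 <- build_stage1_network(dict2, sigma = 2), "constant")
  expect_equal(nrow(net2$W), 1L)
})

test_that("every dictionary element's own patch activates its own neuron", {
  set.seed(407)
  els <- replicate(20, random_smooth_patch(9), simplify = FALSE)
  dict <- structure(list(elements = lapply(seq_along(els), function(i) {
    list(pixels = els[[i]], label = "t", scale_index = 0L, member_count = 1L)
  }), params = list(kappa = 0.5, lambda_min = 0L)),
  class = "pcbc_dictionary")
  net <- build_stage1_network(dict, sigma = 2)
  for (i in seq_along(els)) {
    x <- contrast_vector(local_contrast(els[[i]], 2))
    st <- dim_solve(net, x)
    expect_equal(which.max(st$y), i)
  }
})
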