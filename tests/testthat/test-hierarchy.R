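test_that("stage-1 responses are recorded per image with labels", {
  set.seed(501)
  els <- replicate(6, random_smooth_patch(9), simplify = FALSE)
  dict <- structure(list(elements = lapply(els, function(e) {
    list(pixels = e, label = "t", scale_index = 0L, member_count = 1L)
  }), params = list(kappa = 0.5, lambda_min = 0L)),
  class = "pcbc_dictionary")
  net <- build_stage1_network(dict, sigma = 2)

  resp <- collect_stage1_responses(net, els[3], labels = "t")
  expect_equal(which.max(resp$responses[, 1]), 3L)

  empty <- collect_stage1_responses(net, list())
  expect_equal(ncol(empty$responses), 0L)
})

test_that("responses to synthetic glyphs are non-negative and sparse", {
  ds <- tiny_classifier()
  resp <- collect_stage1_responses(ds$hierarchy$stage1,
                                   ds$data$test$images[1:10])
  expect_true(all(resp$responses >= 0))
  expect_lt(mean(resp$responses > 0), 0.5)
})

test_that("class weights are the normalized per-class response sums", {
  resp <- list(form = "matrix",
               responses = cbind(c(1, 0, 2), c(3, 0, 0), c(0, 1, 0)),
               labels = c("A", "A", "B"))
  net <- learn_class_weights(resp)
  expect_equal(net$classes, c("A", "B"))
  expect_equal(net$W[1, ], c(4, 0, 2) / 6)
  expect_equal(net$W[2, ], c(0, 1, 0))

  # one prediction neuron per class
  ds <- tiny_classifier()
  expect_equal(nrow(ds$hierarchy$stage2$W), 4L)
  expect_equal(ds$hierarchy$stage2$classes, paste0("c", 1:4))

  resp$responses[, 3] <- 0
  expect_error(learn_class_weights(resp), "B")
})

test_that("class weights depend only on per-class sums", {
  set.seed(502)
  resp <- list(form = "matrix", responses = matrix(runif(5 * 6), 5, 6),
               labels = rep(c("A", "B"), 3))
  perm <- c(3, 1, 5, 2, 6, 4)  # permutes images within their classes
  resp_p <- list(form = "matrix", responses = resp$responses[, perm],
                 labels = resp$labels[perm])
  expect_equal(learn_class_weights(resp)$W, learn_class_weights(resp_p)$W)
})

test_that("location weights are centred, smoothed voting kernels", {
  # a single response at offset (-3, 0) from the centre of an 11x11 map
  m <- array(0, c(11, 11, 2))
  m[3, 6, 1] <- 1  # centre is (6, 6); offset (-3, 0)
  resp <- list(form = "conv", labels = NULL, maps = list(m))
  net <- learn_location_weights(resp, smoothing_sigma = 2)
  K <- net$kernels_w[[1]]
  pk <- which(K[, , 1] == max(K[, , 1]), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(3, 6))
  expect_equal(max(K[, , 2]), 0)
  # the blob is the (max-normalized) 2-px Gaussian
  expect_equal(max(K), 1)
  expect_equal(K[4, 6, 1] / K[3, 6, 1], exp(-1 / (2 * 4)), tolerance = 1e-9)

  # duplicated training images leave the normalized network unchanged
  resp2 <- list(form = "conv", labels = NULL, maps = list(m, m))
  net2 <- learn_location_weights(resp2, smoothing_sigma = 2)
  expect_equal(net$kernels_w, net2$kernels_w)

  # even-sized maps are rejected (no centre pixel)
  bad <- list(form = "conv", labels = NULL, maps = list(array(0, c(10, 11, 2))))
  expect_error(learn_location_weights(bad), "odd")
  # inconsistent sizes are rejected
  bad2 <- list(form = "conv", labels = NULL,
               maps = list(array(0, c(11, 11, 2)), array(0, c(9, 9, 2))))
  expect_error(learn_location_weights(bad2), "unregistered")
})

test_that("voting-kernel mass is conserved by the spatial smoothing", {
  # votes at least 4 sigma from every border keep their mass
  m <- matrix(0, 25, 25)
  m[12, 13] <- 2; m[13, 12] <- 1
  expect_equal(sum(gaussian_smooth(m, 2)), 3, tolerance = 1e-9)
})

test_that("stage 2 suppresses the weaker of two overlapping classes", {
  # stage-1 pattern axes: class A uses elements {1,2,3}, class B {3,4};
  # the test pattern matches A fully and B only through the shared element
  respA <- c(1, 1, 1, 0, 0)
  respB <- c(0, 0, 1, 1, 0)
  net <- learn_class_weights(list(form = "matrix",
                                  responses = cbind(respA, respB),
                                  labels = c("A", "B")))
  x <- c(1, 1, 1, 0.2, 0)
  st <- dim_solve(net, x)
  yA <- st$y[net$classes == "A"]; yB <- st$y[net$classes == "B"]
  expect_gt(yA, yB)
  expect_lt(yB, yA / 2)
})

test_that("multi-scale location weights couple scales by 3D smoothing", {
  m1 <- array(0, c(11, 11, 2)); m1[4, 6, 1] <- 1
  m2 <- array(0, c(11, 11, 2)); m2[8, 6, 2] <- 1
  resp <- list(list(form = "conv", labels = NULL, maps = list(m1)),
               list(form = "conv", labels = NULL, maps = list(m2)))
  net <- learn_location_weights(resp, smoothing_sigma = 1, scale_sigma = 0.5)
  expect_equal(net$p, 2L)
  # scale 1's kernel now contains leakage from scale 2's vote
  expect_gt(max(net$kernels_w[[1]][, , 2]), 0)
  expect_gt(max(net$kernels_w[[2]][, , 1]), 0)
})

test_that("a trained detector localizes a stamped object", {
  set.seed(503)
  gs <- glyph_spec(jitter_deg = 0, scale_range = c(1, 1), noise_sigma = 0,
                   illumination = c(0, 0), seed = 504)
  crops <- make_object_crops(gs, 10, clutter = 0, seed = 505)
  negs <- replicate(4, pcbcdim:::clutter_background(41, 41, 0.5),
                    simplify = FALSE)
  h <- pcbc_train_detector(crops, negs, lambda_min = 2L)
  scene <- matrix(0.15, 41, 41)
  scene[9:33, 9:33] <- pmax(scene[9:33, 9:33], crops[[1]])
  d <- detect(h, scene)
  expect_gt(nrow(d), 0L)
  expect_lt(abs(d$row[1] - 21) + abs(d$col[1] - 21), 2)
})

test_that("hierarchies round-trip through the archive format", {
  h <- tiny_classifier()$hierarchy
  path <- tempfile(fileext = ".rds")
  write_hierarchy(h, path)
  h2 <- read_hierarchy(path)
  expect_equal(h2$stage1$W, h$stage1$W)
  expect_equal(h2$classes, h$classes)

  bad <- h; bad$version <- "pcbc-hierarchy-0"
  saveRDS(bad, path)
  expect_error(read_hierarchy(path), "version")
})
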