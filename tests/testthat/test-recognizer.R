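test_that("classify picks the maximal stage-2 unit and supports no-decision", {
  tc <- tiny_classifier()
  h <- tc$hierarchy

  # a training exemplar of a well-separated class is classified correctly
  res <- classify(h, tc$data$train$images[[1]])
  expect_equal(res$class, tc$data$train$labels[1])
  expect_length(res$stage2, 4L)
  expect_equal(unname(which.max(res$stage2)), match(res$class, h$classes))

  # a blank image yields "no decision", distinct from any class
  expect_true(is.na(classify(h, matrix(0.5, 25, 25))$class))

  expect_error(classify(structure(list(mode = "location"),
                                  class = "pcbc_hierarchy"), matrix(0, 2, 2)),
               "not trained for classification")
})

test_that("classification is invariant to photometric gain and offset", {
  tc <- tiny_classifier()
  img <- tc$data$test$images[[3]]
  base <- classify(tc$hierarchy, img)$class
  for (a in c(0.5, 2)) {
    for (b in c(-0.1, 0.1)) {
      expect_equal(classify(tc$hierarchy, a * img + b)$class, base)
    }
  }
})

test_that("nms_same_element keeps local maxima with scan-order tie-breaks", {
  m <- matrix(0, 5, 5); m[3, 3] <- 1; m[3, 2] <- 0.5
  out <- nms_same_element(m)
  expect_equal(sum(out > 0), 1L)
  expect_equal(out[3, 3], 1)

  # constant plateau: first pixel in column-major scan order survives
  cst <- matrix(0.2, 4, 4)
  outc <- nms_same_element(cst)
  expect_equal(which(outc > 0), 1L)

  # two separated peaks both survive
  m2 <- matrix(0, 7, 7); m2[2, 2] <- 1; m2[6, 6] <- 0.8
  out2 <- nms_same_element(m2)
  expect_equal(sum(out2 > 0), 2L)

  # slices are suppressed independently
  A <- array(0, c(5, 5, 2)); A[2, 2, 1] <- 1; A[2, 3, 1] <- 0.9; A[4, 4, 2] <- 1
  outA <- nms_same_element(A)
  expect_equal(sum(outA > 0), 2L)
})

test_that("find_regions labels supra-floor connected components", {
  m <- matrix(0, 8, 8)
  m[2:3, 2:3] <- 0.5
  expect_length(find_regions(m), 1L)
  expect_length(find_regions(matrix(0.0005, 8, 8)), 0L)

  m[6:7, 6:7] <- 0.4  # second blob, sub-floor gap between them
  regs <- find_regions(m)
  expect_length(regs, 2L)

  # 4-connectivity: diagonal touch is two regions
  d <- matrix(0, 4, 4); d[1, 1] <- 0.1; d[2, 2] <- 0.1
  expect_length(find_regions(d), 2L)

  # 3D: blobs in adjacent scale slices connect (6-connectivity)
  A <- array(0, c(4, 4, 2)); A[2, 2, 1] <- 0.1; A[2, 2, 2] <- 0.1
  expect_length(find_regions(A), 1L)
})

test_that("decode_region performs population-vector decoding", {
  reg <- list(coords = cbind(row = c(2, 2), col = c(2, 4)),
              responses = c(1, 3))
  d <- decode_region(reg)
  expect_equal(d$col, 3.5)
  expect_equal(d$row, 2)
  expect_equal(d$score, 4)

  s <- list(coords = cbind(row = 5, col = 7), responses = 0.2)
  ds <- decode_region(s)
  expect_equal(c(ds$row, ds$col, ds$score), c(5, 7, 0.2))

  # symmetric blob decodes to its centre of symmetry
  g <- gaussian_smooth({m <- matrix(0, 9, 9); m[5, 5] <- 1; m}, 1.5)
  regs <- find_regions(g, floor = 1e-4)
  dg <- decode_region(regs[[1]])
  expect_equal(c(dg$row, dg$col), c(5, 5), tolerance = 1e-6)
})

test_that("decoded positions stay inside their region's coordinate hull", {
  set.seed(601)
  for (rep in 1:20) {
    n <- sample(1:6, 1)
    reg <- list(coords = cbind(row = sample(1:10, n, TRUE),
                               col = sample(1:10, n, TRUE)),
                responses = runif(n) + 1e-3)
    d <- decode_region(reg)
    eps <- 1e-9
    expect_gte(d$row, min(reg$coords[, "row"]) - eps)
    expect_lte(d$row, max(reg$coords[, "row"]) + eps)
    expect_gte(d$col, min(reg$coords[, "col"]) - eps)
    expect_lte(d$col, max(reg$coords[, "col"]) + eps)
  }
})

detector_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gs <- glyph_spec(jitter_deg = 4, scale_range = c(0.95, 1.05),
                       seed = 602)
      crops <- make_object_crops(gs, 40, seed = 603)
      sc <- make_scene_dataset(scene_spec(n_objects = c(2L, 2L), seed = 604),
                               gs, 3)
      cache <<- list(h = pcbc_train_detector(crops, sc$negatives),
                     scenes = sc)
    }
    cache
  }
})

test_that("detect finds planted objects and respects its threshold", {
  fx <- detector_fixture()
  # a blank scene yields no detections at any positive threshold
  expect_equal(nrow(detect(fx$h, matrix(0.3, 64, 64), score_threshold = 1e-6)),
               0L)

  truth <- fx$scenes$annotations[fx$scenes$annotations$image == 1, ]
  d <- detect(fx$h, fx$scenes$scenes[[1]], score_threshold = 0.3)
  expect_equal(nrow(d), 2L)
  for (q in seq_len(nrow(truth))) {
    err <- sqrt((d$row - truth$row[q])^2 + (d$col - truth$col[q])^2)
    expect_lte(min(err), 3)
  }

  # detection count is non-increasing in the score threshold
  d_all <- detect(fx$h, fx$scenes$scenes[[1]], score_threshold = 0)
  counts <- vapply(c(0, 0.01, 0.1, 0.5, 1, 5),
                   function(th) sum(d_all$score >= th), 0L)
  expect_true(all(diff(counts) <= 0))
  expect_true(all(diff(d_all$score) <= 0))  # sorted by decreasing score
})
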