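#' Classify an image with a trained hierarchy
#'
#' The image is preprocessed into ON/OFF channels, stage 1 is run to
#' steady state, the floored stage-1 responses are fed as input to stage
#' 2, and the class of the maximally responding stage-2 unit is returned.
#' If every stage-2 response is zero the outcome is "no decision"
#' (`NA_character_`), distinct from any class.
#'
#' @param hierarchy a `pcbc_hierarchy` trained with
#'   [pcbc_train_classifier()].
#' @param image numeric matrix, or a list of matrices to classify a whole
#'   set in one (vectorized) call.
#' @return for one image, a list with `class`, `stage1` and `stage2`
#'   response vectors; for a list of images, a list with `class` (character
#'   vector) and `stage2` (matrix, classes x images).
#' @export
classify <- function(hierarchy, image) {
  stopifnot(inherits(hierarchy, "pcbc_hierarchy"))
  if (hierarchy$mode != "class") stop("hierarchy was not trained for classification")
  single <- !is.list(image)
  images <- if (single) list(image) else image
  n_iter <- hierarchy$params$n_iter
  fl <- hierarchy$params$response_floor
  ci <- lapply(images, local_contrast, sigma = hierarchy$params$sigma)
  X <- vapply(ci, contrast_vector, numeric(ncol(hierarchy$stage1$W)))
  if (length(ci) == 1L) X <- matrix(X, ncol = 1L)
  s1 <- dim_solve(hierarchy$stage1, X, n_iter = n_iter, response_floor = fl)
  s2 <- dim_solve(hierarchy$stage2, s1$y, n_iter = n_iter,
                  response_floor = fl)
  y2 <- if (is.matrix(s2$y)) s2$y else matrix(s2$y, ncol = 1L)
  cls <- apply(y2, 2L, function(v) {
    if (max(v) <= 0) NA_character_ else hierarchy$classes[which.max(v)]
  })
  if (single) {
    list(class = cls[[1L]], stage1 = drop(s1$y), stage2 = drop(y2))
  } else {
    list(class = unname(cls), stage2 = y2)
  }
}

#' Non-maximum suppression within each dictionary element's response map
#'
#' Within the response map of each stage-1 element, responses that are not
#' local maxima of their 8-neighbourhood are set to zero.  On a plateau of
#' equal values the first pixel in scan order (column-major) is kept.
#'
#' @param stage1_maps `h x w x n_elements` array (or a single matrix).
#' @return array/matrix of the same shape.
#' @export
nms_same_element <- function(stage1_maps) {
  one <- is.matrix(stage1_maps)
  A <- as_stack(stage1_maps)
  h <- dim(A)[1L]; w <- dim(A)[2L]
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  # column-major scan order: (dr, dc) is "earlier" if dc < 0 or
  # (dc == 0 and dr < 0)
  earlier <- shifts$dc < 0 | (shifts$dc == 0 & shifts$dr < 0)
  shifted_max <- function(map, rows) {
    mx <- matrix(-Inf, h, w)
    for (q in rows) {
      dr <- shifts$dr[q]; dc <- shifts$dc[q]
      sh <- matrix(-Inf, h, w)
      r_dst <- max(1L, 1L - dr):min(h, h - dr)
      c_dst <- max(1L, 1L - dc):min(w, w - dc)
      sh[r_dst, c_dst] <- map[r_dst + dr, c_dst + dc]
      mx <- pmax(mx, sh)
    }
    mx
  }
  for (i in seq_len(dim(A)[3L])) {
    map <- A[, , i]
    keep <- map > shifted_max(map, which(earlier)) &
      map >= shifted_max(map, which(!earlier))
    A[, , i] <- map * keep
  }
  if (one) A[, , 1L] else A
}

#' Find contiguous regions of supra-floor response
#'
#' Connected components of `{response > floor}` using 4-connectivity in 2D
#' maps and 6-connectivity in 3D (position x scale) maps.
#'
#' @param maps numeric matrix (2D) or `h x w x S` array (3D).
#' @param floor region membership threshold; default 0.001.
#' @return list of regions; each region is a list with `coords` (matrix
#'   with columns row, col and, for 3D input, scale) and `responses`.
#' @export
find_regions <- function(maps, floor = 0.001) {
  three_d <- !is.matrix(maps)
  A <- as_stack(maps)
  d <- dim(A)
  above <- A > floor
  lab <- array(0L, dim = d)
  nb <- rbind(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L), c(0L, 1L, 0L))
  if (three_d) nb <- rbind(nb, c(0L, 0L, -1L), c(0L, 0L, 1L))
  regions <- list()
  idx_all <- which(above)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    id <- length(regions) + 1L
    queue <- start
    lab[start] <- id
    members <- integer(0)
    while (length(queue) > 0L) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      members <- c(members, cur)
      z <- (cur - 1L) %/% (d[1L] * d[2L])
      rem <- (cur - 1L) %% (d[1L] * d[2L])
      r <- rem %% d[1L] + 1L
      cc <- rem %/% d[1L] + 1L
      z <- z + 1L
      for (q in seq_len(nrow(nb))) {
        r2 <- r + nb[q, 1L]; c2 <- cc + nb[q, 2L]; z2 <- z + nb[q, 3L]
        if (r2 < 1L || r2 > d[1L] || c2 < 1L || c2 > d[2L] ||
            z2 < 1L || z2 > d[3L]) next
        lin <- (z2 - 1L) * d[1L] * d[2L] + (c2 - 1L) * d[1L] + r2
        if (above[lin] && lab[lin] == 0L) {
          lab[lin] <- id
          queue <- c(queue, lin)
        }
      }
    }
    rem <- (members - 1L) %% (d[1L] * d[2L])
    coords <- cbind(row = rem %% d[1L] + 1L, col = rem %/% d[1L] + 1L)
    if (three_d) coords <- cbind(coords,
                                 scale = (members - 1L) %/% (d[1L] * d[2L]) + 1L)
    regions[[id]] <- list(coords = coords, responses = A[members])
  }
  regions
}

#' Population-vector decoding of a response region
#'
#' The decoded coordinates are the average of the coordinates represented
#' by the region's neurons, weighted by each neuron's response; the score
#' is the total response of the region.
#'
#' @param region one element of a [find_regions()] result.
#' @return list with `row`, `col`, `scale_index` (`NA` for 2D regions) and
#'   `score`.
#' @export
decode_region <- function(region) {
  w <- region$responses
  s <- sum(w)
  stopifnot(length(w) > 0L, s > 0)
  ctr <- colSums(region$coords * w) / s
  list(row = unname(ctr["row"]), col = unname(ctr["col"]),
       scale_index = if ("scale" %in% names(ctr)) unname(ctr["scale"]) else NA_real_,
       score = s)
}

#' Detect objects in an image with a trained location hierarchy
#'
#' Preprocess, run convolutional stage 1 to steady state, optionally apply
#' per-element non-maximum suppression, run stage 2 (the voting stage),
#' extract contiguous supra-floor regions from the stage-2 response maps,
#' decode each region by population vector, and keep detections whose
#' region response sum reaches `score_threshold`.
#'
#' @param hierarchy a `pcbc_hierarchy` trained with
#'   [pcbc_train_detector()].
#' @param image numeric matrix (a scene).
#' @param score_threshold minimum region response sum; default 0 (keep
#'   all).
#' @param nms apply [nms_same_element()] to the stage-1 maps before stage
#'   2; default `TRUE`.
#' @return data frame with columns `row`, `col`, `scale_index`, `score`,
#'   sorted by decreasing score (possibly 0 rows).
#' @export
detect <- function(hierarchy, image, score_threshold = 0, nms = TRUE) {
  stopifnot(inherits(hierarchy, "pcbc_hierarchy"))
  if (!hierarchy$mode %in% c("location", "location_scale")) {
    stop("hierarchy was not trained for detection")
  }
  p <- hierarchy$params
  ci <- local_contrast(image, p$sigma)
  s1 <- conv_solve(hierarchy$stage1, contrast_stack(ci), n_iter = p$n_iter,
                   response_floor = p$response_floor)
  Y1 <- if (nms) nms_same_element(s1$Y) else s1$Y
  s2 <- conv_solve(hierarchy$stage2, Y1, n_iter = p$n_iter,
                   response_floor = p$response_floor)
  maps <- if (hierarchy$mode == "location") s2$Y[, , 1L] else s2$Y
  regions <- find_regions(maps, floor = p$response_floor)
  dets <- lapply(regions, decode_region)
  df <- data.frame(
    row = vapply(dets, `[[`, numeric(1L), "row"),
    col = vapply(dets, `[[`, numeric(1L), "col"),
    scale_index = vapply(dets, `[[`, numeric(1L), "scale_index"),
    score = vapply(dets, `[[`, numeric(1L), "score"))
  df <- df[df$score >= score_threshold, , drop = FALSE]
  df <- df[order(-df$score), , drop = FALSE]
  rownames(df) <- NULL
  df
}
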