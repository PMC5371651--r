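#' Treat each labelled training image as one patch
#'
#' Used for tasks where object location and scale are fixed (whole-image
#' matching), e.g. digit or face classification.
#'
#' @param images list of numeric matrices, all the same size.
#' @param labels character (or coercible) vector of class labels, one per
#'   image.
#' @return list of patches; each patch is a list with `pixels`, `label`,
#'   `scale_index` (0) and `source`.
#' @export
extract_whole_image_patches <- function(images, labels) {
  if (length(images) == 0L) return(list())
  if (length(images) != length(labels)) {
    stop("images and labels have different lengths")
  }
  d <- dim(images[[1L]])
  labels <- as.character(labels)
  lapply(seq_along(images), function(i) {
    if (!identical(dim(images[[i]]), d)) {
      stop("image ", i, " has size ", paste(dim(images[[i]]), collapse = "x"),
           "; expected ", paste(d, collapse = "x"))
    }
    list(pixels = images[[i]], label = labels[i], scale_index = 0L,
         source = list(image = i, row = NA_real_, col = NA_real_))
  })
}

# Running maximum over a (2r+1)^2 neighbourhood (values outside the map
# count as -Inf).
max_filter <- function(map, radius) {
  h <- nrow(map); w <- ncol(map)
  out <- map
  for (dr in -radius:radius) {
    for (dc in -radius:radius) {
      if (dr == 0L && dc == 0L) next
      sh <- matrix(-Inf, h, w)
      r_dst <- max(1L, 1L - dr):min(h, h - dr)
      c_dst <- max(1L, 1L - dc):min(w, w - dc)
      sh[r_dst, c_dst] <- map[r_dst + dr, c_dst + dc]
      out <- pmax(out, sh)
    }
  }
  out
}

#' Harris corner keypoints
#'
#' Local maxima of the Harris corner response
#' `det(M) - sensitivity * trace(M)^2` (M the Gaussian-smoothed structure
#' tensor) that exceed `rel_threshold` times the maximum response and lie
#' at least `border` pixels from the image border.
#'
#' @param image numeric matrix.
#' @param sensitivity Harris `k`; default 0.05.
#' @param rel_threshold keep responses above this fraction of the maximum
#'   response; default 0.01.
#' @param nms_radius non-maximum-suppression radius in pixels; default 3.
#' @param border minimum distance from the border in pixels; default 0.
#' @param smooth_sigma standard deviation of the structure-tensor
#'   smoothing; default 1.5.
#' @return integer matrix with columns `row`, `col` (possibly 0 rows).
#' @export
harris_keypoints <- function(image, sensitivity = 0.05, rel_threshold = 0.01,
                             nms_radius = 3L, border = 0L,
                             smooth_sigma = 1.5) {
  h <- nrow(image); w <- ncol(image)
  empty <- matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("row", "col")))
  if (h < 3L || w < 3L) return(empty)
  Ix <- matrix(0, h, w); Iy <- matrix(0, h, w)
  Ix[, 2:(w - 1)] <- (image[, 3:w] - image[, 1:(w - 2)]) / 2
  Iy[2:(h - 1), ] <- (image[3:h, ] - image[1:(h - 2), ]) / 2
  Sxx <- gaussian_smooth(Ix * Ix, smooth_sigma)
  Syy <- gaussian_smooth(Iy * Iy, smooth_sigma)
  Sxy <- gaussian_smooth(Ix * Iy, smooth_sigma)
  R <- (Sxx * Syy - Sxy^2) - sensitivity * (Sxx + Syy)^2
  mx <- max(R)
  if (mx <= 0) return(empty)
  keep <- R >= rel_threshold * mx & R >= max_filter(R, nms_radius)
  if (border > 0L) {
    mask <- matrix(FALSE, h, w)
    if (h > 2L * border && w > 2L * border) {
      mask[(border + 1L):(h - border), (border + 1L):(w - border)] <- TRUE
    }
    keep <- keep & mask
  }
  idx <- which(keep)
  if (length(idx) == 0L) return(empty)
  cbind(row = (idx - 1L) %% h + 1L, col = (idx - 1L) %/% h + 1L)
}

#' Extract fixed-size patches around Harris keypoints, optionally over scales
#'
#' Each image is resized by every factor in `scales`; Harris keypoints are
#' found in the resized image and a `patch_size` x `patch_size` patch is
#' cut around each keypoint.  Patches that would overlap the border are
#' discarded (keypoints are required to lie at least half a patch from the
#' border).
#'
#' @param images list of numeric matrices.
#' @param labels label per image (e.g. `"target"` / `"non-target"`, or a
#'   class name).
#' @param patch_size odd patch side length in pixels; default 15.
#' @param scales numeric vector of resize factors; default 1 (scale index
#'   `i - 1` is attached to patches from `scales[i]`).
#' @param ... further arguments passed to [harris_keypoints()].
#' @return list of patches (see [extract_whole_image_patches()] for the
#'   fields).
#' @export
extract_keypoint_patches <- function(images, labels, patch_size = 15L,
                                     scales = 1, ...) {
  if (patch_size %% 2L == 0L) stop("patch_size must be odd")
  if (length(images) != length(labels)) {
    stop("images and labels have different lengths")
  }
  half <- patch_size %/% 2L
  labels <- as.character(labels)
  out <- list()
  for (i in seq_along(images)) {
    for (si in seq_along(scales)) {
      im <- if (scales[si] == 1) images[[i]] else {
        resize_bilinear(images[[i]], scales[si])
      }
      if (nrow(im) < patch_size || ncol(im) < patch_size) {
        stop("image ", i, " at scale ", scales[si], " is smaller than the patch size")
      }
      kps <- harris_keypoints(im, border = half, ...)
      for (q in seq_len(nrow(kps))) {
        r <- kps[q, 1L]; cc <- kps[q, 2L]
        out[[length(out) + 1L]] <- list(
          pixels = im[(r - half):(r + half), (cc - half):(cc + half)],
          label = labels[i], scale_index = si - 1L,
          source = list(image = i, row = r, col = cc))
      }
    }
  }
  out
}

# Pairwise ZMNCC matrix of a list of equally sized patches.  Zero-variance
# patches correlate 0 with everything.
zmncc_matrix <- function(mats) {
  M <- vapply(mats, as.numeric, numeric(length(mats[[1L]])))
  S <- suppressWarnings(cor(M))
  S[!is.finite(S)] <- 0
  S
}

# Greedy best-first complete-linkage agglomeration on a similarity matrix:
# repeatedly merge the most similar cluster pair (similarity = minimum
# pairwise ZMNCC across the two clusters, i.e. their most different
# members) while that similarity is >= kappa.  Ties are broken by the
# lowest (i, j) index pair.  Returns a list of member index vectors.
cluster_indices <- function(S, kappa) {
  n <- nrow(S)
  members <- as.list(seq_len(n))
  sim <- S
  diag(sim) <- -Inf
  alive <- rep(TRUE, n)
  repeat {
    live <- which(alive)
    if (length(live) < 2L) break
    sub <- sim[live, live, drop = FALSE]
    best <- max(sub)
    if (best < kappa) break
    hit <- which(sub == best, arr.ind = TRUE)
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    i <- live[hit[1L, 1L]]; j <- live[hit[1L, 2L]]
    members[[i]] <- c(members[[i]], members[[j]])
    members[j] <- list(NULL)
    alive[j] <- FALSE
    # complete linkage: similarity to the merged cluster is the worse of
    # the similarities to its parts
    sim[i, ] <- pmin(sim[i, ], sim[j, ])
    sim[, i] <- sim[i, ]
    sim[i, i] <- -Inf
    sim[j, ] <- -Inf
    sim[, j] <- -Inf
  }
  members[alive]
}

#' Cluster patches by agglomerative complete-linkage ZMNCC clustering
#'
#' Patches are grouped by `(label, scale_index)` and each group is
#' clustered separately (per class for classification; target versus
#' non-target, and per scale, for detection).  Within a group, the most
#' similar pair of clusters is merged repeatedly, where cluster similarity
#' is the ZMNCC between their two most different members (complete
#' linkage), until every inter-cluster similarity is below `kappa`.
#' Clusters with fewer than `lambda_min` members are discarded.  Each
#' surviving cluster contributes one dictionary element: the arithmetic
#' mean of its member patches.
#'
#' @param patches list of patches (see [extract_keypoint_patches()]).
#' @param kappa similarity threshold in `(0, 1]`.
#' @param lambda_min minimum cluster size; default 0 (keep all).
#' @return an object of class `pcbc_dictionary`: list with `elements`
#'   (each a list with `pixels`, `label`, `scale_index`, `member_count`)
#'   and `params`.
#' @export
agglomerative_cluster <- function(patches, kappa, lambda_min = 0L) {
  if (!is.numeric(kappa) || kappa <= 0 || kappa > 1) {
    stop("kappa must be in (0, 1]")
  }
  elements <- list()
  if (length(patches) > 0L) {
    d <- dim(patches[[1L]]$pixels)
    labs <- vapply(patches, function(p) p$label, character(1L))
    scls <- vapply(patches, function(p) as.integer(p$scale_index), integer(1L))
    # label-major pooling order, then scale
    for (lab in sort(unique(labs))) {
      for (sc in sort(unique(scls[labs == lab]))) {
        idx <- which(labs == lab & scls == sc)
        mats <- lapply(patches[idx], `[[`, "pixels")
        if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1L)))) {
          stop("patches have inconsistent shapes")
        }
        groups <- if (length(idx) == 1L) list(1L) else {
          cluster_indices(zmncc_matrix(mats), kappa)
        }
        for (g in groups) {
          if (length(g) < lambda_min) next
          elements[[length(elements) + 1L]] <- list(
            pixels = Reduce(`+`, mats[g]) / length(g),
            label = lab, scale_index = sc, member_count = length(g))
        }
      }
    }
  }
  structure(list(elements = elements,
                 params = list(kappa = kappa, lambda_min = lambda_min)),
            class = "pcbc_dictionary")
}

#' @export
print.pcbc_dictionary <- function(x, ...) {
  labs <- vapply(x$elements, `[[`, character(1L), "label")
  cat(sprintf("PC/BC-DIM dictionary: %d elements (kappa = %g, lambda = %d)\n",
              length(x$elements), x$params$kappa, x$params$lambda_min))
  if (length(labs)) print(table(labs))
  invisible(x)
}

#' Build the first processing stage from a dictionary
#'
#' Every dictionary element is preprocessed in an identical way to the
#' input images ([local_contrast()] with the same `sigma`) and its ON/OFF
#' channels become the receptive field of one stage-1 prediction neuron:
#' concatenated into one row in matrix form, or used as a two-channel
#' kernel in convolutional form.  Receptive fields are normalized to sum
#' to one.  Elements whose contrast is all zero (constant patches) are
#' excluded with a warning.
#'
#' @param dictionary a [agglomerative_cluster()] result.
#' @param sigma preprocessing Gaussian standard deviation (pixels).
#' @param form `"matrix"` for one neuron per element, or `"conv"` for
#'   elements replicated at every pixel.
#' @param epsilon2 stage parameter; default 1e-2.
#' @return a [dim_network()] or [conv_network()] with a `meta` field
#'   recording element labels, scale indices, patch shape and `sigma`.
#' @export
build_stage1_network <- function(dictionary, sigma,
                                 form = c("matrix", "conv"),
                                 epsilon2 = 1e-2) {
  form <- match.arg(form)
  stopifnot(inherits(dictionary, "pcbc_dictionary"))
  if (length(dictionary$elements) == 0L) stop("dictionary is empty")
  ci <- lapply(dictionary$elements, function(el) {
    local_contrast(el$pixels, sigma)
  })
  ok <- vapply(ci, function(x) max(x$on, x$off) > 0, logical(1L))
  if (!any(ok)) stop("all dictionary elements have zero contrast")
  if (!all(ok)) {
    warning(sum(!ok), " constant dictionary element(s) excluded (zero contrast)")
  }
  elements <- dictionary$elements[ok]
  ci <- ci[ok]
  meta <- list(
    labels = vapply(elements, `[[`, character(1L), "label"),
    scale_index = vapply(elements, function(e) as.integer(e$scale_index),
                         integer(1L)),
    patch_dim = dim(elements[[1L]]$pixels),
    sigma = sigma, form = form)
  net <- if (form == "matrix") {
    raw <- t(vapply(ci, contrast_vector,
                    numeric(2L * prod(meta$patch_dim))))
    if (length(ci) == 1L) raw <- matrix(raw, nrow = 1L)
    dim_network(raw, epsilon2)
  } else {
    conv_network(lapply(ci, contrast_stack), epsilon2)
  }
  net$meta <- meta
  net
}
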