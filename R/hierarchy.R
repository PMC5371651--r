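#' Record steady-state stage-1 responses to a set of training images
#'
#' Each image is preprocessed into ON/OFF channels with the sigma the
#' stage-1 network was built with, the stage is run to steady state, and
#' the floored prediction responses are recorded.
#'
#' For a matrix-form stage the result holds a response matrix (one column
#' per image); for a convolutional stage it holds one `h x w x n_elements`
#' response array per image.
#'
#' @param net stage-1 network from [build_stage1_network()].
#' @param images list of numeric matrices.
#' @param labels optional label per image.
#' @param n_iter,response_floor steady-state parameters; defaults 50 and
#'   0.001.
#' @return list with `form`, `labels`, and `responses` (matrix, neurons x
#'   images) or `maps` (list of arrays).
#' @export
collect_stage1_responses <- function(net, images, labels = NULL,
                                     n_iter = 50L, response_floor = 0.001) {
  if (is.null(net$meta)) stop("network lacks dictionary metadata; build it with build_stage1_network()")
  if (!is.null(labels) && length(labels) != length(images)) {
    stop("images and labels have different lengths")
  }
  form <- net$meta$form
  ci <- lapply(seq_along(images), function(i) {
    tryCatch(local_contrast(images[[i]], net$meta$sigma),
             error = function(e) stop("image ", i, ": ", conditionMessage(e),
                                      call. = FALSE))
  })
  out <- list(form = form,
              labels = if (is.null(labels)) NULL else as.character(labels))
  if (form == "matrix") {
    if (length(images) == 0L) {
      out$responses <- matrix(0, nrow(net$W), 0L)
      return(out)
    }
    X <- vapply(ci, contrast_vector, numeric(ncol(net$W)))
    if (length(ci) == 1L) X <- matrix(X, ncol = 1L)
    st <- dim_solve(net, X, n_iter = n_iter, response_floor = response_floor)
    out$responses <- st$y
  } else {
    out$maps <- lapply(ci, function(x) {
      conv_solve(net, contrast_stack(x), n_iter = n_iter,
                 response_floor = response_floor)$Y
    })
  }
  out
}

#' Define stage-2 class units from summed stage-1 responses
#'
#' One stage-2 prediction neuron per class; its raw weight vector is the
#' sum of the stage-1 response vectors over all training images of that
#' class ("proportional to" is resolved by the usual receptive-field
#' normalization to unit sum).
#'
#' @param responses a matrix-form result of [collect_stage1_responses()]
#'   with labels.
#' @param epsilon2 stage parameter; default 1e-2.
#' @return a [dim_network()] with a `classes` field (sorted class names,
#'   one per prediction neuron, in row order).
#' @export
learn_class_weights <- function(responses, epsilon2 = 1e-2) {
  if (is.null(responses$responses) || is.null(responses$labels)) {
    stop("need matrix-form responses with labels")
  }
  classes <- sort(unique(responses$labels))
  raw <- t(vapply(classes, function(cl) {
    rowSums(responses$responses[, responses$labels == cl, drop = FALSE])
  }, numeric(nrow(responses$responses))))
  if (length(classes) == 1L) raw <- matrix(raw, nrow = 1L)
  dead <- rowSums(raw) <= 0
  if (any(dead)) {
    stop("class(es) with all-zero summed stage-1 response: ",
         paste(classes[dead], collapse = ", "))
  }
  net <- dim_network(raw, epsilon2)
  net$classes <- classes
  net
}

# 1D Gaussian smoothing along the 3rd (scale) axis of a h x w x S array.
smooth_scale_axis <- function(A, sigma) {
  S <- dim(A)[3L]
  if (sigma <= 0 || S == 1L) return(A)
  k <- gaussian_kernel1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  out <- array(0, dim = dim(A))
  for (s in seq_len(S)) {
    for (u in -r:r) {
      s2 <- s + u
      if (s2 >= 1L && s2 <= S) out[, , s] <- out[, , s] + k[u + r + 1L] * A[, , s2]
    }
  }
  out
}

#' Define stage-2 location (and scale) units from stage-1 response maps
#'
#' The training object images must be registered so the object centre is
#' the image centre (all images the same odd size).  The stage-1 response
#' maps of such an image are then already expressed as offsets relative to
#' the object centre, so summing them over all training images yields one
#' voting kernel per stage-1 element.  The kernels are smoothed across
#' space with a unit-integral circular Gaussian (`smoothing_sigma`, default
#' 2 px) and, when `scale_sigma` is set, across the scale axis with a 1D
#' Gaussian, giving the three-dimensional smoothing used for multi-scale
#' detection.  The kernels are replicated convolutionally so that one
#' stage-2 prediction neuron exists per pixel (and per scale).
#'
#' The voting weights are only defined up to proportionality; here the
#' feedforward kernels are rescaled so each class's maximum weight is one
#' (the same rule the feedback kernels use).  With receptive fields
#' normalized to unit sum instead, the spatial smoothing dilutes the
#' per-tap weights so much that the voting units' multiplicative drive
#' stays below one for any input bounded by the stage-1 response range,
#' and the whole stage falls below the 0.001 response floor.
#'
#' @param responses a convolutional result of [collect_stage1_responses()]
#'   (single scale), or a list of such results, one per scale.
#' @param smoothing_sigma spatial Gaussian std in pixels; default 2.
#' @param scale_sigma Gaussian std along the scale axis in scale steps;
#'   default 0.5 when multiple scales are given, unused otherwise.
#' @param epsilon2 stage parameter; default 1e-2.
#' @return a [conv_network()] whose prediction classes are locations (one
#'   map) or location/scale combinations (one map per scale).
#' @export
learn_location_weights <- function(responses, smoothing_sigma = 2,
                                   scale_sigma = NULL, epsilon2 = 1e-2) {
  per_scale <- if (!is.null(responses$form)) list(responses) else responses
  kernels <- lapply(per_scale, function(rs) {
    if (is.null(rs$maps) || length(rs$maps) == 0L) {
      stop("need convolutional responses for at least one training image")
    }
    d <- dim(rs$maps[[1L]])
    if (d[1L] %% 2L == 0L || d[2L] %% 2L == 0L) {
      stop("training images must have odd dimensions so the object centre is a pixel")
    }
    if (!all(vapply(rs$maps, function(m) identical(dim(m), d), logical(1L)))) {
      stop("training response maps have inconsistent sizes (unregistered training images)")
    }
    K <- Reduce(`+`, rs$maps)
    for (i in seq_len(d[3L])) K[, , i] <- gaussian_smooth(K[, , i], smoothing_sigma)
    K
  })
  S <- length(kernels)
  if (S > 1L) {
    if (is.null(scale_sigma)) scale_sigma <- 0.5
    d <- dim(kernels[[1L]])
    for (i in seq_len(d[3L])) {
      A <- array(0, dim = c(d[1L], d[2L], S))
      for (s in seq_len(S)) A[, , s] <- kernels[[s]][, , i]
      A <- smooth_scale_axis(A, scale_sigma)
      for (s in seq_len(S)) kernels[[s]][, , i] <- A[, , s]
    }
  }
  conv_network(kernels, epsilon2, w_norm = "max")
}

#' Train a two-stage PC/BC-DIM classifier
#'
#' Whole training images become patches, are clustered per class into a
#' dictionary, the dictionary defines the matrix-form stage 1, and the
#' per-class sums of stage-1 responses define the stage-2 class units.
#'
#' @param images list of training images (numeric matrices, equal size).
#' @param labels class label per image.
#' @param sigma preprocessing Gaussian std in pixels.
#' @param kappa clustering similarity threshold; default 0.85.
#' @param lambda_min minimum cluster size; default 0.
#' @param n_iter,response_floor steady-state parameters.
#' @param epsilon2 stage parameter; default 1e-2.
#' @return an object of class `pcbc_hierarchy` with `mode = "class"`.
#' @export
pcbc_train_classifier <- function(images, labels, sigma, kappa = 0.85,
                                  lambda_min = 0L, n_iter = 50L,
                                  response_floor = 0.001, epsilon2 = 1e-2) {
  patches <- extract_whole_image_patches(images, labels)
  dict <- agglomerative_cluster(patches, kappa, lambda_min)
  stage1 <- build_stage1_network(dict, sigma, form = "matrix",
                                 epsilon2 = epsilon2)
  resp <- collect_stage1_responses(stage1, images, labels,
                                   n_iter = n_iter,
                                   response_floor = response_floor)
  stage2 <- learn_class_weights(resp, epsilon2)
  structure(list(mode = "class", stage1 = stage1, stage2 = stage2,
                 classes = stage2$classes, dictionary = dict,
                 params = list(sigma = sigma, kappa = kappa,
                               lambda_min = lambda_min, n_iter = n_iter,
                               response_floor = response_floor,
                               epsilon2 = epsilon2),
                 version = hierarchy_version()),
            class = "pcbc_hierarchy")
}

#' Train a two-stage PC/BC-DIM detector
#'
#' Harris keypoint patches are harvested from the registered object images
#' ("target") and from object-free images ("non-target"), clustered
#' separately, and the pooled dictionary defines the convolutional stage 1
#' (each element replicated at every pixel).  The stage-1 responses to the
#' object images, which are registered so the object centre is the image
#' centre, define the spatially smoothed voting kernels of the stage-2
#' location units.
#'
#' @param object_images list of equally sized, odd-sized object crops with
#'   the object centred.
#' @param background_images list of images not containing the object.
#' @param sigma preprocessing Gaussian std; default 3.5.
#' @param kappa clustering similarity threshold; default 0.4.
#' @param lambda_min minimum cluster size; default 12.
#' @param patch_size Harris patch side (odd); default 15.
#' @param scales resize factors for multi-scale training; default 1.
#' @param smoothing_sigma stage-2 spatial smoothing; default 2.
#' @param scale_sigma stage-2 scale-axis smoothing (multi-scale only).
#' @param n_iter,response_floor steady-state parameters.
#' @param epsilon2 stage parameter; default 1e-2.
#' @return an object of class `pcbc_hierarchy` with `mode = "location"` or
#'   `"location_scale"`.
#' @export
pcbc_train_detector <- function(object_images, background_images,
                                sigma = 3.5, kappa = 0.4, lambda_min = 12L,
                                patch_size = 15L, scales = 1,
                                smoothing_sigma = 2, scale_sigma = NULL,
                                n_iter = 50L, response_floor = 0.001,
                                epsilon2 = 1e-2) {
  tp <- extract_keypoint_patches(object_images,
                                 rep("target", length(object_images)),
                                 patch_size = patch_size, scales = scales)
  np <- extract_keypoint_patches(background_images,
                                 rep("non-target", length(background_images)),
                                 patch_size = patch_size, scales = scales)
  dict <- agglomerative_cluster(c(tp, np), kappa, lambda_min)
  if (length(dict$elements) == 0L) {
    stop("clustering produced no dictionary elements; lower lambda_min or kappa")
  }
  stage1 <- build_stage1_network(dict, sigma, form = "conv",
                                 epsilon2 = epsilon2)
  multi <- length(scales) > 1L
  if (!multi) {
    resp <- collect_stage1_responses(stage1, object_images,
                                     n_iter = n_iter,
                                     response_floor = response_floor)
    stage2 <- learn_location_weights(resp, smoothing_sigma,
                                     epsilon2 = epsilon2)
  } else {
    resp <- lapply(scales, function(s) {
      imgs <- lapply(object_images, function(im) {
        im2 <- resize_bilinear(im, s)
        odd_crop(im2)
      })
      collect_stage1_responses(stage1, imgs, n_iter = n_iter,
                               response_floor = response_floor)
    })
    stage2 <- learn_location_weights(resp, smoothing_sigma, scale_sigma,
                                     epsilon2 = epsilon2)
  }
  structure(list(mode = if (multi) "location_scale" else "location",
                 stage1 = stage1, stage2 = stage2, dictionary = dict,
                 params = list(sigma = sigma, kappa = kappa,
                               lambda_min = lambda_min,
                               patch_size = patch_size, scales = scales,
                               smoothing_sigma = smoothing_sigma,
                               scale_sigma = scale_sigma, n_iter = n_iter,
                               response_floor = response_floor,
                               epsilon2 = epsilon2),
                 version = hierarchy_version()),
            class = "pcbc_hierarchy")
}

# Crop a matrix symmetrically to odd dimensions.
odd_crop <- function(im) {
  h <- nrow(im); w <- ncol(im)
  if (h %% 2L == 0L) im <- im[seq_len(h - 1L), , drop = FALSE]
  if (w %% 2L == 0L) im <- im[, seq_len(w - 1L), drop = FALSE]
  im
}

hierarchy_version <- function() "pcbc-hierarchy-1"

#' @export
print.pcbc_hierarchy <- function(x, ...) {
  cat(sprintf("PC/BC-DIM hierarchy (%s mode)\n", x$mode))
  n1 <- if (x$stage1$meta$form == "matrix") nrow(x$stage1$W) else x$stage1$p
  cat(sprintf("  stage 1: %d dictionary elements (%s form)\n", n1,
              x$stage1$meta$form))
  if (x$mode == "class") {
    cat(sprintf("  stage 2: %d class units\n", length(x$classes)))
  } else {
    cat(sprintf("  stage 2: location units, %d scale map(s)\n", x$stage2$p))
  }
  invisible(x)
}

#' Save a trained hierarchy to disk
#' @param hierarchy a `pcbc_hierarchy`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(hierarchy, path) {
  stopifnot(inherits(hierarchy, "pcbc_hierarchy"))
  saveRDS(hierarchy, path)
  invisible(path)
}

#' Load a trained hierarchy, checking the archive version
#' @param path file path written by [write_hierarchy()].
#' @return a `pcbc_hierarchy`.
#' @export
read_hierarchy <- function(path) {
  h <- readRDS(path)
  if (!inherits(h, "pcbc_hierarchy") ||
      !identical(h$version, hierarchy_version())) {
    stop("incompatible hierarchy archive version in ", path)
  }
  h
}
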