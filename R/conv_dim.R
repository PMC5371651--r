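#' Rotate a kernel by 180 degrees
#' @param k numeric matrix.
#' @return the matrix rotated by 180 degrees.
#' @keywords internal
rot180 <- function(k) k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k))), drop = FALSE]

as_stack <- function(X) {
  if (is.matrix(X)) X <- array(X, dim = c(dim(X), 1L))
  if (!is.array(X) || length(dim(X)) != 3L) {
    stop("expected a matrix or an h x w x k array")
  }
  X
}

#' Build a convolutional PC/BC-DIM stage
#'
#' Each prediction class `j` has one kernel per input channel `i`.  The
#' feedforward kernels `w_ji` are normalized so that, per class, the sum
#' over all channels and positions is one (the convolutional analogue of a
#' receptive field summing to one).  The feedback kernels `v_ji` are the
#' `w_ji` rotated by 180 degrees and rescaled so that for each class the
#' maximum weight across all channels is one.  `epsilon1` is
#' `epsilon2 / max(Vtilde)` where `Vtilde[i]` is the total feedback weight
#' targeting an interior reconstruction neuron of channel `i`.
#'
#' Prediction neurons are replicated at every pixel: cross-correlation uses
#' zero padding so every map keeps the input's spatial size.  Kernels of
#' even size anchor at `floor((size - 1) / 2)`.
#'
#' @param kernels list of length `p`; each element an `kh x kw x k` array
#'   (or an `kh x kw` matrix when there is a single input channel) of
#'   non-negative weights.
#' @param epsilon2 small positive scalar; default 1e-2.
#' @param w_norm feedforward kernel normalization: `"sum"` (default; each
#'   class's receptive field sums to one) or `"max"` (each class's maximum
#'   weight is one, the same rescaling rule the feedback kernels use; used
#'   by the location-voting stage, where the paper fixes only the
#'   proportionality of the weights).
#' @return an object of class `conv_network`.
#' @export
conv_network <- function(kernels, epsilon2 = 1e-2,
                         w_norm = c("sum", "max")) {
  w_norm <- match.arg(w_norm)
  if (!is.list(kernels) || length(kernels) == 0L) {
    stop("kernels must be a non-empty list")
  }
  kernels <- lapply(kernels, as_stack)
  d <- dim(kernels[[1L]])
  if (!all(vapply(kernels, function(k) identical(dim(k), d), logical(1L)))) {
    stop("all kernels must share the same dimensions")
  }
  p <- length(kernels)
  kh <- d[1L]; kw <- d[2L]; k <- d[3L]
  kernels_w <- vector("list", p)
  kernels_v <- vector("list", p)
  for (j in seq_len(p)) {
    kj <- kernels[[j]]
    if (any(kj < 0) || any(!is.finite(kj))) {
      stop("kernel ", j, " has negative or non-finite weights")
    }
    s <- if (w_norm == "sum") sum(kj) else max(kj)
    if (s <= 0) stop("kernel ", j, " is all zero (cannot normalize)")
    wj <- kj / s
    vj <- array(0, dim = d)
    for (i in seq_len(k)) vj[, , i] <- rot180(matrix(wj[, , i], kh, kw))
    vj <- vj / max(vj)
    kernels_w[[j]] <- wj
    kernels_v[[j]] <- vj
  }
  v_tilde <- vapply(seq_len(k), function(i) {
    sum(vapply(kernels_v, function(v) sum(v[, , i]), numeric(1L)))
  }, numeric(1L))
  structure(
    list(kernels_w = kernels_w, kernels_v = kernels_v,
         w_norm = w_norm, p = p, k = k, kh = kh, kw = kw,
         anchor = c((kh - 1L) %/% 2L, (kw - 1L) %/% 2L),
         anchor_v = c(kh - 1L - (kh - 1L) %/% 2L, kw - 1L - (kw - 1L) %/% 2L),
         epsilon1 = epsilon2 / max(v_tilde), epsilon2 = epsilon2,
         v_channel_sums = v_tilde),
    class = "conv_network")
}

#' @export
print.conv_network <- function(x, ...) {
  cat(sprintf("convolutional PC/BC-DIM stage: %d classes x %d channels, %dx%d kernels\n",
              x$p, x$k, x$kh, x$kw))
  invisible(x)
}

check_conv_input <- function(net, X) {
  X <- as_stack(X)
  if (dim(X)[3L] != net$k) {
    stop("input has ", dim(X)[3L], " channels; network expects ", net$k)
  }
  if (any(X < 0) || any(!is.finite(X))) {
    stop("input maps must be non-negative and finite")
  }
  X
}

#' Initial state for a convolutional stage
#' @param net a [conv_network()].
#' @param X input maps, `h x w x k` array (or matrix for k = 1).
#' @return a `conv_state` with zero prediction maps.
#' @export
conv_state <- function(net, X) {
  X <- check_conv_input(net, X)
  h <- dim(X)[1L]; w <- dim(X)[2L]
  Y <- array(0, dim = c(h, w, net$p))
  R <- array(0, dim = dim(X))
  E <- X / pmax(net$epsilon2, R)
  structure(list(X = X, Y = Y, R = R, E = E, iteration = 0L),
            class = "conv_state")
}

#' One iteration of the convolutional PC/BC-DIM dynamics
#'
#' `R_i = sum_j v_ji * Y_j`, `E_i = X_i / max(epsilon2, R_i)`,
#' `Y_j <- max(epsilon1, Y_j) . sum_i w_ji * E_i` where `*` is
#' cross-correlation with zero padding.
#'
#' @param net a [conv_network()].
#' @param state a `conv_state`.
#' @return the updated `conv_state`.
#' @export
conv_step <- function(net, state) {
  stopifnot(inherits(net, "conv_network"), inherits(state, "conv_state"))
  if (dim(state$Y)[3L] != net$p) {
    stop("state has ", dim(state$Y)[3L], " prediction maps; network has ", net$p)
  }
  out <- conv_solve_cpp(state$X, net$kernels_w, net$kernels_v,
                        net$anchor[1L], net$anchor[2L],
                        net$anchor_v[1L], net$anchor_v[2L],
                        1L, net$epsilon1, net$epsilon2, 0, state$Y)
  structure(list(X = state$X, Y = out$Y, R = out$R, E = out$E,
                 iteration = state$iteration + 1L),
            class = "conv_state")
}

#' Iterate a convolutional stage to steady state
#'
#' Prediction maps start at zero, [conv_step()] is applied `n_iter` times,
#' and responses below `response_floor` are then zeroed (with `R` and `E`
#' recomputed from the floored maps).
#'
#' @inheritParams conv_state
#' @param n_iter number of iterations; default 50.
#' @param response_floor final response floor; default 0.001.
#' @return the final `conv_state`.
#' @export
conv_solve <- function(net, X, n_iter = 50L, response_floor = 0.001) {
  X <- check_conv_input(net, X)
  out <- conv_solve_cpp(X, net$kernels_w, net$kernels_v,
                        net$anchor[1L], net$anchor[2L],
                        net$anchor_v[1L], net$anchor_v[2L],
                        as.integer(n_iter), net$epsilon1, net$epsilon2,
                        response_floor, array(0, dim = c(0L, 0L, 0L)))
  structure(list(X = X, Y = out$Y, R = out$R, E = out$E,
                 iteration = as.integer(n_iter)),
            class = "conv_state")
}

#' Cross-correlation of an image with a kernel, keeping the image size
#'
#' Zero padding outside the image; the kernel anchors at
#' `floor((size - 1) / 2)` unless `anchor` is given.
#'
#' @param image numeric matrix.
#' @param kernel numeric matrix.
#' @param anchor integer pair (row, col), 1-based; defaults to the centre.
#' @return matrix of the same size as `image`.
#' @export
xcorr_same <- function(image, kernel, anchor = NULL) {
  if (is.null(anchor)) {
    anchor <- c((nrow(kernel) - 1L) %/% 2L, (ncol(kernel) - 1L) %/% 2L) + 1L
  }
  xcorr_same_cpp(image, kernel, anchor[1L] - 1L, anchor[2L] - 1L)
}
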