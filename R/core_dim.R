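#' Build a PC/BC-DIM processing stage from raw weights
#'
#' Normalizes a non-negative weight matrix into the feedforward weights `W`
#' (each prediction neuron's receptive field sums to one) and the feedback
#' weights `V` (the transpose of `W` with each column rescaled to a maximum
#' of one).  `epsilon1` is derived from the sums of feedback weights
#' targeting each reconstruction neuron: `epsilon1 = epsilon2 / max(Vtilde)`
#' where `Vtilde` holds the row sums of `V`.
#'
#' @param raw_weights non-negative numeric matrix, one row per prediction
#'   neuron (n x m).
#' @param epsilon2 small positive scalar preventing division by zero in the
#'   error computation; default 1e-2.
#' @return an object of class `dim_network` with elements `W`, `V`,
#'   `epsilon1`, `epsilon2` and `v_row_sums`.
#' @examples
#' net <- dim_network(rbind(c(2, 2), c(0, 4)))
#' net$W            # rows sum to one
#' net$epsilon1     # 0.01 / max(row sums of V)
#' @export
dim_network <- function(raw_weights, epsilon2 = 1e-2) {
  W <- as.matrix(raw_weights)
  if (!is.numeric(W) || any(!is.finite(W))) {
    stop("raw_weights must be a finite numeric matrix")
  }
  if (any(W < 0)) stop("raw_weights must be non-negative")
  if (!is.numeric(epsilon2) || length(epsilon2) != 1L || epsilon2 <= 0) {
    stop("epsilon2 must be a positive scalar")
  }
  rs <- rowSums(W)
  if (any(rs <= 0)) {
    stop("raw_weights has an all-zero row (cannot normalize row ",
         paste(which(rs <= 0), collapse = ", "), ")")
  }
  W <- W / rs
  V <- t(W)
  cmax <- apply(V, 2L, max)
  V <- sweep(V, 2L, cmax, "/")
  v_row_sums <- rowSums(V)
  structure(
    list(W = W, V = V,
         epsilon1 = epsilon2 / max(v_row_sums),
         epsilon2 = epsilon2,
         v_row_sums = v_row_sums),
    class = "dim_network")
}

#' @export
print.dim_network <- function(x, ...) {
  cat(sprintf("PC/BC-DIM stage: %d prediction neurons, %d input elements\n",
              nrow(x$W), ncol(x$W)))
  cat(sprintf("  epsilon1 = %.4g, epsilon2 = %.4g\n", x$epsilon1, x$epsilon2))
  invisible(x)
}

#' Create an initial DIM state for an input
#'
#' Prediction responses start at zero; `r` and `e` are made consistent with
#' that choice (`r = Vy = 0`).
#'
#' @param net a [dim_network()].
#' @param x non-negative input vector of length `m` (or an m x N matrix to
#'   process N inputs in parallel).
#' @return a `dim_state` list with `x`, `y`, `r`, `e`, `iteration`.
#' @export
dim_state <- function(net, x) {
  x <- check_dim_input(net, x)
  n <- nrow(net$W)
  y <- if (is.matrix(x)) matrix(0, n, ncol(x)) else numeric(n)
  r <- x * 0
  e <- x / pmax(net$epsilon2, r)
  structure(list(x = x, y = y, r = r, e = e, iteration = 0L),
            class = "dim_state")
}

check_dim_input <- function(net, x) {
  m <- ncol(net$W)
  if (is.matrix(x)) {
    if (nrow(x) != m) stop("input has ", nrow(x), " rows; network expects ", m)
  } else {
    x <- as.numeric(x)
    if (length(x) != m) stop("input has length ", length(x),
                             "; network expects ", m)
  }
  if (any(!is.finite(x))) stop("input contains non-finite values")
  if (any(x < 0)) stop("input must be non-negative")
  x
}

#' One iteration of the PC/BC-DIM dynamics
#'
#' Applies the update `r = V y`, `e = x / max(epsilon2, r)` (element-wise),
#' `y <- max(epsilon1, y) * (W e)` (element-wise product).
#'
#' @param net a [dim_network()].
#' @param state a `dim_state` as returned by [dim_state()] or a previous
#'   call to `dim_step`.
#' @return the updated `dim_state` with `iteration` incremented.
#' @export
dim_step <- function(net, state) {
  stopifnot(inherits(net, "dim_network"), inherits(state, "dim_state"))
  x <- state$x
  y <- state$y
  nlen <- if (is.matrix(y)) nrow(y) else length(y)
  if (nlen != nrow(net$W)) {
    stop("state has ", nlen, " prediction neurons; network has ", nrow(net$W))
  }
  r <- net$V %*% y
  if (!is.matrix(x)) r <- drop(r)
  e <- x / pmax(net$epsilon2, r)
  y <- pmax(net$epsilon1, y) * (net$W %*% e)
  if (!is.matrix(x)) y <- drop(y)
  structure(list(x = x, y = y, r = r, e = e,
                 iteration = state$iteration + 1L),
            class = "dim_state")
}

#' Iterate the PC/BC-DIM dynamics to steady state
#'
#' Starts from `y = 0`, iterates [dim_step()] `n_iter` times (50 by
#' default), then sets responses below `response_floor` (0.001 by default)
#' to zero and recomputes `r` and `e` from the floored responses so the
#' returned state is internally consistent.
#'
#' @inheritParams dim_state
#' @param n_iter number of iterations; default 50.
#' @param response_floor responses below this are zeroed after the final
#'   iteration; default 0.001.
#' @param trace_kl if `TRUE`, attach the per-iteration generalized KL
#'   divergence between `x` and `r` as attribute `"kl_trace"` (vector input
#'   only).
#' @return the final `dim_state`.
#' @export
dim_solve <- function(net, x, n_iter = 50L, response_floor = 0.001,
                      trace_kl = FALSE) {
  stopifnot(inherits(net, "dim_network"), n_iter >= 1L)
  state <- dim_state(net, x)
  kl <- if (trace_kl) numeric(n_iter) else NULL
  for (t in seq_len(n_iter)) {
    state <- dim_step(net, state)
    if (trace_kl) {
      r_now <- net$V %*% state$y
      if (!is.matrix(state$x)) r_now <- drop(r_now)
      kl[t] <- kl_divergence(state$x, r_now, net$epsilon2)
    }
  }
  y <- state$y
  y[y < response_floor] <- 0
  r <- net$V %*% y
  if (!is.matrix(state$x)) r <- drop(r)
  e <- state$x / pmax(net$epsilon2, r)
  out <- structure(list(x = state$x, y = y, r = r, e = e,
                        iteration = state$iteration),
                   class = "dim_state")
  if (trace_kl) attr(out, "kl_trace") <- kl
  out
}

#' Generalized Kullback-Leibler divergence between input and reconstruction
#'
#' Computes `sum(x * log(x / r) - x + r)` with the `0 * log(0) = 0`
#' convention.  For numerical stability `r` is floored at `epsilon2` inside
#' the logarithm only (the linear term uses the raw `r`), matching the
#' divisive-error computation of the network.  The inputs need not be
#' probability vectors.
#'
#' @param x non-negative vector (or matrix).
#' @param r non-negative reconstruction of the same shape.
#' @param epsilon2 floor applied to `r` inside the log; default 1e-2.
#' @return a non-negative scalar (summed over all elements).
#' @export
kl_divergence <- function(x, r, epsilon2 = 1e-2) {
  if (length(x) != length(r)) {
    stop("x and r have different lengths (", length(x), " vs ", length(r), ")")
  }
  if (any(x < 0) || any(r < 0)) stop("x and r must be non-negative")
  rf <- pmax(r, epsilon2)
  term <- ifelse(x > 0, x * log(x / rf), 0)
  sum(term - x + r)
}
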