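test_that("dim_network applies the stated normalizations", {
  net <- dim_network(rbind(c(2, 2), c(0, 4)), epsilon2 = 0.01)
  expect_equal(net$W, rbind(c(0.5, 0.5), c(0, 1)))
  expect_equal(net$V, rbind(c(1, 0), c(1, 1)))
  expect_equal(net$v_row_sums, c(1, 2))
  expect_equal(net$epsilon1, 0.005)

  # already row-stochastic input is unchanged
  W0 <- rbind(c(0.25, 0.75), c(0.6, 0.4))
  expect_equal(dim_network(W0)$W, W0)

  expect_error(dim_network(rbind(c(1, 1), c(0, 0))), "all-zero row")
  expect_error(dim_network(rbind(c(-1, 2))), "non-negative")
})

test_that("network invariants hold for random weight matrices", {
  set.seed(101)
  for (rep in 1:20) {
    net <- random_dim_network(sample(2:8, 1), sample(2:8, 1))
    expect_equal(rowSums(net$W), rep(1, nrow(net$W)), tolerance = 1e-9)
    expect_equal(unname(apply(net$V, 2, max)), rep(1, nrow(net$W)))
    expect_true(all(net$W >= 0) && all(net$V >= 0))
    expect_equal(net$epsilon1, net$epsilon2 / max(net$v_row_sums))
  }
})

test_that("dim_step follows the update equations and preserves closure", {
  # all-zero input and responses stay zero
  net <- dim_network(rbind(c(1, 1), c(1, 3)))
  st <- dim_step(net, dim_state(net, c(0, 0)))
  expect_equal(st$y, c(0, 0))
  expect_equal(st$iteration, 1L)

  # single-neuron fixed point: W = [0.5, 0.5], x = [a, a] with a > eps2
  a <- 0.7
  net1 <- dim_network(matrix(c(1, 1), 1, 2))
  st <- structure(list(x = c(a, a), y = a, r = c(a, a), e = c(1, 1),
                       iteration = 0L), class = "dim_state")
  st2 <- dim_step(net1, st)
  expect_equal(st2$y, a, tolerance = 1e-12)
  expect_equal(st2$r, c(a, a))
  expect_equal(st2$e, c(1, 1))

  # non-negativity and finiteness closure on random networks
  set.seed(102)
  for (rep in 1:20) {
    net <- random_dim_network(sample(2:6, 1), sample(2:6, 1))
    st <- dim_state(net, random_x(ncol(net$W)))
    for (t in 1:10) {
      st <- dim_step(net, st)
      expect_true(all(is.finite(st$y)) && all(st$y >= 0))
      expect_true(all(is.finite(st$r)) && all(st$r >= 0))
      expect_true(all(is.finite(st$e)) && all(st$e >= 0))
    }
  }

  expect_error(dim_step(net, dim_state(dim_network(matrix(1, 1, 3)), c(1, 1, 1))),
               "prediction neurons")
})

test_that("dim_solve floors responses and returns a consistent state", {
  net <- random_dim_network(4, 5)
  set.seed(103)
  x <- random_x(5)
  st <- dim_solve(net, x)
  expect_true(all(st$y == 0 | st$y >= 0.001))
  expect_equal(st$r, drop(net$V %*% st$y))  # recomputed from floored y
  expect_equal(st$e, x / pmax(net$epsilon2, st$r))

  # zero input gives zero responses and reconstruction
  st0 <- dim_solve(net, rep(0, 5))
  expect_equal(st0$y, rep(0, 4))
  expect_equal(st0$r, rep(0, 5))
})

test_that("an input equal to one dictionary element activates that element", {
  # near-orthogonal dictionary rows
  raw <- rbind(c(1, 0.05, 0, 0), c(0, 1, 0.05, 0), c(0, 0.05, 0, 1))
  net <- dim_network(raw)
  c0 <- 0.8
  x <- c0 * raw[2, ] / sum(raw[2, ])  # element 2 at strength c0 (row of W)
  x <- x / max(x)                      # inputs fill [0,1]
  st <- dim_solve(net, x)
  expect_equal(which.max(st$y), 2L)
  expect_true(all(st$y[-2] < 0.05 * st$y[2]))
})

test_that("batched dim_solve matches per-vector solves", {
  set.seed(104)
  net <- random_dim_network(5, 7)
  X <- replicate(4, random_x(7))
  stB <- dim_solve(net, X)
  for (i in 1:4) {
    st1 <- dim_solve(net, X[, i])
    expect_equal(stB$y[, i], st1$y, tolerance = 1e-12)
  }
})

test_that("kl_divergence matches closed forms and rejects bad input", {
  expect_equal(kl_divergence(c(0.5, 0.2), c(0.5, 0.2)), 0)
  expect_equal(kl_divergence(c(1, 0), c(1, 1)), 1)
  expect_error(kl_divergence(c(1, 0), c(1, 1, 1)), "length")
  expect_error(kl_divergence(c(-1, 0), c(1, 1)), "non-negative")
})

test_that("KL divergence is non-increasing along the iteration", {
  set.seed(105)
  for (rep in 1:20) {
    net <- random_dim_network(sample(5:16, 1), sample(8:32, 1))
    st <- dim_solve(net, random_x(ncol(net$W)), trace_kl = TRUE)
    kl <- attr(st, "kl_trace")
    expect_true(all(diff(kl) <= 1e-6))
  }
})

test_that("steady state matches the brute-force KL minimizer on tiny nets", {
  set.seed(106)
  for (rep in 1:5) {
    n <- sample(2:4, 1)
    m <- n + sample.int(4L - n + 1L, 1L) - 1L  # n <= m <= 4
    net <- random_dim_network(n, m)
    x <- random_x(m)
    y_net <- dim_solve(net, x, n_iter = 500, response_floor = 0)$y
    y_opt <- oracle_kl_minimizer(net, x)
    expect_lt(max(abs(y_net - y_opt)), 1e-2)
  }
})

test_that("perfect matches calibrate to W e = 1 at the active units", {
  raw <- rbind(c(1, 0, 0.05), c(0, 1, 0.05))
  net <- dim_network(raw)
  x <- drop(0.9 * net$V %*% c(1, 0))  # element 1's reconstruction pattern
  st <- dim_solve(net, x, n_iter = 200)
  we <- drop(net$W %*% st$e)
  expect_equal(we[1], 1, tolerance = 1e-2)
})

test_that("halving the epsilons changes the steady state by under 1%", {
  set.seed(107)
  for (rep in 1:10) {
    n <- sample(5:12, 1); m <- sample(8:24, 1)
    raw <- matrix(runif(n * m), n, m) + 1e-3
    x <- random_x(m)
    y1 <- dim_solve(dim_network(raw, epsilon2 = 1e-2), x, response_floor = 0)$y
    net_half <- dim_network(raw, epsilon2 = 5e-3)  # halves eps2, hence eps1
    y2 <- dim_solve(net_half, x, response_floor = 0)$y
    expect_lt(max(abs(y1 - y2)) / max(y1), 0.01)
  }
})
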