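test_that("beta = 1 returns the prior as the posterior", {
  set.seed(3)
  net <- random_net(15)
  q <- transition_matrix(net)
  pr <- kngp_prior(net, c("n1", "n5"), f = 3)
  po <- propagate(q, pr, beta = 1)
  expect_equal(as.numeric(po), as.numeric(pr), tolerance = 1e-15)
  expect_true(attr(po, "converged"))
})

test_that("two-node symmetric walk has the closed-form fixed point", {
  q <- matrix(c(0, 1, 1, 0), 2, dimnames = rep(list(c("a", "b")), 2))
  po <- propagate(q, c(a = 1, b = 0), beta = 0.5, delta = 1e-12)
  expect_equal(as.numeric(po), c(2 / 3, 1 / 3), tolerance = 1e-10)
})

test_that("iterative propagation matches the dense linear solve", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(5:50, 1)
    net <- random_net(n, zero_frac = runif(1, 0, 0.5))
    q <- transition_matrix(net)
    roots <- sample(net$node_ids, sample(1:3, 1))
    pr <- kngp_prior(net, roots, f = runif(1, 0, 100))
    beta <- runif(1, 0.1, 0.95)  # error bound (1-beta)/beta*delta <= 10*delta
    delta <- 1e-10
    po <- propagate(q, pr, beta, delta = delta)
    expect_lt(max(abs(po - solve_posterior(q, pr, beta))), 10 * delta)
  }
})

test_that("matrix propagation equals column-by-column propagation", {
  set.seed(4)
  net <- random_net(20)
  q <- transition_matrix(net)
  prm <- cbind(kngp_prior(net, "n1", 2), kngp_prior(net, c("n2", "n3"), 5))
  pom <- propagate(q, prm, beta = 0.3)
  for (j in 1:2)
    expect_equal(unname(pom[, j]),
                 unname(as.numeric(propagate(q, prm[, j], beta = 0.3))),
                 tolerance = 1e-12)
})

test_that("successive iterate differences contract for beta > 0", {
  set.seed(5)
  net <- random_net(25)
  q <- transition_matrix(net)
  pr <- kngp_prior(net, c("n1", "n2"), 10)
  po <- matrix(0, nrow(q), 1)
  diffs <- numeric(40)
  for (i in 1:40) {
    po_next <- 0.2 * pr + 0.8 * (q %*% po)
    diffs[i] <- max(abs(po_next - po))
    po <- po_next
  }
  expect_true(all(diff(diffs[-1]) <= 1e-15))
})

test_that("small-beta posterior aligns with the walk's stationary distribution", {
  set.seed(6)
  net <- random_net(12)
  q <- transition_matrix(net)
  stat <- Re(eigen(q)$vectors[, 1])
  stat <- stat / sum(stat)
  # total mass builds at rate 1 - beta, so runtime scales with 1/beta;
  # beta = 1e-4 keeps the prior's imprint below the comparison tolerance
  for (roots in list("n1", c("n3", "n7", "n9"))) {
    po <- propagate(q, kngp_prior(net, roots, 4), beta = 1e-4,
                    delta = 1e-12, max_iter = 5e5)
    expect_equal(unname(as.numeric(po) / sum(po)), stat, tolerance = 1e-3)
  }
})

test_that("posterior sums to 1 on dangling-free networks, less with leaks", {
  set.seed(7)
  net <- random_net(18)
  q <- transition_matrix(net)
  po <- propagate(q, prp_prior(net, c("n1", "n2")), beta = 0.4,
                  delta = 1e-12)
  expect_lt(abs(sum(po) - 1), 1e-6)

  lw <- net$link_weights
  lw["n18", ] <- 0; lw[, "n18"] <- 0  # isolate a node: mass leaks there
  net2 <- knowledge_network(lw, node_weights = net$node_weights)
  po2 <- propagate(transition_matrix(net2), prp_prior(net2, "n18"),
                   beta = 0.4, delta = 1e-12)
  expect_lt(sum(po2), 1)
})

test_that("propagation rejects bad inputs and flags non-convergence", {
  q <- matrix(c(0, 1, 1, 0), 2, dimnames = rep(list(c("a", "b")), 2))
  pr <- c(a = 1, b = 0)
  expect_error(propagate(q, pr, beta = -0.1), "beta")
  expect_error(propagate(q, pr, beta = 1.1), "beta")
  expect_error(propagate(q, c(pr, c = 0), beta = 0.5), "dimensions")
  expect_warning(po <- propagate(q, pr, beta = 0.01, delta = 1e-14,
                                 max_iter = 3),
                 "did not converge")
  expect_false(attr(po, "converged"))
})

test_that("candidates are ranked by posterior with average-rank ties", {
  po <- c(a = 0.5, b = 0.3, c = 0.2)
  rk <- rank_candidates(po, c("b", "c"))
  expect_equal(rk$node, c("b", "c"))
  expect_equal(rk$rank, c(1, 2))

  tied <- c(a = 0.5, b = 0.2, c = 0.2)
  rk <- rank_candidates(tied, c("a", "b", "c"))
  expect_equal(rk$rank, c(1, 2.5, 2.5))
  expect_equal(rk$node, c("a", "b", "c"))  # ties ordered by id

  expect_error(rank_candidates(po, c("b", "zz")), "zz")

  set.seed(8)
  vals <- round(runif(100), 2)  # rounding forces some ties
  names(vals) <- paste0("g", 1:100)
  rk <- rank_candidates(vals, names(vals))
  expect_equal(sum(rk$rank), 100 * 101 / 2)
  expect_true(all(diff(rk$posterior) <= 0))
})
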