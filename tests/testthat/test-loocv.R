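test_that("a network where left-out roots always win gives AUC 1", {
  # two tightly linked roots with huge node weights; weakly linked rest
  n <- 12
  lw <- matrix(0.01, n, n); diag(lw) <- 0
  lw[1, 2] <- lw[2, 1] <- 5
  w <- c(50, 50, rep(0.01, n - 2))
  net <- knowledge_network(lw, node_weights = w,
                           node_ids = paste0("n", 1:n))
  res <- loocv_auc(net, c("n1", "n2"), f = 5, beta = 0.5,
                   k = 3, list_size = 8, seed = 2)
  expect_true(all(res$ranks == 1))
  expect_equal(res$auc, 1)
})

test_that("toy LOOCV ranks match a hand-rolled enumeration oracle", {
  set.seed(21)
  net <- random_net(6)
  roots <- c("n1", "n2")
  f <- 3; beta <- 0.4; L <- 4; seed <- 99
  res <- loocv_auc(net, roots, f = f, beta = beta, k = 2,
                   list_size = L, seed = seed)

  q <- transition_matrix(net)
  nonroot <- setdiff(net$node_ids, roots)
  for (ri in seq_along(roots)) {
    # prior by hand: f scales kept-in roots, normalize; solve directly
    mass <- net$node_weights
    kept <- setdiff(roots, roots[ri])
    mass[kept] <- f * mass[kept]
    po <- solve_posterior(q, mass / sum(mass), beta)
    for (s in 1:2) {
      set.seed(kngp:::subseed(seed, roots[ri], s))
      fill <- sample(nonroot, L - 1)
      vals <- po[c(roots[ri], fill)]
      expect_equal(unname(res$ranks[ri, s]),
                   unname(rank(-vals, ties.method = "average")[1]))
    }
  }
})

test_that("LOOCV is bit-reproducible and f sweeps share candidate lists", {
  syn <- synthetic_network(3, seed = 5, n_nodes = 60, n_roots = 10)
  a <- loocv_auc(syn$network, syn$roots, f = 15, k = 3, list_size = 20,
                 seed = 42)
  b <- loocv_auc(syn$network, syn$roots, f = 15, k = 3, list_size = 20,
                 seed = 42)
  expect_identical(a$ranks, b$ranks)
  expect_identical(a$auc, b$auc)
  c2 <- loocv_auc(syn$network, syn$roots, f = 15, k = 3, list_size = 20,
                  seed = 43)
  expect_false(identical(a$ranks, c2$ranks))
})

test_that("left-out fillers exclude every root, including co-roots", {
  # every root has a huge tied node weight: if a co-root ever entered a
  # list it would tie the left-out node and drag its rank to >= 1.5
  n <- 30; n_roots <- 6
  lw <- matrix(1, n, n); diag(lw) <- 0
  set.seed(23)
  w <- c(rep(100, n_roots), runif(n - n_roots))
  net <- knowledge_network(lw, node_weights = w,
                           node_ids = paste0("n", 1:n))
  roots <- paste0("n", 1:n_roots)
  res <- loocv_auc(net, roots, f = 1, beta = 0.9, k = 4, list_size = 20,
                   seed = 5)
  expect_true(all(res$ranks == 1))
  # a list needing more fillers than there are candidates is impossible
  expect_error(loocv_auc(net, roots, f = 1, list_size = 26),
               "not enough non-root")
})

test_that("f search returns the argmax with ties to the smallest f", {
  syn <- synthetic_network(2, seed = 7, n_nodes = 60, n_roots = 10)
  single <- find_best_f(syn$network, syn$roots, f_grid = 42, k = 2,
                        list_size = 20, seed = 1)
  expect_equal(single$best_f, 42)
  expect_equal(nrow(single$table), 1)

  ev <- find_best_f(syn$network, syn$roots, f_grid = c(0, 1, 1e6),
                    k = 2, list_size = 20, seed = 1)
  expect_equal(ev$best_f, ev$table$f[which.max(ev$table$auc)])
  # node-weight-biased design: small f must beat the uniform-roots limit
  expect_gt(ev$table$auc[ev$table$f == 0],
            ev$table$auc[ev$table$f == 1e6])
  expect_error(find_best_f(syn$network, syn$roots, f_grid = numeric(0)),
               "non-empty")
  expect_error(find_best_f(syn$network, syn$roots, f_grid = c(1, -2)),
               ">= 0")
})

test_that("uniform node weights make the knowledge model match the baseline", {
  set.seed(22)
  lw <- random_net(30)$link_weights
  net <- knowledge_network(lw)  # unit node weights
  roots <- paste0("n", 1:6)
  fit_k <- kngp(net, roots, f = 1e12, beta = 0.3)
  fit_p <- kngp(net, roots, prior = "prp", beta = 0.3)
  rk <- predict(fit_k)
  rp <- predict(fit_p)
  expect_equal(rk$node, rp$node)
  expect_equal(rk$rank, rp$rank)
  expect_equal(rk$posterior, rp$posterior, tolerance = 1e-9)

  res_k <- loocv_auc(net, roots, f = 1e12, k = 2, list_size = 15, seed = 9)
  res_p <- loocv_auc(net, roots, prior = "prp", k = 2, list_size = 15,
                     seed = 9)
  expect_equal(res_k$ranks, res_p$ranks)
})

test_that("beta calibration scores each beta by mean AUC over the grid", {
  syn <- synthetic_network(2, seed = 8, n_nodes = 60, n_roots = 10)
  cal <- calibrate_beta(syn$network, syn$roots, betas = c(0.3, 0.7),
                        f_grid = c(0, 100), k = 2, list_size = 20,
                        seed = 4)
  expect_equal(nrow(cal$summary), 2)
  expect_equal(cal$best_beta,
               cal$summary$beta[which.max(cal$summary$mean_auc)])
  for (i in 1:2)
    expect_equal(cal$summary$mean_auc[i],
                 mean(cal$evals[[i]]$table$auc))
})
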