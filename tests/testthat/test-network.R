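test_that("absolute Spearman similarity has rank-invariance and sign-folding", {
  set.seed(1)
  base <- matrix(rnorm(4 * 8), 4, 8, dimnames = list(paste0("P", 1:4), NULL))
  M <- rbind(base,
             P5 = exp(base[1, ]),          # monotone transform of P1
             P6 = -base[2, ])              # order reversal of P2
  D <- spearman_abs_matrix(M)
  expect_equal(D["P1", "P5"], 1)
  expect_equal(D["P2", "P6"], 1)
  expect_true(isSymmetric(D))
  expect_true(all(D >= 0 & D <= 1 + 1e-12))
})

test_that("similarity matches a hand-computed rank correlation", {
  # ranks (1,2,3,4) vs (2,1,4,3): Pearson on ranks = 0.6
  M <- rbind(a = c(10, 20, 30, 40), b = c(15, 5, 40, 30), c = c(1, 3, 2, 4))
  D <- spearman_abs_matrix(M)
  expect_equal(D["a", "b"], 0.6, tolerance = 1e-12)
  expect_error(spearman_abs_matrix(rbind(M, d = c(7, 7, 7, 7))), "constant")
})

test_that("betweenness and entropy agree with hand-enumerated graphs", {
  path3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  expect_equal(graph_betweenness(path3), c(0, 1, 0))
  expect_equal(graph_betweenness(matrix(1, 4, 4) - diag(4)), rep(0, 4))
  c4 <- rbind(c(0, 1, 0, 1), c(1, 0, 1, 0), c(0, 1, 0, 1), c(1, 0, 1, 0))
  expect_equal(graph_betweenness(c4), rep(0.5, 4))
  # path of 4: b = (0,2,2,0), p = (0,.5,.5,0), H = 1 bit
  p4 <- rbind(c(0, 1, 0, 0), c(1, 0, 1, 0), c(0, 1, 0, 1), c(0, 0, 1, 0))
  expect_equal(entropy_of_betweenness(p4), 1)
  star <- matrix(0, 5, 5); star[1, -1] <- 1; star[-1, 1] <- 1
  expect_equal(entropy_of_betweenness(star), 0)    # point mass on the hub
  expect_equal(entropy_of_betweenness(diag(0, 3)), 0)  # no paths at all
})

test_that("centralities match the brute-force oracle on random small graphs", {
  set.seed(7)
  for (rep in 1:30) {
    n <- sample(3:7, 1)
    C <- random_adjacency(n, runif(1, 0.2, 0.8))
    net <- structure(list(adjacency = C, n_nodes = n), class = "province_network")
    cf <- centrality_features(net)
    expect_equal(cf$degree, rowSums(C))
    expect_equal(cf$betweenness, bf_betweenness(C), tolerance = 1e-12)
    expect_equal(cf$closeness, bf_closeness(C), tolerance = 1e-12)
    # eigenvector: residual against the dense-solver principal eigenvalue
    ev <- eigen(C, symmetric = TRUE)
    lambda <- max(ev$values)
    if (sum(C) > 0) {
      expect_lt(max(abs(C %*% cf$eigenvector - lambda * cf$eigenvector)), 1e-6)
      expect_equal(sum(cf$eigenvector^2), 1, tolerance = 1e-8)
    }
  }
})

test_that("star and clique centralities take their closed-form values", {
  K5 <- matrix(1, 5, 5) - diag(5)
  cf <- centrality_features(structure(list(adjacency = K5, n_nodes = 5),
                                      class = "province_network"))
  expect_equal(cf$degree, rep(4, 5))
  expect_equal(cf$closeness, rep(1, 5))
  expect_equal(cf$eigenvector, rep(1 / sqrt(5), 5), tolerance = 1e-8)
  star <- matrix(0, 5, 5); star[1, -1] <- 1; star[-1, 1] <- 1
  cs <- centrality_features(structure(list(adjacency = star, n_nodes = 5),
                                      class = "province_network"))
  expect_equal(cs$closeness, c(1, rep(4 / 7, 4)))
  expect_equal(cs$eigenvector[1] / cs$eigenvector[2], 2, tolerance = 1e-8)
})

test_that("threshold scan maximizes entropy with ties toward density", {
  D <- matrix(0.5, 4, 4); diag(D) <- 1
  net <- threshold_scan(D)
  expect_equal(net$threshold, min(net$entropy_curve$threshold))
  expect_true(all(net$entropy_curve$entropy == 0))
  # two dense blocks joined by one bridge: chosen threshold keeps the bridge
  D2 <- diag(10)
  block <- function(idx, v) for (i in idx) for (j in idx) if (i != j) D2[i, j] <<- v
  block(1:5, 0.9); block(6:10, 0.9)
  D2[5, 6] <- D2[6, 5] <- 0.6
  net2 <- threshold_scan(D2)
  expect_lte(net2$threshold, 0.6)
  expect_equal(net2$adjacency[5, 6], 1)
  H_best <- max(vapply(sort(unique(D2[upper.tri(D2)])),
                       function(th) bf_entropy(adjacency_at(D2, th)), numeric(1)))
  expect_equal(max(net2$entropy_curve$entropy), H_best, tolerance = 1e-12)
})

test_that("raising the threshold never adds edges and relabeling permutes results", {
  set.seed(9)
  M <- matrix(rnorm(8 * 10), 8, 10, dimnames = list(paste0("P", 1:8), NULL))
  D <- spearman_abs_matrix(M)
  ths <- sort(unique(D[upper.tri(D)]))
  for (i in seq_along(ths)[-1]) {
    C_lo <- adjacency_at(D, ths[i - 1]); C_hi <- adjacency_at(D, ths[i])
    expect_true(all(C_hi <= C_lo))
  }
  perm <- sample(8)
  net_a <- threshold_scan(D)
  net_b <- threshold_scan(D[perm, perm])
  expect_equal(net_b$threshold, net_a$threshold)
  expect_equal(net_b$adjacency, net_a$adjacency[perm, perm])
})

test_that("panel augmentation appends exactly four aligned network columns", {
  set.seed(4)
  cfg <- synthetic_config(n_provinces = 12, years = 2015, seed = 4)
  panel <- generate_panel(cfg)
  X <- panel$values[, , 1]
  net <- threshold_scan(spearman_abs_matrix(X))
  feats <- centrality_features(net)
  Xa <- augment_panel(X, feats)
  expect_equal(dim(Xa), c(12, 35))
  expect_identical(Xa[, 1:31], X)
  expect_identical(colnames(Xa)[32:35],
                   c("net_degree", "net_betweenness", "net_closeness", "net_eigenvector"))
  # empty network: zero-valued degree/betweenness/closeness columns
  empty <- structure(list(adjacency = diag(0, 12), n_nodes = 12,
                          D = NULL), class = "province_network")
  f0 <- centrality_features(empty)
  expect_true(all(f0$degree == 0 & f0$betweenness == 0 & f0$closeness == 0))
  feats_bad <- feats; feats_bad$province_id <- rev(feats_bad$province_id)
  expect_error(augment_panel(X, feats_bad), "disagree")
})
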