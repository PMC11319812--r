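# Brute-force graph oracles: all-pairs BFS with geodesic counting and a
# dense eigensolver. Independent of the igraph-backed implementation.

bf_geodesics <- function(C) {
  n <- nrow(C)
  dist <- matrix(Inf, n, n)
  cnt <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0
    cnt[s, s] <- 1
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(C[v, ] == 1)) {
          if (is.infinite(dist[s, w])) {
            dist[s, w] <- d
            nxt <- c(nxt, w)
          }
          if (dist[s, w] == d) cnt[s, w] <- cnt[s, w] + cnt[s, v]
        }
      }
      frontier <- unique(nxt)
    }
  }
  list(dist = dist, cnt = cnt)
}

bf_betweenness <- function(C) {
  g <- bf_geodesics(C)
  n <- nrow(C)
  b <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      for (k in seq_len(n)) {
        if (j >= k || j == i || k == i) next
        if (!is.finite(g$dist[j, k])) next
        if (g$dist[j, i] + g$dist[i, k] == g$dist[j, k])
          b[i] <- b[i] + g$cnt[j, i] * g$cnt[i, k] / g$cnt[j, k]
      }
    }
  }
  b
}

bf_closeness <- function(C) {
  g <- bf_geodesics(C)
  n <- nrow(C)
  vapply(seq_len(n), function(i) {
    reach <- is.finite(g$dist[i, ]) & seq_len(n) != i
    n_c <- sum(reach) + 1
    if (n_c == 1) return(0)
    ((n_c - 1) / (n - 1)) * ((n_c - 1) / sum(g$dist[i, reach]))
  }, numeric(1))
}

bf_entropy <- function(C) {
  b <- bf_betweenness(C)
  s <- sum(b)
  if (s == 0) return(0)
  p <- b[b > 0] / s
  -sum(p * log2(p))
}

random_adjacency <- function(n, p = 0.4) {
  C <- matrix(0, n, n)
  C[upper.tri(C)] <- as.numeric(runif(n * (n - 1) / 2) < p)
  C + t(C)
}

# Small hand-checkable mortality fixture: 3 provinces x 3 age classes.
# Reference rates 0.001 / 0.01 / 0.1; expected deaths by hand:
#   PA: 1 + 5 + 20  = 26     PB: 2 + 10 + 10 = 22     PC: 0.5 + 5 + 50 = 55.5
toy_mortality <- function(observed = c(26, 11, 111)) {
  pop <- rbind(PA = c(1000, 500, 200),
               PB = c(2000, 1000, 100),
               PC = c(500, 500, 500))
  storage.mode(pop) <- "integer"
  colnames(pop) <- 1:3
  structure(list(
    observed = data.frame(province_id = rownames(pop), year = 2015,
                          observed_deaths = observed),
    population = pop,
    reference = data.frame(age_class = 1:3,
                           ref_deaths = c(10L, 50L, 200L),
                           ref_population = c(10000L, 5000L, 2000L)),
    linpred = NULL), class = "age_mortality")
}

small_panel <- function(n_prov = 20, n_ind = 8, years = 2015:2016, seed = 1) {
  cfg <- synthetic_config(n_provinces = n_prov, n_indicators = n_ind,
                          years = years, effect_spec = list(),
                          negative_effect_spec = list(), seed = seed)
  generate_panel(cfg)
}

fast_rf <- function(n_trees = 100, seed = NULL)
  rf_config(n_trees = n_trees, min_node_size = 5, seed = seed)
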