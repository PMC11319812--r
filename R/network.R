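#' Absolute Spearman similarity between provinces
#'
#' `d_ij` is the absolute Spearman rank correlation between the indicator
#' vectors of provinces `i` and `j` (average ranks on ties), so both
#' strongly correlated and strongly anti-correlated provinces are
#' maximally similar. The diagonal is set to 1 and ignored downstream.
#'
#' @param panel_year province x indicator matrix (imputed, at least 3
#'   indicators).
#' @param zscore standardize indicator columns first; off by default, the
#'   similarity is computed on raw values whose within-province ranks mix
#'   the indicators' native units.
#' @return symmetric similarity matrix `D` with entries in `[0, 1]`.
#' @export
spearman_abs_matrix <- function(panel_year, zscore = FALSE) {
  if (!is.matrix(panel_year) || ncol(panel_year) < 3)
    stop("need a matrix with at least 3 indicators")
  if (anyNA(panel_year)) stop("missing values; impute first")
  if (zscore) panel_year <- scale(panel_year)
  const <- apply(panel_year, 1, function(r) diff(range(r)) == 0)
  if (any(const))
    stop("constant indicator vector for province(s): ",
         paste(rownames(panel_year)[const], collapse = ", "))
  D <- abs(cor(t(panel_year), method = "spearman"))
  diag(D) <- 1
  dimnames(D) <- list(rownames(panel_year), rownames(panel_year))
  D
}

.graph_from_adjacency <- function(C) {
  igraph::graph_from_adjacency_matrix(C, mode = "undirected", diag = FALSE)
}

#' Hard-threshold a similarity matrix into an adjacency matrix
#'
#' `C_ij = 1` iff `d_ij >= th` and `i != j`.
#' @param D similarity matrix.
#' @param th threshold in `[0, 1]`.
#' @return binary symmetric adjacency with zero diagonal.
#' @export
adjacency_at <- function(D, th) {
  C <- (D >= th) * 1
  diag(C) <- 0
  C
}

#' Freeman betweenness centrality
#'
#' For each node, the sum over distinct node pairs of the fraction of
#' shortest paths (geodesics) passing through it; pairs in different
#' components contribute nothing.
#'
#' @param C binary symmetric adjacency matrix.
#' @return betweenness vector.
#' @export
graph_betweenness <- function(C) {
  if (nrow(C) == 0) return(numeric(0))
  igraph::betweenness(.graph_from_adjacency(C), directed = FALSE)
}

#' Shannon entropy of the betweenness distribution
#'
#' Betweenness values are normalized to a probability distribution
#' `p_i = b_i / sum(b)` and `H = -sum(p_i log2 p_i)` with `0 log 0 = 0`;
#' a graph with no intermediate nodes (`sum(b) = 0`) has entropy 0.
#'
#' @param C binary symmetric adjacency matrix.
#' @return entropy in bits.
#' @export
entropy_of_betweenness <- function(C) {
  b <- graph_betweenness(C)
  s <- sum(b)
  if (s == 0) return(0)
  p <- b / s
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Select the adjacency threshold by maximizing betweenness entropy
#'
#' Evaluates the Shannon entropy of the betweenness distribution at every
#' candidate threshold (by default all distinct off-diagonal similarity
#' values, which enumerates every attainable adjacency matrix) and keeps
#' the network whose betweenness distribution has maximal entropy. Ties
#' are broken toward the smallest threshold, i.e. the densest network.
#'
#' @param D similarity matrix from [spearman_abs_matrix()].
#' @param thresholds optional candidate grid; `NULL` uses all distinct
#'   off-diagonal values of `D`.
#' @return object of class `province_network` with the similarity matrix,
#'   chosen threshold, adjacency and the full entropy curve.
#' @export
threshold_scan <- function(D, thresholds = NULL) {
  if (!is.matrix(D) || nrow(D) < 2) stop("similarity matrix needs at least 2 nodes")
  if (is.null(thresholds))
    thresholds <- sort(unique(D[upper.tri(D)]))
  H <- vapply(thresholds, function(th) entropy_of_betweenness(adjacency_at(D, th)),
              numeric(1))
  best <- which(H >= max(H) - 1e-12)[1]
  structure(list(D = D, threshold = thresholds[best],
                 adjacency = adjacency_at(D, thresholds[best]),
                 entropy_curve = data.frame(threshold = thresholds, entropy = H),
                 n_nodes = nrow(D)),
            class = "province_network")
}

#' @export
print.province_network <- function(x, ...) {
  cat(sprintf("province_network: %d nodes, %d edges at threshold %.4f (entropy %.3f bits)\n",
              x$n_nodes, sum(x$adjacency) / 2, x$threshold,
              max(x$entropy_curve$entropy)))
  invisible(x)
}

# Power iteration for the principal eigenvector of a nonnegative symmetric
# adjacency matrix: uniform nonnegative start, unit Euclidean norm. Iterates
# on C + I so bipartite graphs (paired +/- extreme eigenvalues) cannot make
# the iteration oscillate; the shift leaves eigenvectors unchanged.
.eigenvector_centrality <- function(C, tol = 1e-10, max_iter = 100000) {
  n <- nrow(C)
  if (n == 0 || sum(C) == 0) return(rep(0, n))
  x <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    x_new <- as.numeric(C %*% x) + x
    nrm <- sqrt(sum(x_new^2))
    if (nrm == 0) return(rep(0, n))
    x_new <- x_new / nrm
    if (max(abs(x_new - x)) < tol) return(abs(x_new))
    x <- x_new
  }
  abs(x)
}

#' Centrality features of a thresholded network
#'
#' Degree `k_i = sum_j C_ij`, Freeman betweenness, closeness
#' `cl_i = (N-1) / sum_j s_ij` (computed within a node's component and
#' scaled by `(n_c - 1)/(N - 1)` on disconnected graphs, the
#' Wasserman-Faust convention; isolated nodes get 0) and eigenvector
#' centrality (principal eigenvector, nonnegative, unit Euclidean norm).
#'
#' @param net a `province_network` from [threshold_scan()].
#' @return data.frame with `province_id`, `degree`, `betweenness`,
#'   `closeness`, `eigenvector`.
#' @export
centrality_features <- function(net) {
  stopifnot(inherits(net, "province_network"))
  C <- net$adjacency
  N <- nrow(C)
  g <- .graph_from_adjacency(C)
  d <- igraph::distances(g)
  closeness <- vapply(seq_len(N), function(i) {
    reach <- is.finite(d[i, ]) & seq_len(N) != i
    n_c <- sum(reach) + 1
    if (n_c == 1) return(0)
    ((n_c - 1) / (N - 1)) * ((n_c - 1) / sum(d[i, reach]))
  }, numeric(1))
  data.frame(province_id = rownames(C) %||% as.character(seq_len(N)),
             degree = unname(rowSums(C)),
             betweenness = unname(graph_betweenness(C)),
             closeness = closeness,
             eigenvector = .eigenvector_centrality(C),
             row.names = NULL)
}

#' Append network centrality features to an indicator matrix
#'
#' Adds four columns (`net_degree`, `net_betweenness`, `net_closeness`,
#' `net_eigenvector`) to the per-year province x indicator matrix, leaving
#' the original columns unchanged.
#'
#' @param panel_year province x indicator matrix with province row names.
#' @param feats output of [centrality_features()].
#' @return augmented matrix.
#' @export
augment_panel <- function(panel_year, feats) {
  if (!identical(as.character(rownames(panel_year)), as.character(feats$province_id)))
    stop("province ids of the panel and the centrality features disagree")
  cbind(panel_year,
        net_degree = feats$degree, net_betweenness = feats$betweenness,
        net_closeness = feats$closeness, net_eigenvector = feats$eigenvector)
}

#' Export a province network as an edge list and entropy curve
#' @param net a `province_network`.
#' @param edge_path tab-separated edge list (source, target).
#' @param curve_path CSV of the threshold-entropy curve.
#' @export
write_network <- function(net, edge_path, curve_path = NULL) {
  idx <- which(upper.tri(net$adjacency) & net$adjacency == 1, arr.ind = TRUE)
  ids <- rownames(net$adjacency) %||% as.character(seq_len(net$n_nodes))
  edges <- data.frame(source = ids[idx[, 1]], target = ids[idx[, 2]])
  utils::write.table(edges, edge_path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(curve_path)) write.csv(net$entropy_curve, curve_path, row.names = FALSE)
  invisible(edge_path)
}
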