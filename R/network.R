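#' Node strength
#'
#' Sum of the weights incident to each node: row sums for a symmetric
#' matrix; out-, in-, or total (out + in) sums for a directed one.
#'
#' @param m a `dyad_matrix`
#' @param mode `"total"` (default), `"out"` or `"in"` (directed only)
#' @return named numeric vector
#' @export
node_strength <- function(m, mode = c("total", "out", "in")) {
  mode <- match.arg(mode)
  v <- dyad_values(m)
  if (!is_directed(m)) return(rowSums(v))
  switch(mode, total = rowSums(v) + colSums(v),
         out = rowSums(v), `in` = colSums(v))
}

#' Weighted degree with tie-number tuning
#'
#' Opsahl-style generalised degree `k^(1 - alpha) * S^alpha`, where `k`
#' is the number of nonzero ties of the node (outgoing ties for a
#' directed matrix) and `S` its strength (total strength for directed).
#' `alpha = 0` returns the binary degree, `alpha = 1` the strength;
#' intermediate values weigh how concentrated the node's total weight
#' is across its ties. The default `alpha = 0.5` is the geometric mean
#' of tie count and strength.
#'
#' @param m a `dyad_matrix`
#' @param alpha tuning parameter in `[0, 1]`
#' @return named numeric vector
#' @export
#' @examples
#' ai <- load_fixture("ai")
#' weighted_degree(ai)["Lovelas"]  # sqrt(1 * 0.665) = 0.815
weighted_degree <- function(m, alpha = 0.5) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  v <- dyad_values(m)
  k <- rowSums(v > 0)  # outgoing ties when directed
  S <- node_strength(m, mode = "total")
  ifelse(k == 0, 0, k^(1 - alpha) * S^alpha)
}

#' @keywords internal
as_igraph <- function(m) {
  v <- dyad_values(m)
  if (is_directed(m)) v <- v + t(v)  # symmetrize by summing directions
  igraph::graph_from_adjacency_matrix(v, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Weighted Newman--Girvan modularity of a partition
#'
#' `Q = (1/2W) * sum_ij [w_ij - s_i s_j / 2W] * delta(c_i, c_j)` on the
#' symmetrized matrix, with `W` the total edge weight and `s` the node
#' strengths.
#'
#' @param m a `dyad_matrix` (directed input is symmetrized by summing)
#' @param partition a `social_partition`, or a vector of cluster labels
#'   named by (or ordered as) the matrix ids
#' @return modularity Q
#' @export
modularity_q <- function(m, partition) {
  v <- dyad_values(m)
  if (is_directed(m)) v <- v + t(v)
  mem <- partition_membership(partition, dyad_ids(m))
  W2 <- sum(v)  # = 2W for a symmetric matrix with zero diagonal
  if (W2 == 0) stop("modularity undefined on a zero-weight matrix")
  s <- rowSums(v)
  same <- outer(mem, mem, "==")
  sum((v - outer(s, s) / W2) * same) / W2
}

#' @keywords internal
partition_membership <- function(partition, ids) {
  mem <- if (inherits(partition, "social_partition")) partition$membership
  else partition
  if (!is.null(names(mem))) {
    if (!all(ids %in% names(mem))) stop("partition does not cover all ids")
    mem <- mem[ids]
  } else if (length(mem) != length(ids)) {
    stop("partition does not cover all ids")
  }
  as.integer(factor(mem))
}

#' Community detection by multilevel modularity optimisation
#'
#' Louvain greedy modularity optimisation (via igraph) restarted over
#' `n_restart` random node orders; the best-Q partition is returned.
#' Directed matrices are symmetrized by summing the two directions.
#'
#' @param m a `dyad_matrix` with nonnegative weights
#' @param seed integer seed fixing the restart schedule
#' @param n_restart number of random-order restarts
#' @return a `social_partition` carrying its modularity
#' @export
detect_communities <- function(m, seed = 1, n_restart = 100) {
  g <- as_igraph(m)
  if (igraph::vcount(g) == 0) stop("empty graph")
  ids <- dyad_ids(m)
  set.seed(seed)
  best_mem <- NULL
  best_q <- -Inf
  for (r in seq_len(n_restart)) {
    ord <- sample(seq_along(ids))
    gp <- igraph::permute(g, ord)
    cl <- igraph::cluster_louvain(gp, weights = igraph::E(gp)$weight)
    mem <- igraph::membership(cl)[ord]  # back to original vertex order
    q <- modularity_q(m, setNames(as.integer(mem), ids))
    if (q > best_q) {
      best_q <- q
      best_mem <- setNames(as.integer(mem), ids)
    }
  }
  social_partition(best_mem, modularity = best_q)
}

#' Permutation p-value for the modularity of a detected partition
#'
#' Null model: the off-diagonal edge weights are randomly permuted
#' among dyads (weight multiset preserved, structure destroyed),
#' community detection is re-run on each null matrix, and the p-value
#' is the proportion of null best-Q values at least as large as the
#' observed one.
#'
#' @param m a symmetric `dyad_matrix` (directed input symmetrized)
#' @param partition the observed partition (its Q is the observed stat);
#'   if `NULL`, detected from `m`
#' @param n_perm number of weight permutations
#' @param seed integer seed
#' @param n_restart restarts per null detection (kept small for speed)
#' @return a `permutation_result`
#' @export
partition_pvalue <- function(m, partition = NULL, n_perm = 1000, seed = 1,
                             n_restart = 5) {
  v <- dyad_values(m)
  if (is_directed(m)) v <- v + t(v)
  ids <- dyad_ids(m)
  if (is.null(partition)) partition <- detect_communities(m, seed = seed)
  observed <- modularity_q(m, partition)
  ut <- which(upper.tri(v))
  set.seed(seed)
  null_stats <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    w <- v
    w[ut] <- v[ut][sample.int(length(ut))]
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
    mk <- dyad_matrix(w, directed = FALSE, ids = ids)
    pk <- detect_communities(mk, seed = sample.int(.Machine$integer.max %/% 2, 1),
                             n_restart = n_restart)
    null_stats[k] <- pk$modularity
  }
  permutation_result(observed, null_stats, mean(null_stats >= observed),
                     seed, "greater")
}

#' Continuous-trait assortment coefficient
#'
#' Weighted assortativity for a continuous node trait: the weighted
#' Pearson correlation of trait values across edge endpoints, each
#' undirected edge contributing both orientations and each ordered
#' edge weighted by its weight. Positive values mean individuals carry
#' ties to others with similar trait values. The p-value comes from
#' node-label permutations of the trait vector.
#'
#' @param m a `dyad_matrix` (directed input symmetrized by summing)
#' @param trait numeric vector, named by id or ordered as the matrix ids
#' @param n_node_perm number of trait permutations (0 skips the test)
#' @param seed integer seed
#' @param alternative `"two.sided"` (default), `"greater"`, `"less"`
#' @return list with `ac` and, when permuted, `p_value` and `null_stats`
#' @export
assortment_continuous <- function(m, trait, n_node_perm = 1000, seed = 1,
                                  alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  v <- dyad_values(m)
  if (is_directed(m)) v <- v + t(v)
  ids <- dyad_ids(m)
  if (!is.null(names(trait))) {
    if (!all(ids %in% names(trait))) stop("trait not defined for all ids")
    trait <- trait[ids]
  } else if (length(trait) != length(ids)) {
    stop("trait not defined for all ids")
  }
  if (sd(trait) == 0) stop("assortment undefined for a constant trait")
  ac_of <- function(x) {
    W <- sum(v)
    mi <- sum(v * x) / W           # row-endpoint weighted mean
    mj <- sum(t(v) * x) / W        # column-endpoint weighted mean
    vi <- sum(v * x^2) / W - mi^2
    vj <- sum(t(v) * x^2) / W - mj^2
    (sum(v * outer(x, x)) / W - mi * mj) / sqrt(vi * vj)
  }
  observed <- ac_of(trait)
  out <- list(ac = observed)
  if (n_node_perm > 0) {
    set.seed(seed)
    null_stats <- vapply(seq_len(n_node_perm),
                         function(k) ac_of(trait[sample.int(length(trait))]),
                         numeric(1))
    out$null_stats <- null_stats
    out$p_value <- switch(alternative,
      greater = mean(null_stats >= observed),
      less = mean(null_stats <= observed),
      two.sided = mean(abs(null_stats) >= abs(observed)))
    out$alternative <- alternative
    out$seed <- seed
  }
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same
#' individuals; 1 for identical partitions, about 0 for independent
#' ones. Used to score recovery of planted cluster structure.
#'
#' @param a,b partitions (`social_partition` or label vectors, named or
#'   ordered alike)
#' @return the adjusted Rand index
#' @export
adjusted_rand <- function(a, b) {
  la <- if (inherits(a, "social_partition")) a$membership else a
  lb <- if (inherits(b, "social_partition")) b$membership else b
  if (!is.null(names(la)) && !is.null(names(lb))) lb <- lb[names(la)]
  if (length(la) != length(lb)) stop("partitions cover different individuals")
  tab <- table(la, lb)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  ex <- si * sj / ch2(sum(tab))
  mx <- (si + sj) / 2
  if (mx == ex) return(1)
  (sij - ex) / (mx - ex)
}
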