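#' Win matrix from agonistic events
#'
#' Builds the directed matrix of encounter wins. The initiator of an
#' offensive interaction is the winner of that encounter; defensive
#' (submissive) interactions are reversed so that the individual the
#' submission is directed to is credited with the win.
#'
#' @param events validated event data.frame; only `kind == "agonistic"`
#'   rows are used, and each must carry a `role_class`
#' @param ids id order for the matrix
#' @return directed `dyad_matrix` of win counts
#' @export
win_matrix <- function(events, ids = NULL) {
  events <- validate_events(events)
  ag <- events[events$kind == "agonistic", , drop = FALSE]
  if (anyNA(ag$role_class))
    stop("agonistic event without role_class at row(s) ",
         paste(head(which(is.na(ag$role_class))), collapse = ", "))
  if (is.null(ids)) ids <- sort(unique(c(events$actor, events$recipient)))
  winner <- ifelse(ag$role_class == "offensive", ag$actor, ag$recipient)
  loser <- ifelse(ag$role_class == "offensive", ag$recipient, ag$actor)
  n <- length(ids)
  w <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(ag)) {
    tab <- table(factor(winner, ids), factor(loser, ids))
    w <- w + unclass(tab)
  }
  dyad_matrix(w, directed = TRUE)
}

#' David's scores
#'
#' Cardinal dominance index from a win matrix. With raw win
#' proportions `P_ij = wins(i,j) / (wins(i,j) + wins(j,i))` (a dyad
#' with no encounters contributes 0 to both sums),
#' `DS_i = w_i + w2_i - l_i - l2_i` where `w_i = sum_j P_ij`,
#' `w2_i = sum_j P_ij * w_j`, and `l`, `l2` are the loss-side
#' analogues. Scores sum to zero over the group by construction.
#'
#' @param w directed `dyad_matrix` of win counts
#' @return named numeric vector of David's scores
#' @export
davids_score <- function(w) {
  v <- dyad_values(w)
  if (nrow(v) < 2) stop("David's score needs at least two individuals")
  tot <- v + t(v)
  P <- ifelse(tot > 0, v / ifelse(tot > 0, tot, 1), 0)
  diag(P) <- 0
  wi <- rowSums(P)
  li <- colSums(P)
  w2 <- as.vector(P %*% wi)
  l2 <- as.vector(t(P) %*% li)
  setNames(wi + w2 - li - l2, rownames(v))
}

#' @keywords internal
landau_h <- function(V, n) {
  (12 / (n^3 - n)) * sum((V - (n - 1) / 2)^2)
}

#' Landau's h' linearity of a dominance hierarchy
#'
#' Randomization-adjusted linearity after de Vries (1995). A dyad is
#' decided for the member with more wins; tied and unknown
#' (zero-encounter) dyads are assigned a random direction in each of
#' `n_rand` fill-ins, Landau's h is computed from the dominance
#' out-degrees of each filled tournament, and h' is the mean. The
#' p-value is the right-tail proportion of h values from fully random
#' tournaments of the same size at or above h'.
#'
#' @param w directed `dyad_matrix` of win counts (>= 3 individuals)
#' @param n_rand number of randomizations
#' @param seed integer seed
#' @return list with `h_prime`, `p_linearity`, `n_unknown` (undecided
#'   dyads), `davids_scores`, `n_rand`, `seed`
#' @export
landau_h_prime <- function(w, n_rand = 1000, seed = 1) {
  if (n_rand < 1) stop("n_rand must be >= 1")
  v <- dyad_values(w)
  n <- nrow(v)
  if (n < 3) stop("linearity needs at least three individuals")
  ut <- which(upper.tri(v), arr.ind = TRUE)
  wij <- v[ut]; wji <- v[cbind(ut[, 2], ut[, 1])]
  decided <- wij != wji
  # +1: row individual dominates; -1: column individual dominates
  dir0 <- ifelse(wij > wji, 1L, -1L)
  n_und <- sum(!decided)
  set.seed(seed)
  h_fill <- numeric(n_rand)
  for (k in seq_len(n_rand)) {
    dir <- dir0
    if (n_und)
      dir[!decided] <- sample(c(-1L, 1L), n_und, replace = TRUE)
    V <- tabulate(c(ut[dir == 1L, 1], ut[dir == -1L, 2]), nbins = n)
    h_fill[k] <- landau_h(V, n)
  }
  h_prime <- mean(h_fill)
  h_rand <- numeric(n_rand)
  nd <- nrow(ut)
  for (k in seq_len(n_rand)) {
    dir <- sample(c(-1L, 1L), nd, replace = TRUE)
    V <- tabulate(c(ut[dir == 1L, 1], ut[dir == -1L, 2]), nbins = n)
    h_rand[k] <- landau_h(V, n)
  }
  list(h_prime = h_prime, p_linearity = mean(h_rand >= h_prime),
       n_unknown = n_und, davids_scores = davids_score(w),
       n_rand = n_rand, seed = seed)
}
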