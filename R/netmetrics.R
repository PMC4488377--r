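# Graph metrics on connectivity matrices: distance transform, weighted and
# binary directed betweenness centrality, degree metrics, and significance
# by randomization nulls pooled across nodes.

#' Convert connectivity weights to path distances
#'
#' `d[A, B] = 1 / w[A, B]` for positive weights; non-positive weights map to
#' infinity (absent edge). Binary matrices therefore map 1 -> 1 and 0 -> Inf.
#'
#' @param matrix a [connectivity_matrix()] or plain square matrix.
#' @return square numeric matrix of distances (Inf = no edge), zero diagonal.
#' @export
weights_to_distances <- function(matrix) {
  w <- unclass(as.matrix(matrix))
  if (nrow(w) != ncol(w)) stop("matrix must be square", call. = FALSE)
  d <- ifelse(!is.na(w) & w > 0, 1 / w, Inf)
  diag(d) <- 0
  d
}

#' Betweenness centrality of a directed distance matrix
#'
#' For every ordered pair (s, t) with s, t distinct from v, the fraction of
#' shortest directed paths from s to t that pass through v is accumulated
#' (all co-minimal paths counted, ties resolved within a relative tolerance
#' of 1e-12). Unreachable pairs contribute nothing. With `normalized = TRUE`
#' the result is divided by (N-1)(N-2).
#'
#' @param dist square distance matrix (Inf = absent edge).
#' @param normalized divide by the number of ordered pairs excluding v.
#' @return named numeric vector of per-node betweenness values.
#' @export
betweenness_centrality <- function(dist, normalized = FALSE) {
  d <- as.matrix(dist)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square", call. = FALSE)
  if (any(d[row(d) != col(d)] < 0, na.rm = TRUE))
    stop("distances must be non-negative", call. = FALSE)
  d[is.na(d)] <- Inf
  bc <- .brandes_betweenness(d)
  if (normalized && nrow(d) > 2) bc <- bc / ((nrow(d) - 1) * (nrow(d) - 2))
  names(bc) <- rownames(d)
  bc
}

#' Degree metrics of a binary directed network
#'
#' @param matrix a binary [connectivity_matrix()].
#' @return data.frame with per-node `outdegree` (row sum), `indegree`
#'   (column sum), `degree` (their sum) and `outdegree_proportion`
#'   (outdegree / degree; 0 when the degree is 0).
#' @export
degree_metrics <- function(matrix) {
  w <- unclass(as.matrix(matrix))
  off <- w[row(w) != col(w)]
  if (!all(off %in% c(0, 1)))
    stop("degree metrics require a binary matrix", call. = FALSE)
  diag(w) <- 0
  outdeg <- rowSums(w)
  indeg <- colSums(w)
  deg <- outdeg + indeg
  data.frame(node = rownames(w) %||% sprintf("R%02d", seq_len(nrow(w))),
             degree = deg, indegree = indeg, outdegree = outdeg,
             outdegree_proportion = ifelse(deg == 0, 0, outdeg / deg),
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pooled-null p-values with the add-one continuity estimator.
pooled_p <- function(observed, null_pool) {
  ns <- sort(null_pool)
  n_ge <- length(ns) - findInterval(observed, ns, left.open = TRUE)
  (1 + n_ge) / (length(ns) + 1)
}

#' Weighted randomization null for betweenness centrality
#'
#' Each randomization permutes the multiset of the N(N-1) off-diagonal
#' weights uniformly over the ordered pairs (values preserved, pattern
#' shuffled), recomputes the betweenness of every node, and pools all
#' values from all nodes of all randomized networks into a single null
#' distribution. Per-node p is the fraction of the pooled null at or above
#' the observed value, with an add-one continuity correction.
#'
#' @param matrix a weighted [connectivity_matrix()].
#' @param n_rand number of randomizations (>= 100; the reference analysis
#'   used 100,000).
#' @param rng_seed integer seed.
#' @return an object of class `centrality_report`: list with `nodes`
#'   (data.frame of node, betweenness, p_value), `null_betweenness`,
#'   `n_rand`, `rng_seed`, `metric`.
#' @export
randomization_null_weighted <- function(matrix, n_rand = 100000,
                                        rng_seed = NULL) {
  if (n_rand < 100) stop("`n_rand` must be at least 100", call. = FALSE)
  w <- unclass(as.matrix(matrix))
  n <- nrow(w)
  off_idx <- which(row(w) != col(w))
  w_off <- w[off_idx]
  obs <- betweenness_centrality(weights_to_distances(w))
  if (length(unique(w_off)) == 1L) {
    warning("all off-diagonal weights equal: randomization null is ",
            "degenerate; all p-values set to 1")
    nodes <- data.frame(node = names(obs), betweenness = obs,
                        p_value = rep(1, n), row.names = NULL,
                        stringsAsFactors = FALSE)
    return(structure(list(nodes = nodes, null_betweenness = rep(obs[1], n),
                          n_rand = n_rand, rng_seed = rng_seed,
                          metric = "betweenness_weighted"),
                     class = "centrality_report"))
  }
  E <- length(w_off)
  null_bc <- with_seed(rng_seed, {
    chunks <- split(seq_len(n_rand), ceiling(seq_len(n_rand) / 5000))
    do.call(rbind, lapply(chunks, function(ch) {
      perm <- t(vapply(ch, function(i) sample.int(E), integer(E)))
      .null_betweenness_weighted(w_off, perm, n)
    }))
  })
  pool <- as.numeric(null_bc)
  nodes <- data.frame(node = names(obs), betweenness = obs,
                      p_value = pooled_p(obs, pool), row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, null_betweenness = pool, n_rand = n_rand,
                 rng_seed = rng_seed, metric = "betweenness_weighted"),
            class = "centrality_report")
}

#' Binary randomization null for betweenness and degree
#'
#' Each randomization places the observed number of edges E uniformly among
#' the N(N-1) ordered pairs. Degree and betweenness nulls are pooled across
#' nodes and randomizations; per-node p as in
#' [randomization_null_weighted()]. Every draw preserves E exactly.
#'
#' @param matrix a binary [connectivity_matrix()].
#' @param n_rand number of randomizations.
#' @param rng_seed integer seed.
#' @return a `centrality_report` whose `nodes` table carries betweenness,
#'   degree metrics and their p-values.
#' @export
randomization_null_binary <- function(matrix, n_rand = 100000,
                                      rng_seed = NULL) {
  if (n_rand < 100) stop("`n_rand` must be at least 100", call. = FALSE)
  w <- unclass(as.matrix(matrix))
  off <- w[row(w) != col(w)]
  if (!all(off %in% c(0, 1)))
    stop("binary randomization requires a binary matrix", call. = FALSE)
  n <- nrow(w)
  E <- sum(off)
  obs_bc <- betweenness_centrality(weights_to_distances(w))
  obs_deg <- degree_metrics(matrix)
  if (E == 0 || E == n * (n - 1)) {
    warning("empty or complete network: randomization null is degenerate; ",
            "all p-values set to 1")
    nodes <- cbind(obs_deg, betweenness = obs_bc,
                   p_betweenness = 1, p_degree = 1)
    return(structure(list(nodes = nodes, null_betweenness = rep(obs_bc[1], n),
                          null_degree = rep(obs_deg$degree[1], n),
                          n_rand = n_rand, rng_seed = rng_seed,
                          metric = "betweenness_binary"),
                     class = "centrality_report"))
  }
  n_slots <- n * (n - 1)
  nulls <- with_seed(rng_seed, {
    chunks <- split(seq_len(n_rand), ceiling(seq_len(n_rand) / 5000))
    parts <- lapply(chunks, function(ch) {
      slots <- t(vapply(ch, function(i) sample.int(n_slots, E), integer(E)))
      .null_betweenness_binary(slots, n)
    })
    list(bc = do.call(rbind, lapply(parts, `[[`, "betweenness")),
         deg = do.call(rbind, lapply(parts, function(p)
           p$outdegree + p$indegree)))
  })
  pool_bc <- as.numeric(nulls$bc)
  pool_deg <- as.numeric(nulls$deg)
  nodes <- cbind(obs_deg, betweenness = obs_bc,
                 p_betweenness = pooled_p(obs_bc, pool_bc),
                 p_degree = pooled_p(obs_deg$degree, pool_deg))
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, null_betweenness = pool_bc,
                 null_degree = pool_deg, n_rand = n_rand,
                 rng_seed = rng_seed, metric = "betweenness_binary"),
            class = "centrality_report")
}

#' Hub analysis of a binary anatomical network
#'
#' Validates the matrix (binary, directed, no self-connections), converts
#' presence/absence to unit/infinite distances, and runs the
#' edge-count-preserving binary randomization null.
#'
#' @param matrix a `binary_anatomy` [connectivity_matrix()].
#' @param n_rand number of randomizations.
#' @param rng_seed integer seed.
#' @return a `centrality_report`.
#' @export
anatomy_betweenness <- function(matrix, n_rand = 100000, rng_seed = NULL) {
  w <- unclass(as.matrix(matrix))
  if (any(diag(w) != 0))
    stop("anatomical matrix must contain no self-connections", call. = FALSE)
  if (!all(w %in% c(0, 1)))
    stop("anatomical matrix must be binary", call. = FALSE)
  randomization_null_binary(matrix, n_rand = n_rand, rng_seed = rng_seed)
}

#' @export
print.centrality_report <- function(x, ...) {
  cat("Centrality report (", x$metric, "), ", x$n_rand,
      " randomizations\n", sep = "")
  print(x$nodes, ...)
  invisible(x)
}
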