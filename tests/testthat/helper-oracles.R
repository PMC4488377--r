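# Independent oracles used across the suite.

# Exhaustive shortest-path betweenness: enumerates every simple directed
# path between all ordered node pairs, finds the co-minimal total lengths
# within a relative tolerance, and accumulates the interior-node fractions.
# Exponential in N; intended for N <= 8.
brute_force_betweenness <- function(d, tol = 1e-9) {
  n <- nrow(d)
  bc <- numeric(n)
  if (n < 3) return(bc)
  paths_between <- function(s, t) {
    out <- list()
    walk <- function(path, len) {
      last <- path[length(path)]
      if (last == t) {
        out[[length(out) + 1]] <<- list(path = path, len = len)
        return(invisible())
      }
      for (v in seq_len(n)) {
        if (v %in% path) next
        if (!is.finite(d[last, v])) next
        walk(c(path, v), len + d[last, v])
      }
    }
    walk(s, 0)
    out
  }
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) next
      ps <- paths_between(s, t)
      if (!length(ps)) next
      lens <- vapply(ps, `[[`, 0, "len")
      best <- min(lens)
      onbest <- which(lens <= best + tol * max(1, abs(best)))
      sigma <- length(onbest)
      for (k in onbest) {
        interior <- setdiff(ps[[k]]$path, c(s, t))
        bc[interior] <- bc[interior] + 1 / sigma
      }
    }
  }
  bc
}

# Brute-force Benjamini-Hochberg: largest k with p_(k) <= k q / m; all
# hypotheses with p <= p_(k) rejected.
brute_force_bh <- function(p, q) {
  m <- length(p)
  ord <- sort(p)
  k <- suppressWarnings(max(which(ord <= seq_len(m) * q / m)))
  if (!is.finite(k)) return(rep(FALSE, length(p)))
  p <= ord[k]
}

# Random weighted digraph fixture: weights drawn iid, a fraction of edges
# absent.
random_weight_matrix <- function(n, p_absent = 0.3) {
  w <- matrix(runif(n * n, 0.1, 2), n, n)
  w[runif(n * n) < p_absent] <- 0
  diag(w) <- 0
  w
}
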