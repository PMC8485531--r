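# --- brute-force graph oracles (BFS shortest-path counting) ----------------

bfs_dist_paths <- function(adj, src) {
  n <- nrow(adj)
  d <- rep(Inf, n); nsp <- rep(0, n)
  d[src] <- 0; nsp[src] <- 1
  frontier <- src
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in which(adj[v, ] == 1)) {
        if (is.infinite(d[w])) {
          d[w] <- d[v] + 1
          nxt <- c(nxt, w)
        }
        if (d[w] == d[v] + 1) nsp[w] <- nsp[w] + nsp[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(d = d, nsp = nsp)
}

oracle_topology <- function(adj) {
  n <- nrow(adj)
  paths <- lapply(seq_len(n), function(s) bfs_dist_paths(adj, s))
  d <- do.call(rbind, lapply(paths, `[[`, "d"))
  nsp <- do.call(rbind, lapply(paths, `[[`, "nsp"))
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in seq.int(s + 1, n)) {
        if (s == v || t == v || is.infinite(d[s, t])) next
        if (d[s, v] + d[v, t] == d[s, t]) {
          btw[v] <- btw[v] + nsp[s, v] * nsp[v, t] / nsp[s, t]
        }
      }
    }
  }
  clo <- vapply(seq_len(n), function(v) {
    reach <- which(is.finite(d[v, ]) & seq_len(n) != v)
    if (!length(reach)) 0 else 1 / sum(d[v, reach])
  }, numeric(1))
  list(degree = rowSums(adj), closeness = clo, betweenness = btw)
}

net_from_adj <- function(adj) {
  nodes <- rownames(adj)
  idx <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
  list(edges = data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                          r = 1, p = 0, sign = "+",
                          stringsAsFactors = FALSE),
       nodes = nodes)
}


# independently coded brute-force connectedness/cohesion oracle.
# Pearson correlation is computed from sums (not stats::cor) and the
# permutation stream mirrors the documented pair order (j < k,
# iterations innermost), so the two implementations consume identical
# random numbers.
pearson_sum <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- sum(x * y) - sx * sy / n
  den <- sqrt((sum(x^2) - sx^2 / n) * (sum(y^2) - sy^2 / n))
  num / den
}

oracle_connectedness <- function(rel, null_iters, seed) {
  T_ <- ncol(rel); n <- nrow(rel)
  corrected <- matrix(0, T_, T_)
  withr::with_seed(seed, {
    for (j in seq_len(T_ - 1)) {
      for (k in seq.int(j + 1, T_)) {
        obs <- pearson_sum(rel[, j], rel[, k])
        nulls <- numeric(null_iters)
        for (it in seq_len(null_iters)) {
          nulls[it] <- pearson_sum(rel[, j], rel[sample.int(n), k])
        }
        corrected[j, k] <- corrected[k, j] <- obs - mean(nulls)
      }
    }
  })
  pos <- neg <- numeric(T_)
  for (j in seq_len(T_)) {
    v <- corrected[j, -j]
    pos[j] <- if (any(v > 0)) mean(v[v > 0]) else 0
    neg[j] <- if (any(v < 0)) mean(v[v < 0]) else 0
  }
  list(corrected = corrected, pos = pos, neg = neg)
}

fixed_toy_rel <- function(seed = 1, n = 10, t = 6) {
  withr::with_seed(seed, {
    m <- matrix(rgamma(n * t, shape = 2), n, t,
                dimnames = list(paste0("s", 1:n), paste0("tx", 1:t)))
  })
  sweep(m, 1, rowSums(m), "/")
}

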