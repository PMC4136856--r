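# Independent oracles used across the suite. Each re-derives the quantity it
# checks by a different route than the implementation.

# per-site closed-form occupancy likelihood, summed naively
oracle_occupancy_nll <- function(beta, alpha, X_occ, X_det, y) {
  n <- nrow(y); T_ <- ncol(y)
  total <- 0
  for (i in seq_len(n)) {
    psi <- 1 / (1 + exp(-sum(X_occ[i, ] * beta)))
    prod_p <- 1
    never <- TRUE
    for (t in seq_len(T_)) {
      if (is.na(y[i, t])) next
      p <- 1 / (1 + exp(-sum(X_det[(t - 1) * n + i, ] * alpha)))
      prod_p <- prod_p * ifelse(y[i, t] == 1, p, 1 - p)
      if (y[i, t] == 1) never <- FALSE
    }
    L <- psi * prod_p + (1 - psi) * as.numeric(never)
    total <- total - log(L)
  }
  total
}

# exact minimal accumulated cost by Bellman-Ford-style relaxation to fixpoint
# (different algorithm from the Dijkstra implementation; exact on any grid)
oracle_min_cost <- function(cost, cell_size, src_rc) {
  nr <- nrow(cost); nc <- ncol(cost)
  dist <- matrix(Inf, nr, nc)
  for (k in seq_len(nrow(src_rc))) dist[src_rc[k, 1], src_rc[k, 2]] <- 0
  steps <- cbind(dr = c(-1, -1, 0, 1, 1, 1, 0, -1),
                 dc = c(0, 1, 1, 1, 0, -1, -1, -1))
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      if (is.na(cost[r, cc])) next
      for (k in 1:8) {
        r2 <- r + steps[k, 1]; c2 <- cc + steps[k, 2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (is.na(cost[r2, c2])) next
        d <- ifelse(k %% 2 == 0, sqrt(2), 1) * cell_size
        w <- 0.5 * (cost[r, cc] + cost[r2, c2]) * d
        if (dist[r2, c2] + w < dist[r, cc] - 1e-15) {
          dist[r, cc] <- dist[r2, c2] + w
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  dist[is.na(cost)] <- NA
  dist[is.infinite(dist)] <- NA
  dist
}

# AUC by exhaustive presence x absence pair counting, ties 1/2
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# effective resistance by dense direct solve of the full Laplacian
oracle_reff_dense <- function(edges, n, src, gnd) {
  L <- matrix(0, n, n)
  for (k in seq_len(nrow(edges))) {
    i <- edges$i[k]; j <- edges$j[k]; g <- edges$conductance[k]
    L[i, j] <- L[i, j] - g; L[j, i] <- L[j, i] - g
    L[i, i] <- L[i, i] + g; L[j, j] <- L[j, j] + g
  }
  keep <- setdiff(seq_len(n), gnd)
  rhs <- numeric(n); rhs[src] <- 1 / length(src)
  v <- solve(L[keep, keep], rhs[keep])
  full <- numeric(n); full[keep] <- v
  mean(full[src])
}

# brute-force nearest-feature distance from cell centres (point features)
oracle_point_distance <- function(grid, px, py) {
  out <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  for (r in seq_len(grid$n_rows)) for (cc in seq_len(grid$n_cols)) {
    ctr <- cell_center(grid, r, cc)
    out[r, cc] <- sqrt(min((px - ctr$x)^2 + (py - ctr$y)^2))
  }
  out
}
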