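# independent brute-force oracles for the HMM: dense transition matrix
# built directly from the kernel definition, and exhaustive path
# enumeration of likelihood, marginals and the MAP path.

oracle_transition <- function(env, D) {
  nc <- env$ny * env$nx
  sea <- as.numeric(env$sea)
  sdc <- sqrt(2 * D) / env$cell_km
  k <- if (sdc > 0) ceiling(4 * sdc) else 0
  Tm <- matrix(0, nc, nc)
  for (from in seq_len(nc)) {
    if (sea[from] == 0) next
    rc1 <- bassgeo:::cell_rc(env, from)
    for (to in seq_len(nc)) {
      rc2 <- bassgeo:::cell_rc(env, to)
      dr <- abs(rc2[, "row"] - rc1[, "row"])
      dc <- abs(rc2[, "col"] - rc1[, "col"])
      g <- if (sdc == 0) as.numeric(dr == 0 && dc == 0)
      else if (dr > k || dc > k) 0
      else exp(-(dr^2 + dc^2) / (2 * sdc^2))
      Tm[from, to] <- g * sea[to]
    }
  }
  rs <- rowSums(Tm)
  Tm[rs > 0, ] <- Tm[rs > 0, ] / rs[rs > 0]
  Tm
}

# enumerate all joint (cell, behaviour) paths for a small instance
oracle_enumerate <- function(env, model, lik, init, binit) {
  nc <- env$ny * env$nx
  nd <- dim(lik)[3]
  T1 <- oracle_transition(env, model$D_res)
  T2 <- oracle_transition(env, model$D_mig)
  sw <- model$switch_matrix
  TJ <- matrix(0, 2 * nc, 2 * nc)
  for (b1 in 1:2) for (b2 in 1:2) {
    Tb <- if (b2 == 1) T1 else T2
    TJ[(b1 - 1) * nc + (1:nc), (b2 - 1) * nc + (1:nc)] <- sw[b1, b2] * Tb
  }
  prior <- c(binit[1] * c(init), binit[2] * c(init))
  Lv <- apply(lik, 3, c)
  Lj <- rbind(Lv, Lv)
  paths <- as.matrix(do.call(expand.grid,
                             rep(list(seq_len(2 * nc)), nd)))
  p <- prior[paths[, 1]] * Lj[paths[, 1], 1]
  for (t in 2:nd)
    p <- p * TJ[cbind(paths[, t - 1], paths[, t])] * Lj[paths[, t], t]
  Ltot <- sum(p)
  marg <- sapply(seq_len(nd), function(t) {
    mm <- rep(0, 2 * nc)
    agg <- rowsum(p, paths[, t])
    mm[as.integer(rownames(agg))] <- agg[, 1]
    mm <- mm / Ltot
    mm[1:nc] + mm[nc + (1:nc)]
  })
  best <- which.max(p)
  list(likelihood = Ltot, marginals = marg,
       map_path = paths[best, ], map_prob = max(p))
}
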