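# Shared fixtures and independent oracles.  Heavyweight objects are computed
# once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

tiny_mols <- function() {
  cached("tiny_mols", {
    m <- parse_smiles(c("CCO", "CCC", "c1ccccc1", "C", "N", "CC(=O)C"),
                      c("ethanol", "propane", "benzene", "methane",
                        "ammonia", "acetone"))
    stats::setNames(m, vapply(m, function(x) x$id, ""))
  })
}

# a pool of parse-checked drug-like SMILES for randomized property suites
mol_pool <- function() {
  cached("mol_pool", {
    smi <- c("CCO", "CCC", "c1ccccc1", "CC(=O)C", "c1ccncc1", "C1CCCCC1",
             "CC(=O)c1ccccc1", "c1ccc2ccccc2c1", "CCOC(=O)C", "CC(C)CO",
             "c1cc[nH]c1", "CCNC(=O)C", "c1ccsc1", "OCC(O)CO",
             "CCC(=O)c1c[nH]c2ccccc12", "Cc1ccc(O)cc1")
    parse_smiles(smi, paste0("p", seq_along(smi)))
  })
}

# small planted-pharmacophore fixture for unit tests (desk-scale)
small_fixture <- function() {
  cached("small_fixture", {
    generate_planted_dataset(fixture_spec(n_actives = 12, n_decoys = 40,
                                          n_clusters = 3, seed = 7))
  })
}

# ---------------------------------------------------------------------------
# Independent oracles
# ---------------------------------------------------------------------------

# all permutations of 1..n (n <= 7), cached by size
perms <- function(n) {
  key <- paste0("perms", n)
  cached(key, {
    if (n == 1) matrix(1L, 1, 1)
    else {
      p <- perms(n - 1L)
      do.call(rbind, lapply(seq_len(n), function(k)
        cbind(k, ifelse(p >= k, p + 1L, p))))
    }
  })
}

# brute-force maximum-sum assignment of the smaller side of S (vectorized
# over all column permutations)
bf_assignment_max <- function(S) {
  if (nrow(S) > ncol(S)) S <- t(S)
  n <- nrow(S); m <- ncol(S)
  P <- perms(m)
  acc <- numeric(nrow(P))
  for (j in seq_len(n)) acc <- acc + S[(P[, j] - 1L) * n + j]
  max(acc)
}

# hand-rolled reference recursion for the atom-environment similarity,
# independent of the compiled implementation (uses the brute-force assignment)
ref_atom_similarity <- function(A, i, B, j, depth = 2, dist = 0,
                                ga = 8, gab = 8, lambda = 0.5) {
  rbf_c <- exp(-ga * sum((A$A[i, ] - B$A[j, ])^2))
  if (depth == 0) return(rbf_c)
  nu <- length(A$nbrs[[i]]); nv <- length(B$nbrs[[j]])
  if (nu == 0 && nv == 0) return(rbf_c)
  nbterm <- 0
  if (nu > 0 && nv > 0) {
    M <- matrix(0, nu, nv)
    for (u in seq_len(nu)) {
      au <- A$nbrs[[i]][u]
      for (v in seq_len(nv)) {
        bv <- B$nbrs[[j]][v]
        d2 <- sum((A$A[au, ] - B$A[bv, ])^2) +
          sum((A$bdesc[[i]][u, ] - B$bdesc[[j]][v, ])^2)
        M[u, v] <- exp(-gab * d2) *
          ref_atom_similarity(A, au, B, bv, depth - 1, dist + 1,
                              ga, gab, lambda)
      }
    }
    nbterm <- bf_assignment_max(M) / max(nu, nv)
  }
  d <- (1 - (dist + 1) / 3)^2
  val <- ((1 - lambda) * rbf_c + lambda * d * nbterm) /
    ((1 - lambda) + lambda * d)
  min(1, max(0, val))
}

# Mann-Whitney pair-count AUC oracle (ties 1/2)
mw_auc <- function(score, act) {
  a <- score[act]; d <- score[!act]
  tot <- 0
  for (x in a) tot <- tot + sum(x > d) + 0.5 * sum(x == d)
  tot / (length(a) * length(d))
}

# breadth-first-search shortest-path oracle on a molecule's bond graph
bfs_dist <- function(mol, from) {
  n <- mol$n
  adj <- lapply(seq_len(n), function(a) {
    c(mol$bonds$j[mol$bonds$i == a], mol$bonds$i[mol$bonds$j == a])
  })
  d <- rep(Inf, n); d[from] <- 0
  q <- from
  while (length(q) > 0) {
    v <- q[1]; q <- q[-1]
    for (w in adj[[v]]) if (d[w] == Inf) { d[w] <- d[v] + 1; q <- c(q, w) }
  }
  d
}
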