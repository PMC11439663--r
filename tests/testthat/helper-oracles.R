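# Brute-force oracles, independent of the package's implementation path:
# breadth-first-search distances, direct triangle enumeration, exhaustive
# modularity search over all set partitions, pair-enumeration segregation,
# and hypergeometric tail enumeration for Fisher's test.

bfs_distances_oracle <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    dist <- 0
    while (length(frontier)) {
      dist <- dist + 1
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(a[v, ] == 1)
        new <- nb[d[s, nb] == Inf & nb != s]
        d[s, new] <- dist
        nxt <- c(nxt, new)
      }
      frontier <- unique(nxt)
    }
  }
  d
}

cpl_oracle <- function(a) {
  d <- bfs_distances_oracle(a)
  diag(d) <- NA
  vals <- d[is.finite(d) & !is.na(d)]
  if (!length(vals)) NA_real_ else mean(vals)
}

efficiency_oracle <- function(a) {
  d <- bfs_distances_oracle(a)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  n <- nrow(a)
  sum(inv) / (n * (n - 1))
}

triangles_per_node_oracle <- function(a) {
  n <- nrow(a)
  t <- integer(n)
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      if (a[i, j] && a[j, k] && a[i, k]) {
        t[i] <- t[i] + 1L; t[j] <- t[j] + 1L; t[k] <- t[k] + 1L
      }
    }
  }
  t
}

clustering_oracle <- function(a) {
  k <- rowSums(a)
  t <- triangles_per_node_oracle(a)
  mean(ifelse(k < 2, 0, 2 * t / (k * (k - 1))))
}

transitivity_oracle <- function(a) {
  k <- rowSums(a)
  triples <- sum(k * (k - 1) / 2)
  if (triples == 0) return(NA_real_)
  sum(triangles_per_node_oracle(a)) / triples
}

modularity_formula_oracle <- function(a, member) {
  m2 <- sum(a)            # 2m
  if (m2 == 0) return(NA_real_)
  k <- rowSums(a)
  same <- outer(member, member, "==")
  sum((a - outer(k, k) / m2) * same) / m2
}

# all set partitions of n items via restricted growth strings
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, maxv) {
    i <- length(prefix) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxv + 1L)) grow(c(prefix, v), max(maxv, v))
  }
  grow(integer(0), 0L)
  out
}

best_modularity_oracle <- function(a) {
  parts <- all_partitions(nrow(a))
  qs <- vapply(parts, function(p) modularity_formula_oracle(a, p),
               numeric(1))
  list(q = max(qs), partition = parts[[which.max(qs)]])
}

# random simple graph with at least min_edges edges
random_adjacency <- function(n, p, min_edges = 1L) {
  repeat {
    a <- matrix(0L, n, n)
    ut <- which(upper.tri(a))
    a[ut] <- rbinom(length(ut), 1L, p)
    a <- a + t(a)
    if (sum(a) / 2 >= min_edges) return(a)
  }
}

# exhaustive pair-enumeration segregation oracle
sysseg_oracle <- function(z, member, analysis_set, exclude_negative = TRUE) {
  n <- nrow(z)
  zw <- c(); zb <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (!(member[i] %in% analysis_set) || !(member[j] %in% analysis_set))
      next
    v <- z[i, j]
    if (exclude_negative && v < 0) next
    if (member[i] == member[j]) zw <- c(zw, v) else zb <- c(zb, v)
  }
  mw <- mean(zw); mb <- mean(zb)
  list(sysseg = (mw - mb) / mw, zw = mw, zb = mb,
       nw = length(zw), nb = length(zb))
}

fisher_2x2_oracle <- function(tab) {
  # two-sided: sum of hypergeometric probabilities <= that of the
  # observed table (with the conventional 1 + 1e-7 slack)
  m <- sum(tab[1, ]); n_ <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n_):min(k, m)
  probs <- dhyper(support, m, n_, k)
  p_obs <- dhyper(tab[1, 1], m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# small convenience: block z matrix with constant within/between values
block_z_matrix <- function(sizes, z_within, z_between) {
  member <- rep(names(sizes), sizes)
  z <- ifelse(outer(member, member, "=="), z_within, z_between)
  diag(z) <- 0
  labels <- sprintf("%s_%02d", member, ave(seq_along(member), member,
                                           FUN = seq_along))
  dimnames(z) <- list(labels, labels)
  list(z = pscdnet::as_fc_matrix(z, "fisher_z"),
       partition = pscdnet::canonical_partition(labels, member,
                                                analysis_set = names(sizes)))
}
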