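# Independent brute-force re-implementations of the four scores, written
# directly against raw edge lists with plain loops.  These never touch
# the package's network object internals and serve as the oracle the
# implementation is checked against.

oracle_pooled_edges <- function(ppi, reg) {
  # one row per link; undirected protein pair once, directed pair once
  rbind(ppi, reg)
}

oracle_touches <- function(edges, g) {
  if (nrow(edges) == 0L) return(logical(0))
  edges[, 1L] == g | edges[, 2L] == g
}

oracle_nl <- function(ppi, reg, g) {
  sum(oracle_touches(ppi, g)) + sum(oracle_touches(reg, g))
}

oracle_links_to_set <- function(ppi, reg, g, members) {
  members <- setdiff(members, g)
  cnt <- 0L
  for (edges in list(ppi, reg)) {
    for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1L]; b <- edges[r, 2L]
      if ((a == g && b %in% members) || (b == g && a %in% members)) {
        cnt <- cnt + 1L
      }
    }
  }
  cnt
}

oracle_ct <- function(ppi, reg, w, genes, m1, m2) {
  N <- length(genes)
  score <- 0
  for (g in setdiff(genes, c(m1, m2))) {
    n1 <- oracle_links_to_set(ppi, reg, g, m1)
    n2 <- oracle_links_to_set(ppi, reg, g, m2)
    nl <- oracle_nl(ppi, reg, g)
    b1 <- n1 > (length(m1) / N) * nl
    b2 <- n2 > (length(m2) / N) * nl
    if (b1 && b2) score <- score + w[[g]]
    else if (b1 || b2) score <- score - w[[g]]
  }
  score
}

oracle_neighbors <- function(ppi, reg, g) {
  nb <- character()
  for (edges in list(ppi, reg)) {
    for (r in seq_len(nrow(edges))) {
      if (edges[r, 1L] == g) nb <- c(nb, edges[r, 2L])
      if (edges[r, 2L] == g) nb <- c(nb, edges[r, 1L])
    }
  }
  sort(unique(nb))
}

oracle_cmratio <- function(ppi, reg, i, j) {
  ni <- oracle_neighbors(ppi, reg, i)
  nj <- oracle_neighbors(ppi, reg, j)
  u <- union(ni, nj)
  if (length(u) == 0L) return(0)
  length(intersect(ni, nj)) / length(u)
}

oracle_coopmed <- function(ppi, reg, w, genes, j, mod, opp, R = 0.9) {
  meds <- setdiff(mod, c(j, opp))
  if (length(meds) == 0L) return(0)
  best <- -Inf
  for (i in meds) {
    p <- oracle_cmratio(ppi, reg, i, j) *
      oracle_ct(ppi, reg, w, genes, i, opp)
    if (p > best) best <- p
  }
  R * best
}

oracle_mcoop <- function(ppi, reg, w, genes, g1, g2, s, t, R = 0.9) {
  score <- oracle_ct(ppi, reg, w, genes, s, t)
  for (u in setdiff(g1, s)) {
    score <- score + max(oracle_ct(ppi, reg, w, genes, u, t),
                         oracle_coopmed(ppi, reg, w, genes, u, g1, t, R))
  }
  for (v in setdiff(g2, t)) {
    score <- score + max(oracle_ct(ppi, reg, w, genes, v, s),
                         oracle_coopmed(ppi, reg, w, genes, v, g2, s, R))
  }
  score
}

# exhaustive spanning oracle: best cooperation score over all pairs of
# disjoint connected extensions of the seed (for networks small enough
# to enumerate 3^k assignments)
oracle_connected <- function(ppi, reg, members) {
  if (length(members) <= 1L) return(TRUE)
  adj <- lapply(members, function(g)
    intersect(oracle_neighbors(ppi, reg, g), members))
  names(adj) <- members
  seen <- members[[1L]]
  repeat {
    grow <- unique(unlist(adj[seen]))
    new <- union(seen, intersect(grow, members))
    if (length(new) == length(seen)) break
    seen <- new
  }
  length(seen) == length(members)
}

oracle_best_extension <- function(ppi, reg, w, genes, s, t, R = 0.9) {
  rest <- setdiff(genes, c(s, t))
  k <- length(rest)
  best <- oracle_ct(ppi, reg, w, genes, s, t)
  for (code in seq_len(3L^k) - 1L) {
    assign <- integer(k)
    x <- code
    for (d in seq_len(k)) { assign[[d]] <- x %% 3L; x <- x %/% 3L }
    g1 <- c(s, rest[assign == 1L])
    g2 <- c(t, rest[assign == 2L])
    if (!oracle_connected(ppi, reg, g1)) next
    if (!oracle_connected(ppi, reg, g2)) next
    sc <- oracle_mcoop(ppi, reg, w, genes, g1, g2, s, t, R)
    if (sc > best) best <- sc
  }
  best
}

# random test network generator used across oracle-equivalence tests
random_test_network <- function(n, p_ppi = 0.25, max_reg = 6L,
                                max_w = 6L) {
  genes <- sprintf("g%02d", seq_len(n))
  prs <- t(combn(genes, 2L))
  ppi <- prs[runif(nrow(prs)) < p_ppi, , drop = FALSE]
  nreg <- sample(0:max_reg, 1L)
  reg <- if (nreg > 0L) {
    cbind(sample(genes, nreg, replace = TRUE),
          sample(genes, nreg, replace = TRUE))
  } else {
    matrix(character(), ncol = 2L)
  }
  reg <- reg[reg[, 1L] != reg[, 2L], , drop = FALSE]
  w <- stats::setNames(sample(0:max_w, n, replace = TRUE), genes)
  if (nrow(ppi) + nrow(reg) == 0L) ppi <- prs[1L, , drop = FALSE]
  # deduplicate like the network constructor so the oracle sees the
  # same edge multiset
  ppi <- unique(cbind(pmin(ppi[, 1L], ppi[, 2L]),
                      pmax(ppi[, 1L], ppi[, 2L])))
  reg <- unique(reg)
  list(genes = genes, ppi = ppi, reg = reg, w = w,
       net = suppressMessages(
         assemble_wpi(ppi, reg, weights = w, extra_genes = genes)))
}
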