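#' Create a module
#'
#' A module is an ordered set of genes (insertion order is the spanning
#' order) anchored on the seed gene it grew from.
#'
#' @param genes Character vector of gene ids, no duplicates, non-empty.
#' @param anchor The anchor gene (must be among `genes`; defaults to the
#'   first one).
#' @param id Optional integer id.
#' @return An object of class `cm_module`.
#' @export
new_module <- function(genes, anchor = genes[[1L]], id = NA_integer_) {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("module must be non-empty", call. = FALSE)
  if (anyDuplicated(genes)) stop("duplicate genes in module", call. = FALSE)
  if (!anchor %in% genes) stop("anchor must be a module member",
                               call. = FALSE)
  structure(list(id = as.integer(id), genes = genes, anchor = anchor),
            class = "cm_module")
}

module_genes <- function(m) {
  if (inherits(m, "cm_module")) m$genes else as.character(m)
}

#' Create a seed (initial module pair of two genes)
#'
#' @param net A `wpi_network`.
#' @param s,t Distinct gene ids present in the network.
#' @return An object of class `cm_seed` with the consistency score of the
#'   singleton pair attached.
#' @export
new_seed <- function(net, s, t) {
  if (identical(s, t)) stop("seed genes must differ", call. = FALSE)
  if (!all(c(s, t) %in% net$genes)) {
    stop("seed genes must exist in the network", call. = FALSE)
  }
  structure(list(s = s, t = t,
                 ct_score = consistency_score(net, s, t)),
            class = "cm_seed")
}

#' Create a module pair
#'
#' @param m1,m2 `cm_module` objects (disjoint gene sets).
#' @param seed The `cm_seed` the pair grew from.
#' @param mcoop_score Optional cooperation score to attach.
#' @return An object of class `cm_module_pair`.
#' @export
new_module_pair <- function(m1, m2, seed, mcoop_score = NA_real_) {
  stopifnot(inherits(m1, "cm_module"), inherits(m2, "cm_module"),
            inherits(seed, "cm_seed"))
  structure(list(m1 = m1, m2 = m2, seed = seed,
                 mcoop_score = mcoop_score),
            class = "cm_module_pair")
}

#' Number of physical links between a gene and a module
#'
#' Counts pooled links (protein plus regulatory, direction ignored)
#' between gene `i` and the members of module `m`; links of `i` to itself
#' are never counted.
#'
#' @param net A `wpi_network`.
#' @param i A gene id.
#' @param m A module or character vector of gene ids.
#' @return Integer link count.
#' @export
module_link_count <- function(net, i, m) {
  idx <- match(i, net$genes)
  if (is.na(idx)) stop("gene not in network: ", i, call. = FALSE)
  members <- match(setdiff(module_genes(m), i), net$genes)
  sum(net$adj[[idx]] %in% members)
}

#' Consistency score of a module pair
#'
#' Contrasts the co-expression weights of genes linked to both modules
#' above expectation against the weights of genes linked to only one of
#' them.  For every gene `i` outside both modules, the observed link
#' counts to each module are compared with the expected counts
#' `(M/N) * NL_i` (module size over network size, times the gene's total
#' link count); `i` contributes `+CopL_i` when both counts are strictly
#' above expectation and `-CopL_i` when exactly one is.  The score is
#' symmetric in its two module arguments.
#'
#' @param net A `wpi_network`.
#' @param m1,m2 Disjoint, non-empty modules (or gene id vectors).
#' @return The (signed) consistency score.
#' @export
consistency_score <- function(net, m1, m2) {
  g1 <- module_genes(m1); g2 <- module_genes(m2)
  if (length(g1) == 0L || length(g2) == 0L) {
    stop("modules must be non-empty", call. = FALSE)
  }
  if (length(intersect(g1, g2)) > 0L) {
    stop("modules must be disjoint", call. = FALSE)
  }
  if (length(g1) == 1L && length(g2) == 1L) {
    return(ct_single(net, g1, g2))
  }
  consistency_score_impl(net, g1, g2)
}

consistency_score_impl <- function(net, g1, g2) {
  i1 <- match(g1, net$genes); i2 <- match(g2, net$genes)
  if (anyNA(c(i1, i2))) stop("module gene absent from network",
                             call. = FALSE)
  N <- length(net$genes)
  M1 <- length(i1); M2 <- length(i2)
  inside <- c(i1, i2)
  cand <- setdiff(unique(unlist(net$adj[inside], use.names = FALSE)),
                  inside)
  score <- 0
  for (i in cand) {
    v <- net$adj[[i]]
    n1 <- sum(v %in% i1)
    n2 <- sum(v %in% i2)
    nl <- net$link_count[[i]]
    b1 <- n1 > (M1 / N) * nl
    b2 <- n2 > (M2 / N) * nl
    if (b1 && b2) {
      score <- score + net$weight[[i]]
    } else if (b1 || b2) {
      score <- score - net$weight[[i]]
    }
  }
  score
}

# cached single-gene-pair consistency score (the seed-style CT score);
# symmetric, so cached under an unordered key
ct_single <- function(net, a, b) {
  key <- if (a < b) paste0("ct\r", a, "\r", b) else paste0("ct\r", b, "\r", a)
  cache <- net$.cache
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- consistency_score_impl(net, a, b)
  assign(key, val, envir = cache)
  val
}

#' Ratio of shared interaction partners of two genes (CMRatio)
#'
#' The Jaccard index of the two genes' neighbor sets in the WPI network
#' (pooled protein and regulatory links): the number of genes linked by
#' both, over the number of genes linked by either.  Bounded in \[0, 1\]
#' and 0 when the neighborhood union is empty.
#'
#' @param net A `wpi_network`.
#' @param i,j Distinct gene ids.
#' @return The shared-partner ratio in \[0, 1\].
#' @export
cmratio <- function(net, i, j) {
  if (identical(i, j)) stop("cmratio requires two distinct genes",
                            call. = FALSE)
  key <- if (i < j) paste0("cm\r", i, "\r", j) else paste0("cm\r", j, "\r", i)
  cache <- net$.cache
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  ii <- match(i, net$genes); jj <- match(j, net$genes)
  if (is.na(ii) || is.na(jj)) stop("gene not in network", call. = FALSE)
  ni <- net$nbr[[ii]]; nj <- net$nbr[[jj]]
  u <- length(ni) + length(nj) - (shared <- length(intersect(ni, nj)))
  val <- if (u == 0L) 0 else shared / u
  assign(key, val, envir = cache)
  val
}

#' Mediation score of a candidate gene for a module (CoopMed)
#'
#' Measures how well gene `j`'s cooperation with the opposite seed gene
#' is mediated by a member of the module being extended: the best
#' mediator `i` in `m` maximizes `CMRatio(i, j) * CT(i, t_opp)`, where
#' `t_opp` is the seed gene anchoring the opposite module, and the
#' product is attenuated by the link-reliability factor `R`.  Returns 0
#' when no mediator exists (the module holds nothing besides `j` and
#' the opposite anchor); with mediators present the best product is
#' returned even when negative, so that a gene whose direct and
#' mediated consistency are both negative lowers the cooperation score
#' and can be rejected by the spanning algorithm.  The maximizing
#' mediator is attached as attribute `"mediator"`.
#'
#' @param net A `wpi_network`.
#' @param j Candidate gene id.
#' @param m The module being extended (module object or gene ids).
#' @param seed The `cm_seed`; the opposite anchor is the seed gene not
#'   contained in `m`.
#' @param R Link reliability in \[0, 1\] (default 0.9).
#' @return The mediation score (>= 0) with attribute `mediator`.
#' @export
mediation_score <- function(net, j, m, seed, R = 0.9) {
  genes <- module_genes(m)
  opp <- if (seed$s %in% genes && !seed$t %in% genes) seed$t else seed$s
  mediators <- setdiff(genes, c(j, opp))
  if (length(mediators) == 0L) {
    return(structure(0, mediator = NA_character_))
  }
  best <- -Inf
  best_med <- NA_character_
  for (i in mediators) {
    p <- cmratio(net, i, j) * ct_single(net, i, opp)
    if (p > best) {
      best <- p
      best_med <- i
    }
  }
  structure(R * best, mediator = best_med)
}

#' Cooperation score of a module pair (MCoop score)
#'
#' The objective of the spanning algorithm: the seed's consistency score
#' plus, for every non-anchor member of each module, the better of its
#' direct consistency with the opposite seed gene and its mediation
#' score through the module it belongs to.
#'
#' @param net A `wpi_network`.
#' @param pair A `cm_module_pair` (modules disjoint, anchors present).
#' @param R Link reliability passed to [mediation_score()].
#' @return The cooperation score.
#' @export
cooperation_score <- function(net, pair, R = 0.9) {
  stopifnot(inherits(pair, "cm_module_pair"))
  m1 <- pair$m1; m2 <- pair$m2; seed <- pair$seed
  if (!seed$s %in% m1$genes || !seed$t %in% m2$genes) {
    stop("anchors missing from modules", call. = FALSE)
  }
  if (length(intersect(m1$genes, m2$genes)) > 0L) {
    stop("modules must be disjoint", call. = FALSE)
  }
  score <- ct_single(net, seed$s, seed$t)
  for (u in setdiff(m1$genes, seed$s)) {
    score <- score + max(ct_single(net, u, seed$t),
                         as.numeric(mediation_score(net, u, m1, seed, R)))
  }
  for (v in setdiff(m2$genes, seed$t)) {
    score <- score + max(ct_single(net, v, seed$s),
                         as.numeric(mediation_score(net, v, m2, seed, R)))
  }
  score
}

# ---- fast all-pairs machinery for seed selection -------------------------

# Sparse "strong link" indicator B[i, s]: gene i has more links to s than
# the size-1 expectation NL_i / N.  Used to evaluate all singleton-pair
# consistency scores at once:
#   CT(s, t) = 3 * (B' W B)[s, t] - c_s - c_t + w_t B[t, s] + w_s B[s, t]
# with c = colSums(W B); identical to the per-pair definition because
# B[i, i] = 0 (no self-links).
strong_link_matrix <- function(net) {
  n <- length(net$genes)
  pi1 <- match(net$ppi[, 1L], net$genes)
  pi2 <- match(net$ppi[, 2L], net$genes)
  ri1 <- match(net$reg[, 1L], net$genes)
  ri2 <- match(net$reg[, 2L], net$genes)
  A <- Matrix::sparseMatrix(i = c(pi1, pi2, ri1, ri2),
                            j = c(pi2, pi1, ri2, ri1),
                            x = 1, dims = c(n, n))
  nl <- as.numeric(net$link_count)
  B <- A > (nl / n)            # row-wise expectation, column-major recycle
  B * 1
}

# All singleton-pair consistency scores as a dense n x n matrix, plus the
# candidate-pair mask (pairs with at least one strong external linker).
consistency_pair_scores <- function(net) {
  B <- strong_link_matrix(net)
  n <- length(net$genes)
  w <- as.numeric(net$weight)
  WB <- B * w                   # row-scaled: WB[i, s] = w_i * B[i, s]
  M <- as.matrix(Matrix::crossprod(B, WB))
  cs <- Matrix::colSums(WB)
  WBd <- as.matrix(WB)
  ones <- rep(1, n)
  # i = s and i = t must not enter the sums; B[i, i] = 0 already removes
  # i = s from c_s, the transposed-correction terms remove i = t.
  score <- 3 * M - outer(cs, ones) - outer(ones, cs) + WBd + t(WBd)
  Bd <- as.matrix(B)
  cnt <- Matrix::colSums(B)
  ext <- outer(cnt, ones) + outer(ones, cnt) - Bd - t(Bd)
  dimnames(score) <- list(net$genes, net$genes)
  cand <- ext > 0
  dimnames(cand) <- dimnames(score)
  list(score = score, candidate = cand)
}

#' Enumerate seed candidate gene pairs
#'
#' Returns the unordered gene pairs that can have a nonzero singleton
#' consistency score: pairs for which at least one third gene is linked
#' above expectation to either member.  This restricts the quadratic
#' all-pairs scan without excluding any scoring pair.
#'
#' @param net A `wpi_network`.
#' @return A two-column character matrix of gene pairs (lexicographically
#'   ordered within and across rows).
#' @export
enumerate_seed_candidates <- function(net) {
  ps <- consistency_pair_scores(net)
  hit <- which(ps$candidate & upper.tri(ps$candidate), arr.ind = TRUE)
  out <- cbind(net$genes[hit[, 1L]], net$genes[hit[, 2L]])
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}
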