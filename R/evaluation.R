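#' Upper-tail hypergeometric probability
#'
#' `P(X >= b)` for `X` hypergeometric with population size `G`, `B`
#' successes in the population and `C` draws.  Computed in log space via
#' [stats::phyper()], numerically stable for genome-scale `G`.
#'
#' @param G Population (universe) size.
#' @param B Number of successes in the population (gene set size).
#' @param C Number of draws (correlated-gene count).
#' @param b Observed overlap.
#' @return The upper-tail probability `P(X >= b)`.
#' @export
hypergeom_tail <- function(G, B, C, b) {
  if (b > C || b > B || B > G || C > G || min(G, B, C, b) < 0) {
    stop("invalid hypergeometric parameters", call. = FALSE)
  }
  if (b == 0L) return(1)
  exp(stats::phyper(b - 1, m = B, n = G - B, k = C, lower.tail = FALSE,
                    log.p = TRUE))
}

#' Gene-set association of a module pair's correlated genes
#'
#' Tests whether the correlated genes of a module pair overlap a named
#' gene set more than expected by chance, with an upper-tail
#' hypergeometric test over a fixed gene universe.  Significance uses a
#' strict `p < alpha` comparison and no multiple-testing correction by
#' default (a `p_adjust_method` hook is provided).
#'
#' @param correlated_genes Character vector of the pair's correlated
#'   gene ids.
#' @param set Named list element or character vector of gene set
#'   members; may also be a one-element named list.
#' @param universe Universe size `G` (typically the number of genes in
#'   the WPI network), or a character vector of universe gene ids.
#' @param alpha Significance level (default 0.05).
#' @param set_name Label for the output.
#' @param pair_id Pair identifier for the output.
#' @return A one-row data frame with columns `pair_id`, `set_name`, `G`,
#'   `C`, `B`, `b`, `p_value`, `significant`.
#' @export
pair_geneset_significance <- function(correlated_genes, set, universe,
                                      alpha = 0.05, set_name = "set",
                                      pair_id = NA_integer_) {
  set_genes <- if (is.list(set)) {
    if (!is.null(names(set)) && length(set) == 1L) set_name <- names(set)
    unlist(set, use.names = FALSE)
  } else {
    as.character(set)
  }
  if (is.character(universe)) {
    set_genes <- intersect(set_genes, universe)
    correlated_genes <- intersect(correlated_genes, universe)
    G <- length(universe)
  } else {
    G <- as.integer(universe)
  }
  C <- length(unique(correlated_genes))
  B <- length(unique(set_genes))
  b <- length(intersect(unique(correlated_genes), unique(set_genes)))
  if (C == 0L) {
    cm_log("empty correlated-gene list: p = 1", level = "debug")
    p <- 1
  } else {
    p <- hypergeom_tail(G, B, C, b)
  }
  data.frame(pair_id = pair_id, set_name = set_name, G = G, C = C,
             B = B, b = b, p_value = p, significant = p < alpha,
             stringsAsFactors = FALSE)
}

#' Rank phase-related module pairs
#'
#' Among the pairs significant for a phase, ranks by the number of
#' phase-regulated correlated genes (`b`, descending), breaking ties by
#' p-value (ascending) then pair id, and returns the top `k` per phase.
#'
#' @param results Data frame of [pair_geneset_significance()] rows, one
#'   per (pair, phase set), with `set_name` holding the phase label.
#' @param k Number of top pairs to keep per phase (default 3).
#' @return A data frame of the top-k rows per phase with a `rank`
#'   column, ordered by phase then rank.
#' @export
rank_phase_pairs <- function(results, k = 3L) {
  if (nrow(results) == 0L) return(cbind(results, rank = integer()))
  out <- list()
  for (ph in unique(results$set_name)) {
    sub <- results[results$set_name == ph & results$significant, ,
                   drop = FALSE]
    if (nrow(sub) == 0L) next
    o <- order(-sub$b, sub$p_value, sub$pair_id)
    sub <- sub[o[seq_len(min(k, nrow(sub)))], , drop = FALSE]
    sub$rank <- seq_len(nrow(sub))
    out[[ph]] <- sub
  }
  if (length(out) == 0L) {
    return(cbind(results[0, , drop = FALSE], rank = integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# count pooled physical links with both endpoints in `a` (within) or one
# endpoint in each of `a`, `b` (between)
count_internal_links <- function(ppi, reg, a, b = NULL) {
  cnt <- 0L
  for (edges in list(ppi, reg)) {
    if (nrow(edges) == 0L) next
    x <- edges[, 1L]; y <- edges[, 2L]
    if (is.null(b)) {
      cnt <- cnt + sum(x %in% a & y %in% a)
    } else {
      cnt <- cnt + sum((x %in% a & y %in% b) | (x %in% b & y %in% a))
    }
  }
  cnt
}

count_coexpressed_pairs <- function(expr, a, b = NULL, threshold = 0.683) {
  a <- intersect(a, rownames(expr))
  if (is.null(b)) {
    if (length(a) < 2L) return(0L)
    cm <- suppressWarnings(stats::cor(t(expr[a, , drop = FALSE])))
    sum(abs(cm[upper.tri(cm)]) >= threshold, na.rm = TRUE)
  } else {
    b <- intersect(b, rownames(expr))
    if (length(a) == 0L || length(b) == 0L) return(0L)
    cm <- suppressWarnings(stats::cor(t(expr[a, , drop = FALSE]),
                                      t(expr[b, , drop = FALSE])))
    sum(abs(cm) >= threshold, na.rm = TRUE)
  }
}

#' Significance of correlations within and between modules
#'
#' For each module, the number of pooled physical links among its genes
#' is compared with the same count in degree-preserving rewired
#' networks; for each pair, the crosstalk links between its two modules
#' are tested the same way.  Co-expression is tested analogously: the
#' number of gene pairs with `|r| >= threshold` within (and between)
#' modules is compared against expression matrices in which every gene's
#' profile is independently permuted across conditions, which preserves
#' per-gene marginals while destroying pairwise correlation.  All
#' p-values are add-one empirical upper tails.
#'
#' @param net A `wpi_network`.
#' @param expr Expression matrix (genes x conditions).
#' @param modules List of `cm_module`.
#' @param pairs List of `cm_module_pair`.
#' @param cfg A `null_model_config`.
#' @param nulls Optional precomputed network ensemble.
#' @param threshold Co-expression cutoff (default 0.683).
#' @return A list of two data frames: `modules` (`module_id`, `size`,
#'   `p_physical_within`, `p_coexpr_within`) and `pairs` (`pair_id`,
#'   `p_physical_between`, `p_coexpr_between`).
#' @export
module_correlation_significance <- function(net, expr, modules, pairs,
                                            cfg = null_model_config(),
                                            nulls = NULL,
                                            threshold = 0.683) {
  if (is.null(nulls)) nulls <- make_null_ensemble(net, cfg)
  nr <- length(nulls)
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed + 1L)

  obs_w_phys <- vapply(modules, function(m)
    count_internal_links(net$ppi, net$reg, m$genes), integer(1L))
  obs_b_phys <- vapply(pairs, function(p)
    count_internal_links(net$ppi, net$reg, p$m1$genes, p$m2$genes),
    integer(1L))
  ge_w_phys <- integer(length(modules))
  ge_b_phys <- integer(length(pairs))
  for (e in nulls) {
    nw <- vapply(modules, function(m)
      count_internal_links(e$ppi, e$reg, m$genes), integer(1L))
    nb <- vapply(pairs, function(p)
      count_internal_links(e$ppi, e$reg, p$m1$genes, p$m2$genes),
      integer(1L))
    ge_w_phys <- ge_w_phys + (nw >= obs_w_phys)
    ge_b_phys <- ge_b_phys + (nb >= obs_b_phys)
  }

  obs_w_co <- vapply(modules, function(m)
    count_coexpressed_pairs(expr, m$genes, threshold = threshold),
    integer(1L))
  obs_b_co <- vapply(pairs, function(p)
    count_coexpressed_pairs(expr, p$m1$genes, p$m2$genes,
                            threshold = threshold), integer(1L))
  ge_w_co <- integer(length(modules))
  ge_b_co <- integer(length(pairs))
  for (r in seq_len(nr)) {
    perm <- t(apply(expr, 1L, sample))
    rownames(perm) <- rownames(expr)
    nw <- vapply(modules, function(m)
      count_coexpressed_pairs(perm, m$genes, threshold = threshold),
      integer(1L))
    nb <- vapply(pairs, function(p)
      count_coexpressed_pairs(perm, p$m1$genes, p$m2$genes,
                              threshold = threshold), integer(1L))
    ge_w_co <- ge_w_co + (nw >= obs_w_co)
    ge_b_co <- ge_b_co + (nb >= obs_b_co)
  }

  list(
    modules = data.frame(
      module_id = vapply(modules, function(m) m$id, integer(1L)),
      size = vapply(modules, function(m) length(m$genes), integer(1L)),
      physical_within = obs_w_phys,
      p_physical_within = (1 + ge_w_phys) / (1 + nr),
      coexpr_within = obs_w_co,
      p_coexpr_within = (1 + ge_w_co) / (1 + nr),
      stringsAsFactors = FALSE),
    pairs = data.frame(
      pair_id = vapply(pairs, function(p)
        if (is.null(p$pair_id)) NA_integer_ else p$pair_id, integer(1L)),
      physical_between = obs_b_phys,
      p_physical_between = (1 + ge_b_phys) / (1 + nr),
      coexpr_between = obs_b_co,
      p_coexpr_between = (1 + ge_b_co) / (1 + nr),
      stringsAsFactors = FALSE)
  )
}
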