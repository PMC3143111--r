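#' Pearson correlation of two expression profiles
#'
#' A thin, checked wrapper around [stats::cor()] used when screening gene
#' pairs for co-expression.  Profiles must have equal length (at least 3
#' conditions) and nonzero variance; a zero-variance profile makes the
#' correlation undefined and raises an error so the pair can be skipped
#' and logged upstream.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return The Pearson correlation coefficient, in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    stop("profiles have unequal lengths", call. = FALSE)
  }
  if (length(x) < 3L) {
    stop("need >= 3 conditions for a Pearson correlation", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("undefined correlation: zero-variance profile", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Build a co-expression network by thresholding pairwise correlations
#'
#' Gene pairs whose Pearson correlation is at least `threshold` in
#' absolute value become edges; both strong positive and strong negative
#' co-expression qualify.  The default cutoff of 0.683 is the
#' significance threshold used for the yeast cell cycle expression
#' compendium this method was developed on.  The sign of each edge is
#' retained as an attribute but is not used downstream.
#'
#' @param expr Numeric matrix, genes in rows (row names = gene ids),
#'   conditions in columns.
#' @param threshold Absolute-correlation cutoff in (0, 1].
#' @return An object of class `coexpression_network`: a list with
#'   `nodes` (gene ids), `edges` (two-column character matrix) and `r`
#'   (numeric vector of edge correlations).
#' @export
build_coexpression_network <- function(expr, threshold = 0.683) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (!(threshold > 0 && threshold <= 1)) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  genes <- rownames(expr)
  if (nrow(expr) < 2L) {
    cm_log("fewer than 2 genes: empty co-expression network",
           level = "warn")
    return(structure(list(nodes = genes,
                          edges = matrix(character(), ncol = 2L),
                          r = numeric()),
                     class = "coexpression_network"))
  }
  if (ncol(expr) < 3L) {
    stop("need >= 3 conditions", call. = FALSE)
  }
  sds <- apply(expr, 1L, stats::sd)
  flat <- sds == 0
  if (any(flat)) {
    cm_log(sum(flat), " zero-variance gene(s) skipped in co-expression ",
           "screen")
  }
  keep <- genes[!flat]
  edges <- matrix(character(), ncol = 2L)
  rvals <- numeric()
  if (length(keep) >= 2L) {
    cmat <- suppressWarnings(stats::cor(t(expr[keep, , drop = FALSE])))
    hit <- which(abs(cmat) >= threshold & upper.tri(cmat), arr.ind = TRUE)
    if (nrow(hit) > 0L) {
      edges <- cbind(keep[hit[, 1L]], keep[hit[, 2L]])
      rvals <- cmat[hit]
    }
  }
  structure(list(nodes = genes, edges = edges, r = rvals),
            class = "coexpression_network")
}

#' Co-expression degree of every gene in a universe
#'
#' The degree of a gene in the co-expression network is its weight in the
#' WPI network; genes absent from the co-expression network get weight 0.
#'
#' @param coexp A `coexpression_network`.
#' @param universe Character vector of gene ids to report weights for.
#' @return A named integer vector over `universe`.
#' @export
compute_gene_weights <- function(coexp, universe) {
  stopifnot(inherits(coexp, "coexpression_network"))
  w <- setNames(integer(length(universe)), universe)
  if (nrow(coexp$edges) > 0L) {
    tab <- table(factor(c(coexp$edges[, 1L], coexp$edges[, 2L]),
                        levels = universe))
    w[] <- as.integer(tab)
  }
  w
}

# canonicalize an undirected edge matrix: sort within rows, dedup,
# drop self-loops; returns list(edges, n_self, n_dup)
canon_undirected <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0L) {
    return(list(edges = matrix(character(), ncol = 2L), n_self = 0L,
                n_dup = 0L))
  }
  a <- pmin(edges[, 1L], edges[, 2L])
  b <- pmax(edges[, 1L], edges[, 2L])
  self <- a == b
  a <- a[!self]; b <- b[!self]
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  list(edges = cbind(a[!dup], b[!dup]), n_self = sum(self),
       n_dup = sum(dup))
}

canon_directed <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0L) {
    return(list(edges = matrix(character(), ncol = 2L), n_self = 0L,
                n_dup = 0L))
  }
  a <- edges[, 1L]; b <- edges[, 2L]
  self <- a == b
  a <- a[!self]; b <- b[!self]
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  list(edges = cbind(a[!dup], b[!dup]), n_self = sum(self),
       n_dup = sum(dup))
}

#' Assemble the weighted physical interaction (WPI) network
#'
#' Combines undirected protein-protein interaction pairs, directed
#' regulatory (TF, target) pairs and per-gene co-expression weights into
#' one network object.  The gene universe is the union of all edge
#' endpoints plus any `extra_genes`.  Self-loops are dropped and
#' duplicate edges are deduplicated within each edge kind (both logged).
#'
#' Link counting: each undirected protein pair contributes one link to
#' both endpoints, and each directed regulatory pair contributes one link
#' to both endpoints regardless of direction; a gene pair connected by
#' both kinds therefore contributes two links to each endpoint.
#' Direction is retained as metadata for the regulatory edge set.
#'
#' @param ppi_edges Two-column character matrix of undirected pairs.
#' @param reg_edges Two-column character matrix of (TF, target) pairs.
#' @param weights Named numeric vector of co-expression degrees (genes
#'   absent get weight 0).
#' @param extra_genes Additional gene ids to include in the universe.
#' @return An object of class `wpi_network` with elements `genes`,
#'   `weight`, `ppi`, `reg`, `link_count` and internal adjacency indexes.
#' @export
assemble_wpi <- function(ppi_edges, reg_edges,
                         weights = numeric(), extra_genes = character()) {
  ppi <- canon_undirected(ppi_edges)
  reg <- canon_directed(reg_edges)
  if (ppi$n_self + reg$n_self > 0L) {
    cm_log(ppi$n_self + reg$n_self, " self-loop(s) dropped")
  }
  if (ppi$n_dup + reg$n_dup > 0L) {
    cm_log(ppi$n_dup + reg$n_dup, " duplicate edge(s) deduplicated")
  }
  if (nrow(ppi$edges) + nrow(reg$edges) == 0L) {
    stop("empty combined edge set: no network to analyze", call. = FALSE)
  }
  genes <- sort(unique(c(ppi$edges, reg$edges, extra_genes)))
  n <- length(genes)
  w <- setNames(numeric(n), genes)
  shared <- intersect(names(weights), genes)
  w[shared] <- weights[shared]

  pi1 <- match(ppi$edges[, 1L], genes); pi2 <- match(ppi$edges[, 2L], genes)
  ri1 <- match(reg$edges[, 1L], genes); ri2 <- match(reg$edges[, 2L], genes)
  # multiset adjacency over pooled links (one entry per incident link)
  adj <- split(c(pi2, pi1, ri2, ri1),
               factor(c(pi1, pi2, ri1, ri2), levels = seq_len(n)))
  adj <- lapply(adj, as.integer)
  nbr <- lapply(adj, function(v) sort(unique(v)))
  link_count <- setNames(lengths(adj), genes)
  names(adj) <- names(nbr) <- genes

  structure(list(genes = genes,
                 weight = w,
                 ppi = ppi$edges,
                 reg = reg$edges,
                 link_count = link_count,
                 adj = adj,
                 nbr = nbr,
                 .cache = new.env(parent = emptyenv())),
            class = "wpi_network")
}

#' @export
print.wpi_network <- function(x, ...) {
  cat(sprintf(paste0("wpi_network: %d genes, %d protein links, ",
                     "%d regulatory links, total weight %d\n"),
              length(x$genes), nrow(x$ppi), nrow(x$reg),
              as.integer(sum(x$weight))))
  invisible(x)
}

#' Build a WPI network directly from expression and edge data
#'
#' Convenience composition of [build_coexpression_network()],
#' [compute_gene_weights()] and [assemble_wpi()].  The gene universe is
#' taken from the interaction and regulatory data; expression-only genes
#' are not added (co-expression only sets node weights).
#'
#' @param expr Expression matrix (genes x conditions).
#' @param ppi_edges,reg_edges Edge matrices as for [assemble_wpi()].
#' @param threshold Co-expression cutoff passed on.
#' @param extra_genes Optional extra universe genes.
#' @return A `wpi_network`.
#' @export
build_wpi_network <- function(expr, ppi_edges, reg_edges,
                              threshold = 0.683,
                              extra_genes = character()) {
  coexp <- build_coexpression_network(expr, threshold = threshold)
  universe <- sort(unique(c(ppi_edges, reg_edges, extra_genes)))
  w <- compute_gene_weights(coexp, universe)
  assemble_wpi(ppi_edges, reg_edges, weights = w,
               extra_genes = extra_genes)
}

# recompute link counts from stored edge sets (invariant check helper)
recompute_link_count <- function(net) {
  n <- length(net$genes)
  cnt <- setNames(integer(n), net$genes)
  add <- function(ids) {
    t <- table(factor(ids, levels = net$genes))
    cnt <<- cnt + as.integer(t)
  }
  if (nrow(net$ppi) > 0L) add(c(net$ppi[, 1L], net$ppi[, 2L]))
  if (nrow(net$reg) > 0L) add(c(net$reg[, 1L], net$reg[, 2L]))
  cnt
}
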