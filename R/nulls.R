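#' Null model configuration
#'
#' Settings for the degree-preserving random-network null used to judge
#' the significance of gene-module link counts.
#'
#' @param n_random Number of randomized networks (default 1000).
#' @param swaps_per_edge Attempted double-edge swaps per edge (default
#'   10).
#' @param alpha Significance level for empirical p-values (default
#'   0.05).
#' @param rng_seed Optional integer seed; when given, the generator is
#'   seeded before the ensemble is drawn so results are reproducible.
#' @return A `null_model_config` list.
#' @export
null_model_config <- function(n_random = 1000L, swaps_per_edge = 10L,
                              alpha = 0.05, rng_seed = NULL) {
  stopifnot(n_random >= 1L, alpha > 0, alpha < 1, swaps_per_edge >= 1L)
  structure(list(n_random = as.integer(n_random),
                 swaps_per_edge = as.integer(swaps_per_edge),
                 alpha = alpha, rng_seed = rng_seed),
            class = "null_model_config")
}

# rewire one edge matrix with double-edge swaps; returns a matrix of the
# same shape.  Undirected swaps preserve the degree sequence, directed
# swaps preserve every in- and out-degree; swaps creating self-loops or
# duplicate edges are rejected by igraph.
rewire_edges <- function(edges, genes, directed, swaps_per_edge) {
  ne <- nrow(edges)
  if (ne < 2L) return(edges)
  g <- igraph::graph_from_edgelist(edges, directed = directed)
  g <- igraph::rewire(g, igraph::keeping_degseq(
    loops = FALSE, niter = swaps_per_edge * ne))
  igraph::as_edgelist(g)
}

#' Degree-preserving randomization of a WPI network
#'
#' Protein edges are randomized by undirected double-edge swaps that
#' preserve every gene's protein degree exactly; regulatory edges by
#' directed swaps preserving every in- and out-degree.  Swaps that would
#' create self-loops or duplicate edges are rejected.  Node weights and
#' the gene universe are carried over unchanged.
#'
#' @param net A `wpi_network`.
#' @param swaps_per_edge Attempted swaps per edge in each edge set.
#' @return A rewired `wpi_network`.
#' @export
rewire_degree_preserving <- function(net, swaps_per_edge = 10L) {
  ppi <- rewire_edges(net$ppi, net$genes, directed = FALSE,
                      swaps_per_edge = swaps_per_edge)
  reg <- rewire_edges(net$reg, net$genes, directed = TRUE,
                      swaps_per_edge = swaps_per_edge)
  assemble_wpi(ppi, reg, weights = net$weight, extra_genes = net$genes)
}

#' Draw an ensemble of degree-preserving null networks
#'
#' Generates `n_random` independently rewired copies of the network's
#' edge sets.  The ensemble is generated once per analysis run and
#' reused across genes and module pairs so that all empirical p-values
#' are computed against the same exchangeable null.
#'
#' @param net A `wpi_network`.
#' @param cfg A `null_model_config`.
#' @return A list of `n_random` elements, each `list(ppi =, reg =)` edge
#'   matrices.
#' @export
make_null_ensemble <- function(net, cfg = null_model_config()) {
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  lapply(seq_len(cfg$n_random), function(k) {
    list(ppi = rewire_edges(net$ppi, net$genes, directed = FALSE,
                            swaps_per_edge = cfg$swaps_per_edge),
         reg = rewire_edges(net$reg, net$genes, directed = TRUE,
                            swaps_per_edge = cfg$swaps_per_edge))
  })
}

# per-gene link counts into a module, for all genes at once.
# kind: "ppi" (undirected), "reg_in" (module -> gene), "reg_out"
# (gene -> module).  Self-links never arise (no self-loops).
count_links_to_module <- function(edges, members, genes, kind) {
  if (nrow(edges) == 0L) {
    return(setNames(integer(length(genes)), genes))
  }
  a <- edges[, 1L]; b <- edges[, 2L]
  vec <- switch(kind,
    ppi = c(a[b %in% members], b[a %in% members]),
    reg_in = b[a %in% members],
    reg_out = a[b %in% members],
    stop("unknown link kind: ", kind, call. = FALSE))
  cnt <- table(factor(vec, levels = genes))
  setNames(as.integer(cnt), genes)
}

obs_count_matrix <- function(ppi, reg, m1, m2, genes) {
  cbind(
    ppi_m1     = count_links_to_module(ppi, m1, genes, "ppi"),
    ppi_m2     = count_links_to_module(ppi, m2, genes, "ppi"),
    reg_in_m1  = count_links_to_module(reg, m1, genes, "reg_in"),
    reg_in_m2  = count_links_to_module(reg, m2, genes, "reg_in"),
    reg_out_m1 = count_links_to_module(reg, m1, genes, "reg_out"),
    reg_out_m2 = count_links_to_module(reg, m2, genes, "reg_out")
  )
}

#' Empirical p-value for a gene-module link count
#'
#' Upper-tail add-one empirical p-value: the probability, under
#' degree-preserving rewiring, of seeing at least the observed number of
#' links of the given kind between the gene and the module.
#' `p = (1 + #\{null >= observed\}) / (1 + n_random)`, bounded in
#' `[1/(n_random + 1), 1]`.
#'
#' @param net A `wpi_network`.
#' @param gene Gene id.
#' @param module Module or gene id vector.
#' @param link_kind One of `"ppi"`, `"reg_in"` (module regulates gene),
#'   `"reg_out"` (gene regulates module).
#' @param cfg A `null_model_config`.
#' @param nulls Optional precomputed ensemble from
#'   [make_null_ensemble()]; drawn fresh otherwise.
#' @return The empirical p-value.
#' @export
link_count_pvalue <- function(net, gene, module,
                              link_kind = c("ppi", "reg_in", "reg_out"),
                              cfg = null_model_config(), nulls = NULL) {
  link_kind <- match.arg(link_kind)
  members <- setdiff(module_genes(module), gene)
  if (is.null(nulls)) nulls <- make_null_ensemble(net, cfg)
  pick <- function(e) if (link_kind == "ppi") e$ppi else e$reg
  obs <- count_links_to_module(pick(list(ppi = net$ppi, reg = net$reg)),
                               members, net$genes, link_kind)[[gene]]
  ge <- 0L
  for (e in nulls) {
    nullcnt <- count_links_to_module(pick(e), members, net$genes,
                                     link_kind)[[gene]]
    if (nullcnt >= obs) ge <- ge + 1L
  }
  (1 + ge) / (1 + length(nulls))
}

#' Classify a correlated gene into one of five cooperation types
#'
#' Given the six empirical p-values of a gene against the two modules of
#' a pair, determines which association patterns are significant at
#' `alpha`:
#' \describe{
#'   \item{A}{protein links to one module and regulatory links from the
#'     other module to the gene}
#'   \item{B}{protein links to one module and regulatory links from the
#'     gene into the other module}
#'   \item{C}{protein links to both modules}
#'   \item{D}{regulatory links from both modules to the gene}
#'   \item{E}{regulatory links from the gene into both modules}
#' }
#' When several patterns hold, all are reported and the primary label
#' follows the priority C > D > E > A > B (symmetric types first).
#'
#' @param evidence Named numeric vector with elements `ppi_m1`,
#'   `ppi_m2`, `reg_in_m1`, `reg_in_m2`, `reg_out_m1`, `reg_out_m2`.
#' @param alpha Significance level.
#' @return A list with `primary` (single letter) and `all` (character
#'   vector of all satisfied types).
#' @export
classify_cooperation_type <- function(evidence, alpha = 0.05) {
  sig <- evidence <= alpha
  types <- character()
  if (sig[["ppi_m1"]] && sig[["ppi_m2"]]) types <- c(types, "C")
  if (sig[["reg_in_m1"]] && sig[["reg_in_m2"]]) types <- c(types, "D")
  if (sig[["reg_out_m1"]] && sig[["reg_out_m2"]]) types <- c(types, "E")
  if ((sig[["ppi_m1"]] && sig[["reg_in_m2"]]) ||
      (sig[["ppi_m2"]] && sig[["reg_in_m1"]])) types <- c(types, "A")
  if ((sig[["ppi_m1"]] && sig[["reg_out_m2"]]) ||
      (sig[["ppi_m2"]] && sig[["reg_out_m1"]])) types <- c(types, "B")
  if (length(types) == 0L) {
    stop("no qualifying cooperation pattern: caller filtered incorrectly",
         call. = FALSE)
  }
  prio <- c("C", "D", "E", "A", "B")
  types <- prio[prio %in% types]
  list(primary = types[[1L]], all = types)
}

#' Identify genes correlated with both modules of a pair
#'
#' For every gene in the network, computes six empirical p-values
#' (protein links to each module; regulatory links from each module to
#' the gene; regulatory links from the gene into each module) against a
#' shared degree-preserving null ensemble, retains genes with at least
#' one significant association to each module, and classifies each into
#' a cooperation type.
#'
#' @param net A `wpi_network`.
#' @param pair A `cm_module_pair`.
#' @param cfg A `null_model_config`.
#' @param nulls Optional precomputed ensemble (reused across pairs).
#' @return A data frame with columns `gene`, `pair_id`, the six p-value
#'   columns (prefixed `p_`), `coop_type` and `coop_types_all`.
#' @export
identify_correlated_genes <- function(net, pair,
                                      cfg = null_model_config(),
                                      nulls = NULL) {
  stopifnot(inherits(pair, "cm_module_pair"))
  if (is.null(nulls)) nulls <- make_null_ensemble(net, cfg)
  g1 <- pair$m1$genes
  g2 <- pair$m2$genes
  genes <- net$genes
  obs <- obs_count_matrix(net$ppi, net$reg, g1, g2, genes)
  ge <- matrix(0L, nrow = length(genes), ncol = 6L,
               dimnames = dimnames(obs))
  for (e in nulls) {
    nullcnt <- obs_count_matrix(e$ppi, e$reg, g1, g2, genes)
    ge <- ge + (nullcnt >= obs)
  }
  p <- (1 + ge) / (1 + length(nulls))
  sig <- p <= cfg$alpha
  m1_sig <- sig[, "ppi_m1"] | sig[, "reg_in_m1"] | sig[, "reg_out_m1"]
  m2_sig <- sig[, "ppi_m2"] | sig[, "reg_in_m2"] | sig[, "reg_out_m2"]
  keep <- which(m1_sig & m2_sig)
  pid <- if (!is.null(pair$pair_id)) pair$pair_id else NA_integer_
  rows <- lapply(keep, function(i) {
    cls <- classify_cooperation_type(p[i, ], cfg$alpha)
    data.frame(gene = genes[[i]], pair_id = pid,
               p_ppi_m1 = p[i, "ppi_m1"], p_ppi_m2 = p[i, "ppi_m2"],
               p_reg_in_m1 = p[i, "reg_in_m1"],
               p_reg_in_m2 = p[i, "reg_in_m2"],
               p_reg_out_m1 = p[i, "reg_out_m1"],
               p_reg_out_m2 = p[i, "reg_out_m2"],
               coop_type = cls$primary,
               coop_types_all = paste(cls$all, collapse = ","),
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(gene = character(), pair_id = integer(),
                      p_ppi_m1 = numeric(), p_ppi_m2 = numeric(),
                      p_reg_in_m1 = numeric(), p_reg_in_m2 = numeric(),
                      p_reg_out_m1 = numeric(),
                      p_reg_out_m2 = numeric(),
                      coop_type = character(),
                      coop_types_all = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
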