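#' Build the cooperative module network (CMN)
#'
#' One node per merged module (with its size as an attribute), one
#' undirected edge per retained cooperative module pair.  Duplicate
#' pairs collapse to a single edge.
#'
#' @param result A `cm_discovery` (or a list with `modules` and `pairs`).
#' @return An undirected [igraph::igraph] graph with vertex attributes
#'   `size` and `label`, and edge attribute `pair_id`.
#' @export
build_cmn <- function(result) {
  modules <- result$modules
  pairs <- result$pairs
  ids <- vapply(modules, function(m) as.character(m$id), character(1L))
  sizes <- vapply(modules, function(m) length(m$genes), integer(1L))
  vertices <- data.frame(name = ids, size = sizes,
                         label = paste0("module_", ids),
                         stringsAsFactors = FALSE)
  if (length(pairs) == 0L) {
    return(igraph::graph_from_data_frame(
      data.frame(from = character(), to = character(),
                 pair_id = integer()),
      directed = FALSE, vertices = vertices))
  }
  e1 <- vapply(pairs, function(p) as.character(min(p$m1$id, p$m2$id)),
               character(1L))
  e2 <- vapply(pairs, function(p) as.character(max(p$m1$id, p$m2$id)),
               character(1L))
  pid <- vapply(pairs, function(p)
    if (is.null(p$pair_id)) NA_integer_ else p$pair_id, integer(1L))
  key <- paste(e1, e2)
  keep <- !duplicated(key)
  edges <- data.frame(from = e1[keep], to = e2[keep],
                      pair_id = pid[keep], stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = vertices)
}

#' Build the per-phase regulator-mediated relationship graph
#'
#' Considers every (retained pair, phase regulator) combination where
#' the regulator is a correlated gene of the pair, and draws module-level
#' edges according to the kind of significant association: an undirected
#' (protein-mediated) edge between the module and the regulator's node,
#' a directed (transcriptional) edge from the regulator's node into a
#' module it significantly regulates, and a directed edge from a module
#' into the regulator's node when the module's genes significantly
#' regulate it.  The regulator's node is each module containing it, or a
#' dedicated regulator node when it belongs to no module.  Parallel
#' edges of identical endpoints, direction and type collapse to one edge
#' carrying the list of mediating regulators; nodes without any edge are
#' excluded.
#'
#' @param pairs List of retained `cm_module_pair`.
#' @param correlated Data frame from [identify_correlated_genes()]
#'   (rows for all pairs, with `pair_id`).
#' @param regulators Character vector of the phase's regulator gene ids.
#' @param modules List of merged `cm_module` (for module membership).
#' @param phase Phase label attached to the graph and its edges.
#' @param alpha Significance level applied to the stored p-values.
#' @return A directed [igraph::igraph]; undirected protein-mediated
#'   associations are encoded as edge attribute `directed = FALSE` (and
#'   drawn once, from the lexicographically smaller endpoint).  Edge
#'   attributes: `type` (`ppi`/`transcriptional`), `phase`,
#'   `regulators`, `pair_ids`.
#' @export
build_phase_graph <- function(pairs, correlated, regulators, modules,
                              phase, alpha = 0.05) {
  if (is.null(phase) || is.na(phase) || !nzchar(phase)) {
    stop("unknown phase label", call. = FALSE)
  }
  membership <- list()
  for (m in modules) {
    for (g in m$genes) {
      membership[[g]] <- c(membership[[g]], paste0("module_", m$id))
    }
  }
  node_of <- function(gene) {
    if (!is.null(membership[[gene]])) membership[[gene]] else
      paste0("gene_", gene)
  }
  acc <- new.env(parent = emptyenv())
  add_edge <- function(a, b, directed, type, reg, pid) {
    if (identical(a, b)) return(invisible(NULL))
    if (!directed && a > b) { tmp <- a; a <- b; b <- tmp }
    key <- paste(a, b, directed, type, sep = "\r")
    cur <- acc[[key]]
    if (is.null(cur)) {
      cur <- list(from = a, to = b, directed = directed, type = type,
                  regulators = character(), pair_ids = integer())
    }
    cur$regulators <- union(cur$regulators, reg)
    cur$pair_ids <- union(cur$pair_ids, pid)
    assign(key, cur, envir = acc)
    invisible(NULL)
  }
  for (p in pairs) {
    pid <- if (is.null(p$pair_id)) NA_integer_ else p$pair_id
    sub <- correlated[correlated$pair_id %in% pid &
                        correlated$gene %in% regulators, , drop = FALSE]
    for (r in seq_len(nrow(sub))) {
      x <- sub$gene[[r]]
      xnodes <- node_of(x)
      mods <- list(list(node = paste0("module_", p$m1$id),
                        ppi = sub$p_ppi_m1[[r]],
                        reg_in = sub$p_reg_in_m1[[r]],
                        reg_out = sub$p_reg_out_m1[[r]]),
                   list(node = paste0("module_", p$m2$id),
                        ppi = sub$p_ppi_m2[[r]],
                        reg_in = sub$p_reg_in_m2[[r]],
                        reg_out = sub$p_reg_out_m2[[r]]))
      for (mm in mods) {
        for (xn in xnodes) {
          if (mm$ppi <= alpha) {
            add_edge(xn, mm$node, directed = FALSE, type = "ppi",
                     reg = x, pid = pid)
          }
          if (mm$reg_out <= alpha) {   # x regulates the module
            add_edge(xn, mm$node, directed = TRUE,
                     type = "transcriptional", reg = x, pid = pid)
          }
          if (mm$reg_in <= alpha) {    # the module regulates x
            add_edge(mm$node, xn, directed = TRUE,
                     type = "transcriptional", reg = x, pid = pid)
          }
        }
      }
    }
  }
  keys <- ls(acc)
  if (length(keys) == 0L) {
    g <- igraph::make_empty_graph(n = 0, directed = TRUE)
    g <- igraph::set_graph_attr(g, "phase", phase)
    return(g)
  }
  rows <- lapply(keys, function(k) acc[[k]])
  edges <- data.frame(
    from = vapply(rows, `[[`, character(1L), "from"),
    to = vapply(rows, `[[`, character(1L), "to"),
    directed = vapply(rows, `[[`, logical(1L), "directed"),
    type = vapply(rows, `[[`, character(1L), "type"),
    phase = phase,
    regulators = vapply(rows, function(r)
      paste(sort(r$regulators), collapse = ","), character(1L)),
    pair_ids = vapply(rows, function(r)
      paste(sort(r$pair_ids), collapse = ","), character(1L)),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  g <- igraph::set_graph_attr(g, "phase", phase)
  g
}

#' Export a graph to GraphML, SIF or TSV
#'
#' GraphML round-trips all node and edge attributes; SIF and TSV keep
#' only endpoints and edge type.
#'
#' @param graph An [igraph::igraph].
#' @param path Output file path.
#' @param format One of `"graphml"`, `"sif"`, `"tsv"`.
#' @return Invisibly, `path`.
#' @export
export_graph <- function(graph, path, format = c("graphml", "sif", "tsv")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown format",
                                              call. = FALSE))
  el <- igraph::as_edgelist(graph)
  type <- igraph::edge_attr(graph, "type")
  if (is.null(type)) type <- rep("link", nrow(el))
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else if (format == "sif") {
    lines <- if (nrow(el) == 0L) character() else
      paste(el[, 1L], type, el[, 2L], sep = "\t")
    writeLines(lines, path)
  } else {
    directed <- igraph::edge_attr(graph, "directed")
    if (is.null(directed)) directed <- rep(igraph::is_directed(graph),
                                           nrow(el))
    df <- data.frame(source = el[, 1L], target = el[, 2L],
                     directed = directed, type = type,
                     stringsAsFactors = FALSE)
    write_schema_tsv(df, path)
  }
  invisible(path)
}
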