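#' Read a gene-by-condition expression matrix from TSV
#'
#' The file must have a header row of condition labels and a first column
#' of gene identifiers.  Rows containing any missing value are dropped
#' (with a logged count), matching the requirement that downstream
#' correlation computations see complete profiles only.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix with gene ids as row names and condition
#'   labels as column names.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) {
    stop("expression file not found: ", path, call. = FALSE)
  }
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) {
    stop("expression matrix needs >= 3 conditions, got ", ncol(df) - 1L,
         call. = FALSE)
  }
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate gene ids in expression matrix: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  bad <- rowSums(is.na(m)) > 0L
  if (any(bad)) {
    cm_log(sum(bad), " gene(s) dropped from expression matrix due to ",
           "missing values")
    m <- m[!bad, , drop = FALSE]
  }
  m
}

#' Read a two-column edge list from TSV
#'
#' Lines starting with `#` are ignored.  Used both for undirected
#' protein-protein interaction pairs and for directed regulatory
#' (TF, target) pairs.
#'
#' @param path Path to a tab-separated file with two columns of gene ids.
#' @return A two-column character matrix.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) {
    stop("edge list file not found: ", path, call. = FALSE)
  }
  df <- read.delim(path, header = FALSE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0L && identical(tolower(df[1L, 1L]), "source")) {
    df <- df[-1L, , drop = FALSE]   # tolerate a plain header row
  }
  if (ncol(df) < 2L) {
    stop("edge list must have two columns: ", path, call. = FALSE)
  }
  cbind(as.character(df[[1L]]), as.character(df[[2L]]))
}

#' Read named gene sets from GMT or two-column TSV
#'
#' GMT rows are `name<TAB>description<TAB>gene1<TAB>gene2...`; the TSV
#' dialect is `(set, gene)` pairs which are grouped by set.  Duplicate
#' genes within a set are deduplicated with a warning-level log entry.
#'
#' @param path Path to the gene set file.
#' @param format One of `"auto"`, `"gmt"`, `"tsv"`.  With `"auto"` the
#'   `.gmt` extension selects GMT, anything else the TSV dialect.
#' @return A named list of character vectors of gene ids.
#' @export
read_gene_sets <- function(path, format = c("auto", "gmt", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("gene set file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("empty gene set file: ", path, call. = FALSE)
  }
  sets <- list()
  if (format == "gmt") {
    for (k in seq_along(lines)) {
      fields <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1L]]
      if (length(fields) < 3L) {
        stop("malformed GMT row at line ", k, " of ", path, call. = FALSE)
      }
      sets[[fields[[1L]]]] <- fields[-(1:2)]
    }
  } else {
    for (k in seq_along(lines)) {
      fields <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1L]]
      if (length(fields) < 2L) {
        stop("malformed gene set row at line ", k, " of ", path,
             call. = FALSE)
      }
      sets[[fields[[1L]]]] <- c(sets[[fields[[1L]]]], fields[[2L]])
    }
  }
  lapply(sets, function(g) {
    if (anyDuplicated(g)) {
      cm_log("duplicate genes within a gene set were deduplicated",
             level = "warn")
    }
    unique(g)
  })
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description column (recycled).
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, description = "coopmods") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

# Shared writer: TSV with a '#'-prefixed schema header line so that every
# output table declares its columns.
write_schema_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(names(df), collapse = "\t")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_schema_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  if (grepl("^#", first)) {
    declared <- strsplit(sub("^#\\s*", "", first), "\t", fixed = TRUE)[[1L]]
    if (!identical(declared, names(df))) {
      stop("schema header does not match columns in ", path, call. = FALSE)
    }
  }
  df
}

#' Write a WPI network to disk
#'
#' Produces a 4-column edge table `(source, target, kind, directed)` with
#' `kind` in `{ppi, reg}`, plus a companion node table carrying the
#' co-expression weight and total link count of every gene.  Optionally a
#' GraphML file with the same content.
#'
#' @param net A `wpi_network`.
#' @param dir Output directory (created if needed).
#' @param graphml Also write `wpi_network.graphml`?
#' @return Invisibly, the paths written.
#' @export
write_wpi_network <- function(net, dir, graphml = FALSE) {
  stopifnot(inherits(net, "wpi_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edge_df <- function(m, kind, directed) {
    data.frame(source = m[, 1L], target = m[, 2L],
               kind = rep(kind, nrow(m)),
               directed = rep(directed, nrow(m)),
               stringsAsFactors = FALSE)
  }
  edges <- rbind(edge_df(net$ppi, "ppi", FALSE),
                 edge_df(net$reg, "reg", TRUE))
  nodes <- data.frame(gene = net$genes,
                      weight = unname(net$weight[net$genes]),
                      link_count = unname(net$link_count[net$genes]),
                      stringsAsFactors = FALSE)
  p1 <- write_schema_tsv(edges, file.path(dir, "wpi_edges.tsv"))
  p2 <- write_schema_tsv(nodes, file.path(dir, "wpi_nodes.tsv"))
  paths <- c(p1, p2)
  if (graphml) {
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = nodes)
    p3 <- file.path(dir, "wpi_network.graphml")
    igraph::write_graph(g, p3, format = "graphml")
    paths <- c(paths, p3)
  }
  invisible(paths)
}

#' Packaged phase-specific regulator table
#'
#' Returns the bundled assignment of cell cycle regulators (transcription
#' factors, the Cdc28 kinase, cyclins and CDC genes) to the G1, S, G2 and
#' M phases of the budding yeast cell cycle, as shipped in
#' `inst/extdata/phase_regulators.tsv`.  Users analysing their own data
#' can supply any table with the same `(phase, regulator, class)` layout.
#'
#' @return A data frame with columns `phase`, `regulator` and `class`
#'   (`tf` or `cdc`).
#' @export
phase_regulators <- function() {
  path <- system.file("extdata", "phase_regulators.tsv",
                      package = "coopmods", mustWork = TRUE)
  read_schema_tsv(path)
}
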