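#' Pipeline run configuration
#'
#' Bundles input paths, the output directory, the global seed and all
#' stage configurations.  Serializable to YAML/JSON with
#' [write_run_config()] and back with [read_run_config()]; unknown keys
#' are rejected on read.
#'
#' @param expression,ppi,reg Input file paths (TSV).
#' @param gene_sets Optional gene set file path (GMT or two-column TSV).
#' @param out_dir Output directory.
#' @param rng_seed Global integer seed; per-stage seeds are derived from
#'   it deterministically.
#' @param coexpr_threshold Co-expression cutoff.
#' @param discovery A `discovery_config`.
#' @param null_model A `null_model_config`.
#' @param log_level `"debug"`, `"info"` or `"warn"`.
#' @return A `run_config` list.
#' @export
run_config <- function(expression, ppi, reg, gene_sets = NULL,
                       out_dir = "coopmods_out", rng_seed = 1L,
                       coexpr_threshold = 0.683,
                       discovery = discovery_config(),
                       null_model = null_model_config(),
                       log_level = "info") {
  structure(list(expression = expression, ppi = ppi, reg = reg,
                 gene_sets = gene_sets, out_dir = out_dir,
                 rng_seed = as.integer(rng_seed),
                 coexpr_threshold = coexpr_threshold,
                 discovery = discovery, null_model = null_model,
                 log_level = log_level),
            class = "run_config")
}

# deterministic per-stage seed fan-out: global seed mixed with a stage
# name hash, kept below 2^31
stage_seed <- function(rng_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(rng_seed) * 7919 + h * 104729) %% 2147483647)
}

run_config_keys <- c("expression", "ppi", "reg", "gene_sets", "out_dir",
                     "rng_seed", "coexpr_threshold", "discovery",
                     "null_model", "log_level")

#' Read a run configuration from YAML or JSON
#'
#' @param path Config file path (`.json` selects JSON, anything else
#'   YAML).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(raw), run_config_keys)
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  dc <- do.call(discovery_config, as.list(raw$discovery %||% list()))
  nc <- do.call(null_model_config, as.list(raw$null_model %||% list()))
  run_config(expression = raw$expression, ppi = raw$ppi, reg = raw$reg,
             gene_sets = raw$gene_sets, out_dir = raw$out_dir %||%
               "coopmods_out",
             rng_seed = raw$rng_seed %||% 1L,
             coexpr_threshold = raw$coexpr_threshold %||% 0.683,
             discovery = dc, null_model = nc,
             log_level = raw$log_level %||% "info")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run configuration to YAML
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(cfg, path) {
  flat <- unclass(cfg)
  flat$discovery <- unclass(flat$discovery)
  flat$null_model <- unclass(flat$null_model)
  flat$null_model$rng_seed <- NULL
  flat <- Filter(Negate(is.null), flat)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Run the full cooperative-module pipeline
#'
#' Network construction, module pair discovery, correlated-gene
#' identification, gene-set evaluation and graph construction, with all
#' artifacts written under `cfg$out_dir`.  Outputs are deterministic
#' given identical inputs, configuration and seed.
#'
#' @param cfg A `run_config`.
#' @return A `run_report` list with per-stage counts, the config echo
#'   and wall-clock timestamps.
#' @export
run_all <- function(cfg) {
  old <- options(coopmods.log_level = cfg$log_level)
  on.exit(options(old))
  t0 <- Sys.time()
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # stage 1: network construction
  net <- NULL; expr <- NULL
  stage("network", function() {
    expr <<- read_expression_matrix(cfg$expression)
    ppi <- read_edge_list(cfg$ppi)
    reg <- read_edge_list(cfg$reg)
    net <<- build_wpi_network(expr, ppi, reg,
                              threshold = cfg$coexpr_threshold)
    write_wpi_network(net, cfg$out_dir)
  })

  # stage 2: discovery
  result <- NULL
  stage("discovery", function() {
    result <<- discover(net, cfg$discovery)
    mods <- result$modules
    if (length(mods) > 0L) {
      sets <- setNames(lapply(mods, function(m) m$genes),
                       paste0("module_", vapply(mods, function(m) m$id,
                                                integer(1L))))
      write_gmt(sets, file.path(cfg$out_dir, "modules.gmt"))
    } else {
      writeLines(character(), file.path(cfg$out_dir, "modules.gmt"))
    }
    pair_df <- if (length(result$pairs) > 0L) {
      data.frame(
        pair_id = vapply(result$pairs, function(p) p$pair_id,
                         integer(1L)),
        module1_id = vapply(result$pairs, function(p) p$m1$id,
                            integer(1L)),
        module2_id = vapply(result$pairs, function(p) p$m2$id,
                            integer(1L)),
        seed_s = vapply(result$pairs, function(p) p$seed$s,
                        character(1L)),
        seed_t = vapply(result$pairs, function(p) p$seed$t,
                        character(1L)),
        mcoop_score = vapply(result$pairs, function(p) p$mcoop_score,
                             numeric(1L)),
        stringsAsFactors = FALSE)
    } else {
      data.frame(pair_id = integer(), module1_id = integer(),
                 module2_id = integer(), seed_s = character(),
                 seed_t = character(), mcoop_score = numeric())
    }
    write_schema_tsv(pair_df, file.path(cfg$out_dir, "pairs.tsv"))
    jsonlite::write_json(result$provenance,
                         file.path(cfg$out_dir, "provenance.json"),
                         dataframe = "rows", digits = NA)
  })

  # stage 3: correlated genes (shared null ensemble)
  correlated <- NULL; nulls <- NULL
  stage("correlated_genes", function() {
    ncfg <- cfg$null_model
    ncfg$rng_seed <- stage_seed(cfg$rng_seed, "correlated_genes")
    nulls <<- make_null_ensemble(net, ncfg)
    tabs <- lapply(result$pairs, function(p)
      identify_correlated_genes(net, p, ncfg, nulls = nulls))
    correlated <<- if (length(tabs) > 0L) do.call(rbind, tabs) else
      data.frame(gene = character(), pair_id = integer(),
                 p_ppi_m1 = numeric(), p_ppi_m2 = numeric(),
                 p_reg_in_m1 = numeric(), p_reg_in_m2 = numeric(),
                 p_reg_out_m1 = numeric(), p_reg_out_m2 = numeric(),
                 coop_type = character(), coop_types_all = character(),
                 stringsAsFactors = FALSE)
    write_schema_tsv(correlated,
                     file.path(cfg$out_dir, "correlated_genes.tsv"))
  })

  # stage 4: evaluation
  enrich <- NULL
  stage("evaluation", function() {
    sets <- if (!is.null(cfg$gene_sets)) read_gene_sets(cfg$gene_sets)
      else list()
    rows <- list()
    for (p in result$pairs) {
      cg <- correlated$gene[correlated$pair_id == p$pair_id]
      for (nm in names(sets)) {
        rows[[length(rows) + 1L]] <- pair_geneset_significance(
          cg, sets[[nm]], universe = length(net$genes),
          alpha = cfg$null_model$alpha, set_name = nm,
          pair_id = p$pair_id)
      }
    }
    enrich <<- if (length(rows) > 0L) do.call(rbind, rows) else
      data.frame(pair_id = integer(), set_name = character(),
                 G = integer(), C = integer(), B = integer(),
                 b = integer(), p_value = numeric(),
                 significant = logical())
    write_schema_tsv(enrich, file.path(cfg$out_dir, "enrichment.tsv"))
    phase_rows <- enrich[grepl("^phase_", enrich$set_name), ,
                         drop = FALSE]
    ranked <- rank_phase_pairs(phase_rows)
    write_schema_tsv(ranked, file.path(cfg$out_dir, "phase_ranking.tsv"))
  })

  # stage 5: graphs
  stage("graphs", function() {
    cmn <- build_cmn(result)
    export_graph(cmn, file.path(cfg$out_dir, "cmn.tsv"), "tsv")
    export_graph(cmn, file.path(cfg$out_dir, "cmn.graphml"), "graphml")
    regs <- phase_regulators()
    for (ph in unique(regs$phase)) {
      pg <- build_phase_graph(result$pairs, correlated,
                              regs$regulator[regs$phase == ph],
                              result$modules, phase = ph,
                              alpha = cfg$null_model$alpha)
      export_graph(pg, file.path(cfg$out_dir,
                                 paste0("phase_graph_", ph, ".tsv")),
                   "tsv")
    }
  })

  t1 <- Sys.time()
  report <- list(
    tool = "coopmods",
    version = as.character(utils::packageVersion("coopmods")),
    config = unclass(cfg),
    counts = list(
      genes = length(net$genes),
      ppi_edges = nrow(net$ppi),
      reg_edges = nrow(net$reg),
      seeds = nrow(result$provenance),
      modules = length(result$modules),
      pairs = length(result$pairs),
      correlated_genes = nrow(correlated),
      significant_enrichments = sum(enrich$significant)
    ),
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    finished = format(t1, "%Y-%m-%dT%H:%M:%S")
  )
  class(report) <- "run_report"
  # report carries wall timestamps, so it is written separately from the
  # deterministic result tables
  jsonlite::write_json(report[c("tool", "version", "counts")],
                       file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("coopmods run report\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-24s %s\n", nm, x$counts[[nm]]))
  }
  invisible(x)
}
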