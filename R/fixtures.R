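#' Synthetic fixture configuration
#'
#' Parameters of the synthetic data generator, which emulates the three
#' input data types (expression, protein interactions, regulatory links)
#' with two planted cooperative modules and a set of mediator genes
#' linking both.
#'
#' @param n_background_genes Background genes outside the planted
#'   structure (default 200).
#' @param module_sizes Integer pair: sizes of the two planted modules
#'   (default `c(8, 8)`).
#' @param n_mediators Mediator genes densely linked to both modules
#'   (default 3).
#' @param within_module_edge_prob Protein-edge probability within each
#'   planted module (default 0.3).
#' @param background_edge_prob Protein-edge probability outside the
#'   planted structure (default 0.01).
#' @param mediator_link_fraction Fraction of each module's members every
#'   mediator is linked to (default 1).
#' @param n_conditions Expression conditions (default 24).
#' @param coexpr_noise_sd Standard deviation of per-gene expression
#'   noise around the shared latent profile (default 0.2; the latent
#'   profile has unit variance).
#' @param planted_tf Also plant a transcription factor with directed
#'   links into both modules? (default TRUE).
#' @param profile Latent profile shape: `"latent"` (standard normal) or
#'   `"sinusoid"` (one full period across conditions, for demo realism).
#' @param rng_seed Optional integer seed used by [generate_fixture()].
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_background_genes = 200L,
                           module_sizes = c(8L, 8L),
                           n_mediators = 3L,
                           within_module_edge_prob = 0.3,
                           background_edge_prob = 0.01,
                           mediator_link_fraction = 1,
                           n_conditions = 24L,
                           coexpr_noise_sd = 0.2,
                           planted_tf = TRUE,
                           profile = c("latent", "sinusoid"),
                           rng_seed = NULL) {
  profile <- match.arg(profile)
  stopifnot(all(module_sizes >= 3L), n_conditions >= 6L,
            within_module_edge_prob >= 0, within_module_edge_prob <= 1,
            background_edge_prob >= 0, background_edge_prob <= 1,
            mediator_link_fraction >= 0, mediator_link_fraction <= 1,
            coexpr_noise_sd >= 0, n_mediators >= 0L)
  structure(list(n_background_genes = as.integer(n_background_genes),
                 module_sizes = as.integer(module_sizes),
                 n_mediators = as.integer(n_mediators),
                 within_module_edge_prob = within_module_edge_prob,
                 background_edge_prob = background_edge_prob,
                 mediator_link_fraction = mediator_link_fraction,
                 n_conditions = as.integer(n_conditions),
                 coexpr_noise_sd = coexpr_noise_sd,
                 planted_tf = isTRUE(planted_tf),
                 profile = profile,
                 rng_seed = rng_seed),
            class = "fixture_config")
}

fixture_gene_names <- function(cfg) {
  list(
    background = sprintf("bg%03d", seq_len(cfg$n_background_genes)),
    module_a = sprintf("modA%02d", seq_len(cfg$module_sizes[[1L]])),
    module_b = sprintf("modB%02d", seq_len(cfg$module_sizes[[2L]])),
    mediators = if (cfg$n_mediators > 0L)
      sprintf("med%02d", seq_len(cfg$n_mediators)) else character(),
    tf = if (cfg$planted_tf) "tfx01" else character()
  )
}

#' Generate the planted interaction and regulatory networks
#'
#' Draws protein edges within each planted module
#' (`within_module_edge_prob`), links every mediator to
#' `mediator_link_fraction` of both modules' members, adds a sparse
#' protein background over all remaining gene pairs
#' (`background_edge_prob`), and, when `planted_tf` is set, directed
#' regulatory edges from the planted TF into the same fraction of both
#' modules (plus a couple of background regulatory edges so the directed
#' edge set is never degenerate).  Uses the current RNG state; seed with
#' `set.seed()` or use [generate_fixture()] for end-to-end
#' reproducibility.
#'
#' @param cfg A `fixture_config`.
#' @return A list `ppi` (matrix), `reg` (matrix), `truth` (list of
#'   planted gene groups, mediator phases and TF targets).
#' @export
generate_network_fixture <- function(cfg = fixture_config()) {
  nm <- fixture_gene_names(cfg)
  ppi <- list()
  add_und <- function(a, b) ppi[[length(ppi) + 1L]] <<- c(a, b)

  for (mod in list(nm$module_a, nm$module_b)) {
    prs <- combn(mod, 2L)
    hit <- runif(ncol(prs)) < cfg$within_module_edge_prob
    for (k in which(hit)) add_und(prs[1L, k], prs[2L, k])
  }
  k_a <- ceiling(cfg$mediator_link_fraction * length(nm$module_a))
  k_b <- ceiling(cfg$mediator_link_fraction * length(nm$module_b))
  for (md in nm$mediators) {
    for (g in sample(nm$module_a, k_a)) add_und(md, g)
    for (g in sample(nm$module_b, k_b)) add_und(md, g)
  }
  planted <- c(nm$module_a, nm$module_b, nm$mediators, nm$tf)
  genes <- c(nm$background, planted)
  same_module <- function(a, b) {
    (a %in% nm$module_a && b %in% nm$module_a) ||
      (a %in% nm$module_b && b %in% nm$module_b)
  }
  med_mod <- function(a, b) {
    (a %in% nm$mediators && b %in% c(nm$module_a, nm$module_b)) ||
      (b %in% nm$mediators && a %in% c(nm$module_a, nm$module_b))
  }
  if (cfg$background_edge_prob > 0) {
    prs <- combn(genes, 2L)
    hit <- which(runif(ncol(prs)) < cfg$background_edge_prob)
    for (k in hit) {
      a <- prs[1L, k]; b <- prs[2L, k]
      if (!same_module(a, b) && !med_mod(a, b)) add_und(a, b)
    }
  }
  ppi <- do.call(rbind, ppi)

  reg <- list()
  tf_targets <- character()
  if (cfg$planted_tf) {
    tf_targets <- c(sample(nm$module_a, k_a), sample(nm$module_b, k_b))
    for (g in tf_targets) reg[[length(reg) + 1L]] <- c(nm$tf, g)
  }
  n_bg_reg <- max(2L, round(cfg$background_edge_prob *
                              cfg$n_background_genes))
  for (k in seq_len(n_bg_reg)) {
    pr <- sample(nm$background, 2L)
    reg[[length(reg) + 1L]] <- pr
  }
  reg <- do.call(rbind, reg)

  phases <- c("G1", "S", "G2", "M")
  truth <- list(
    module_a = nm$module_a,
    module_b = nm$module_b,
    mediators = nm$mediators,
    mediator_phases = if (cfg$n_mediators > 0L)
      setNames(phases[(seq_len(cfg$n_mediators) - 1L) %% 4L + 1L],
               nm$mediators) else setNames(character(), character()),
    tf = nm$tf,
    tf_targets = tf_targets,
    background = nm$background
  )
  list(ppi = ppi, reg = reg, truth = truth)
}

#' Generate the synthetic expression matrix
#'
#' Planted module members, mediators and the planted TF share a common
#' latent profile (unit variance) plus independent Gaussian noise with
#' sd `coexpr_noise_sd`; background genes get independent standard
#' normal profiles.  At zero noise all planted pairwise correlations are
#' exactly 1.
#'
#' @param cfg A `fixture_config`.
#' @param truth Truth list from [generate_network_fixture()].
#' @return A numeric matrix (genes x conditions).
#' @export
generate_expression_fixture <- function(cfg, truth) {
  nm <- fixture_gene_names(cfg)
  genes <- c(nm$background, nm$module_a, nm$module_b, nm$mediators,
             nm$tf)
  nc <- cfg$n_conditions
  z <- switch(cfg$profile,
    latent = stats::rnorm(nc),
    sinusoid = sin(seq(0, 2 * pi, length.out = nc)))
  z <- as.numeric(scale(z))
  planted <- c(truth$module_a, truth$module_b, truth$mediators,
               truth$tf)
  expr <- matrix(stats::rnorm(length(genes) * nc), nrow = length(genes),
                 dimnames = list(genes, sprintf("cond%02d", seq_len(nc))))
  for (g in planted) {
    expr[g, ] <- z + stats::rnorm(nc, sd = cfg$coexpr_noise_sd)
  }
  expr
}

#' Generate gene set fixtures
#'
#' Builds a cell cycle-like benchmark set (all planted genes plus a few
#' background decoys) and one phase-regulated set per phase (planted
#' genes assigned phases round-robin; mediators keep their truth
#' phases).
#'
#' @param cfg A `fixture_config`.
#' @param truth Truth list from [generate_network_fixture()].
#' @return Named list of character vectors.
#' @export
generate_geneset_fixture <- function(cfg, truth) {
  planted <- c(truth$module_a, truth$module_b, truth$mediators,
               truth$tf)
  decoys <- sample(truth$background, min(5L, length(truth$background)))
  phases <- c("G1", "S", "G2", "M")
  members <- c(truth$module_a, truth$module_b)
  assign_phase <- setNames(phases[(seq_along(members) - 1L) %% 4L + 1L],
                           members)
  sets <- list(cell_cycle = c(planted, decoys))
  for (ph in phases) {
    sets[[paste0("phase_", ph)]] <- c(
      names(assign_phase)[assign_phase == ph],
      names(truth$mediator_phases)[truth$mediator_phases == ph])
  }
  sets
}

#' Generate a complete synthetic fixture
#'
#' Seeds the RNG from `cfg$rng_seed` (when given) and produces all four
#' input data types plus the ground truth.
#'
#' @param cfg A `fixture_config`.
#' @return A list with `expr`, `ppi`, `reg`, `gene_sets`, `truth`, and
#'   the `config` echoed back.
#' @export
generate_fixture <- function(cfg = fixture_config()) {
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  netfix <- generate_network_fixture(cfg)
  expr <- generate_expression_fixture(cfg, netfix$truth)
  sets <- generate_geneset_fixture(cfg, netfix$truth)
  list(expr = expr, ppi = netfix$ppi, reg = netfix$reg,
       gene_sets = sets, truth = netfix$truth, config = cfg)
}

#' Write a synthetic fixture to disk
#'
#' Writes `expression.tsv`, `ppi.tsv`, `reg.tsv`, `genesets.gmt` and
#' `truth.json` under `dir`.
#'
#' @param fix Result of [generate_fixture()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_fixture <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr_df <- data.frame(gene = rownames(fix$expr), fix$expr,
                        check.names = FALSE, stringsAsFactors = FALSE)
  write.table(expr_df, file.path(dir, "expression.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(fix$ppi, file.path(dir, "ppi.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(fix$reg, file.path(dir, "reg.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_gmt(fix$gene_sets, file.path(dir, "genesets.gmt"))
  truth <- fix$truth
  truth$mediator_phases <- as.list(truth$mediator_phases)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
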