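#!/usr/bin/env Rscript
# Fixture calibration: explores the free generator parameters (module
# edge density, mediator link fraction) and records how well the
# discovery stage recovers the planted module pair and how often
# mediators are re-identified.  Run once during fixture design; the
# chosen defaults are frozen in fixture_config().
#
# Usage: Rscript scripts/calibrate_fixture.R [n_seeds] [out_tsv]

suppressMessages({
  if (requireNamespace("pkgload", quietly = TRUE) &&
      file.exists("DESCRIPTION")) {
    pkgload::load_all(".", quiet = TRUE)
  } else {
    library(coopmods)
  }
})

args <- commandArgs(trailingOnly = TRUE)
n_seeds <- if (length(args) >= 1) as.integer(args[[1]]) else 3L
out <- if (length(args) >= 2) args[[2]] else "scratch/calibration.tsv"

jacc <- function(a, b) length(intersect(a, b)) / length(union(a, b))

pair_recovery <- function(res, truth) {
  best <- 0
  best_pair <- NA_integer_
  for (p in res$pairs) {
    j1 <- max(jacc(p$m1$genes, truth$module_a),
              jacc(p$m1$genes, truth$module_b))
    j2 <- max(jacc(p$m2$genes, truth$module_a),
              jacc(p$m2$genes, truth$module_b))
    # both sides must hit different planted modules
    d1 <- c(jacc(p$m1$genes, truth$module_a),
            jacc(p$m1$genes, truth$module_b))
    d2 <- c(jacc(p$m2$genes, truth$module_a),
            jacc(p$m2$genes, truth$module_b))
    v <- max(min(d1[1], d2[2]), min(d1[2], d2[1]))
    if (v > best) { best <- v; best_pair <- p$pair_id }
  }
  list(best = best, pair_id = best_pair)
}

module_recovery <- function(res, truth) {
  ja <- jb <- 0
  for (m in res$modules) {
    ja <- max(ja, jacc(m$genes, truth$module_a))
    jb <- max(jb, jacc(m$genes, truth$module_b))
  }
  c(ja, jb)
}

grid <- expand.grid(within = c(0.25, 0.5, 0.8, 1.0),
                    frac = c(0.75, 1.0))
rows <- list()
for (g in seq_len(nrow(grid))) {
  for (sd_i in seq_len(n_seeds)) {
    cfg <- fixture_config(within_module_edge_prob = grid$within[[g]],
                          mediator_link_fraction = grid$frac[[g]],
                          rng_seed = 1000L + sd_i)
    fix <- generate_fixture(cfg)
    net <- suppressMessages(
      build_wpi_network(fix$expr, fix$ppi, fix$reg))
    t0 <- Sys.time()
    res <- discover(net)
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    pr <- pair_recovery(res, fix$truth)
    mr <- module_recovery(res, fix$truth)
    med_rec <- NA_integer_
    if (!is.na(pr$pair_id)) {
      p <- Filter(function(q) q$pair_id == pr$pair_id, res$pairs)[[1]]
      ncfg <- null_model_config(n_random = 300L, rng_seed = 99L + sd_i)
      cg <- identify_correlated_genes(net, p, ncfg)
      med_rec <- sum(fix$truth$mediators %in% cg$gene)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      within = grid$within[[g]], frac = grid$frac[[g]], seed = sd_i,
      n_pairs = length(res$pairs), pair_jaccard = pr$best,
      modA_j = mr[1], modB_j = mr[2], mediators = med_rec,
      secs = round(dt, 1))
    cat(sprintf(
      "within=%.2f frac=%.2f seed=%d pairs=%d pairJ=%.2f modJ=%.2f/%.2f med=%s t=%.1fs\n",
      grid$within[[g]], grid$frac[[g]], sd_i, length(res$pairs),
      pr$best, mr[1], mr[2], med_rec, dt))
  }
}
df <- do.call(rbind, rows)
dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
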