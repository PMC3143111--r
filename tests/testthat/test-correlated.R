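test_that("rewiring preserves degree sequences exactly", {
  set.seed(17)
  for (k in 1:10) {
    rt <- random_test_network(sample(8:20, 1L), p_ppi = 0.3,
                              max_reg = 12L)
    rw <- rewire_degree_preserving(rt$net)
    deg <- function(edges, genes) {
      table(factor(c(edges[, 1L], edges[, 2L]), levels = genes))
    }
    expect_equal(deg(rw$ppi, rt$genes), deg(rt$net$ppi, rt$genes))
    outdeg <- function(edges, genes)
      table(factor(edges[, 1L], levels = genes))
    indeg <- function(edges, genes)
      table(factor(edges[, 2L], levels = genes))
    expect_equal(outdeg(rw$reg, rt$genes), outdeg(rt$net$reg, rt$genes))
    expect_equal(indeg(rw$reg, rt$genes), indeg(rt$net$reg, rt$genes))
    # no self-loops or duplicate edges introduced
    expect_true(all(rw$ppi[, 1L] != rw$ppi[, 2L]))
    expect_false(any(duplicated(paste(rw$ppi[, 1L], rw$ppi[, 2L]))))
  }
})

test_that("a 4-cycle reaches every valid rewiring over seeded draws", {
  # the all-degree-2 graphs on {a,b,c,d} are exactly the three labeled
  # 4-cycles (enumerated by brute force below); double-edge swaps must
  # visit all of them and nothing else
  edges <- rbind(c("a", "b"), c("c", "d"), c("a", "d"), c("b", "c"))
  verts <- c("a", "b", "c", "d")
  all_pairs <- t(combn(verts, 2L))
  valid <- character()
  for (pick in combn(6L, 4L, simplify = FALSE)) {
    sub <- all_pairs[pick, , drop = FALSE]
    d <- table(factor(c(sub[, 1L], sub[, 2L]), levels = verts))
    if (all(d == 2L)) {
      valid <- c(valid, paste(sort(paste(sub[, 1L], sub[, 2L])),
                              collapse = ";"))
    }
  }
  expect_length(valid, 3L)
  net <- suppressMessages(assemble_wpi(edges,
                                       matrix(character(), ncol = 2L)))
  seen <- character()
  set.seed(9)
  for (k in 1:300) {
    rw <- rewire_degree_preserving(net)
    key <- paste(sort(paste(pmin(rw$ppi[, 1L], rw$ppi[, 2L]),
                            pmax(rw$ppi[, 1L], rw$ppi[, 2L]))),
                 collapse = ";")
    seen <- union(seen, key)
  }
  expect_setequal(seen, valid)
})

test_that("empirical p-values are bounded, monotone and attain the minimum on planted hubs", {
  # observed count 0 -> p = 1
  net <- toy_net()
  cfg <- null_model_config(n_random = 50L, rng_seed = 1L)
  nulls <- make_null_ensemble(net, cfg)
  expect_equal(link_count_pvalue(net, "c", new_module(c("s", "b")),
                                 "ppi", cfg, nulls), 1)
  # a gene linked to every member of a degree-1-partner module cannot
  # be matched by the null once the stubs scatter
  star <- cbind("hub", sprintf("leaf%02d", 1:12))
  more <- t(combn(sprintf("x%02d", 1:10), 2L))
  set.seed(33)
  more <- more[runif(nrow(more)) < 0.4, , drop = FALSE]
  netp <- suppressMessages(assemble_wpi(rbind(star, more),
                                        matrix(character(), ncol = 2L)))
  cfgp <- null_model_config(n_random = 200L, rng_seed = 4L)
  nullsp <- make_null_ensemble(netp, cfgp)
  mod <- new_module(sprintf("leaf%02d", 1:12))
  p_hub <- link_count_pvalue(netp, "hub", mod, "ppi", cfgp, nullsp)
  expect_equal(p_hub, 1 / (cfgp$n_random + 1))
  expect_lte(p_hub, cfgp$alpha)
  # monotonicity in the observed count against a fixed null tabulation
  nullcnt <- vapply(nullsp, function(e)
    coopmods:::count_links_to_module(e$ppi, mod$genes, netp$genes,
                                     "ppi")[["hub"]], integer(1L))
  p_of <- function(obs) (1 + sum(nullcnt >= obs)) / (1 + length(nullcnt))
  ps <- vapply(0:12, p_of, numeric(1L))
  expect_true(all(diff(ps) <= 0))
  expect_equal(ps[[1L]], 1)
})

test_that("cooperation types follow the significance patterns and priority", {
  ev <- function(...) {
    base <- c(ppi_m1 = 1, ppi_m2 = 1, reg_in_m1 = 1, reg_in_m2 = 1,
              reg_out_m1 = 1, reg_out_m2 = 1)
    over <- c(...)
    base[names(over)] <- over
    base
  }
  expect_equal(classify_cooperation_type(
    ev(ppi_m1 = 0.01, reg_in_m2 = 0.01))$primary, "A")
  expect_equal(classify_cooperation_type(
    ev(ppi_m2 = 0.01, reg_out_m1 = 0.01))$primary, "B")
  expect_equal(classify_cooperation_type(
    ev(ppi_m1 = 0.01, ppi_m2 = 0.01))$primary, "C")
  expect_equal(classify_cooperation_type(
    ev(reg_in_m1 = 0.01, reg_in_m2 = 0.01))$primary, "D")
  expect_equal(classify_cooperation_type(
    ev(reg_out_m1 = 0.01, reg_out_m2 = 0.01))$primary, "E")
  # multi-pattern: C beats A/B; all patterns reported
  multi <- classify_cooperation_type(
    ev(ppi_m1 = 0.01, ppi_m2 = 0.01, reg_in_m2 = 0.01))
  expect_equal(multi$primary, "C")
  expect_true(all(c("C", "A") %in% multi$all))
  expect_error(classify_cooperation_type(ev()), "filtered")
})

test_that("correlated-gene identification finds planted bridges, not one-sided genes", {
  # two 4-cliques plus one mediator linked to everything, one gene
  # linked only to module 1, in a background of random edges
  mods <- list(sprintf("a%d", 1:4), sprintf("b%d", 1:4))
  edges <- do.call(rbind, lapply(mods, function(m) t(combn(m, 2L))))
  med_edges <- cbind("med", c(mods[[1L]], mods[[2L]]))
  one_sided <- cbind("uni", mods[[1L]])
  set.seed(101)
  bg <- t(combn(sprintf("z%02d", 1:14), 2L))
  bg <- bg[runif(nrow(bg)) < 0.25, , drop = FALSE]
  net <- suppressMessages(assemble_wpi(
    rbind(edges, med_edges, one_sided, bg),
    rbind(c("tf", "a1"), c("tf", "a2"), c("z01", "z02"))))
  seed <- new_seed(net, "a1", "b1")
  pair <- new_module_pair(new_module(mods[[1L]], anchor = "a1"),
                          new_module(mods[[2L]], anchor = "b1"), seed)
  pair$pair_id <- 7L
  cfg <- null_model_config(n_random = 300L, rng_seed = 11L)
  cg <- identify_correlated_genes(net, pair, cfg)
  expect_true("med" %in% cg$gene)
  expect_false("uni" %in% cg$gene)
  expect_equal(unique(cg$pair_id), 7L)
  expect_true(all(cg$p_ppi_m1 >= 1 / (cfg$n_random + 1)))
  # determinism under the same seed
  cg2 <- identify_correlated_genes(net, pair, cfg)
  expect_equal(cg, cg2)
  # label equivariance: relabeling genes relabels but does not change
  # the correlated set
  ren <- function(x) paste0("R", x)
  net_r <- suppressMessages(assemble_wpi(
    cbind(ren(rbind(edges, med_edges, one_sided, bg)[, 1L]),
          ren(rbind(edges, med_edges, one_sided, bg)[, 2L])),
    cbind(ren(c("tf", "tf", "z01")), ren(c("a1", "a2", "z02")))))
  pair_r <- new_module_pair(new_module(ren(mods[[1L]])),
                            new_module(ren(mods[[2L]])),
                            new_seed(net_r, "Ra1", "Rb1"))
  cg_r <- identify_correlated_genes(net_r, pair_r, cfg)
  expect_setequal(cg_r$gene, ren(cg$gene))
})

test_that("small-network empirical p agrees with exhaustive enumeration of rewirings", {
  # 6-node protein network, module {m1, m2}; the null distribution of
  # gene g's links into the module is enumerated over all simple graphs
  # with the same degree sequence
  edges <- rbind(c("g", "m1"), c("g", "m2"), c("u", "v"), c("m1", "u"))
  net <- suppressMessages(assemble_wpi(edges,
                                       matrix(character(), ncol = 2L),
                                       extra_genes = c("w1")))
  mod <- c("m1", "m2")
  genes <- net$genes
  deg <- table(factor(c(edges[, 1L], edges[, 2L]), levels = genes))
  # enumerate all 4-edge simple graphs on these nodes with this exact
  # degree sequence and tabulate g's links into the module
  verts <- genes
  all_pairs <- t(combn(verts, 2L))
  combos <- combn(nrow(all_pairs), 4L)
  cnts <- c()
  for (k in seq_len(ncol(combos))) {
    sub <- all_pairs[combos[, k], , drop = FALSE]
    d <- table(factor(c(sub[, 1L], sub[, 2L]), levels = verts))
    if (all(d == deg)) {
      cnts <- c(cnts, sum((sub[, 1L] == "g" & sub[, 2L] %in% mod) |
                            (sub[, 2L] == "g" & sub[, 1L] %in% mod)))
    }
  }
  exact_p <- mean(cnts >= 2L)
  cfg <- null_model_config(n_random = 1000L, rng_seed = 21L)
  nulls <- make_null_ensemble(net, cfg)
  p_emp <- link_count_pvalue(net, "g", mod, "ppi", cfg, nulls)
  se <- sqrt(exact_p * (1 - exact_p) / cfg$n_random)
  expect_lt(abs(p_emp - exact_p), 3 * se + 2 / cfg$n_random)
})
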