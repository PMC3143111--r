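test_that("seed candidates include bridged pairs and exclude edgeless networks", {
  net <- toy_net()
  cand <- enumerate_seed_candidates(net)
  keys <- paste(cand[, 1L], cand[, 2L])
  expect_true("s t" %in% keys)
  # star network: every leaf pair is bridged by the center
  star <- suppressMessages(assemble_wpi(
    cbind("c", paste0("l", 1:4)), matrix(character(), ncol = 2L),
    weights = c(c = 1, l1 = 1, l2 = 1, l3 = 1, l4 = 1)))
  keys2 <- paste(enumerate_seed_candidates(star)[, 1L],
                 enumerate_seed_candidates(star)[, 2L])
  for (pr in combn(paste0("l", 1:4), 2L, simplify = FALSE)) {
    expect_true(paste(pr, collapse = " ") %in% keys2)
  }
})

test_that("seed selection is strictly-above-percentile over nonzero scores", {
  # single non-zero pair: its score equals the percentile value, so the
  # strict comparison yields no seeds
  net1 <- suppressMessages(assemble_wpi(
    rbind(c("s", "a"), c("t", "a")), matrix(character(), ncol = 2L),
    weights = c(s = 0, t = 0, a = 5)))
  expect_length(select_seeds(net1), 0L)
  # all-zero scores: no seeds, with a warning log
  net0 <- suppressMessages(assemble_wpi(
    rbind(c("a", "b")), matrix(character(), ncol = 2L)))
  expect_message(select_seeds(net0), "no seeds")
  expect_length(suppressMessages(select_seeds(net0)), 0L)
  # against an independent recomputation on a random network
  set.seed(31)
  rt <- random_test_network(12L, p_ppi = 0.3)
  scores <- c()
  prs <- combn(rt$genes, 2L)
  for (k in seq_len(ncol(prs))) {
    scores[k] <- oracle_ct(rt$ppi, rt$reg, rt$w, rt$genes,
                           prs[1L, k], prs[2L, k])
  }
  nz <- scores[scores != 0]
  cfg <- discovery_config(seed_percentile = 75)
  thr <- quantile(nz, 0.75, names = FALSE)
  want <- which(scores > thr & scores != 0)
  seeds <- select_seeds(rt$net, cfg)
  got <- vapply(seeds, function(s) paste(s$s, s$t), character(1L))
  expect_setequal(got, paste(prs[1L, want], prs[2L, want]))
  # deterministic ordering: score descending
  sc <- vapply(seeds, function(s) s$ct_score, numeric(1L))
  expect_true(all(diff(sc) <= 0))
})

test_that("spanning reproduces the toy hand trace and basic guards", {
  net <- toy_net()
  seed <- new_seed(net, "s", "t")
  sp <- span_module_pair(net, seed)
  # chain: b joins (MCoop 7 >= 3, CT(b,t)=4 >= CT(s,t)=3 -> continue);
  # a then joins via its positive mediation term but CT(a,t) = -3 stops
  # the chain; t's only neighbor is already consumed
  expect_true(all(c("s", "b") %in% sp$m1$genes))
  expect_equal(sp$m1$genes, c("s", "b", "a"))
  expect_equal(sp$m2$genes, "t")
  # final score equals independent recomputation of the pair score
  expect_equal(sp$mcoop_score,
               oracle_mcoop(net$ppi, net$reg, net$weight, net$genes,
                            sp$m1$genes, sp$m2$genes, "s", "t"))
  # isolated seed genes: pair stays singletons at the seed score
  net_iso <- suppressMessages(assemble_wpi(
    rbind(c("a", "b")), matrix(character(), ncol = 2L),
    extra_genes = c("s", "t")))
  seed_iso <- new_seed(net_iso, "s", "t")
  sp2 <- span_module_pair(net_iso, seed_iso)
  expect_equal(sp2$m1$genes, "s")
  expect_equal(sp2$m2$genes, "t")
  expect_equal(sp2$mcoop_score, seed_iso$ct_score)
  expect_error(span_module_pair(net, structure(
    list(s = "nope", t = "t", ct_score = 0), class = "cm_seed")),
    "not in network")
})

test_that("a rejected candidate is consumed from the visit list and left out", {
  # triangle s-u-x with a heavy singly-linked x: CT(s,t) and CT(u,t)
  # are negative and u's only mediator product (via s) is negative, so
  # u is added to m1, drops the score, and is removed; the visit list
  # is not restored, so m2 (anchored at t, whose neighbor u was) cannot
  # pick u up either
  ppi <- rbind(c("s", "u"), c("s", "x"), c("u", "x"), c("x", "z"),
               c("t", "u"), c("t", "y"))
  net <- suppressMessages(assemble_wpi(
    ppi, matrix(character(), ncol = 2L),
    weights = c(s = 1, t = 1, u = 1, x = 5, y = 0, z = 0)))
  seed <- new_seed(net, "s", "t")
  expect_equal(seed$ct_score, -4)
  sp <- span_module_pair(net, seed)
  expect_equal(sp$m1$genes, "s")
  expect_false("u" %in% c(sp$m1$genes, sp$m2$genes))
})

test_that("spanning never crosses modules, and the visit list shrinks monotonically", {
  set.seed(77)
  for (k in 1:20) {
    rt <- random_test_network(sample(6:12, 1L), p_ppi = 0.35)
    pr <- sample(rt$genes, 2L)
    seed <- new_seed(rt$net, pr[1L], pr[2L])
    sp <- span_module_pair(rt$net, seed)
    expect_length(intersect(sp$m1$genes, sp$m2$genes), 0L)
    expect_true(seed$s %in% sp$m1$genes)
    expect_true(seed$t %in% sp$m2$genes)
    expect_false(anyDuplicated(c(sp$m1$genes, sp$m2$genes)) > 0)
  }
})

test_that("merging follows the one-module overlap rule to a fixpoint", {
  # |A n B| = 3 > (2/3)*3 -> merge
  m <- merge_overlapping_modules(list(new_module(c("1", "2", "3")),
                                      new_module(c("1", "2", "3", "9"))))
  expect_length(m$modules, 1L)
  expect_setequal(m$modules[[1L]]$genes, c("1", "2", "3", "9"))
  expect_equal(unname(m$merge_map), c(1L, 1L))
  # boundary: |A n B| = 2 = (2/3)*3 exactly -> no merge (strict rule)
  m2 <- merge_overlapping_modules(list(new_module(c("1", "2", "3")),
                                       new_module(c("2", "3", "4"))))
  expect_length(m2$modules, 2L)
  # disjoint modules unchanged, identity map
  m3 <- merge_overlapping_modules(list(new_module(c("a", "b", "c")),
                                       new_module(c("d", "e", "f"))))
  expect_equal(unname(m3$merge_map), c(1L, 2L))
  # asymmetric sizes: the rule is tested against each module's own size
  m4 <- merge_overlapping_modules(list(
    new_module(c("1", "2", "3")),
    new_module(c("1", "2", "3", "4", "5", "6", "7", "8", "9", "10"))))
  expect_length(m4$modules, 1L)
  # fixpoint + idempotence on random module collections
  set.seed(13)
  for (k in 1:15) {
    mods <- lapply(1:8, function(i)
      new_module(sample(sprintf("g%d", 1:15), sample(3:7, 1L))))
    r1 <- merge_overlapping_modules(mods)
    crit <- function(mm) {
      for (i in seq_along(mm)) for (j in seq_len(i - 1L)) {
        A <- mm[[i]]$genes; B <- mm[[j]]$genes
        if (length(intersect(A, B)) >
            (2 / 3) * min(length(A), length(B))) return(TRUE)
      }
      FALSE
    }
    expect_false(crit(r1$modules))
    r2 <- merge_overlapping_modules(r1$modules)
    expect_equal(lapply(r2$modules, `[[`, "genes"),
                 lapply(r1$modules, `[[`, "genes"))
  }
})

test_that("pair filtering drops merged-together, undersized and duplicate pairs", {
  net <- toy_net()
  seed <- new_seed(net, "s", "t")
  mk <- function(g1, g2, id1, id2, score) {
    p <- new_module_pair(new_module(g1, anchor = g1[[1L]]),
                         new_module(g2, anchor = g2[[1L]]), seed, score)
    p$m1$id <- id1; p$m2$id <- id2
    p
  }
  mods <- list(new_module(c("a", "b", "c"), id = 1L),
               new_module(c("a", "b", "c", "d"), id = 2L),
               new_module(c("x", "y", "z"), id = 3L),
               new_module(c("p", "q"), id = 4L))
  merged <- merge_overlapping_modules(mods)
  # modules 1 and 2 merged together -> a pair across them is dropped
  p_same <- mk(c("a", "b", "c"), c("a", "b", "c", "d"), 1L, 2L, 5)
  # two pairs that map to the same merged pair -> one survivor (higher
  # score kept)
  p_dup1 <- mk(c("a", "b", "c"), c("x", "y", "z"), 1L, 3L, 10)
  p_dup2 <- mk(c("a", "b", "c", "d"), c("x", "y", "z"), 2L, 3L, 8)
  # undersized module -> dropped
  p_small <- mk(c("x", "y", "z"), c("p", "q"), 3L, 4L, 9)
  out <- filter_pairs(list(p_same, p_dup1, p_dup2, p_small), merged)
  expect_length(out, 1L)
  expect_equal(out[[1L]]$mcoop_score, 10)
  expect_setequal(out[[1L]]$m2$genes, c("x", "y", "z"))
})

test_that("discovery is deterministic and returns empty results without seeds", {
  net0 <- suppressMessages(assemble_wpi(
    rbind(c("a", "b")), matrix(character(), ncol = 2L)))
  r0 <- suppressMessages(discover(net0))
  expect_length(r0$pairs, 0L)
  expect_length(r0$modules, 0L)
  set.seed(55)
  rt <- random_test_network(14L, p_ppi = 0.3)
  r1 <- discover(rt$net)
  r2 <- discover(rt$net)
  expect_equal(lapply(r1$modules, `[[`, "genes"),
               lapply(r2$modules, `[[`, "genes"))
  expect_equal(vapply(r1$pairs, `[[`, numeric(1L), "mcoop_score"),
               vapply(r2$pairs, `[[`, numeric(1L), "mcoop_score"))
  # after merge + filter, no retained pair satisfies the overlap rule
  for (p in r1$pairs) {
    A <- p$m1$genes; B <- p$m2$genes
    expect_lte(length(intersect(A, B)),
               (2 / 3) * min(length(A), length(B)))
  }
})

test_that("zeroing a bridge gene's weight never raises a seed score", {
  set.seed(91)
  for (k in 1:10) {
    rt <- random_test_network(10L, p_ppi = 0.3)
    g <- sample(rt$genes, 1L)
    w2 <- rt$w; w2[[g]] <- 0
    net2 <- suppressMessages(assemble_wpi(rt$ppi, rt$reg, w2,
                                          extra_genes = rt$genes))
    others <- setdiff(rt$genes, g)
    for (q in 1:5) {
      pr <- sample(others, 2L)
      s1 <- consistency_score(rt$net, pr[1L], pr[2L])
      s2 <- consistency_score(net2, pr[1L], pr[2L])
      # g bridges the pair when both link counts beat expectation;
      # zeroing its weight then removes a positive contribution
      n1 <- oracle_links_to_set(rt$ppi, rt$reg, g, pr[1L])
      n2 <- oracle_links_to_set(rt$ppi, rt$reg, g, pr[2L])
      nl <- oracle_nl(rt$ppi, rt$reg, g)
      if (n1 > nl / 10 && n2 > nl / 10) {
        expect_lte(s2, s1)
      }
    }
  }
}
)
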