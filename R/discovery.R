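#' Discovery configuration
#'
#' Tuning parameters for seed selection, spanning and merging.
#'
#' @param seed_percentile Percentile (0-100, exclusive) of the non-zero
#'   singleton consistency-score distribution above which gene pairs
#'   become seeds (default 99).
#' @param R Link-reliability factor for the mediation score (default
#'   0.9).
#' @param overlap_fraction Fraction of one module's genes that must be
#'   contained in another for the two to count as highly overlapped
#'   (default 2/3).
#' @param min_module_size Minimum module size for a pair to be reported
#'   (default 3).
#' @return A `discovery_config` list.
#' @export
discovery_config <- function(seed_percentile = 99, R = 0.9,
                             overlap_fraction = 2 / 3,
                             min_module_size = 3L) {
  stopifnot(seed_percentile > 0, seed_percentile < 100,
            R >= 0, R <= 1,
            overlap_fraction > 0, overlap_fraction <= 1,
            min_module_size >= 1L)
  structure(list(seed_percentile = seed_percentile, R = R,
                 overlap_fraction = overlap_fraction,
                 min_module_size = as.integer(min_module_size)),
            class = "discovery_config")
}

#' Select seed gene pairs
#'
#' Computes the consistency score of every candidate gene pair (see
#' [enumerate_seed_candidates()]), ranks the non-zero scores and keeps
#' the pairs scoring strictly above the `seed_percentile`-th percentile
#' (linear-interpolation percentile).  Seeds are returned in
#' deterministic order: score descending, then lexicographic pair.
#'
#' @param net A `wpi_network`.
#' @param cfg A `discovery_config`.
#' @return A list of `cm_seed` objects (possibly empty, with a warning
#'   log when all scores are zero).
#' @export
select_seeds <- function(net, cfg = discovery_config()) {
  ps <- consistency_pair_scores(net)
  ut <- upper.tri(ps$score)
  sel <- ut & ps$candidate & ps$score != 0
  if (!any(sel)) {
    cm_log("all pair consistency scores are zero: no seeds",
           level = "warn")
    return(list())
  }
  idx <- which(sel, arr.ind = TRUE)
  scores <- ps$score[sel]
  thr <- stats::quantile(scores, probs = cfg$seed_percentile / 100,
                         names = FALSE, type = 7)
  keep <- scores > thr
  if (!any(keep)) return(list())
  s <- net$genes[idx[keep, 1L]]
  t <- net$genes[idx[keep, 2L]]
  sc <- scores[keep]
  a <- pmin(s, t); b <- pmax(s, t)
  o <- order(-sc, a, b)
  mapply(function(si, ti, v) {
    structure(list(s = si, t = ti, ct_score = v), class = "cm_seed")
  }, a[o], b[o], sc[o], SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

# One extension sweep of the spanning algorithm (the recursive
# Module_extend subroutine, realized iteratively; the printed recursion
# is tail-recursive so a loop reproduces it exactly).
#
# state: environment with visit (logical over gene indices), max_score.
# Extends `mod_genes` (anchored at `anchor`, growing from `y`) against
# the fixed opposite module; cooper_center is the opposite anchor gene.
module_extend_sweep <- function(net, cooper_center, mod_genes, other_genes,
                                seed, state, y, R) {
  repeat {
    yi <- match(y, net$genes)
    cand <- unique(net$nbr[[yi]])
    cand <- cand[state$visit[cand]]
    if (length(cand) == 0L) return(mod_genes)
    # best CMRatio neighbor, ties broken by lexicographic gene id
    ids <- net$genes[cand]
    cm <- vapply(ids, function(g) cmratio(net, y, g), numeric(1L))
    o <- order(-cm, ids)
    pick <- ids[o[1L]]
    state$visit[match(pick, net$genes)] <- FALSE
    trial <- c(mod_genes, pick)
    trial_pair <- make_trial_pair(net, trial, other_genes, seed)
    mcoop <- cooperation_score(net, trial_pair, R)
    if (mcoop >= state$max_score) {
      state$max_score <- mcoop
      mod_genes <- trial
      if (ct_single(net, pick, cooper_center) >=
          ct_single(net, y, cooper_center)) {
        y <- pick          # recurse from the newly placed gene
        next
      }
      return(mod_genes)    # kept, but the chain stops here
    }
    # score dropped: remove the candidate from the module (it stays
    # consumed from the visit list) and stop
    return(mod_genes)
  }
}

make_trial_pair <- function(net, g1, g2, seed) {
  if (seed$s %in% g1) {
    new_module_pair(new_module(g1, anchor = seed$s),
                    new_module(g2, anchor = seed$t), seed)
  } else {
    new_module_pair(new_module(g2, anchor = seed$s),
                    new_module(g1, anchor = seed$t), seed)
  }
}

#' Grow a module pair from a seed (the spanning algorithm)
#'
#' Starting from `m1 = {s}`, `m2 = {t}` and a shared running maximum
#' initialized to the seed's consistency score, the first module is
#' extended with cooperation center `t`, then the second with
#' cooperation center `s`.  Each extension step takes the current gene's
#' best-shared-partner unvisited neighbor, accepts it if the cooperation
#' score does not fall below the running maximum, and continues the
#' chain only while the direct consistency with the cooperation center
#' is non-decreasing.  Genes consumed from the visit list during a
#' failed addition are never reconsidered.
#'
#' @param net A `wpi_network`.
#' @param seed A `cm_seed` (genes must exist in the network).
#' @param cfg A `discovery_config` (supplies `R`).
#' @return A `cm_module_pair` with the final cooperation score attached.
#' @export
span_module_pair <- function(net, seed, cfg = discovery_config()) {
  if (!all(c(seed$s, seed$t) %in% net$genes)) {
    stop("seed genes not in network", call. = FALSE)
  }
  state <- new.env(parent = emptyenv())
  state$visit <- rep(TRUE, length(net$genes))
  state$visit[match(c(seed$s, seed$t), net$genes)] <- FALSE
  state$max_score <- ct_single(net, seed$s, seed$t)
  g1 <- seed$s
  g2 <- seed$t
  g1 <- module_extend_sweep(net, cooper_center = seed$t, mod_genes = g1,
                            other_genes = g2, seed = seed, state = state,
                            y = seed$s, R = cfg$R)
  g2 <- module_extend_sweep(net, cooper_center = seed$s, mod_genes = g2,
                            other_genes = g1, seed = seed, state = state,
                            y = seed$t, R = cfg$R)
  pair <- new_module_pair(new_module(g1, anchor = seed$s),
                          new_module(g2, anchor = seed$t), seed)
  pair$mcoop_score <- cooperation_score(net, pair, cfg$R)
  pair
}

#' Iteratively merge highly overlapped modules
#'
#' Two modules are highly overlapped when more than `overlap_fraction`
#' of either module's genes are contained in the other, i.e.
#' `|A n B| > overlap_fraction * min(|A|, |B|)`.  Qualifying pairs are
#' merged by set union, highest overlap ratio first (ties by smallest
#' module ids), and the criterion is re-evaluated until no pair
#' qualifies.  Merging is therefore idempotent on its own output.
#'
#' @param modules List of `cm_module` objects (ids are assigned by
#'   position when missing).
#' @param cfg A `discovery_config`.
#' @return A list with `modules` (the merged modules, re-indexed) and
#'   `merge_map` (named integer vector: original module id -> merged
#'   module id).
#' @export
merge_overlapping_modules <- function(modules, cfg = discovery_config()) {
  k <- length(modules)
  if (k == 0L) {
    return(list(modules = list(), merge_map = integer()))
  }
  sets <- lapply(modules, module_genes)
  anchors <- vapply(modules, function(m) {
    if (inherits(m, "cm_module")) m$anchor else module_genes(m)[[1L]]
  }, character(1L))
  group <- seq_len(k)          # original module -> current cluster
  # membership matrix over the union of genes; overlap counts are kept
  # incrementally so each merge only recomputes one row/column
  univ <- sort(unique(unlist(sets)))
  M <- matrix(0, nrow = k, ncol = length(univ))
  for (i in seq_len(k)) M[i, match(sets[[i]], univ)] <- 1
  OV <- tcrossprod(M)
  size <- rowSums(M)
  active <- rep(TRUE, k)
  repeat {
    minsz <- outer(size, size, pmin)
    qual <- OV > cfg$overlap_fraction * minsz
    qual[!upper.tri(qual)] <- FALSE
    qual[!active, ] <- FALSE
    qual[, !active] <- FALSE
    if (!any(qual)) break
    ratio <- ifelse(qual, OV / minsz, -Inf)
    rmax <- max(ratio)
    cand <- which(ratio >= rmax - 1e-12, arr.ind = TRUE)
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    keep <- cand[1L, 1L]; gone <- cand[1L, 2L]
    M[keep, ] <- pmax(M[keep, ], M[gone, ])
    size[[keep]] <- sum(M[keep, ])
    OV[keep, ] <- as.numeric(M %*% M[keep, ])
    OV[, keep] <- OV[keep, ]
    active[[gone]] <- FALSE
    group[group == gone] <- keep
  }
  for (i in which(active)) sets[[i]] <- univ[M[i, ] == 1]
  reps <- sort(unique(group))
  merged <- lapply(seq_along(reps), function(j) {
    r <- reps[[j]]
    g <- sets[[r]]
    anc <- anchors[[r]]
    if (!anc %in% g) anc <- g[[1L]]
    new_module(g, anchor = anc, id = j)
  })
  merge_map <- match(group, reps)
  names(merge_map) <- as.character(seq_len(k))
  list(modules = merged, merge_map = merge_map)
}

#' Filter module pairs after merging
#'
#' Drops pairs whose two modules merged together or whose merged modules
#' still satisfy the overlap criterion, pairs with a module smaller than
#' `min_module_size`, and duplicate pairs that became identical after
#' mapping (the highest-scoring instance is kept).
#'
#' @param pairs List of `cm_module_pair` (with original module ids 1..k
#'   in discovery order, two per pair).
#' @param merged Result of [merge_overlapping_modules()].
#' @param cfg A `discovery_config`.
#' @return A list of retained `cm_module_pair` objects whose modules are
#'   the merged modules.
#' @export
filter_pairs <- function(pairs, merged, cfg = discovery_config()) {
  if (length(pairs) == 0L) return(list())
  out <- list()
  seen_key <- character()
  seen_score <- numeric()
  ord <- order(-vapply(pairs, function(p) p$mcoop_score, numeric(1L)))
  for (p in pairs[ord]) {
    id1 <- merged$merge_map[[as.character(p$m1$id)]]
    id2 <- merged$merge_map[[as.character(p$m2$id)]]
    if (id1 == id2) next
    mm1 <- merged$modules[[id1]]
    mm2 <- merged$modules[[id2]]
    ov <- length(intersect(mm1$genes, mm2$genes))
    if (ov > cfg$overlap_fraction * min(length(mm1$genes),
                                        length(mm2$genes))) next
    if (length(mm1$genes) < cfg$min_module_size ||
        length(mm2$genes) < cfg$min_module_size) next
    key <- paste(sort(c(id1, id2)), collapse = "-")
    if (key %in% seen_key) next
    seen_key <- c(seen_key, key)
    q <- p
    lo <- min(id1, id2); hi <- max(id1, id2)
    q$m1 <- merged$modules[[lo]]
    q$m2 <- merged$modules[[hi]]
    q$merged <- TRUE
    out[[length(out) + 1L]] <- q
  }
  for (k in seq_along(out)) out[[k]]$pair_id <- k
  out
}

#' Discover cooperative module pairs
#'
#' Composes seed selection, spanning, merging and filtering into the
#' full discovery stage.  Deterministic given the network and
#' configuration.
#'
#' @param net A `wpi_network`.
#' @param cfg A `discovery_config`.
#' @return A `cm_discovery` list: `modules` (merged modules), `pairs`
#'   (retained pairs over merged modules), `merge_map`, and `provenance`
#'   (per-seed data frame of seed genes, seed score and spanned score).
#' @export
discover <- function(net, cfg = discovery_config()) {
  seeds <- select_seeds(net, cfg)
  if (length(seeds) == 0L) {
    return(structure(list(modules = list(), pairs = list(),
                          merge_map = integer(),
                          provenance = data.frame()),
                     class = "cm_discovery"))
  }
  raw_pairs <- vector("list", length(seeds))
  raw_modules <- vector("list", 2L * length(seeds))
  for (k in seq_along(seeds)) {
    p <- span_module_pair(net, seeds[[k]], cfg)
    p$m1$id <- 2L * k - 1L
    p$m2$id <- 2L * k
    raw_pairs[[k]] <- p
    raw_modules[[2L * k - 1L]] <- p$m1
    raw_modules[[2L * k]] <- p$m2
  }
  merged <- merge_overlapping_modules(raw_modules, cfg)
  pairs <- filter_pairs(raw_pairs, merged, cfg)
  provenance <- data.frame(
    seed_s = vapply(seeds, function(s) s$s, character(1L)),
    seed_t = vapply(seeds, function(s) s$t, character(1L)),
    seed_score = vapply(seeds, function(s) s$ct_score, numeric(1L)),
    mcoop_score = vapply(raw_pairs, function(p) p$mcoop_score,
                         numeric(1L)),
    m1_size = vapply(raw_pairs, function(p) length(p$m1$genes),
                     integer(1L)),
    m2_size = vapply(raw_pairs, function(p) length(p$m2$genes),
                     integer(1L)),
    stringsAsFactors = FALSE
  )
  structure(list(modules = merged$modules, pairs = pairs,
                 merge_map = merged$merge_map, provenance = provenance),
            class = "cm_discovery")
}

#' @export
print.cm_discovery <- function(x, ...) {
  cat(sprintf("cm_discovery: %d merged modules, %d retained pairs\n",
              length(x$modules), length(x$pairs)))
  invisible(x)
}
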