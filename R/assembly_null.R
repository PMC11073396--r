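# Ecological assembly inference: betaMNTD, the betaNTI tip-shuffle null,
# Raup-Crick with Bray-Curtis, and classification of sample pairs into
# assembly processes (selection / dispersal / drift) with group-level
# process fractions.
#
# The inferential logic follows the standard null-model framework for
# microbial community assembly: |betaNTI| > 2 marks deterministic
# (selection) processes, with the sign separating heterogeneous (+) from
# homogeneous (-) selection; pairs inside the stochastic band are split by
# RCbray beyond +/-0.95 into dispersal limitation (+) or homogenizing
# dispersal (-), the remainder being drift.

#' Null-model configuration
#' @param n_null Number of null randomisations (>= 99; default 999).
#' @param seed Seed for the randomisations.
#' @param abundance_weighted Weight betaMNTD by relative abundance
#'   (default `TRUE`).
#' @param pool_scope `"per_lake"` (null pool and pairs within each lake,
#'   the default) or `"global"`.
#' @return A `null_config` list.
#' @export
null_config <- function(n_null = 999, seed = 1L,
                        abundance_weighted = TRUE,
                        pool_scope = c("per_lake", "global")) {
  pool_scope <- match.arg(pool_scope)
  if (n_null < 99) stop("n_null must be >= 99")
  structure(list(n_null = as.integer(n_null), seed = as.integer(seed),
                 abundance_weighted = abundance_weighted,
                 pool_scope = pool_scope),
            class = "null_config")
}

## fast row/col minima of a positive matrix via max.col (C code)
row_mins <- function(m) m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]

## betaMNTD for one pair given the patristic matrix and index/weight sets
bmntd_pair <- function(D, ix, iy, wx, wy) {
  sub <- D[ix, iy, drop = FALSE]
  0.5 * (sum(wx * row_mins(sub)) + sum(wy * row_mins(t(sub))))
}

#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' Average patristic distance from each taxon of one community to its
#' nearest relative in the other, in both directions:
#' `0.5 * (sum_i f_i min_j d_ij + sum_j g_j min_i d_ij)` with `f`, `g` the
#' relative abundances (uniform over present taxa when unweighted).
#'
#' @param tree A `phylo`, or a precomputed patristic matrix with taxon
#'   dimnames.
#' @param x,y Named non-negative count vectors (names are taxa).
#' @param abundance_weighted Weight by relative abundance (default `TRUE`).
#' @return Non-negative real.
#' @export
bmntd <- function(tree, x, y, abundance_weighted = TRUE) {
  D <- if (is.matrix(tree)) tree else patristic_distances(tree)
  if (is.null(names(x)) || is.null(names(y))) stop("x and y must be named by taxon")
  px <- names(x)[x > 0]; py <- names(y)[y > 0]
  if (!length(px) || !length(py)) stop("empty community")
  unknown <- setdiff(c(px, py), rownames(D))
  if (length(unknown)) stop("taxa not in tree: ", paste(unknown, collapse = ", "))
  wx <- if (abundance_weighted) x[px] / sum(x[px]) else rep(1 / length(px), length(px))
  wy <- if (abundance_weighted) y[py] / sum(y[py]) else rep(1 / length(py), length(py))
  bmntd_pair(D, match(px, rownames(D)), match(py, rownames(D)), wx, wy)
}

## presence index sets and weights for every sample of a community matrix
community_sets <- function(comm, abundance_weighted) {
  lapply(seq_len(ncol(comm)), function(s) {
    ix <- which(comm[, s] > 0)
    if (!length(ix)) stop("empty sample: ", colnames(comm)[s])
    w <- if (abundance_weighted) comm[ix, s] / sum(comm[ix, s]) else
      rep(1 / length(ix), length(ix))
    list(ix = ix, w = w)
  })
}

#' betaNTI for all sample pairs of a table
#'
#' Standardised effect size of observed betaMNTD against a null built by
#' shuffling taxon labels across the tips of the pool (equivalently,
#' jointly permuting the rows/columns of the patristic matrix while holding
#' every community's abundance structure fixed). Each pair receives its own
#' independent set of `n_null` shuffles.
#'
#' @param counts Abundance matrix (taxa x samples); its taxa with any
#'   presence form the null pool.
#' @param tree A `phylo` covering the taxa, or a patristic matrix.
#' @param n_null Number of shuffles (default 999).
#' @param seed Seed.
#' @param abundance_weighted Weight betaMNTD by relative abundances.
#' @return data.frame per unordered pair: `sample_i`, `sample_j`,
#'   `bmntd_obs`, `bnti` (`NA` with a warning where the null sd is 0).
#' @export
bnti_pairs <- function(counts, tree, n_null = 999, seed = 1L,
                       abundance_weighted = TRUE) {
  D <- if (is.matrix(tree)) tree else patristic_distances(tree)
  pres <- rowSums(counts) > 0
  comm <- counts[pres, , drop = FALSE]
  comm <- comm[order(rownames(comm)), , drop = FALSE]  # canonical taxon order
  miss <- setdiff(rownames(comm), rownames(D))
  if (length(miss)) stop("taxa not in tree: ", paste(miss, collapse = ", "))
  D <- D[rownames(comm), rownames(comm)]
  S <- ncol(comm)
  sets <- community_sets(comm, abundance_weighted)
  pk <- pair_index(S)
  np <- nrow(pk)
  ntip <- nrow(D)
  obs <- numeric(np); mu <- numeric(np); sdv <- numeric(np)
  with_seed(seed, {
    for (k in seq_len(np)) {
      a <- sets[[pk[k, 1]]]; b <- sets[[pk[k, 2]]]
      obs[k] <- bmntd_pair(D, a$ix, b$ix, a$w, b$w)
      nulls <- vapply(seq_len(n_null), function(r) {
        p <- sample.int(ntip)
        bmntd_pair(D, p[a$ix], p[b$ix], a$w, b$w)
      }, numeric(1))
      mu[k] <- mean(nulls)
      sdv[k] <- stats::sd(nulls)
    }
  })
  bnti <- (obs - mu) / sdv
  degenerate <- sdv == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " pair(s) with zero null sd: betaNTI undefined, excluded")
    bnti[degenerate] <- NA_real_
  }
  data.frame(sample_i = colnames(comm)[pk[, 1]],
             sample_j = colnames(comm)[pk[, 2]],
             bmntd_obs = obs, bnti = bnti, stringsAsFactors = FALSE)
}

#' betaNTI for a single pair of communities
#'
#' The null pool is the full tip set of `tree` (prune the tree to the
#' configured pool beforehand).
#'
#' @param tree `phylo` or patristic matrix spanning the pool.
#' @param x,y Named count vectors.
#' @param config A [null_config()].
#' @return List with `bmntd_obs`, `bnti`, `null_mean`, `null_sd`.
#' @export
bnti <- function(tree, x, y, config = null_config()) {
  D <- if (is.matrix(tree)) tree else patristic_distances(tree)
  obs <- bmntd(D, x, y, config$abundance_weighted)
  nulls <- with_seed(config$seed, {
    vapply(seq_len(config$n_null), function(b) {
      p <- sample(rownames(D))
      Dp <- D
      dimnames(Dp) <- list(p, p)
      bmntd(Dp, x, y, config$abundance_weighted)
    }, numeric(1))
  })
  sdv <- stats::sd(nulls)
  z <- if (sdv == 0) {
    warning("zero null sd: betaNTI undefined")
    NA_real_
  } else (obs - mean(nulls)) / sdv
  list(bmntd_obs = obs, bnti = z, null_mean = mean(nulls), null_sd = sdv)
}

## Raup-Crick score from an observed value and its null sample, rescaled to
## [-1, 1], ties at half weight (mid-p convention):
## rc = 2 * ((#null < obs) + 0.5 (#null = obs)) / n_null - 1
rc_score <- function(obs, nulls, eps = 1e-12) {
  2 * ((sum(nulls < obs - eps) + 0.5 * sum(abs(nulls - obs) <= eps)) /
         length(nulls)) - 1
}

## null communities for RCbray: for each sample, n_null random assemblies
## preserving observed richness (inclusion prob ~ pool occupancy; each
## drawn taxon seeded with one read) and observed total (remainder filled
## multinomially ~ pool mean relative abundance among the drawn taxa)
rc_null_communities <- function(comm, occ, relab, n_null) {
  nt <- nrow(comm)
  lapply(seq_len(ncol(comm)), function(s) {
    R <- sum(comm[, s] > 0); N <- sum(comm[, s])
    out <- matrix(0L, nt, n_null)
    for (b in seq_len(n_null)) {
      taxa <- sample.int(nt, R, prob = occ)
      p <- relab[taxa]
      out[taxa, b] <- 1L + stats::rmultinom(1, N - R, p / sum(p))
    }
    out
  })
}

#' Raup-Crick (Bray-Curtis) for all sample pairs of a table
#'
#' For each randomisation every community is reassembled from the regional
#' pool (all taxa of `counts`) preserving its observed richness and total;
#' RCbray is the position of the observed Bray-Curtis within that null,
#' rescaled to `[-1, 1]` with half-weight for ties (mid-p convention):
#' `rc = 2 * ((#null < obs) + 0.5 (#null = obs)) / n_null - 1`.
#'
#' @param counts Abundance matrix (taxa x samples); defines the pool.
#' @param n_null Number of null assemblies (default 999).
#' @param seed Seed.
#' @return data.frame per unordered pair: `sample_i`, `sample_j`,
#'   `bray_obs`, `rc_bray`.
#' @export
rc_bray_pairs <- function(counts, n_null = 999, seed = 1L) {
  pres <- rowSums(counts) > 0
  comm <- counts[pres, , drop = FALSE]
  comm <- comm[order(rownames(comm)), , drop = FALSE]  # canonical taxon order
  if (nrow(comm) < max(colSums(comm > 0))) stop("pool smaller than maximum richness")
  occ <- rowSums(comm > 0)
  relab <- rowMeans(sweep(comm, 2, colSums(comm), "/"))
  S <- ncol(comm)
  nulls <- with_seed(seed, rc_null_communities(comm, occ, relab, n_null))
  pk <- pair_index(S)
  out <- data.frame(sample_i = colnames(comm)[pk[, 1]],
                    sample_j = colnames(comm)[pk[, 2]],
                    bray_obs = NA_real_, rc_bray = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(pk))) {
    i <- pk[k, 1]; j <- pk[k, 2]
    obs <- bray_curtis(comm[, i], comm[, j])
    nb <- colSums(abs(nulls[[i]] - nulls[[j]])) / colSums(nulls[[i]] + nulls[[j]])
    out$bray_obs[k] <- obs
    out$rc_bray[k] <- rc_score(obs, nb)
  }
  out
}

#' Raup-Crick (Bray-Curtis) for one sample pair
#'
#' Pool statistics (occupancy, mean relative abundance) come from the whole
#' table; null assemblies are built only for the two samples.
#'
#' @param counts Abundance matrix defining the regional pool.
#' @param pair Length-2 vector of sample ids (or column indices).
#' @param config A [null_config()].
#' @return RCbray value in `[-1, 1]`.
#' @export
raup_crick_bray <- function(counts, pair, config = null_config()) {
  if (length(pair) != 2) stop("pair must have length 2")
  if (is.character(pair)) pair <- match(pair, colnames(counts))
  if (anyNA(pair)) stop("unknown sample in pair")
  pres <- rowSums(counts) > 0
  comm <- counts[pres, , drop = FALSE]
  if (nrow(comm) < max(colSums(comm > 0))) stop("pool smaller than maximum richness")
  occ <- rowSums(comm > 0)
  relab <- rowMeans(sweep(comm, 2, colSums(comm), "/"))
  sub <- comm[, pair, drop = FALSE]
  nulls <- with_seed(config$seed, rc_null_communities(sub, occ, relab, config$n_null))
  obs <- bray_curtis(sub[, 1], sub[, 2])
  nb <- colSums(abs(nulls[[1]] - nulls[[2]])) / colSums(nulls[[1]] + nulls[[2]])
  rc_score(obs, nb)
}

#' Classify a sample pair into an ecological assembly process
#'
#' Vectorised over pairs. `betaNTI > 2` is heterogeneous selection,
#' `betaNTI < -2` homogeneous selection (deterministic, strict
#' inequalities, so exactly +/-2 falls in the stochastic band). Inside the
#' band, `RCbray > 0.95` is dispersal limitation, `RCbray < -0.95`
#' homogenizing dispersal, anything else (including exactly +/-0.95) drift.
#' Undefined inputs yield `NA` with a warning.
#'
#' @param bnti Numeric vector of betaNTI values.
#' @param rc_bray Numeric vector of RCbray values in `[-1, 1]`.
#' @param bnti_threshold Selection threshold on `|betaNTI|` (default 2).
#' @param rc_threshold Dispersal threshold on `|RCbray|` (default 0.95).
#' @return Character vector of process labels.
#' @export
classify_assembly <- function(bnti, rc_bray, bnti_threshold = 2,
                              rc_threshold = 0.95) {
  if (length(bnti) != length(rc_bray)) stop("inputs must have equal length")
  if (any(abs(rc_bray) > 1 + 1e-12, na.rm = TRUE)) stop("rc_bray outside [-1, 1]")
  out <- rep(NA_character_, length(bnti))
  ok <- is.finite(bnti) & is.finite(rc_bray)
  if (any(!ok)) warning(sum(!ok), " pair(s) with undefined inputs excluded from classification")
  out[ok & bnti > bnti_threshold] <- "heterogeneous_selection"
  out[ok & bnti < -bnti_threshold] <- "homogeneous_selection"
  mid <- ok & abs(bnti) <= bnti_threshold
  out[mid] <- "drift"
  out[mid & rc_bray > rc_threshold] <- "dispersal_limitation"
  out[mid & rc_bray < -rc_threshold] <- "homogenizing_dispersal"
  out
}

#' Full assembly-process analysis of a study
#'
#' Runs betaNTI and RCbray for every sample pair within each null-pool
#' scope (each lake by default) and classifies the pairs.
#'
#' @param counts Abundance matrix (taxa x samples).
#' @param tree Phylogeny covering the taxa (or patristic matrix).
#' @param metadata Sample metadata.
#' @param config A [null_config()].
#' @return data.frame per pair: scope column(s), ids, `bmntd_obs`, `bnti`,
#'   `bray_obs`, `rc_bray`, `process`.
#' @export
assembly_analysis <- function(counts, tree, metadata, config = null_config()) {
  D <- if (is.matrix(tree)) tree else patristic_distances(match_tree_table(tree, counts))
  meta <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  groups <- if (config$pool_scope == "per_lake") split(colnames(counts), meta$lake)
            else list(global = colnames(counts))
  out <- do.call(rbind, lapply(seq_along(groups), function(g) {
    ids <- groups[[g]]
    if (length(ids) < 2) return(NULL)
    sub <- counts[, ids, drop = FALSE]
    seed_g <- derive_seed(config$seed, "assembly") + g
    bn <- bnti_pairs(sub, D, n_null = config$n_null, seed = seed_g,
                     abundance_weighted = config$abundance_weighted)
    rc <- rc_bray_pairs(sub, n_null = config$n_null, seed = seed_g + 1L)
    stopifnot(identical(bn$sample_i, rc$sample_i))
    cbind(data.frame(pool = names(groups)[g], stringsAsFactors = FALSE),
          bn, rc[, c("bray_obs", "rc_bray")],
          process = classify_assembly(bn$bnti, rc$rc_bray))
  }))
  rownames(out) <- NULL
  out
}

#' Relative contribution of each assembly process per group
#'
#' Fractions over classified pairs, per group (and optionally per
#' succession stage: pairs whose two samples share a collection day). Also
#' reports the deterministic share (both selection types), stochastic
#' share, and the homogenizing (homogeneous selection + homogenizing
#' dispersal) vs differentiating (heterogeneous selection + dispersal
#' limitation) aggregates.
#'
#' @param results Pair table from [assembly_analysis()].
#' @param metadata Sample metadata.
#' @param group_by Metadata column(s) defining groups (default `"lake"`).
#' @param stage_by Optional stage column (e.g. `"day"`); only same-stage
#'   pairs are used when given.
#' @return data.frame keyed by group (and stage), one column per process,
#'   plus the aggregate shares; fractions sum to 1 per row.
#' @export
process_fractions <- function(results, metadata, group_by = "lake",
                              stage_by = NULL) {
  processes <- c("heterogeneous_selection", "homogeneous_selection",
                 "dispersal_limitation", "homogenizing_dispersal", "drift")
  mi <- metadata[match(results$sample_i, metadata$sample_id), , drop = FALSE]
  mj <- metadata[match(results$sample_j, metadata$sample_id), , drop = FALSE]
  keep <- !is.na(results$process)
  for (g in group_by) keep <- keep & mi[[g]] == mj[[g]]
  if (!is.null(stage_by)) keep <- keep & mi[[stage_by]] == mj[[stage_by]]
  res <- results[keep, , drop = FALSE]
  key <- mi[keep, c(group_by, stage_by), drop = FALSE]
  cells <- split(seq_len(nrow(res)), key, drop = TRUE)
  out <- do.call(rbind, lapply(cells, function(ix) {
    f <- table(factor(res$process[ix], levels = processes)) / length(ix)
    f <- as.numeric(f); names(f) <- processes
    cbind(key[ix[1], , drop = FALSE],
          data.frame(n_pairs = length(ix), as.list(f),
                     deterministic_share = f["heterogeneous_selection"] + f["homogeneous_selection"],
                     stochastic_share = f["dispersal_limitation"] + f["homogenizing_dispersal"] + f["drift"],
                     homogenizing_share = f["homogeneous_selection"] + f["homogenizing_dispersal"],
                     differentiating_share = f["heterogeneous_selection"] + f["dispersal_limitation"]))
  }))
  rownames(out) <- NULL
  out
}
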