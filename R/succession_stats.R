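# Succession statistics: time-decay of community similarity (temporal
# turnover rate), PERMANOVA with interactions, Mantel tests against
# environmental distances, and the convergence-trend statistic.

#' Time-decay of community similarity
#'
#' Regresses pairwise community similarity on the time separation between
#' samples, per group; the slope magnitude is the temporal turnover rate.
#' The default is the standard log-log distance-decay form,
#' `log10(similarity) ~ log10(dt)`; a linear form is available and the
#' transform used is recorded in the result. Pairs with similarity <= 0,
#' and (for the log form) pairs with zero time separation, are excluded
#' and counted.
#'
#' @param similarity Sample x sample similarity matrix (e.g. 1 - Sorensen
#'   dissimilarity).
#' @param metadata Sample metadata with `sample_id` and `day`.
#' @param group_by Optional metadata columns splitting the fits.
#' @param transform `"log10"` (default) or `"linear"`.
#' @return data.frame per group: `slope` (signed), `turnover_rate`
#'   (`|slope|`), `intercept`, `r_squared`, `n_pairs`, `n_excluded`,
#'   `transform`. Groups with fewer than 3 usable pairs are skipped with a
#'   warning.
#' @export
time_decay <- function(similarity, metadata, group_by = NULL,
                       transform = c("log10", "linear")) {
  transform <- match.arg(transform)
  ids <- rownames(similarity)
  meta <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop("metadata does not cover all samples in the matrix")
  groups <- if (is.null(group_by)) list(all = seq_along(ids))
            else split(seq_along(ids), meta[, group_by, drop = FALSE], drop = TRUE)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    ix <- groups[[g]]
    pk <- pair_index(length(ix))
    if (nrow(pk) == 0) return(NULL)
    sim <- similarity[cbind(ix[pk[, 1]], ix[pk[, 2]])]
    dt <- abs(meta$day[ix[pk[, 1]]] - meta$day[ix[pk[, 2]]])
    drop <- sim <= 0 | (transform == "log10" & dt == 0)
    n_excluded <- sum(drop)
    sim <- sim[!drop]; dt <- dt[!drop]
    if (length(sim) < 3) {
      warning("group '", g, "': fewer than 3 usable pairs, fit skipped")
      return(NULL)
    }
    if (length(unique(dt)) < 2) stop("group '", g, "': all pairs at one time distance")
    if (transform == "log10") { yv <- log10(sim); xv <- log10(dt) }
    else { yv <- sim; xv <- dt }
    if (stats::var(yv) == 0) {
      slope <- 0; intercept <- yv[1]; r2 <- 0   # flat similarity: nothing explained
    } else {
      fit <- stats::lm(yv ~ xv)
      slope <- unname(stats::coef(fit)[2])
      intercept <- unname(stats::coef(fit)[1])
      # noiseless inputs fit perfectly; the lm summary warning is expected
      r2 <- suppressWarnings(summary(fit)$r.squared)
    }
    key <- if (is.null(group_by)) data.frame(group = g, stringsAsFactors = FALSE)
           else meta[ix[1], group_by, drop = FALSE]
    cbind(key, data.frame(slope = slope, turnover_rate = abs(slope),
                          intercept = intercept, r_squared = r2,
                          n_pairs = length(sim), n_excluded = n_excluded,
                          transform = transform, stringsAsFactors = FALSE))
  }))
  rownames(out) <- NULL
  out
}

#' PERMANOVA of a distance matrix on design factors
#'
#' Sequential (Type-I) partitioning of the Gower-centred distance matrix in
#' the order the terms are supplied, with pseudo-F per term and p-values by
#' free permutation of sample labels (restricted within `strata` blocks
#' when given). A thin, seeded wrapper around `vegan::adonis2(by =
#' "terms")`.
#'
#' @param dm Sample x sample distance matrix (dimnames = sample ids).
#' @param metadata Sample metadata (one row per sample in `dm`).
#' @param terms Character vector of model terms; interactions as `"a:b"`.
#' @param n_permutations Number of permutations (default 9999).
#' @param seed Seed for the permutations.
#' @param strata Optional metadata column restricting permutations.
#' @param permutations Optional explicit permutation matrix (rows are
#'   permutations), e.g. the full enumeration for small n; overrides
#'   `n_permutations`/`strata`.
#' @return data.frame with one row per term plus a `Residual` row:
#'   `term`, `df`, `sum_sq`, `R2`, `F`, `p` (p is `NA` on the residual
#'   row). Term and residual R2 sum to 1.
#' @export
permanova <- function(dm, metadata, terms, n_permutations = 9999,
                      seed = NULL, strata = NULL, permutations = NULL) {
  dm <- validate_distance_matrix(as.matrix(dm))
  ids <- rownames(dm)
  meta <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop("metadata does not cover all samples in the matrix")
  main <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  for (v in main) {
    if (!v %in% names(meta)) stop("unknown term: ", v)
    if (length(unique(meta[[v]])) < 2) stop("term with a single level: ", v)
  }
  d <- stats::as.dist(dm)
  f <- stats::as.formula(paste("d ~", paste(terms, collapse = " + ")))
  environment(f) <- environment()
  perm <- if (!is.null(permutations)) permutations
          else if (!is.null(strata)) permute::how(blocks = factor(meta[[strata]]),
                                                  nperm = n_permutations)
          else n_permutations
  tab <- with_seed(seed, vegan::adonis2(f, data = meta, permutations = perm,
                                        by = "terms"))
  tab <- as.data.frame(tab)
  tab <- tab[rownames(tab) != "Total", , drop = FALSE]
  out <- data.frame(term = rownames(tab), df = tab$Df, sum_sq = tab$SumOfSqs,
                    R2 = tab$R2, F = tab$F, p = tab$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  stopifnot(abs(sum(out$R2) - 1) < 1e-9)
  out
}

#' Mantel test between two distance matrices
#'
#' Correlation of the off-diagonal entries, with significance by jointly
#' permuting one matrix's rows and columns (seeded wrapper around
#' `vegan::mantel`).
#'
#' @param dm_a,dm_b Distance matrices over the same samples (aligned by
#'   dimnames when present).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param n_permutations Number of permutations (default 999).
#' @param seed Seed.
#' @return List with `r`, `p`, `method`, `n_permutations`.
#' @export
mantel <- function(dm_a, dm_b, method = c("pearson", "spearman"),
                   n_permutations = 999, seed = NULL) {
  method <- match.arg(method)
  dm_a <- as.matrix(dm_a); dm_b <- as.matrix(dm_b)
  if (!all(dim(dm_a) == dim(dm_b))) stop("distance matrices differ in size")
  if (!is.null(rownames(dm_a)) && !is.null(rownames(dm_b))) {
    if (!setequal(rownames(dm_a), rownames(dm_b))) stop("sample sets differ")
    dm_b <- dm_b[rownames(dm_a), rownames(dm_a)]
  }
  res <- with_seed(seed, vegan::mantel(stats::as.dist(dm_a), stats::as.dist(dm_b),
                                       method = method,
                                       permutations = n_permutations))
  list(r = unname(res$statistic), p = res$signif, method = method,
       n_permutations = n_permutations)
}

#' Convergence trend of between-polymer community differences
#'
#' For each lake (or other `within` group), computes the mean pairwise
#' dissimilarity between samples of different polymers at each day, then
#' the OLS slope of that mean against day. A negative slope means the
#' communities on different substrates grow more alike over colonisation
#' time — the convergence effect.
#'
#' @param dm Sample x sample dissimilarity matrix (e.g. Bray-Curtis).
#' @param metadata Sample metadata.
#' @param within Metadata column defining groups (default `"lake"`).
#' @param across Metadata column whose levels are compared (default
#'   `"polymer"`).
#' @return List with `per_day` (group, day, `mean_dissimilarity`,
#'   `n_pairs`) and `trend` (group, `slope`, `intercept`, `r_squared`,
#'   `convergence` logical).
#' @export
convergence_trend <- function(dm, metadata, within = "lake", across = "polymer") {
  ids <- rownames(dm)
  meta <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop("metadata does not cover all samples in the matrix")
  groups <- split(seq_along(ids), meta[[within]], drop = TRUE)
  per_day <- list(); trend <- list()
  for (g in names(groups)) {
    gi <- groups[[g]]
    rows <- list()
    for (d in sort(unique(meta$day[gi]))) {
      ix <- gi[meta$day[gi] == d]
      if (length(unique(meta[[across]][ix])) < 2) {
        warning("group '", g, "' day ", d, ": fewer than 2 ", across,
                " levels, cell skipped")
        next
      }
      pk <- pair_index(length(ix))
      cross <- meta[[across]][ix[pk[, 1]]] != meta[[across]][ix[pk[, 2]]]
      vals <- dm[cbind(ix[pk[cross, 1]], ix[pk[cross, 2]])]
      rows[[length(rows) + 1]] <- data.frame(
        group = g, day = d, mean_dissimilarity = mean(vals),
        n_pairs = sum(cross), stringsAsFactors = FALSE
      )
    }
    pd <- do.call(rbind, rows)
    if (is.null(pd) || nrow(pd) < 2) next
    fit <- stats::lm(mean_dissimilarity ~ day, data = pd)
    r2 <- if (stats::var(pd$mean_dissimilarity) == 0) 0 else
      suppressWarnings(summary(fit)$r.squared)
    per_day[[g]] <- pd
    trend[[g]] <- data.frame(
      group = g, slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]), r_squared = r2,
      convergence = unname(stats::coef(fit)[2]) < 0, stringsAsFactors = FALSE
    )
  }
  list(per_day = do.call(rbind, c(per_day, list(make.row.names = FALSE))),
       trend = do.call(rbind, c(trend, list(make.row.names = FALSE))))
}
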