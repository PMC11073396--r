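# Pairwise beta diversity: Bray-Curtis, and Baselga-family partition of
# Sorensen dissimilarity into species turnover (Simpson component) and
# nestedness, with the beta-ratio statistic beta_sim / beta_sor.

#' Bray-Curtis dissimilarity between two count vectors
#' @param x,y Equal-length non-negative count vectors, not both all-zero.
#' @return Dissimilarity in `[0, 1]`: `sum|x - y| / sum(x + y)`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("both communities are empty")
  sum(abs(x - y)) / tot
}

#' All-pairs Bray-Curtis dissimilarity matrix
#' @param counts Abundance matrix (taxa x samples).
#' @return Symmetric sample x sample matrix in `[0, 1]`.
#' @export
bray_curtis_matrix <- function(counts) {
  d <- as.matrix(vegan::vegdist(t(counts), method = "bray"))
  validate_distance_matrix(d, range = c(0, 1))
}

#' Partition Sorensen dissimilarity into turnover and nestedness
#'
#' Pairwise Baselga decomposition from the incidence overlap counts
#' `a` (shared), `b`, `c` (unique to each side):
#' `beta_sor = (b + c) / (2a + b + c)`,
#' `beta_sim = min(b, c) / (a + min(b, c))` (turnover, Simpson component),
#' `beta_sne = beta_sor - beta_sim` (nestedness), and
#' `beta_ratio = beta_sim / beta_sor` (`NA` and flagged when `beta_sor` is 0,
#' i.e. identical incidence).
#'
#' @param x,y Count or incidence vectors over the same taxa, or omit `y` and
#'   pass precomputed overlap counts via `a`, `b`, `c`.
#' @param a,b,c Optional incidence overlap counts (override `x`, `y`).
#' @return A one-row data.frame `a, b, c, beta_sor, beta_sim, beta_sne,
#'   beta_ratio`.
#' @export
sorensen_partition <- function(x = NULL, y = NULL, a = NULL, b = NULL, c = NULL) {
  if (is.null(a)) {
    if (length(x) != length(y)) stop("vectors must have equal length")
    px <- x > 0; py <- y > 0
    a <- sum(px & py); b <- sum(px & !py); c <- sum(!px & py)
  }
  if (a + b == 0 || a + c == 0) stop("both communities must be non-empty")
  beta_sor <- (b + c) / (2 * a + b + c)
  beta_sim <- if (min(b, c) == 0) 0 else min(b, c) / (a + min(b, c))
  data.frame(
    a = a, b = b, c = c,
    beta_sor = beta_sor,
    beta_sim = beta_sim,
    beta_sne = beta_sor - beta_sim,
    beta_ratio = if (beta_sor > 0) beta_sim / beta_sor else NA_real_
  )
}

#' Sorensen partition over all sample pairs of a table
#' @param counts Abundance matrix (taxa x samples).
#' @return data.frame with one row per unordered pair (`sample_i`,
#'   `sample_j`) and the [sorensen_partition()] columns.
#' @export
sorensen_partition_pairs <- function(counts) {
  ids <- colnames(counts)
  pk <- pair_index(length(ids))
  inc <- counts > 0
  out <- do.call(rbind, lapply(seq_len(nrow(pk)), function(k) {
    i <- pk[k, 1]; j <- pk[k, 2]
    cbind(data.frame(sample_i = ids[i], sample_j = ids[j],
                     stringsAsFactors = FALSE),
          sorensen_partition(inc[, i], inc[, j]))
  }))
  rownames(out) <- NULL
  out
}

#' Sorensen dissimilarity matrix (beta_sor over all pairs)
#' @param counts Abundance matrix (taxa x samples).
#' @return Symmetric sample x sample matrix in `[0, 1]`.
#' @export
sorensen_matrix <- function(counts) {
  d <- as.matrix(vegan::vegdist(t(counts > 0), method = "bray"))
  validate_distance_matrix(d, range = c(0, 1))
}

#' Mean beta-ratio per group and succession stage, with dominance call
#'
#' Averages `beta_ratio` over within-cell sample pairs, one cell per
#' group x stage. By default pairs are restricted to samples of different
#' polymers at the same lake and day — the between-substrate comparison —
#' but all within-cell pairs can be used instead.
#'
#' Dominance is `"turnover"` when the mean exceeds 0.5, else
#' `"nestedness"` (turnover dominates beta diversity above the 0.5
#' threshold).
#'
#' @param counts Abundance matrix (taxa x samples).
#' @param metadata Sample metadata.
#' @param group_by Metadata columns defining groups (default `"lake"`).
#' @param stage_by Stage column (default `"day"`).
#' @param pairs `"cross_polymer"` (default) or `"all"`.
#' @param threshold Dominance boundary on the mean beta-ratio (default 0.5).
#' @return data.frame keyed by group and stage with `n_pairs`,
#'   `n_undefined` (pairs with `beta_sor` = 0, excluded), `beta_ratio_mean`
#'   and `dominance`.
#' @export
beta_ratio_by_group <- function(counts, metadata, group_by = "lake",
                                stage_by = "day",
                                pairs = c("cross_polymer", "all"),
                                threshold = 0.5) {
  pairs <- match.arg(pairs)
  meta <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop("metadata does not cover all samples")
  key <- meta[, c(group_by, stage_by), drop = FALSE]
  cells <- split(seq_len(ncol(counts)), key, drop = TRUE)
  inc <- counts > 0
  rows <- lapply(cells, function(ix) {
    if (length(ix) < 2) {
      warning("cell with fewer than 2 samples skipped")
      return(NULL)
    }
    pk <- pair_index(length(ix))
    keep <- rep(TRUE, nrow(pk))
    if (pairs == "cross_polymer") {
      keep <- meta$polymer[ix[pk[, 1]]] != meta$polymer[ix[pk[, 2]]]
      if (!any(keep)) {
        warning("cell with no cross-polymer pairs skipped")
        return(NULL)
      }
    }
    br <- vapply(which(keep), function(k) {
      sorensen_partition(inc[, ix[pk[k, 1]]], inc[, ix[pk[k, 2]]])$beta_ratio
    }, numeric(1))
    m <- mean(br, na.rm = TRUE)
    cbind(
      meta[ix[1], c(group_by, stage_by), drop = FALSE],
      data.frame(n_pairs = sum(keep), n_undefined = sum(is.na(br)),
                 beta_ratio_mean = m,
                 dominance = if (is.nan(m)) NA_character_ else
                   if (m > threshold) "turnover" else "nestedness",
                 stringsAsFactors = FALSE)
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out <- out[do.call(order, out[, c(group_by, stage_by), drop = FALSE]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Optional seeded rarefaction to a common depth
#'
#' Subsamples each sample without replacement to `depth` reads (default the
#' minimum sample total). Off by default throughout the pipeline; provided
#' so depth normalisation is explicit and reproducible when wanted.
#'
#' @param counts Abundance matrix (taxa x samples).
#' @param depth Target depth (default `min(colSums(counts))`).
#' @param seed Seed for the subsampling.
#' @return Rarefied integer matrix (taxa rows retained even if zeroed).
#' @export
rarefy_counts <- function(counts, depth = min(colSums(counts)), seed = 1L) {
  if (any(colSums(counts) < depth)) stop("depth exceeds a sample total")
  with_seed(seed, {
    out <- apply(counts, 2, function(x) {
      picked <- sample(rep.int(seq_along(x), x), depth)
      tabulate(picked, nbins = length(x))
    })
    dimnames(out) <- dimnames(counts)
    storage.mode(out) <- "integer"
    out
  })
}
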