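# Alpha diversity: species richness and Faith's phylogenetic diversity,
# with grouped trajectories over colonisation time.

#' Species richness of one sample
#' @param counts Abundance matrix (taxa x samples).
#' @param sample_id Sample column to evaluate.
#' @return Integer count of taxa with abundance > 0.
#' @export
richness <- function(counts, sample_id) {
  if (!sample_id %in% colnames(counts)) stop("unknown sample: ", sample_id)
  sum(counts[, sample_id] > 0)
}

#' Faith's phylogenetic diversity of a taxon set
#'
#' Sum of branch lengths of the minimal subtree connecting `present_taxa`
#' and the root (the classic rooted variant, which is monotone under set
#' inclusion: adding a taxon can only add branches).
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param present_taxa Non-empty character vector of tip labels.
#' @return Total spanned branch length.
#' @export
faith_pd <- function(tree, present_taxa) {
  validate_tree(tree)
  if (length(present_taxa) == 0) stop("present_taxa must be non-empty")
  unknown <- setdiff(present_taxa, tree$tip.label)
  if (length(unknown)) stop("unknown tip(s): ", paste(unknown, collapse = ", "))
  n <- length(tree$tip.label)
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen <- numeric(n + tree$Nnode)
  elen[tree$edge[, 2]] <- tree$edge.length
  # walk each present tip up to the root, summing each edge once
  seen <- logical(n + tree$Nnode)
  total <- 0
  for (tip in match(present_taxa, tree$tip.label)) {
    nd <- tip
    while (parent[nd] != 0 && !seen[nd]) {
      seen[nd] <- TRUE
      total <- total + elen[nd]
      nd <- parent[nd]
    }
  }
  total
}

#' Per-sample alpha diversity table
#' @param counts Abundance matrix (taxa x samples).
#' @param tree Rooted phylogeny covering the table's taxa.
#' @return data.frame with `sample_id`, `richness`, `faith_pd`.
#' @export
alpha_diversity <- function(counts, tree) {
  tree <- match_tree_table(tree, counts)
  data.frame(
    sample_id = colnames(counts),
    richness = as.integer(colSums(counts > 0)),
    faith_pd = vapply(colnames(counts), function(s) {
      faith_pd(tree, rownames(counts)[counts[, s] > 0])
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Grouped alpha-diversity trajectories over colonisation time
#'
#' Mean and sample standard deviation of each alpha metric per group x day
#' cell. Groups with a single sample report `NA` (not zero) for the sd.
#'
#' @param alpha Result of [alpha_diversity()].
#' @param metadata Sample metadata covering all samples in `alpha`.
#' @param group_by Metadata columns defining the groups.
#' @return data.frame keyed by group columns and `day`, days ascending,
#'   with `n`, `<metric>_mean`, `<metric>_sd` for richness and Faith's PD.
#' @export
alpha_trajectories <- function(alpha, metadata, group_by = c("lake", "fraction")) {
  miss <- setdiff(alpha$sample_id, metadata$sample_id)
  if (length(miss)) stop("metadata missing sample(s): ", paste(miss, collapse = ", "))
  df <- merge(alpha, metadata, by = "sample_id")
  if (nrow(df) == 0) {
    return(data.frame())
  }
  key <- df[, c(group_by, "day"), drop = FALSE]
  cells <- split(seq_len(nrow(df)), key, drop = TRUE)
  out <- do.call(rbind, lapply(cells, function(ix) {
    one_sd <- function(x) if (length(x) > 1) stats::sd(x) else NA_real_
    cbind(
      df[ix[1], c(group_by, "day"), drop = FALSE],
      data.frame(
        n = length(ix),
        richness_mean = mean(df$richness[ix]), richness_sd = one_sd(df$richness[ix]),
        faith_pd_mean = mean(df$faith_pd[ix]), faith_pd_sd = one_sd(df$faith_pd[ix])
      )
    )
  }))
  out <- out[do.call(order, out[, c(group_by, "day"), drop = FALSE]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
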