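# Domain types and readers/writers.
#
# The package's central object is an ASV abundance table stored as a plain
# integer matrix, taxa in rows and samples in columns, with dimnames giving
# the taxon and sample ids (the convention vegan-family packages use, but
# transposed to match how ASV tables are usually exported). Sample metadata
# and the environmental table are plain data.frames; the phylogeny is an
# ape "phylo" object; distance matrices are symmetric base matrices.

#' Validate an abundance table
#'
#' Enforces the invariants of the package's central object: a taxa x samples
#' matrix of non-negative integer counts with unique, non-empty dimnames.
#' Samples (and, optionally, taxa) whose totals are zero are dropped with a
#' warning, so that every retained sample has total count > 0.
#'
#' @param counts Matrix of counts, taxa in rows, samples in columns, with
#'   dimnames.
#' @param drop_empty Drop all-zero samples and taxa (default `TRUE`).
#' @return The validated (possibly pruned) integer matrix.
#' @export
validate_abundance_table <- function(counts, drop_empty = TRUE) {
  if (!is.matrix(counts)) stop("abundance table must be a matrix (taxa x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("abundance table must carry taxon ids (rownames) and sample ids (colnames)")
  }
  dup_t <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup_t)) stop("duplicated taxon id(s): ", paste(unique(dup_t), collapse = ", "))
  dup_s <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup_s)) stop("duplicated sample id(s): ", paste(unique(dup_s), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-integer or negative count at taxon '%s', sample '%s'",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]
    ))
  }
  storage.mode(counts) <- "integer"
  if (drop_empty) {
    empty_s <- colSums(counts) == 0
    if (any(empty_s)) {
      warning("dropping all-zero sample(s): ", paste(colnames(counts)[empty_s], collapse = ", "))
      counts <- counts[, !empty_s, drop = FALSE]
    }
    empty_t <- rowSums(counts) == 0
    if (any(empty_t)) {
      warning(sum(empty_t), " all-zero taxon row(s) dropped")
      counts <- counts[!empty_t, , drop = FALSE]
    }
  }
  counts
}

#' Read an ASV abundance table from TSV
#'
#' The file is tab-separated with a header row; the first column holds taxon
#' ids when `orientation = "taxa_by_samples"` (the canonical layout, first
#' field `taxon_id`), or sample ids when the table was exported transposed.
#'
#' @param path Path to a TSV file.
#' @param orientation `"taxa_by_samples"` (default) or `"samples_by_taxa"`.
#' @return A validated taxa x samples integer matrix.
#' @export
read_abundance_table <- function(path, orientation = c("taxa_by_samples", "samples_by_taxa")) {
  orientation <- match.arg(orientation)
  raw <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", quote = "")
  ids <- raw[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicated id(s) in first column: ", paste(unique(dup), collapse = ", "))
  hdr <- colnames(raw)[-1]
  if (anyDuplicated(hdr)) {
    stop("duplicated id(s) in header: ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  }
  num <- as.matrix(raw[, -1, drop = FALSE])
  colnames(num) <- hdr
  suppressWarnings(storage.mode(num) <- "double")
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric count at row '%s', column '%s'",
                 ids[bad[1]], colnames(num)[bad[2]]))
  }
  rownames(num) <- ids
  if (orientation == "samples_by_taxa") num <- t(num)
  validate_abundance_table(num)
}

#' Write an abundance table to TSV (canonical taxa x samples layout)
#' @param counts Validated abundance matrix.
#' @param path Output path.
#' @export
write_abundance_table <- function(counts, path) {
  df <- data.frame(taxon_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate sample metadata
#'
#' One row per sample with columns `sample_id`, `lake`, `day`, `polymer`,
#' `fraction`. Plastisphere samples carry a polymer label; water samples use
#' the sentinel polymer `"water"` and a `fraction` of `"WP"`
#' (particle-associated) or `"WF"` (free-living).
#'
#' @param meta A data.frame.
#' @param days Optional vector of admissible collection days.
#' @return The validated data.frame (day coerced to integer).
#' @export
validate_sample_metadata <- function(meta, days = NULL) {
  need <- c("sample_id", "lake", "day", "polymer", "fraction")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  dup <- meta$sample_id[duplicated(meta$sample_id)]
  if (length(dup)) stop("duplicated sample_id(s): ", paste(unique(dup), collapse = ", "))
  meta$day <- as.integer(meta$day)
  if (anyNA(meta$day) || any(meta$day < 0)) stop("day must be a non-negative integer")
  if (!is.null(days) && !all(meta$day %in% days)) {
    stop("day value(s) outside the configured design: ",
         paste(setdiff(unique(meta$day), days), collapse = ", "))
  }
  plast <- meta$fraction == "plastisphere"
  if (any(plast & meta$polymer == "water") || any(!plast & meta$polymer != "water")) {
    stop("fraction 'plastisphere' must pair with a polymer label; water fractions with polymer 'water'")
  }
  if (!all(meta$fraction %in% c("plastisphere", "WP", "WF"))) {
    stop("fraction must be one of 'plastisphere', 'WP', 'WF'")
  }
  meta
}

#' Read sample metadata from TSV
#' @param path Path to a TSV with the SampleMetadata columns.
#' @param days Optional admissible days (design check).
#' @return Validated data.frame.
#' @export
read_sample_metadata <- function(path, days = NULL) {
  meta <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "")
  validate_sample_metadata(meta, days = days)
}

#' Write sample metadata to TSV
#' @param meta Metadata data.frame.
#' @param path Output path.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the per-(lake, day) environmental table from TSV
#'
#' Columns `lake` and `day` key the records; the remaining columns are
#' numeric environmental variables (e.g. T, Turb, C, DO, ChlA, TN, TP, TC,
#' TOC, TIC, ORP).
#'
#' @param path Path to a TSV.
#' @return data.frame keyed by (lake, day).
#' @export
read_env_table <- function(path) {
  env <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  if (!all(c("lake", "day") %in% names(env))) stop("environmental table needs 'lake' and 'day' columns")
  if (anyDuplicated(env[c("lake", "day")])) stop("duplicated (lake, day) record in environmental table")
  env$day <- as.integer(env$day)
  env
}

#' Write the environmental table to TSV
#' @param env data.frame keyed by (lake, day).
#' @param path Output path.
#' @export
write_env_table <- function(env, path) {
  utils::write.table(env, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny with branch lengths from a newick file
#'
#' @param path Path to a newick file.
#' @return An ape `phylo` object.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path)
  validate_tree(tree)
}

#' Validate a phylogeny for diversity computations
#' @param tree An ape `phylo`.
#' @return The tree, if valid.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths (required for PD and betaMNTD)")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("branch lengths must be finite and non-negative")
  }
  if (anyDuplicated(tree$tip.label)) stop("duplicated tip labels in tree")
  tree
}

#' Cross-validate a tree against an abundance table
#'
#' Every taxon in the table must be a tip; tips absent from the table are
#' pruned with a warning (permissive but lossless for analysis).
#'
#' @param tree An ape `phylo`.
#' @param counts Abundance matrix (taxa in rows).
#' @return The tree pruned to the table's taxa.
#' @export
match_tree_table <- function(tree, counts) {
  taxa <- rownames(counts)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing)) {
    stop("taxa missing from tree: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(tree$tip.label, taxa)
  if (length(extra)) {
    warning("pruning ", length(extra), " tree tip(s) absent from the table")
    tree <- ape::drop.tip(tree, extra)
  }
  tree
}

#' Patristic (cophenetic) distances between all tips
#'
#' Pairwise sums of branch lengths along tree paths; the substrate for
#' betaMNTD and its null model.
#'
#' @param tree A validated `phylo`.
#' @return Symmetric taxon x taxon matrix with zero diagonal.
#' @export
patristic_distances <- function(tree) {
  validate_tree(tree)
  if (length(tree$tip.label) == 1) {
    return(matrix(0, 1, 1, dimnames = list(tree$tip.label, tree$tip.label)))
  }
  ape::cophenetic.phylo(tree)
}

#' Check a distance matrix object
#' @param d Square numeric matrix.
#' @param range Admissible value range (default `c(0, Inf)`).
#' @return `d`, if symmetric with zero diagonal and within range.
#' @export
validate_distance_matrix <- function(d, range = c(0, Inf)) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have a zero diagonal")
  if (any(d < range[1] - 1e-12) || any(d > range[2] + 1e-12)) {
    stop("distance matrix entries outside declared range [", range[1], ", ", range[2], "]")
  }
  d
}
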