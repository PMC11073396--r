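# End-to-end pipeline: simulate (or load) -> alpha -> beta -> assembly ->
# succession statistics, with a config written back verbatim, per-stage
# seeds derived from one master seed, TSV stage outputs, a run log, and a
# machine-readable JSON summary.

#' Build a pipeline run configuration
#'
#' Either `simulate` (a list with a [design_config()] and a
#' [regime_config()]) or `inputs` (paths to `abundance`, `metadata`,
#' `tree`, and optionally `env`) must be supplied.
#'
#' @param output_dir Directory for all stage outputs.
#' @param simulate Optional `list(design = , regime = )`.
#' @param inputs Optional `list(abundance = , metadata = , tree = , env = )`.
#' @param seed Master seed; every stochastic stage derives its own seed
#'   from it.
#' @param n_null Null-model randomisations for the assembly stage.
#' @param thresholds List of classification thresholds: `bnti` (selection,
#'   default 2), `rc` (dispersal, default 0.95), `beta_ratio` (turnover
#'   dominance, default 0.5).
#' @param stages Character vector of analysis stages to run.
#' @return A `run_config` list.
#' @export
run_config <- function(output_dir, simulate = NULL, inputs = NULL,
                       seed = 1L, n_null = 999,
                       thresholds = list(bnti = 2, rc = 0.95, beta_ratio = 0.5),
                       stages = c("alpha", "beta", "assembly", "succession")) {
  if (is.null(simulate) == is.null(inputs)) {
    stop("exactly one of 'simulate' or 'inputs' must be given")
  }
  structure(list(output_dir = output_dir, simulate = simulate, inputs = inputs,
                 seed = as.integer(seed), n_null = as.integer(n_null),
                 thresholds = utils::modifyList(
                   list(bnti = 2, rc = 0.95, beta_ratio = 0.5), thresholds),
                 stages = stages),
            class = "run_config")
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full analysis pipeline
#'
#' Deterministic given the config's master seed. Writes every stage's TSV,
#' the config (verbatim, as YAML), a run log, and `summary.json` with the
#' headline quantities: sample counts, beta-ratio dominance calls, assembly
#' process fractions and modal processes, time-decay slopes, convergence
#' slopes, and the PERMANOVA table.
#'
#' @param config A [run_config()].
#' @return The summary, invisibly (also written to
#'   `output_dir/summary.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(out, "run.log"), open = "wt")
  on.exit(close(logcon), add = TRUE)
  yaml::write_yaml(serialise_config(config), file.path(out, "config.yaml"))
  summary <- list(seed = config$seed)

  if (!is.null(config$simulate)) {
    log_line(logcon, "stage simulate: generating synthetic study")
    design <- config$simulate$design %||% design_config(seed = config$seed)
    study <- generate_study(design, config$simulate$regime %||% regime_config())
    write_study(study, file.path(out, "simulated"))
  } else {
    log_line(logcon, "stage load: reading inputs")
    study <- list(
      counts = read_abundance_table(config$inputs$abundance),
      metadata = read_sample_metadata(config$inputs$metadata),
      tree = read_tree(config$inputs$tree),
      env = if (!is.null(config$inputs$env)) read_env_table(config$inputs$env)
    )
  }
  counts <- validate_abundance_table(study$counts)
  metadata <- study$metadata[study$metadata$sample_id %in% colnames(counts), ]
  tree <- match_tree_table(study$tree, counts)
  summary$n_samples <- ncol(counts)
  summary$n_plastisphere_samples <- sum(metadata$fraction == "plastisphere")
  summary$n_water_samples <- sum(metadata$fraction != "plastisphere")
  summary$n_taxa <- nrow(counts)
  if (!is.null(study$truth)) summary$ground_truth <- study$truth[
    c("assembly_regime", "convergence_rate", "selection_strength")]

  plast_ids <- metadata$sample_id[metadata$fraction == "plastisphere"]
  pcounts <- counts[, plast_ids, drop = FALSE]

  if ("alpha" %in% config$stages) {
    log_line(logcon, "stage alpha: richness and Faith's PD")
    alpha <- alpha_diversity(counts, tree)
    utils::write.table(alpha, file.path(out, "alpha.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    traj <- alpha_trajectories(alpha, metadata)
    utils::write.table(traj, file.path(out, "alpha_trajectories.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$alpha <- list(mean_richness = mean(alpha$richness),
                          mean_faith_pd = mean(alpha$faith_pd))
  }

  bray <- bray_curtis_matrix(pcounts)
  sor <- sorensen_matrix(pcounts)

  if ("beta" %in% config$stages) {
    log_line(logcon, "stage beta: Sorensen partition and beta-ratio")
    part <- sorensen_partition_pairs(pcounts)
    utils::write.table(part, file.path(out, "beta_pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    br <- beta_ratio_by_group(pcounts, metadata,
                              threshold = config$thresholds$beta_ratio)
    utils::write.table(br, file.path(out, "beta_ratio.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$beta_ratio <- list(
      overall_mean = mean(br$beta_ratio_mean, na.rm = TRUE),
      dominance_calls = as.list(table(br$dominance)))
  }

  if ("assembly" %in% config$stages) {
    log_line(logcon, "stage assembly: betaNTI / RCbray null models (n_null = ",
             config$n_null, ")")
    nc <- null_config(n_null = config$n_null,
                      seed = derive_seed(config$seed, "assembly"))
    res <- assembly_analysis(pcounts, tree, metadata, nc)
    res$process <- classify_assembly(res$bnti, res$rc_bray,
                                     bnti_threshold = config$thresholds$bnti,
                                     rc_threshold = config$thresholds$rc)
    utils::write.table(res, file.path(out, "assembly_pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    fr <- process_fractions(res, metadata)
    utils::write.table(fr, file.path(out, "assembly_fractions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tab <- table(res$process)
    summary$assembly <- list(
      modal_process = names(tab)[which.max(tab)],
      process_fractions = as.list(tab / sum(tab)),
      deterministic_share = mean(abs(res$bnti) > config$thresholds$bnti,
                                 na.rm = TRUE))
  }

  if ("succession" %in% config$stages) {
    log_line(logcon, "stage succession: time decay, PERMANOVA, Mantel, convergence")
    td <- time_decay(1 - sor, metadata, group_by = "lake")
    utils::write.table(td, file.path(out, "time_decay.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$time_decay_slopes <- stats::setNames(as.list(td$turnover_rate), td$lake)

    pm_meta <- metadata[match(plast_ids, metadata$sample_id), ]
    pm_meta$day <- factor(pm_meta$day)
    # colonization time, environment (lake) and polymer, plus the pairwise
    # interactions; terms whose factor is constant in this design are dropped
    main <- c("day", "lake", "polymer")
    main <- main[vapply(main, function(v) length(unique(pm_meta[[v]])) > 1,
                        logical(1))]
    inter <- if (length(main) > 1) combn(main, 2, paste, collapse = ":") else NULL
    pm <- permanova(bray, pm_meta, terms = c(main, inter),
                    n_permutations = 999,
                    seed = derive_seed(config$seed, "permanova"))
    utils::write.table(pm, file.path(out, "permanova.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$permanova <- stats::setNames(as.list(pm$R2), pm$term)

    if (!is.null(study$env)) {
      mt <- lapply(split(plast_ids, pm_meta$lake), function(ids) {
        env <- study$env[study$env$lake == metadata$lake[match(ids[1], metadata$sample_id)], ]
        evars <- as.matrix(env[match(metadata$day[match(ids, metadata$sample_id)],
                                     env$day), !(names(env) %in% c("lake", "day"))])
        ed <- as.matrix(stats::dist(scale(evars)))
        dimnames(ed) <- list(ids, ids)
        mantel(bray[ids, ids], ed, n_permutations = 999,
               seed = derive_seed(config$seed, "mantel"))
      })
      summary$mantel <- lapply(mt, function(m) list(r = m$r, p = m$p))
    }

    cv <- convergence_trend(bray, metadata)
    utils::write.table(cv$trend, file.path(out, "convergence.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$convergence <- stats::setNames(as.list(cv$trend$slope), cv$trend$group)
    summary$convergence_calls <- sum(cv$trend$convergence)
  }

  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  log_line(logcon, "pipeline complete: ", out)
  invisible(summary)
}

## flatten configs into plain lists so YAML round-trips verbatim
serialise_config <- function(config) {
  rapply(unclass(config), unclass, how = "replace")
}
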