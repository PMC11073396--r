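# Synthetic multi-lake, multi-polymer, multi-timepoint community generator.
#
# The generator emulates a plastisphere colonisation experiment: pellets of
# several polymer types incubated in contrasting lakes and collected at a
# fixed series of days, alongside particle-associated (WP) and free-living
# (WF) water communities. Every downstream stage of the pipeline can
# therefore be exercised against known ground truth: the per-kingdom
# assembly regime, the convergence rate and the polymer effect are inputs,
# not estimates.

#' Study design configuration
#'
#' Defaults reproduce a 4-lake x 8-polymer x 5-day plastisphere design with
#' one pooled sample per lake x polymer x day (160 plastisphere samples)
#' plus 4 lakes x 5 days x 2 water fractions (40 water samples).
#'
#' @param n_lakes Number of lakes.
#' @param polymers Polymer labels.
#' @param days Collection days (days since deployment).
#' @param water_fractions Water fraction labels.
#' @param n_taxa Size of the regional taxon pool.
#' @param sequencing_depth Reads per sample (multinomial total).
#' @param seed Master seed; all randomness derives from it.
#' @return A `design_config` list.
#' @export
design_config <- function(n_lakes = 4,
                          polymers = c("PP", "PE", "PVC", "PS", "PLA", "PHA", "PBS", "PBAT"),
                          days = c(3L, 7L, 15L, 30L, 60L),
                          water_fractions = c("WP", "WF"),
                          n_taxa = 300,
                          sequencing_depth = 5000,
                          seed = 1L) {
  stopifnot(n_lakes >= 1, length(polymers) >= 1, length(days) >= 1,
            n_taxa >= 2, sequencing_depth >= 1)
  if (anyDuplicated(polymers)) stop("polymer labels must be unique")
  structure(list(
    n_lakes = as.integer(n_lakes), polymers = polymers,
    days = sort(as.integer(days)), water_fractions = water_fractions,
    n_taxa = as.integer(n_taxa), sequencing_depth = as.integer(sequencing_depth),
    seed = as.integer(seed)
  ), class = "design_config")
}

#' Assembly-regime configuration
#'
#' Controls the mechanisms that downstream analyses are meant to recover.
#'
#' * `pool_divergence` — sd of the per-lake log-normal perturbation of the
#'   shared base composition; 0 makes all lake species pools identical.
#' * `convergence_rate` — kappa, per-day rate of mixing toward a shared
#'   attractor composition; the mixed fraction at day t is 1 - exp(-kappa t),
#'   so kappa = 0 disables convergence entirely.
#' * `polymer_effect` — sd of the per-polymer log-normal perturbation of the
#'   starting composition (the substrate-specific enrichment).
#' * `assembly_regime` — ground-truth regime. Every regime assembles a
#'   sample by drawing a fixed number of taxa (a `sample_richness` fraction
#'   of the pool) and filling reads multinomially; they differ in the
#'   weights: `"homogeneous_selection"` concentrates the weights on one
#'   clade (factor `exp(selection_strength)` for clade tips);
#'   `"dispersal_limitation"` multiplies them by per-sample log-normal
#'   dominance noise with sd `selection_strength`, so each community is
#'   dominated by its own random taxa; `"neutral"` draws taxa uniformly and
#'   fills from the unmodified pool composition.
#' * `selection_strength` — sigma, the intensity of the chosen regime; when
#'   omitted it defaults per regime (4 for homogeneous selection, 2 for
#'   dispersal limitation, 0 for neutral).
#' * `env_coupling` — rho in [0,1], weight of the lake/day structural signal
#'   in the environmental variables (vs pure noise).
#' * `sample_richness` — fraction of the pool drawn per sample.
#'
#' @param pool_divergence Non-negative.
#' @param convergence_rate Non-negative, per day.
#' @param polymer_effect Non-negative.
#' @param assembly_regime One of `"homogeneous_selection"`,
#'   `"dispersal_limitation"`, `"neutral"`.
#' @param selection_strength Non-negative; `NULL` for the per-regime
#'   default.
#' @param env_coupling In `[0, 1]`.
#' @param sample_richness In `(0, 1]`.
#' @return A `regime_config` list.
#' @export
regime_config <- function(pool_divergence = 1,
                          convergence_rate = 0.05,
                          polymer_effect = 0.5,
                          assembly_regime = c("homogeneous_selection",
                                              "dispersal_limitation", "neutral"),
                          selection_strength = NULL,
                          env_coupling = 0.8,
                          sample_richness = 0.3) {
  assembly_regime <- match.arg(assembly_regime)
  if (is.null(selection_strength)) {
    selection_strength <- switch(assembly_regime,
      homogeneous_selection = 4, dispersal_limitation = 2, neutral = 0)
  }
  stopifnot(pool_divergence >= 0, convergence_rate >= 0, polymer_effect >= 0,
            selection_strength >= 0, env_coupling >= 0, env_coupling <= 1,
            sample_richness > 0, sample_richness <= 1)
  structure(list(
    pool_divergence = pool_divergence, convergence_rate = convergence_rate,
    polymer_effect = polymer_effect, assembly_regime = assembly_regime,
    selection_strength = selection_strength, env_coupling = env_coupling,
    sample_richness = sample_richness
  ), class = "regime_config")
}

#' Simulate a rooted ultrametric-free pure-birth phylogeny
#'
#' Pure-birth (Yule) construction with unit birth rate, giving
#' exponential(1) waiting times between successive branching events.
#' Deterministic given the seed.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param seed Integer seed.
#' @return An ape `phylo` with tips `ASV0001 ...`.
#' @export
generate_tree <- function(n_taxa, seed = 1L) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  tree <- with_seed(seed, ape::rphylo(n_taxa, birth = 1, death = 0))
  tree$tip.label <- sprintf("ASV%04d", seq_len(n_taxa))
  # guard against numerically zero branches from the simulator
  tree$edge.length <- pmax(tree$edge.length, 1e-8)
  validate_tree(tree)
}

## pick the internal node whose clade holds roughly a quarter of the tips
## and is phylogenetically tightest (smallest mean within-clade distance):
## the target of homogeneous selection. A small, deep clade is what makes
## selected communities measurably clustered relative to the pool.
select_clade <- function(tree) {
  n <- length(tree$tip.label)
  internal <- (n + 1):(n + tree$Nnode)
  sizes <- vapply(internal, function(nd) length(tip_descendants(tree, nd)),
                  integer(1))
  cand <- internal[sizes >= max(3, 0.15 * n) & sizes <= 0.35 * n]
  if (!length(cand)) cand <- internal[which.min(abs(sizes - n / 4))]
  D <- ape::cophenetic.phylo(tree)
  spread <- vapply(cand, function(nd) {
    tips <- tip_descendants(tree, nd)
    mean(D[tips, tips])
  }, numeric(1))
  tree$tip.label[tip_descendants(tree, cand[which.min(spread)])]
}

## tip indices descending from node (iterative, avoids recursion limits)
tip_descendants <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    tips <- kids[kids <= n]
    out <- c(out, tips)
    stack <- c(stack, kids[kids > n])
  }
  sort(out)
}

#' Generate a full synthetic study
#'
#' Produces the abundance table, sample metadata, phylogeny and
#' environmental table of one simulated colonisation experiment, plus the
#' ground-truth parameters needed for recovery tests.
#'
#' Mechanism: each lake has a Dirichlet-like species pool (shared log-normal
#' base composition perturbed per lake). The plastisphere community of lake
#' l, polymer q at day t is a mixture `(1 - m(t)) * start(l, q) + m(t) *
#' attractor` with `m(t) = 1 - exp(-kappa t)` and an attractor shared by all
#' lakes and polymers — the convergence mechanism. The assembly regime then
#' shapes how counts are drawn (see [regime_config()]). Water samples are
#' drawn from the lake pool with a fraction-specific perturbation. Counts
#' are multinomial at `sequencing_depth`. Fully deterministic given
#' `design$seed`.
#'
#' @param design A [design_config()].
#' @param regime A [regime_config()].
#' @return List with `counts` (taxa x samples integer matrix, all pool taxa
#'   retained), `metadata`, `tree`, `env`, and `truth` (ground-truth list).
#' @export
generate_study <- function(design = design_config(), regime = regime_config()) {
  stopifnot(inherits(design, "design_config"), inherits(regime, "regime_config"))
  tree <- generate_tree(design$n_taxa, derive_seed(design$seed, "tree"))
  taxa <- tree$tip.label
  nt <- design$n_taxa
  lakes <- sprintf("L%d", seq_len(design$n_lakes))

  with_seed(derive_seed(design$seed, "study"), {
    base <- exp(stats::rnorm(nt, 0, 1.2))                 # shared base composition
    pools <- sapply(lakes, function(l) {
      p <- base * exp(regime$pool_divergence * stats::rnorm(nt))
      p / sum(p)
    })
    attractor <- base * exp(stats::rnorm(nt))             # shared convergence target
    attractor <- attractor / sum(attractor)
    poly_eff <- sapply(design$polymers, function(q) {
      exp(regime$polymer_effect * stats::rnorm(nt))
    })
    clade <- if (regime$assembly_regime == "homogeneous_selection") {
      select_clade(tree)
    } else character(0)
    clade_w <- rep(1, nt)
    clade_w[taxa %in% clade] <- exp(regime$selection_strength)

    grid <- expand.grid(lake = lakes, polymer = design$polymers,
                        day = design$days, stringsAsFactors = FALSE)
    water <- expand.grid(lake = lakes, fraction = design$water_fractions,
                         day = design$days, stringsAsFactors = FALSE)

    R <- max(2L, round(regime$sample_richness * nt))
    if (design$sequencing_depth <= R) stop("sequencing_depth must exceed per-sample richness")
    ## Richness-limited assembly, one scheme for all regimes: R taxa are
    ## drawn without replacement (uniformly under neutrality, by weight
    ## otherwise), each is seeded with one read, and the remaining reads
    ## are filled multinomially by weight. The regimes differ only in the
    ## weights: clade-concentrated (selection), per-sample log-normal
    ## dominance noise (dispersal limitation), or the plain pool (neutral).
    draw_sample <- function(comp) {
      comp <- comp / sum(comp)
      w <- switch(regime$assembly_regime,
        homogeneous_selection = comp * clade_w,
        dispersal_limitation = comp * exp(stats::rnorm(nt, 0, regime$selection_strength)),
        neutral = comp
      )
      w <- w / sum(w)
      ## sample_richness = 1: plain multinomial sampling of the full
      ## mixture composition (no membership subsampling)
      if (R == nt) return(stats::rmultinom(1, design$sequencing_depth, w))
      ## membership draw: uniform under neutrality; under selection the
      ## clade preference alone (so which clade members arrive stays
      ## random); under dispersal limitation the sample's own noisy weights
      keep <- switch(regime$assembly_regime,
        homogeneous_selection = sample.int(nt, R, prob = clade_w),
        dispersal_limitation = sample.int(nt, R, prob = w),
        neutral = sample.int(nt, R)
      )
      x <- integer(nt)
      x[keep] <- 1L + stats::rmultinom(1, design$sequencing_depth - R,
                                       w[keep] / sum(w[keep]))
      x
    }

    plast_counts <- matrix(0L, nt, nrow(grid))
    for (k in seq_len(nrow(grid))) {
      l <- grid$lake[k]; q <- grid$polymer[k]; t <- grid$day[k]
      m <- 1 - exp(-regime$convergence_rate * t)
      start <- pools[, l] * poly_eff[, q]
      start <- start / sum(start)
      comp <- (1 - m) * start + m * attractor
      plast_counts[, k] <- draw_sample(comp)
    }
    plast_ids <- sprintf("%s_%s_d%02d", grid$lake, grid$polymer, grid$day)

    frac_eff <- array(exp(0.3 * stats::rnorm(nt * design$n_lakes *
                                             length(design$water_fractions))),
                      dim = c(nt, design$n_lakes, length(design$water_fractions)),
                      dimnames = list(NULL, lakes, design$water_fractions))
    water_counts <- matrix(0L, nt, nrow(water))
    for (k in seq_len(nrow(water))) {
      comp <- pools[, water$lake[k]] * frac_eff[, water$lake[k], water$fraction[k]]
      water_counts[, k] <- stats::rmultinom(1, design$sequencing_depth, comp / sum(comp))
    }
    water_ids <- sprintf("%s_%s_d%02d", water$lake, water$fraction, water$day)

    counts <- cbind(plast_counts, water_counts)
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(taxa, c(plast_ids, water_ids))

    metadata <- rbind(
      data.frame(sample_id = plast_ids, lake = grid$lake, day = grid$day,
                 polymer = grid$polymer, fraction = "plastisphere",
                 stringsAsFactors = FALSE),
      data.frame(sample_id = water_ids, lake = water$lake, day = water$day,
                 polymer = "water", fraction = water$fraction,
                 stringsAsFactors = FALSE)
    )
    metadata <- validate_sample_metadata(metadata, days = design$days)

    env <- generate_env(design, regime, lakes)

    truth <- list(
      assembly_regime = regime$assembly_regime,
      convergence_rate = regime$convergence_rate,
      selection_strength = regime$selection_strength,
      polymer_effect = regime$polymer_effect,
      pool_divergence = regime$pool_divergence,
      selected_clade = clade,
      seed = design$seed
    )
    list(counts = counts, metadata = metadata, tree = tree, env = env, truth = truth)
  })
}

## Environmental variables per (lake, day): a lake effect plus a day trend,
## weighted by env_coupling against iid noise, so environmental distance
## correlates with the lake/day community structure when rho is high.
generate_env <- function(design, regime, lakes) {
  vars <- c("T", "Turb", "C", "DO", "ChlA", "TN", "TP", "TC", "TOC", "TIC", "ORP")
  key <- expand.grid(lake = lakes, day = design$days, stringsAsFactors = FALSE)
  day_std <- as.numeric(scale(key$day))
  rho <- regime$env_coupling
  vals <- sapply(vars, function(v) {
    lake_eff <- stats::rnorm(length(lakes))
    names(lake_eff) <- lakes
    slope <- stats::rnorm(1)
    signal <- lake_eff[key$lake] + slope * day_std
    rho * signal + (1 - rho) * stats::rnorm(nrow(key))
  })
  cbind(key, as.data.frame(vals))
}

#' Write the four study artifacts plus ground truth to a directory
#'
#' @param study Result of [generate_study()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_abundance_table(study$counts, file.path(dir, "abundance.tsv"))
  write_sample_metadata(study$metadata, file.path(dir, "metadata.tsv"))
  ape::write.tree(study$tree, file.path(dir, "tree.nwk"))
  write_env_table(study$env, file.path(dir, "env.tsv"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
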