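test_that("betaMNTD matches hand values and scales with branch lengths", {
  tr <- tiny_tree()
  x <- c(A = 3, B = 2, C = 0)
  expect_equal(bmntd(tr, x, x), 0)

  xa <- c(A = 1, B = 0, C = 0); yc <- c(A = 0, B = 0, C = 5)
  expect_equal(bmntd(tr, xa, yc), 4)

  y <- c(A = 0, B = 1, C = 1)
  b1 <- bmntd(tr, x, y)
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 2
  expect_equal(bmntd(tr2, x, y), 2 * b1)

  expect_error(bmntd(tr, c(A = 0, B = 0, C = 0), y), "empty")
  expect_error(bmntd(tr, c(Z = 1), y), "Z")
})

test_that("betaMNTD agrees with exhaustive enumeration over all community pairs", {
  set.seed(21)
  tr <- ape::rtree(6)
  D <- patristic_distances(tr)
  tips <- tr$tip.label
  subsets <- lapply(1:(2^6 - 1), function(m) tips[bitwAnd(m, 2^(0:5)) > 0])
  # random abundances on each subset, fixed seed
  comms <- lapply(subsets, function(s) {
    x <- setNames(numeric(6), tips)
    x[s] <- sample(1:9, length(s), replace = TRUE)
    x
  })
  idx <- sample(length(comms), 40)
  for (i in idx) for (j in sample(length(comms), 6)) {
    expect_equal(bmntd(D, comms[[i]], comms[[j]]),
                 oracle_bmntd(D, comms[[i]], comms[[j]]), tolerance = 1e-12)
    expect_equal(bmntd(D, comms[[i]], comms[[j]], abundance_weighted = FALSE),
                 oracle_bmntd(D, comms[[i]], comms[[j]], weighted = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("betaMNTD agrees with picante::comdistnt on random tables", {
  set.seed(8)
  tr <- ape::rtree(15)
  tab <- random_counts(15, 6, seed = 8)
  rownames(tab) <- tr$tip.label
  ref <- as.matrix(picante::comdistnt(t(tab), ape::cophenetic.phylo(tr),
                                      abundance.weighted = TRUE))
  D <- patristic_distances(tr)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(bmntd(D, tab[, i], tab[, j]), ref[i, j], tolerance = 1e-9)
  }
})

test_that("betaNTI is equivariant under joint relabelling of tree and table", {
  set.seed(31)
  tr <- ape::rtree(20)
  tab <- random_counts(20, 5, seed = 31)
  rownames(tab) <- tr$tip.label
  b1 <- bnti_pairs(tab, tr, n_null = 99, seed = 7)

  # table row order is irrelevant (alignment is by name)
  b2 <- bnti_pairs(tab[sample(20), ], tr, n_null = 99, seed = 7)
  expect_equal(b1$bmntd_obs, b2$bmntd_obs, tolerance = 1e-12)
  expect_equal(b1$bnti, b2$bnti, tolerance = 1e-12)

  # renaming taxa jointly in tree and table leaves everything unchanged
  # (an order-preserving renaming keeps the seeded nulls aligned too)
  remap <- setNames(paste0("x_", tr$tip.label), tr$tip.label)
  tr3 <- tr; tr3$tip.label <- unname(remap[tr$tip.label])
  tab3 <- tab; rownames(tab3) <- unname(remap[rownames(tab)])
  b3 <- bnti_pairs(tab3, tr3, n_null = 99, seed = 7)
  expect_equal(b1$bmntd_obs, b3$bmntd_obs, tolerance = 1e-12)
  expect_equal(b1$bnti, b3$bnti, tolerance = 1e-12)
})

test_that("single-pair betaNTI flags degenerate nulls and centres exchangeable data", {
  # all tips present in both communities: every shuffle leaves bmntd at 0
  tr <- tiny_tree()
  full <- c(A = 2, B = 2, C = 2)
  expect_warning(res <- bnti(tr, full, full, null_config(n_null = 99)), "zero null sd")
  expect_true(is.na(res$bnti))
  expect_equal(res$bmntd_obs, 0)

  # exchangeable communities: betaNTI is centred near 0 across seeds
  set.seed(41)
  tr <- ape::rtree(30)
  D <- patristic_distances(tr)
  zs <- vapply(1:12, function(s) {
    set.seed(100 + s)
    x <- setNames(numeric(30), tr$tip.label)
    y <- setNames(numeric(30), tr$tip.label)
    x[sample(30, 10)] <- rpois(10, 5) + 1
    y[sample(30, 10)] <- rpois(10, 5) + 1
    bnti(D, x, y, null_config(n_null = 199, seed = s))$bnti
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.75)
})

test_that("Raup-Crick scores sit at the formula boundaries", {
  expect_equal(rc_score(0.2, rep(0.5, 99)), -1)
  expect_equal(rc_score(0.9, rep(0.5, 99)), 1)
  expect_equal(rc_score(0.5, rep(0.5, 99)), 0)   # all ties, half weight
  expect_equal(rc_score(0.5, c(rep(0.4, 50), rep(0.6, 50))), 0)

  # identical samples in a rich pool: observed dissimilarity below every
  # random assembly
  tab <- random_counts(30, 6, seed = 13)
  tab <- cbind(tab, twin1 = tab[, 1], twin2 = tab[, 1])
  rc <- raup_crick_bray(tab, c("twin1", "twin2"), null_config(n_null = 99, seed = 3))
  expect_equal(rc, -1)
})

test_that("rc_bray_pairs is reproducible and bounded", {
  tab <- random_counts(25, 8, seed = 17)
  r1 <- rc_bray_pairs(tab, n_null = 99, seed = 4)
  r2 <- rc_bray_pairs(tab, n_null = 99, seed = 4)
  expect_identical(r1, r2)
  expect_true(all(r1$rc_bray >= -1 & r1$rc_bray <= 1))
  expect_true(all(r1$bray_obs >= 0 & r1$bray_obs <= 1))
})

test_that("assembly classification follows the two-threshold rule exactly", {
  expect_identical(classify_assembly(-3.1, 0.2), "homogeneous_selection")
  expect_identical(classify_assembly(0.4, 0.99), "dispersal_limitation")
  expect_identical(classify_assembly(0, 0), "drift")
  expect_identical(classify_assembly(2.5, -0.99), "heterogeneous_selection")
  expect_identical(classify_assembly(0.3, -0.97), "homogenizing_dispersal")

  # boundary handling: exactly +/-2 is stochastic; exactly +/-0.95 is drift
  expect_identical(classify_assembly(2, 0), "drift")
  expect_identical(classify_assembly(-2, 0), "drift")
  expect_identical(classify_assembly(0, 0.95), "drift")
  expect_identical(classify_assembly(0, -0.95), "drift")
  expect_identical(classify_assembly(2 + 1e-9, 0), "heterogeneous_selection")
  expect_identical(classify_assembly(0, 0.95 + 1e-9), "dispersal_limitation")

  expect_warning(out <- classify_assembly(c(NA, 1), c(0, 0)), "undefined")
  expect_true(is.na(out[1]) && out[2] == "drift")
  expect_error(classify_assembly(0, 1.5), "outside")
})

test_that("process fractions aggregate, normalise and split shares", {
  res <- data.frame(
    sample_i = rep("a", 10), sample_j = rep("b", 10),
    process = c(rep("homogeneous_selection", 10))
  )
  meta <- data.frame(sample_id = c("a", "b"), lake = "L1", day = 3L,
                     polymer = c("PP", "PE"), fraction = "plastisphere")
  fr <- process_fractions(res, meta)
  expect_equal(fr$homogeneous_selection, 1)
  expect_equal(fr$deterministic_share, 1)
  expect_equal(fr$homogenizing_share, 1)

  res2 <- data.frame(
    sample_i = rep("a", 10), sample_j = rep("b", 10),
    process = c(rep("drift", 5), rep("dispersal_limitation", 5))
  )
  fr2 <- process_fractions(res2, meta)
  expect_equal(fr2$stochastic_share, 1)
  expect_equal(fr2$differentiating_share, 0.5)
  total <- fr2$heterogeneous_selection + fr2$homogeneous_selection +
    fr2$dispersal_limitation + fr2$homogenizing_dispersal + fr2$drift
  expect_equal(total, 1, tolerance = 1e-12)
})

test_that("assembly_analysis scopes pools per lake and classifies all pairs", {
  st <- generate_study(
    design_config(n_lakes = 2, polymers = c("PP", "PE", "PLA"), days = c(3L, 30L),
                  n_taxa = 40, sequencing_depth = 400, seed = 23),
    regime_config()
  )
  counts <- validate_abundance_table(st$counts)
  res <- suppressWarnings(
    assembly_analysis(counts, st$tree, st$metadata, null_config(n_null = 99, seed = 1))
  )
  meta <- st$metadata
  li <- meta$lake[match(res$sample_i, meta$sample_id)]
  lj <- meta$lake[match(res$sample_j, meta$sample_id)]
  expect_true(all(li == lj))            # per-lake scope: no cross-lake pairs
  expect_true(all(li == res$pool))
  n1 <- sum(meta$lake == "L1" & meta$sample_id %in% colnames(counts))
  n2 <- sum(meta$lake == "L2" & meta$sample_id %in% colnames(counts))
  expect_equal(nrow(res), choose(n1, 2) + choose(n2, 2))
  ok <- !is.na(res$bnti)
  expect_identical(res$process[ok], classify_assembly(res$bnti, res$rc_bray)[ok])
})
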