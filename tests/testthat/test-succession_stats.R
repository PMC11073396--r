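## similarity matrix over samples at given days with sim = f(|day_i - day_j|)
decay_matrix <- function(days, f) {
  n <- length(days)
  m <- outer(days, days, function(a, b) ifelse(a == b, 1, f(abs(a - b))))
  diag(m) <- 0
  dimnames(m) <- list(sprintf("s%d", 1:n), sprintf("s%d", 1:n))
  m
}

decay_meta <- function(days) {
  data.frame(sample_id = sprintf("s%d", seq_along(days)), lake = "L1",
             day = days, polymer = "PP", fraction = "plastisphere")
}

test_that("time decay recovers a power law exactly under the log-log transform", {
  days <- c(3L, 7L, 15L, 30L, 60L, 3L, 7L, 15L, 30L, 60L)
  sim <- decay_matrix(days, function(dt) dt^(-0.2))
  fit <- time_decay(sim, decay_meta(days))
  expect_equal(fit$slope, -0.2, tolerance = 1e-10)
  expect_equal(fit$turnover_rate, 0.2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_identical(fit$transform, "log10")
})

test_that("constant similarity gives zero slope and zero r-squared by convention", {
  days <- c(3L, 7L, 15L, 30L)
  sim <- decay_matrix(days, function(dt) 0.6)
  fit <- time_decay(sim, decay_meta(days))
  expect_equal(fit$slope, 0)
  expect_equal(fit$r_squared, 0)
})

test_that("time decay slope is invariant to rescaling all similarities", {
  days <- rep(c(3L, 7L, 15L, 30L, 60L), 2)
  sim <- decay_matrix(days, function(dt) 0.9 * dt^(-0.3))
  f1 <- time_decay(sim, decay_meta(days))
  sim2 <- sim * 0.5
  f2 <- time_decay(sim2, decay_meta(days))
  expect_equal(f1$slope, f2$slope, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(f1$intercept, f2$intercept)))
})

test_that("degenerate time designs and zero similarities are handled", {
  days <- c(3L, 7L, 3L, 7L)
  sim <- decay_matrix(days, function(dt) 0.5)
  expect_error(time_decay(sim, decay_meta(days)), "one time distance")

  days2 <- rep(c(3L, 7L, 15L, 30L, 60L), 2)
  sim2 <- decay_matrix(days2, function(dt) dt^(-0.2))
  sim2["s1", "s10"] <- sim2["s10", "s1"] <- 0   # one dead pair
  fit <- time_decay(sim2, decay_meta(days2))
  expect_gte(fit$n_excluded, 1)
})

test_that("time decay orders faster against slower turnover across seeds", {
  slope_for <- function(seed, kappa) {
    st <- generate_study(
      design_config(n_lakes = 1, polymers = sprintf("P%d", 1:4),
                    days = c(3L, 7L, 15L, 30L, 60L), n_taxa = 60,
                    sequencing_depth = 600, seed = seed),
      regime_config(assembly_regime = "neutral", convergence_rate = kappa,
                    polymer_effect = 0.3, sample_richness = 1)
    )
    pl <- st$metadata$sample_id[st$metadata$fraction == "plastisphere"]
    sor <- sorensen_matrix(st$counts[, pl])
    time_decay(1 - sor, st$metadata, group_by = "lake")$turnover_rate
  }
  fast <- vapply(1:8, slope_for, numeric(1), kappa = 0.10)
  slow <- vapply(1:8, slope_for, numeric(1), kappa = 0.01)
  expect_gt(mean(fast > slow), 0.7)
})

test_that("permanova partitions sequentially, sums to one and is scale invariant", {
  st <- generate_study(
    design_config(n_lakes = 2, polymers = c("PP", "PE"), days = c(3L, 30L),
                  n_taxa = 40, sequencing_depth = 400, seed = 3),
    regime_config()
  )
  pl <- st$metadata$sample_id[st$metadata$fraction == "plastisphere"]
  dm <- bray_curtis_matrix(st$counts[, pl])
  meta <- st$metadata
  meta$day <- factor(meta$day)
  out <- permanova(dm, meta, terms = c("day", "lake", "polymer"),
                   n_permutations = 199, seed = 5)
  expect_identical(out$term, c("day", "lake", "polymer", "Residual"))
  expect_equal(sum(out$R2), 1, tolerance = 1e-9)
  expect_true(all(out$p[1:3] > 0 & out$p[1:3] <= 1))

  out2 <- permanova(dm * 2, meta, terms = c("day", "lake", "polymer"),
                    n_permutations = 199, seed = 5)
  expect_equal(out$R2, out2$R2, tolerance = 1e-12)
  expect_equal(out$F, out2$F, tolerance = 1e-9)
  expect_equal(out$p, out2$p)

  expect_error(permanova(dm, transform(meta, lake = "L1"), terms = "lake"),
               "single level")
  expect_error(permanova(dm, meta, terms = "depth"), "unknown term")
})

test_that("permanova p-value equals full enumeration at n = 4", {
  set.seed(12)
  x <- matrix(rnorm(8), 4)
  rownames(x) <- letters[1:4]
  dm <- as.matrix(dist(x))
  meta <- data.frame(sample_id = letters[1:4], grp = c("g1", "g1", "g2", "g2"))
  perms <- all_perms(4)
  ident <- which(apply(perms, 1, function(p) all(p == 1:4)))
  out <- permanova(dm, meta, terms = "grp", permutations = perms[-ident, ])

  Fobs <- oracle_pseudo_F(dm, meta$grp)
  Fall <- apply(perms, 1, function(p) oracle_pseudo_F(dm, meta$grp[p]))
  expect_equal(out$F[1], Fobs, tolerance = 1e-9)
  expect_equal(out$p[1], mean(Fall >= Fobs - 1e-12))
})

test_that("mantel statistic equals the off-diagonal correlation", {
  set.seed(2)
  a <- as.matrix(dist(matrix(rnorm(20 * 3), 20)))
  dimnames(a) <- list(sprintf("s%d", 1:20), sprintf("s%d", 1:20))
  res <- mantel(a, a, n_permutations = 99, seed = 1)
  expect_equal(res$r, 1, tolerance = 1e-12)

  b <- 3 * a + 0.1; diag(b) <- 0
  expect_equal(mantel(a, b, n_permutations = 99, seed = 1)$r, 1, tolerance = 1e-12)

  cmat <- as.matrix(dist(matrix(rnorm(20 * 3), 20)))
  dimnames(cmat) <- dimnames(a)
  res2 <- mantel(a, cmat, n_permutations = 99, seed = 1)
  expect_equal(res2$r, cor(as.vector(as.dist(a)), as.vector(as.dist(cmat))),
               tolerance = 1e-12)
  expect_error(mantel(a, cmat[1:10, 1:10]), "size")
})

test_that("convergence trend is flat for identical communities and calls direction", {
  days <- rep(c(3L, 15L, 60L), each = 2)
  ids <- sprintf("s%d", seq_along(days))
  dm <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  meta <- data.frame(sample_id = ids, lake = "L1", day = days,
                     polymer = rep(c("PP", "PE"), 3), fraction = "plastisphere")
  cv <- convergence_trend(dm, meta)
  expect_equal(cv$per_day$mean_dissimilarity, rep(0, 3))
  expect_equal(cv$trend$slope, 0)
  expect_false(cv$trend$convergence)

  # a cell with a single polymer is skipped with a warning
  meta2 <- meta; meta2$polymer[meta2$day == 15] <- "PP"
  w <- capture_warnings(cv2 <- convergence_trend(dm, meta2))
  expect_true(any(grepl("cell skipped", w)))
  expect_identical(nrow(cv2$per_day), 2L)
})
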