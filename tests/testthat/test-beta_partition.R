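test_that("Bray-Curtis matches the hand formula and its bounds", {
  expect_equal(bray_curtis(c(3, 1, 4), c(3, 1, 4)), 0)
  expect_equal(bray_curtis(c(5, 0, 0), c(0, 2, 3)), 1)
  expect_equal(bray_curtis(c(6, 2, 0), c(0, 2, 4)), 10 / 14)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "empty")
  expect_error(bray_curtis(1:3, 1:2), "equal length")

  tab <- random_counts(25, 8, seed = 7)
  for (k in 1:20) {
    ij <- sample(ncol(tab), 2)
    b1 <- bray_curtis(tab[, ij[1]], tab[, ij[2]])
    expect_equal(b1, bray_curtis(tab[, ij[2]], tab[, ij[1]]))
    expect_gte(b1, 0); expect_lte(b1, 1)
  }
  # matrix route agrees with the pairwise formula
  bm <- bray_curtis_matrix(tab)
  expect_equal(bm[1, 2], bray_curtis(tab[, 1], tab[, 2]))
  expect_equal(bm, t(bm))
})

test_that("Sorensen partition reproduces hand-derived components", {
  p <- sorensen_partition(a = 5, b = 3, c = 1)
  expect_equal(p$beta_sor, 4 / 14)
  expect_equal(p$beta_sim, 1 / 6)
  expect_equal(p$beta_sne, 4 / 14 - 1 / 6)
  expect_equal(p$beta_ratio, (1 / 6) / (4 / 14))

  nested <- sorensen_partition(c(1, 1, 1, 1, 0, 0), c(1, 1, 1, 1, 1, 1))
  expect_equal(nested$beta_sim, 0)
  expect_equal(nested$beta_ratio, 0)

  disjoint <- sorensen_partition(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(disjoint$beta_sor, 1)
  expect_equal(disjoint$beta_sim, 1)
  expect_equal(disjoint$beta_ratio, 1)

  identical_inc <- sorensen_partition(c(2, 1), c(5, 9))
  expect_true(is.na(identical_inc$beta_ratio))
  expect_error(sorensen_partition(c(0, 0), c(0, 0)), "empty")
})

test_that("partition identity and set-arithmetic oracle hold on random pairs", {
  set.seed(11)
  for (k in 1:200) {
    nt <- sample(5:40, 1)
    x <- rbinom(nt, 1, runif(1, 0.2, 0.9))
    y <- rbinom(nt, 1, runif(1, 0.2, 0.9))
    if (sum(x) == 0 || sum(y) == 0) next
    names(x) <- names(y) <- sprintf("t%d", seq_len(nt))
    p <- sorensen_partition(x, y)
    expect_equal(p$beta_sor, p$beta_sim + p$beta_sne, tolerance = 1e-12)
    o <- oracle_sorensen(names(x)[x > 0], names(y)[y > 0])
    expect_equal(p$beta_sor, o$beta_sor, tolerance = 1e-12)
    expect_equal(p$beta_sim, o$beta_sim, tolerance = 1e-12)
    expect_equal(p$beta_sne, o$beta_sne, tolerance = 1e-12)
  }
})

test_that("beta-ratio cells average cross-polymer pairs with dominance calls", {
  # three taxa pools chosen so each cell's pair has a known beta_ratio
  counts <- cbind(
    A1 = c(rep(1L, 5), rep(1L, 3), rep(0L, 1), 0L),
    A2 = c(rep(1L, 5), rep(0L, 3), rep(1L, 1), 0L),  # a=5 b=3 c=1: ratio 0.583
    B1 = c(rep(1L, 6), rep(0L, 4)),
    B2 = c(rep(1L, 4), rep(0L, 2), rep(0L, 2), 1L, 1L) # a=4 b=2 c=2: sor=4/12 sim=2/6 ratio=1
  )
  rownames(counts) <- sprintf("t%02d", 1:10)
  meta <- data.frame(sample_id = colnames(counts),
                     lake = c("L1", "L1", "L2", "L2"), day = 3L,
                     polymer = c("PP", "PE", "PP", "PE"),
                     fraction = "plastisphere")
  br <- beta_ratio_by_group(counts, meta)
  expect_equal(br$beta_ratio_mean[br$lake == "L1"], (1 / 6) / (4 / 14))
  expect_identical(br$dominance[br$lake == "L1"], "turnover")
  expect_equal(br$beta_ratio_mean[br$lake == "L2"], 1)

  # mean below the 0.5 boundary is called nestedness
  br2 <- beta_ratio_by_group(counts, meta, threshold = 0.7)
  expect_identical(br2$dominance[br2$lake == "L1"], "nestedness")

  meta_single <- meta; meta_single$lake <- c("L1", "L2", "L3", "L4")
  w <- capture_warnings(beta_ratio_by_group(counts, meta_single))
  expect_true(any(grepl("fewer than 2", w)))
})

test_that("nested-by-construction succession yields zero beta_ratio", {
  # each later community is a strict subset of the earlier one
  counts <- sapply(0:3, function(k) c(rep(1L, 12 - 2 * k), rep(0L, 2 * k)))
  dimnames(counts) <- list(sprintf("t%02d", 1:12), sprintf("s%d", 1:4))
  pr <- sorensen_partition_pairs(counts)
  expect_true(all(pr$beta_ratio == 0))
  expect_true(all(pr$b == 0 | pr$c == 0))
})

test_that("rarefaction is seeded, depth-exact and count-preserving", {
  tab <- random_counts(15, 4, seed = 2, depth = 300)
  r1 <- rarefy_counts(tab, depth = 100, seed = 5)
  r2 <- rarefy_counts(tab, depth = 100, seed = 5)
  expect_identical(r1, r2)
  expect_true(all(colSums(r1) == 100))
  expect_true(all(r1 <= tab))
  expect_error(rarefy_counts(tab, depth = 301), "depth")
})
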