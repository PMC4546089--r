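test_that("contrasts reproduce the hand-worked pruning example", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  x <- c(A = 1, B = 3, C = 2)
  cc <- as.numeric(pic_contrasts(tr, x))
  expect_equal(sort(cc), sort(c((1 - 3) / sqrt(2), 0)), tolerance = 1e-12)
  # identical tip values: all contrasts zero
  expect_equal(as.numeric(pic_contrasts(tr, c(A = 2, B = 2, C = 2))),
               c(0, 0))
  # two-tip tree: single contrast of magnitude 2 / sqrt(2)
  tr2 <- read_newick("(A:1,B:1);")
  expect_equal(abs(as.numeric(pic_contrasts(tr2, c(A = 0, B = 2)))),
               2 / sqrt(2))
})

test_that("contrasts match ape::pic on random trees", {
  withr::local_seed(15)
  for (i in 1:10) {
    sim <- simulate_tree_and_traits(16, bm_sigma2 = 2, seed = 400 + i)
    ours <- pic_contrasts(sim$tree, sim$trait)
    theirs <- ape::pic(sim$trait, sim$tree)
    expect_equal(sort(abs(unname(ours))), sort(abs(unname(theirs))),
                 tolerance = 1e-9)
  }
})

test_that("Blomberg's K is exactly 1 on star phylogenies", {
  star <- ape::read.tree(text = paste0("(",
    paste0("t", 1:8, ":1.5", collapse = ","), ");"))
  withr::local_seed(16)
  for (i in 1:5) {
    x <- stats::setNames(stats::rnorm(8), star$tip.label)
    expect_equal(blomberg_k(star, x), 1.0, tolerance = 1e-6)
  }
  expect_error(blomberg_k(star, stats::setNames(rep(1, 8), star$tip.label)),
               "variance")
})

test_that("K is invariant under affine trait transforms and matches picante", {
  sim <- simulate_tree_and_traits(24, bm_sigma2 = 1.5, seed = 99)
  k1 <- blomberg_k(sim$tree, sim$trait)
  k2 <- blomberg_k(sim$tree, 3.7 * sim$trait - 11)
  expect_equal(k1, k2, tolerance = 1e-10)
  skip_if_not_installed("picante")
  kp <- picante::Kcalc(sim$trait[sim$tree$tip.label], sim$tree)
  expect_equal(k1, as.numeric(kp), tolerance = 1e-6)
})

test_that("permutation significance is seeded and detects strong signal", {
  sim <- simulate_tree_and_traits(32, bm_sigma2 = 4, seed = 123)
  r1 <- k_significance(sim$tree, sim$trait, n_perm = 199, seed = 5)
  r2 <- k_significance(sim$tree, sim$trait, n_perm = 199, seed = 5)
  expect_identical(r1$p, r2$p)
  expect_lte(r1$p, 0.05)
  expect_warning(k_significance(sim$tree, sim$trait, n_perm = 50, seed = 1),
                 "resolution")
})

test_that("PGLS with identity covariance equals OLS to machine precision", {
  sim <- simulate_tree_and_traits(20, bm_sigma2 = 1, seed = 77)
  withr::local_seed(42)
  x <- stats::setNames(stats::rnorm(20), sim$tree$tip.label)
  y <- 1.5 * x + stats::setNames(stats::rnorm(20, sd = 0.3),
                                 sim$tree$tip.label)
  ours <- pgls(sim$tree, y, x, covariance = "identity")
  ols <- stats::lm(y[sim$tree$tip.label] ~ x[sim$tree$tip.label])
  expect_equal(unname(ours$coefficients), unname(coef(ols)),
               tolerance = 1e-10)
  expect_equal(ours$r_squared, summary(ols)$r.squared, tolerance = 1e-10)
  expect_equal(ours$p_value, summary(ols)$coefficients[2, 4],
               tolerance = 1e-10)
})

test_that("PGLS slope matches nlme's Brownian GLS and exact fits are exact", {
  sim <- simulate_tree_and_traits(20, bm_sigma2 = 1, seed = 31)
  x <- sim$trait
  y3 <- 3 * x
  exact <- pgls(sim$tree, y3, x)
  expect_equal(unname(exact$coefficients[["slope"]]), 3.0, tolerance = 1e-9)
  expect_equal(exact$r_squared, 1.0, tolerance = 1e-9)

  skip_if_not_installed("nlme")
  bm2 <- simulate_tree_and_traits(20, bm_sigma2 = 0.5, seed = 32)
  y <- 2 * x + bm2$trait
  ours <- pgls(sim$tree, y, x)
  df <- data.frame(y = y[sim$tree$tip.label], x = x[sim$tree$tip.label])
  rownames(df) <- sim$tree$tip.label
  gl <- suppressWarnings(nlme::gls(y ~ x, data = df,
                  correlation = ape::corBrownian(1, sim$tree,
                                                 form = ~1)))
  expect_equal(unname(ours$coefficients), unname(coef(gl)),
               tolerance = 1e-6)
})

test_that("PGLS slope recovery over simulated Brownian regressions", {
  slopes <- vapply(1:20, function(i) {
    sim <- simulate_tree_and_traits(24, bm_sigma2 = 1, seed = 600 + i)
    noise <- repeatscape:::with_local_seed(700 + i,
      repeatscape:::bm_on_tree(sim$tree, 0.25))
    y <- 2 * sim$trait + noise
    pgls(sim$tree, y, sim$trait)$coefficients[["slope"]]
  }, 0)
  expect_gte(mean(slopes), 1.8)
  expect_lte(mean(slopes), 2.2)
})

test_that("the ordinal trend test behaves linearly and symmetrically", {
  up <- gls_trend(1:10)
  expect_gt(up$coefficients[["slope"]], 0)
  expect_equal(up$r_squared, 1.0, tolerance = 1e-12)
  down <- gls_trend(rev(1:10))
  expect_equal(down$coefficients[["slope"]],
               -up$coefficients[["slope"]], tolerance = 1e-12)
  const <- gls_trend(rep(2, 5))
  expect_equal(const$coefficients[["slope"]], 0)
  expect_true(is.na(const$r_squared))
  withr::local_seed(55)
  sl <- vapply(1:20, function(i)
    gls_trend(0.5 * (0:9) + stats::rnorm(10, sd = 0.1))$
      coefficients[["slope"]], 0)
  expect_gte(mean(sl), 0.45)
  expect_lte(mean(sl), 0.55)
})

test_that("contrasts of Brownian traits are approximately standard normal", {
  vars <- vapply(1:100, function(i) {
    sim <- simulate_tree_and_traits(16, bm_sigma2 = 1, seed = 900 + i)
    stats::var(unname(pic_contrasts(sim$tree, sim$trait)))
  }, 0)
  expect_gte(mean(vars), 0.9)
  expect_lte(mean(vars), 1.1)
})
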