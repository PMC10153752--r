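test_that("mather_frequencies has the right limits and stationary point", {
  expect_equal(unname(mather_frequencies(0)), c(1, 0, 0))
  # stationary distribution of the per-event transition matrix, solved
  # independently as the left eigenvector
  Tm <- matrix(c(0, 1, 0, 1/4, 1/2, 1/4, 0, 1, 0), 3, 3, byrow = TRUE)
  e <- eigen(t(Tm))
  pi_stat <- Re(e$vectors[, which.min(abs(e$values - 1))])
  pi_stat <- pi_stat / sum(pi_stat)
  expect_equal(unname(mather_frequencies(50)), pi_stat, tolerance = 1e-9)
  expect_equal(pi_stat, c(1/6, 2/3, 1/6), tolerance = 1e-12)
  expect_error(mather_frequencies(-0.1), "non-negative")
})

test_that("the Perkins expectation is unbiased to first order in d", {
  for (d in c(1e-4, 1e-3)) {
    f <- mather_frequencies(d)
    expect_equal(f[["TT"]], 2 * d, tolerance = 5e-3)
    expect_equal(50 * (f[["TT"]] + 6 * f[["NPD"]]), 100 * d, tolerance = 5e-3)
  }
})

test_that("crossover counts are Poisson(2L) without interference", {
  mp <- marker_map(c("A", "B"), "chr", c(0, 50))   # L = 0.5 Morgan
  cfg <- sim_config(mp, 10000, nu = 1, seed = 51)
  ev <- simulate_crossovers(cfg)
  k <- vapply(ev, nrow, integer(1))
  expect_equal(mean(k), 1.0, tolerance = 3 * sqrt(1 / 10000) / 1)
  # index of dispersion close to 1 for a Poisson count
  expect_equal(var(k) / mean(k), 1, tolerance = 0.1)
})

test_that("event draws are deterministic given the seed", {
  mp <- marker_map(c("A", "B"), "chr", c(0, 30))
  cfg <- sim_config(mp, 50, nu = 4, p2 = 0.2, seed = 52)
  expect_identical(simulate_crossovers(cfg), simulate_crossovers(cfg))
  expect_identical(simulate_tetrads(cfg), simulate_tetrads(cfg))
})

test_that("resolution obeys zero- and one-crossover rules", {
  mp <- marker_map(c("A", "B"), "chr", c(0, 20))
  none <- data.frame(pos = numeric(), ca = integer(), cb = integer())
  g <- resolve_tetrad(none, mp)
  expect_equal(g[, "A"], g[, "B"])
  expect_equal(sort(g[, "A"]), c(0L, 0L, 1L, 1L))
  # exactly one event inside the interval -> 2 recombinant chromatids (TT)
  for (ca in 1:2) for (cb in 3:4) {
    one <- data.frame(pos = 0.1, ca = ca, cb = cb)
    g <- resolve_tetrad(one, mp)
    expect_equal(sum(g[, "A"] != g[, "B"]), 2L)
  }
})

test_that("class distribution given k crossovers follows the transition recursion", {
  mp <- marker_map(c("A", "B"), "chr", c(0, 40))
  cfg <- sim_config(mp, 20000, nu = 1, seed = 53)
  tet <- simulate_tetrads(cfg)
  ev <- simulate_crossovers(cfg)   # same seed: same event lists
  k <- vapply(ev, nrow, integer(1))
  cls <- classify_interval(tet, mp, "A-B")
  Tm <- matrix(c(0, 1, 0, 1/4, 1/2, 1/4, 0, 1, 0), 3, 3, byrow = TRUE)
  v <- c(1, 0, 0)
  for (kk in 0:3) {
    sel <- cls[k == kk]
    n <- length(sel)
    if (n < 200) break
    obs <- as.vector(table(factor(sel, levels = c("PD", "TT", "NPD")))) / n
    se <- sqrt(pmax(v * (1 - v), 1e-9) / n)
    expect_true(all(abs(obs - v) <= 3 * se + 1e-9),
                info = paste("k =", kk))
    v <- as.vector(v %*% Tm)
  }
})

test_that("simulated marginal class frequencies match the closed-form oracle", {
  d <- 0.15
  mp <- marker_map(c("A", "B"), "chr", c(0, 100 * d))
  cfg <- sim_config(mp, 10000, nu = 1, seed = 54)
  ct <- tally(simulate_tetrads(cfg), mp, "A-B")
  expected <- mather_frequencies(d)
  obs <- c(ct$PD, ct$TT, ct$NPD) / ct$n
  se <- sqrt(expected * (1 - expected) / ct$n)
  expect_true(all(abs(obs - expected) <= 3 * se))
})

test_that("map length is conserved across interference settings", {
  # expected recombinant-spore frequency over a short interval equals its
  # genetic length regardless of nu and p2 (interference redistributes
  # crossovers, it does not remove map length)
  d <- 0.06
  mp <- marker_map(c("A", "B"), "chr", c(0, 100 * d))
  for (par in list(c(1, 0), c(10, 0), c(10, 0.3), c(5, 1))) {
    cfg <- sim_config(mp, 8000, nu = par[1], p2 = par[2], seed = 55)
    tet <- simulate_tetrads(cfg)
    rec <- xor(tet$A, tet$B)
    # spores within a tetrad are correlated, so allow twice the binomial SE
    se <- sqrt(d * (1 - d) / length(rec))
    expect_equal(mean(rec), d, tolerance = 6 * se / d,
                 info = paste("nu =", par[1], "p2 =", par[2]))
  }
})

test_that("the gamma equilibrium start has the correct mean forward recurrence", {
  # for a stationary renewal process the first-event distance has mean
  # E[X^2] / (2 E[X]) = (nu + 1) / (2 beta) for Gamma(nu, beta) spacings
  mp <- marker_map(c("A", "B"), "chr", c(0, 500))
  for (nu in c(1, 10)) {
    cfg <- sim_config(mp, 4000, nu = nu, seed = 56)
    ev <- simulate_crossovers(cfg)
    first <- vapply(ev, function(e) e$pos[1], numeric(1))
    first <- first[!is.na(first)]
    beta <- 2 * nu
    expect_equal(mean(first), (nu + 1) / (2 * beta), tolerance = 0.05)
  }
})

test_that("the viability model follows its rules and rates", {
  mp <- marker_map(c("A", "B"), "chr", c(0, 20))
  cfg0 <- sim_config(mp, 200, nu = 1, p_death = 0, p_ndj = 0, seed = 57)
  expect_true(all(simulate_tetrads(cfg0)$viable == 1L))
  # certain nondisjunction: zero-crossover meioses lose exactly 2 spores
  cfg1 <- sim_config(mp, 400, nu = 1, p_ndj = 1, seed = 58)
  tet <- simulate_tetrads(cfg1)
  ev <- simulate_crossovers(cfg1)
  k <- vapply(ev, nrow, integer(1))
  viable_per <- tapply(tet$viable, factor(tet$tetrad_id,
                                          levels = unique(tet$tetrad_id)), sum)
  expect_true(all(viable_per[k == 0] == 2L))
  expect_true(all(viable_per[k > 0] == 4L))
  # independent spore death at 10%
  cfg2 <- sim_config(mp, 10000, nu = 1, p_death = 0.1, seed = 59)
  vp <- viability_profile(simulate_tetrads(cfg2))
  expect_equal(vp$overall_viability, 0.9,
               tolerance = 3 * sqrt(0.1 * 0.9 / 40000) / 0.9)
})

test_that("interference statistics respond to nu and move toward 1 with p2", {
  mp <- marker_map(c("A", "B", "C"), "chr", c(0, 20, 40))
  mean_ratio_at <- function(nu, p2, reps = 6, n = 1500, seed0 = 600) {
    vals <- vapply(seq_len(reps), function(r) {
      cfg <- sim_config(mp, n, nu = nu, p2 = p2, seed = seed0 + r)
      j <- joint_tally(simulate_tetrads(cfg), mp, "A-B", "B-C")
      malkova(j)$mean_ratio
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }
  r <- vapply(c(0, 0.3, 0.7, 1), function(p2)
    mean_ratio_at(10, p2, seed0 = 700 + round(1000 * p2)), numeric(1))
  expect_true(all(diff(r) > 0))      # monotone toward 1 in p2
  expect_lt(r[1], 0.5)               # strong interference at nu = 10, p2 = 0
  expect_gt(r[4], 0.8)               # pure class II behaves like Poisson
})

test_that("simulate_dataset writes reproducible files with their truth", {
  dir1 <- withr::local_tempdir()
  mp <- marker_map(c("A", "B", "C"), "chr", c(0, 10, 30))
  cfg <- sim_config(mp, 100, nu = 2, seed = 61)
  p1 <- simulate_dataset(cfg, dir1, "run1")
  p2 <- simulate_dataset(cfg, dir1, "run2")
  expect_identical(readLines(p1$tetrads), readLines(p2$tetrads))
  truth <- jsonlite::read_json(p1$truth)
  expect_equal(truth$nu, 2)
  expect_equal(unlist(truth$interval_cM), c(`A-B` = 10, `B-C` = 20))
  back <- read_tetrad_table(p1$tetrads, mp)
  expect_equal(nrow(back), 400L)
  # empty dataset still yields a parseable header-only table
  p0 <- simulate_dataset(sim_config(mp, 0, seed = 1), dir1, "empty")
  empty <- utils::read.delim(p0$tetrads)
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("tetrad_id", "A", "C") %in% names(empty)))
})

test_that("sim_config validates its parameters", {
  mp <- marker_map(c("A", "B"), "chr", c(0, 20))
  expect_error(sim_config(mp, 10, nu = 0.5), "nu")
  expect_error(sim_config(mp, 10, p2 = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(mp, -1), "non-negative")
  expect_error(sim_config(marker_map(c("A", "B")), 10), "positions")
})
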