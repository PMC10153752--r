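test_that("classify_interval recognises the three ditype classes", {
  m <- map2()
  expect_equal(unname(classify_interval(make_tetrad(pd_spores()), m, "M1-M2")),
               "PD")
  expect_equal(unname(classify_interval(make_tetrad(tt_spores()), m, "M1-M2")),
               "TT")
  expect_equal(unname(classify_interval(make_tetrad(npd_spores()), m, "M1-M2")),
               "NPD")
})

test_that("missing calls, inviable spores and non-2:2 segregation are unscorable", {
  m <- map2()
  missing_allele <- make_tetrad(list(c(0, NA), c(0, 0), c(1, 1), c(1, 1)))
  expect_equal(unname(classify_interval(missing_allele, m, "M1-M2")),
               "UNSCORABLE")
  dead_spore <- make_tetrad(pd_spores(), viable = c(1L, 1L, 1L, 0L))
  expect_equal(unname(classify_interval(dead_spore, m, "M1-M2")),
               "UNSCORABLE")
  # 3:1 segregation at M2 -> one recombinant spore, a putative conversion
  conversion <- make_tetrad(list(c(0, 0), c(0, 0), c(1, 1), c(1, 0)))
  expect_equal(unname(classify_interval(conversion, m, "M1-M2")),
               "UNSCORABLE")
})

test_that("classification is invariant to spore order and phase-label swap", {
  m <- map2()
  for (sp in list(pd_spores(), tt_spores(), npd_spores())) {
    base <- unname(classify_interval(make_tetrad(sp), m, "M1-M2"))
    for (k in 1:5) {
      perm <- sample(4)
      shuffled <- make_tetrad(sp[perm])
      expect_equal(unname(classify_interval(shuffled, m, "M1-M2")), base)
    }
    # swapping which combination is called parental: (0,1)/(1,0) parental
    # exchanges PD and NPD and leaves TT fixed
    swapped <- unname(classify_interval(make_tetrad(sp), m, "M1-M2",
                                        parental_phase = c(0, 1)))
    expect_equal(swapped, switch(base, PD = "NPD", NPD = "PD", base))
  }
})

test_that("phase inference recovers the majority combination", {
  m <- map2()
  tets <- rep_tetrads(pd_spores(), 5)
  expect_equal(unname(classify_interval(tets, m, "M1-M2",
                                        parental_phase = c(0, 1))),
               rep("NPD", 5))
  expect_equal(unname(classify_interval(tets, m, "M1-M2", infer_phase = TRUE)),
               rep("PD", 5))
})

test_that("tally counts scorable classes and excludes unscorable tetrads", {
  m <- map2()
  ct <- tally(rep_tetrads(pd_spores(), 10), m, "M1-M2")
  expect_equal(c(ct$PD, ct$TT, ct$NPD, ct$n, ct$unscorable),
               c(10L, 0L, 0L, 10L, 0L))
  mixed <- rbind(rep_tetrads(tt_spores(), 3),
                 make_tetrad(list(c(0, NA), c(0, 0), c(1, 1), c(1, 1)),
                             id = "t999"))
  ct <- tally(mixed, m, "M1-M2")
  expect_equal(ct$n, 3L)
  expect_equal(ct$unscorable, 1L)
  expect_error(tally(mixed, m, c("M1", "NOPE")), "unknown marker")
})

test_that("joint_tally marginals match per-interval tallies on the shared subset", {
  m3 <- marker_map(c("A", "B", "C"), "chr", c(0, 15, 30))
  set.seed(11)
  tet <- simulate_tetrads(sim_config(m3, 300, nu = 1, seed = 11))
  # knock out some allele calls to create interval-specific unscorables
  tet$A[sample(nrow(tet), 20)] <- NA
  tet$C[sample(nrow(tet), 20)] <- NA
  j <- joint_tally(tet, m3, "A-B", "B-C")
  cx <- classify_interval(tet, m3, "A-B")
  cy <- classify_interval(tet, m3, "B-C")
  both <- cx != "UNSCORABLE" & cy != "UNSCORABLE"
  expect_equal(attr(j, "n") + attr(j, "unscorable"), length(cx))
  expect_equal(unname(rowSums(j)),
               as.vector(table(factor(cx[both], levels = c("PD", "TT", "NPD")))))
  expect_equal(unname(colSums(j)),
               as.vector(table(factor(cy[both], levels = c("PD", "TT", "NPD")))))
  expect_error(joint_tally(tet, m3, "A-B", "A-B"), "distinct")
  m4 <- marker_map(c("A", "B", "C", "D"), "chr", c(0, 10, 20, 30))
  tet4 <- simulate_tetrads(sim_config(m4, 20, seed = 1))
  expect_warning(joint_tally(tet4, m4, "A-B", "C-D"), "not adjacent")
})

test_that("all-PD tetrads give a single nonzero joint cell", {
  m3 <- marker_map(c("A", "B", "C"), "chr", c(0, 15, 30))
  tet <- rep_tetrads(list(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1), c(1, 1, 1)), 7,
                     markers = c("A", "B", "C"))
  j <- joint_tally(tet, m3, "A-B", "B-C")
  expect_equal(j[["PD", "PD"]], 7L)
  expect_equal(sum(j), 7L)
})

test_that("perkins_distance reproduces the formula on constructed counts", {
  expect_equal(perkins_distance(interval_counts(100, 0, 0))$cM, 0)
  expect_equal(perkins_distance(interval_counts(80, 20, 0))$cM, 10)
  expect_equal(perkins_distance(interval_counts(90, 6, 4))$cM, 15)
  expect_error(perkins_distance(interval_counts(0, 0, 0)), "zero tetrads")
  # the estimator is unbounded above 50 cM
  expect_gt(perkins_distance(interval_counts(0, 0, 10))$cM, 50)
})

test_that("perkins distance is scale-invariant; its SE shrinks by sqrt(k)", {
  set.seed(21)
  for (i in 1:10) {
    ct <- interval_counts(sample(0:50, 1), sample(0:50, 1), sample(0:10, 1))
    if (ct$n == 0) next
    k <- sample(2:9, 1)
    scaled <- interval_counts(k * ct$PD, k * ct$TT, k * ct$NPD)
    expect_equal(perkins_distance(scaled)$cM, perkins_distance(ct)$cM)
    expect_equal(perkins_se(scaled), perkins_se(ct) / sqrt(k))
  }
})

test_that("perkins distance is monotone as mass moves from PD to TT or NPD", {
  base <- perkins_distance(interval_counts(80, 15, 5))$cM
  expect_gt(perkins_distance(interval_counts(79, 16, 5))$cM, base)
  expect_gt(perkins_distance(interval_counts(79, 15, 6))$cM, base)
})

test_that("perkins_se matches the stated delta-method value and degenerates to 0", {
  expect_equal(perkins_se(interval_counts(100, 0, 0)), 0)
  expect_equal(perkins_se(interval_counts(0, 50, 0)), 0)
  expect_equal(perkins_se(interval_counts(80, 20, 0)),
               100 * sqrt((0.25 * 0.2 - 0.1^2) / 100))  # 2.0 cM
})

test_that("single-spore RF matches the exact binomial interval", {
  expect_equal(single_spore_rf(50, 50)$rf, 50)
  expect_equal(single_spore_rf(100, 0)$rf, 0)
  expect_error(single_spore_rf(0, 0), "zero spores")
  # oracle: Clopper-Pearson interval from the exact binomial test
  for (case in list(c(90, 10), c(5, 15), c(0, 8), c(33, 0))) {
    r <- single_spore_rf(case[1], case[2])
    n <- sum(case)
    bt <- stats::binom.test(case[2], n)$conf.int
    expect_equal(r$lower, 100 * bt[1], tolerance = 1e-10)
    expect_equal(r$upper, 100 * bt[2], tolerance = 1e-10)
    expect_true(r$lower <= r$rf && r$rf <= r$upper)
  }
})

test_that("viability profile tabulates viable-spore counts", {
  m <- map2()
  all_live <- rep_tetrads(pd_spores(), 6)
  vp <- viability_profile(all_live)
  expect_equal(vp$overall_viability, 1)
  expect_equal(unname(vp$counts["4"]), 6L)
  half <- do.call(rbind, lapply(1:4, function(i)
    make_tetrad(pd_spores(), id = paste0("h", i),
                viable = c(1L, 1L, 0L, 0L))))
  vp <- viability_profile(half)
  expect_equal(vp$overall_viability, 0.5)
  expect_equal(unname(vp$counts["2"]), 4L)
})
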