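test_that("cosine reference ordering: peak rank, periodicity, tie counts", {
  tp <- rep(c(0, 4, 8, 12, 16, 20), each = 5)
  ref <- jtkReference(tp, lag = 8)
  # the lag timepoint holds the top reference rank
  expect_true(all(ref$ranks[tp == 8] == max(ref$ranks)))
  # lag and lag + period give identical orderings
  expect_identical(ref$values, jtkReference(tp, lag = 8 + 24)$values)
  # with a lag whose cosine values are distinct per timepoint, the tie
  # multiplicities are exactly the replicate counts: all 5 (direct count)
  ref3 <- jtkReference(tp, lag = 3)
  expect_equal(sort(ref3$tie_structure), rep(5L, 6))
  expect_equal(sum(ref3$tie_structure), length(tp))
  # on-grid lags make symmetric timepoints coincide; those merge into one
  # reference group (cos(8-8+-8h) pairs ZT0 with ZT16, ZT4 with ZT12)
  expect_equal(sort(ref$tie_structure), c(5L, 5L, 10L, 10L))
})

test_that("S statistic: extremes, antisymmetry, brute-force agreement", {
  ref <- jtkReference(c(0, 3, 6, 9, 12, 15, 18, 21), lag = 0, period = 24)$values
  expect_equal(jtkStatistic(ref, ref), bruteS(ref, ref))
  n_pairs <- sum(outer(ref, ref, "!=")[upper.tri(diag(8))])
  expect_equal(jtkStatistic(ref, ref), n_pairs)        # tau = 1 at maximum
  expect_equal(jtkStatistic(rev(sort(ref)), sort(ref)), -n_pairs)
  set.seed(4)
  for (i in 1:25) {
    x <- rnorm(8)
    r <- sample(rep(1:4, 2))
    expect_equal(jtkStatistic(x, r), bruteS(x, r))
  }
})

test_that("exact null pmf: spec case n=3 and exhaustive checks with ties", {
  null3 <- jtkNull(c(1, 1, 1))
  expect_equal(null3$S, c(-3, -1, 1, 3))
  expect_equal(null3$pmf, c(1, 2, 2, 1) / 6)
  for (ts in list(c(2, 2, 2, 2), c(3, 3, 2), c(4, 4), c(2, 1, 2, 1))) {
    null <- jtkNull(ts)
    expect_equal(sum(null$pmf), 1, tolerance = 1e-12)
    expect_equal(null$pmf, rev(null$pmf), tolerance = 1e-12)  # symmetric
    brute <- brutePmf(rep(seq_along(ts), times = ts))
    expect_equal(null$S[null$pmf > 1e-15], brute$S)
    expect_equal(null$pmf[null$pmf > 1e-15], brute$p, tolerance = 1e-12)
  }
})

test_that("normal-approximation tail is close to exact for moderate n", {
  ts <- rep(3, 4)
  exact <- jtkNull(ts, exactLimit = 60)
  approx <- jtkNull(ts, exactLimit = 5)
  expect_false(approx$exact)
  for (S in c(20, 30, 40))
    expect_equal(jtkTailP(approx, S), jtkTailP(exact, S), tolerance = 0.25)
})

test_that("jtk_p equals exhaustive permutation enumeration on a toy series", {
  tp <- rep(c(0, 6, 12, 18), each = 2)
  set.seed(7)
  x <- rnorm(8)
  got <- jtkCycle(x, tp, period = 24, lagStep = 2)
  perms <- allPerms(seq_len(8))
  lags <- seq(0, 22, 2)
  refs <- lapply(lags, function(l) jtkReference(tp, l)$values)
  p_lag <- vapply(seq_along(lags), function(li) {
    S_obs <- bruteS(x, refs[[li]])
    S_all <- vapply(perms, function(p) bruteS(x[p], refs[[li]]), numeric(1))
    mean(abs(S_all) >= abs(S_obs))
  }, numeric(1))
  # distinct orderings up to reversal, counted from the rank vectors
  keys <- vapply(refs, function(r) {
    a <- paste(rank(r), collapse = ","); b <- paste(rank(-r), collapse = ",")
    min(a, b)
  }, character(1))
  expected <- min(1, length(unique(keys)) * min(p_lag))
  expect_equal(got$jtk_p, expected, tolerance = 1e-12)
})

test_that("jtk_p is invariant under strictly monotone transforms", {
  d <- makeTimeCourseDesign()
  zt <- designSamples(d)$zt
  set.seed(12)
  x <- 50 + 20 * cos(2 * pi * (zt - 6) / 24) + rnorm(length(zt), 0, 5)
  a <- jtkCycle(x, zt)
  for (f in list(exp, function(v) v^3, function(v) 10 + 2 * v)) {
    b <- jtkCycle(f(x), zt)
    expect_equal(b$jtk_p, a$jtk_p)
    expect_equal(b$phase_zt, a$phase_zt)
  }
})

test_that("noise-free cosines are recovered with exact grid phase", {
  d <- makeTimeCourseDesign()
  zt <- designSamples(d)$zt
  cache <- new.env(parent = emptyenv())
  for (ph in seq(0, 22, 2)) {
    x <- 100 * (1 + 0.4 * cos(2 * pi * (zt - ph) / 24))
    r <- jtkCycle(x, zt, nullCache = cache)
    expect_equal(r$phase_zt, ph)
    expect_lt(r$jtk_p, 0.1)
    expect_equal(r$tau, 1)
  }
  cst <- jtkCycle(rep(3, length(zt)), zt, nullCache = cache)
  expect_equal(cst$jtk_p, 1)
  expect_true(is.na(cst$phase_zt))
})

test_that("ANOVA prefilter matches oneway.test and excludes degenerates", {
  zt <- rep(c(0, 4, 8, 12, 16, 20), each = 5)
  sn <- sprintf("s%02d", seq_along(zt))
  set.seed(5)
  raw <- matrix(rlnorm(20 * length(zt), log(50), 0.3), 20,
                dimnames = list(sprintf("P%02d", 1:20), sn))
  raw[1, ] <- raw[1, ] * rep(c(1, 1, 4, 1, 1, 1), each = 5)  # planted effect
  raw[2, ] <- 7                                              # degenerate
  pax <- paxFromMatrix(raw, zt)
  pre <- anovaPrefilter(pax, alpha = 0.1)
  # independent F-distribution evaluation per protein
  for (i in c(1, 3, 4, 5)) {
    ow <- oneway.test(asinh(raw[i, ]) ~ factor(zt), var.equal = TRUE)
    expect_equal(pre$anova_p[i], unname(ow$p.value), tolerance = 1e-10)
  }
  expect_true(pre$retained[1])
  expect_false(pre$eligible[2])
  expect_match(pre$reason[2], "zero within-group variance")
  # a protein missing a whole ZT bin is ineligible
  raw2 <- raw; raw2[3, zt == 12] <- 0
  pre2 <- anovaPrefilter(paxFromMatrix(raw2, zt))
  expect_false(pre2$eligible[3])
  expect_match(pre2$reason[3], "not detected")
})

test_that("BH q-values equal hand-computed step-up values", {
  res <- data.frame(protein_id = letters[1:4],
                    jtk_p = c(0.01, 0.02, 0.03, 0.9))
  out <- callRhythmic(res, alphaJtk = 0.1)
  expect_equal(out$q_value, c(0.04, 0.04, 0.04, 0.9))
  expect_equal(sum(out$rhythmic), 3)
  out2 <- callRhythmic(data.frame(protein_id = c("a", "b", "c"),
                                  jtk_p = c(0.01, 0.05, 0.2)), alphaJtk = 0.1)
  expect_equal(sum(out2$rhythmic), 2)
  empty <- callRhythmic(data.frame(protein_id = character(0),
                                   jtk_p = numeric(0)))
  expect_equal(nrow(empty), 0)
})

test_that("noise-free pipeline recovers exactly the planted rhythmic set", {
  d <- makeTimeCourseDesign()
  sim <- simulateAbundance(d, nProteins = 60, fracRhythmic = 0.25,
                           noiseSd = 0, dropout = NULL, seed = 17)
  pax <- paxFromMatrix(sim$raw, designSamples(d)$zt,
                       designSamples(d)$course)
  res <- rhythmAnalysis(pax)
  called <- res$protein_id[res$rhythmic]
  planted <- sim$truth$protein_id[sim$truth$is_rhythmic]
  expect_setequal(called, planted)
  # exact phase recovery for every planted protein
  ph <- merge(res[res$rhythmic, ], sim$truth, by = "protein_id")
  expect_equal(ph$phase_zt.x, ph$phase_zt.y)
})
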