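test_that("clumping applies the greedy distance/r2 rule", {
  # build a 3-variant panel with controlled LD: v1~v2 tight, v3 independent
  set.seed(51)
  n <- 2000
  h <- rbinom(n, 2, 0.5)
  d1 <- h
  d2 <- ifelse(runif(n) < 0.95, h, rbinom(n, 2, 0.5))   # r2(1,2) high
  d3 <- rbinom(n, 2, 0.5)                               # r2(1,3) ~ 0
  panel <- genotypePanel(cbind(d1, d2, d3),
                         data.frame(chrom = "1", pos = c(1e5, 1.5e5, 1.9e5),
                                    id = c("v1", "v2", "v3"),
                                    ref = "A", alt = "G"))
  s <- sumstatTable("1", c(1e5, 1.5e5, 1.9e5), c("v1", "v2", "v3"),
                    ea = "G", oa = "A", eaf = 0.5, beta = 0.1, se = 0.01,
                    p = c(1e-10, 1e-8, 1e-4), n = n)
  kept <- clumpVariants(s, panel, distance = 250000, r2Threshold = 0.8)
  expect_setequal(kept$id, c("v1", "v3"))
  # vacuous filter: r2Threshold = 1 retains everything (all r2 < 1)
  keptAll <- clumpVariants(s, panel, r2Threshold = 1.0)
  expect_setequal(keptAll$id, c("v1", "v2", "v3"))
  expect_error(clumpVariants(within(s, id <- paste0("x", id)), panel),
               "overlap")
})

test_that("clumping output matches an exhaustive pairwise oracle", {
  for (rep in 1:3) {
    panel <- quickPanel(n = 800, m = 120, freq = 0.4, spacingBp = 15000,
                        ldDecayBp = 40000, seed = 60 + rep)
    v <- variants(panel)
    set.seed(rep)
    s <- sumstatTable(v$chrom, v$pos, v$id, ea = v$alt, oa = v$ref,
                      eaf = 0.4, beta = rnorm(120), se = 0.05,
                      p = runif(120)^3, n = 800)
    kept <- clumpVariants(s, panel, distance = 100000, r2Threshold = 0.5)
    # oracle: replay every removal decision against the full r2 matrix
    D <- dosages(panel); storage.mode(D) <- "double"
    R2 <- cor(D)^2
    ord <- order(s$p, s$pos)
    status <- rep("active", 120)
    for (i in ord) {
      if (status[i] != "active") next
      status[i] <- "kept"
      within <- abs(v$pos - v$pos[i]) <= 100000 & status == "active"
      status[within & R2[i, ] > 0.5] <- "removed"
    }
    expect_setequal(kept$id, v$id[status == "kept"])
    # invariant: no two retained variants in a window exceed the threshold
    ki <- match(kept$id, v$id)
    for (a in seq_along(ki)) for (b in seq_len(a - 1)) {
      if (abs(v$pos[ki[a]] - v$pos[ki[b]]) <= 100000)
        expect_lte(R2[ki[a], ki[b]], 0.5)
    }
  }
})

test_that("scoring is additive, orientation-aware, and counts misses", {
  panel <- genotypePanel(matrix(c(0, 1, 2), 1, 3),
                         data.frame(chrom = "1", pos = c(10, 20, 30),
                                    id = c("a", "b", "c"),
                                    ref = "A", alt = "G"))
  model <- prsModel(data.frame(id = c("a", "b", "c"), effectAllele = "G",
                               beta = c(0.1, 0.2, -0.3)))
  expect_equal(as.numeric(scorePanel(panel, model)), -0.4)
  # zero model scores zero
  m0 <- prsModel(data.frame(id = c("a", "b"), effectAllele = "G", beta = 0))
  expect_equal(as.numeric(scorePanel(panel, m0)), 0)
  # flipping a variant's effect allele and negating its beta shifts every
  # score by the constant -2*beta and leaves all contrasts unchanged
  mFlip <- prsModel(data.frame(id = c("a", "b", "c"),
                               effectAllele = c("A", "G", "G"),
                               beta = c(-0.1, 0.2, -0.3)))
  panel2 <- genotypePanel(matrix(c(0, 2, 1, 1, 2, 0), 2, 3, byrow = TRUE),
                          variants(panel))
  s1 <- scorePanel(panel2, model)
  s2 <- scorePanel(panel2, mFlip)
  expect_equal(diff(as.numeric(s1)), diff(as.numeric(s2)), tolerance = 1e-12)
  expect_equal(as.numeric(s2 - s1), rep(-2 * 0.1, 2), tolerance = 1e-12)
  # unmatched variants contribute zero and are counted; >50% unmatched errors
  mMiss <- prsModel(data.frame(id = c("a", "zzz"), effectAllele = "G",
                               beta = c(0.1, 9)))
  sc <- scorePanel(panel, mMiss)
  expect_equal(attr(sc, "nUnmatched"), 1L)
  mBad <- prsModel(data.frame(id = c("x", "y", "a"), effectAllele = "G",
                              beta = 1))
  expect_error(scorePanel(panel, mBad), "unmatched")
})

test_that("incremental R2 is the nested-model difference with sane limits", {
  set.seed(52)
  n <- 2000
  cov1 <- rnorm(n)
  score <- rnorm(n)
  # perfect predictor
  d <- data.frame(trait = score)
  ev <- incrementalR2(d, score)
  expect_equal(ev$incremental, 1, tolerance = 1e-10)
  # independent score: tiny increment
  d2 <- data.frame(trait = rnorm(n), age = cov1)
  ev2 <- incrementalR2(d2, score, "age")
  expect_lt(ev2$incremental, 0.005)
  expect_gte(ev2$incremental, 0)
  # collinearity: score equal to the covariate adds nothing
  d3 <- data.frame(trait = cov1 + rnorm(n), age = cov1)
  ev3 <- incrementalR2(d3, cov1 + 1e-9 * rnorm(n), "age")
  expect_lt(ev3$incremental, 1e-3)
  expect_error(incrementalR2(d2[1:2, ], score[1:2], "age"), "fewer rows")
})

test_that("threshold search returns the argmax with the strict tie rule", {
  panel <- quickPanel(n = 1000, m = 80, spacingBp = 40000, seed = 53)
  covar <- simulateCovariates(quickSpec(n = 1000), seed = 53)
  arch <- architectureSpec(80, 8, h2 = 0.5, seed = 53)
  ph <- simulatePhenotypes(panel, covar, arch)
  v <- variants(panel)
  set.seed(53)
  s <- sumstatTable(v$chrom, v$pos, v$id, ea = v$alt, oa = v$ref, eaf = 0.4,
                    beta = rnorm(80, 0, 0.1), se = 0.05, p = runif(80),
                    n = 1000)
  # singleton grid returns that threshold
  res1 <- thresholdSearch(s, panel, ph, grid = 0.5)
  expect_equal(scoreParams(res1$best)$pThreshold, 0.5)
  # grid rows are emitted for every threshold; empty cells are NA not errors
  s$p[1] <- 1e-30
  res <- thresholdSearch(s, panel, ph, grid = c(1e-40, 1e-20, 1))
  expect_equal(nrow(res$grid), 3)
  expect_true(is.na(res$grid$incremental[res$grid$threshold == 1e-40]))
  expect_equal(res$grid$nVariants[1], 0L)
})

test_that("the best threshold tracks a sparse true architecture", {
  # trait driven only by variants that are strong in discovery: small
  # thresholds should win over p <= 1
  wins <- 0L
  for (rep in 1:10) {
    arch <- architectureSpec(1000, 5, h2 = 0.4, seed = 500 + rep)
    sims <- simulateMultistudy(
      list(quickSpec("disc", fst = 0, ldDecayBp = 1, n = 4000),
           quickSpec("targ", fst = 0, ldDecayBp = 1, n = 1500)),
      arch, chromLengthBp = 60e6)
    ss <- runGwas(sims$disc$panel, sims$disc$pheno)
    res <- thresholdSearch(ss, sims$targ$panel, sims$targ$pheno,
                           grid = c(1e-6, 1e-4, 0.01, 1))
    best <- scoreParams(res$best)$pThreshold
    wins <- wins + (best <= 1e-4)
  }
  expect_gte(wins, 8)
})

test_that("decile contrasts partition by rank and order monotone traits", {
  score <- runif(10000)
  dc <- decileContrast(score, score)
  expect_equal(dc$diff[1], 0)
  expect_true(all(diff(dc$diff) > 0))
  expect_true(all(dc$n == 1000))
  # n = 10 distinct scores: one individual per decile
  dc10 <- decileContrast(1:10, rnorm(10))
  expect_true(all(dc10$n == 1))
  # independent trait: all contrasts within 3 SE of zero
  set.seed(54)
  tr <- rnorm(10000)
  dcN <- decileContrast(score, tr)
  expect_true(all(abs(dcN$diff[-1]) < 3 * sqrt(2 / 1000)))
  expect_error(decileContrast(1:5, 1:5), "at least 10")
})

test_that("stratified splits hit per-stratum fractions deterministically", {
  ph <- data.frame(sex = rep(c("M", "F"), c(90, 10)),
                   region = "East")
  sp <- stratifiedSplit(ph, 0.1, c("sex", "region"), seed = 9)
  expect_equal(sum(sp$assignment == "validation"), 10)
  expect_equal(sum(sp$assignment[ph$sex == "F"] == "validation"), 1)
  sp2 <- stratifiedSplit(ph, 0.1, c("sex", "region"), seed = 9)
  expect_identical(sp$assignment, sp2$assignment)
  one <- data.frame(g = rep("a", 100))
  expect_equal(sum(stratifiedSplit(one, 0.1, "g", 1)$assignment ==
                     "validation"), 10)
})
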