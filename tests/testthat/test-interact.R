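test_that("interaction model recovers a known coefficient", {
  set.seed(61)
  n <- 50000
  prs <- rnorm(n)
  e <- rnorm(n)
  d <- data.frame(trait = 0.5 * prs + 0.3 * e + 0.2 * prs * e + rnorm(n),
                  env = e)
  fit <- fitInteraction(d, prs, "env", standardizePrs = FALSE)
  expect_equal(fit$contrasts$estimate, 0.2, tolerance = 0.02 / 0.2)
  # closed-form OLS oracle on the same design (env enters standardized, so
  # compare against the same standardized design)
  oracle <- coef(lm(trait ~ prs * scale(env), data = cbind(d, prs = prs)))
  expect_equal(fit$contrasts$estimate, unname(oracle[4]), tolerance = 1e-10)
  expect_error(fitInteraction(d, prs, "missing_col"), "not found")
  d$const <- "x"
  expect_error(fitInteraction(d, prs, "const"), "single level")
})

test_that("categorical modifiers are dummy-coded against the field reference", {
  set.seed(62)
  n <- 4000
  prs <- rnorm(n)
  smoking <- sample(c("never", "ever"), n, TRUE)
  d <- data.frame(trait = 0.3 * prs + 0.25 * prs * (smoking == "ever") +
                    rnorm(n), smoking = smoking)
  fit <- fitInteraction(d, prs, "smoking", standardizePrs = FALSE)
  expect_equal(fit$contrasts$term, "PRS x smoking[ever]")
  expect_equal(fit$contrasts$estimate, 0.25, tolerance = 0.25)
  # omnibus F matches the single contrast for a 2-level factor
  expect_equal(fit$omnibusP, fit$contrasts$pInt, tolerance = 1e-8)
  # multi-level factor: one contrast per non-reference level plus omnibus
  alcohol <- sample(c("never", "former", "current_problematic"), n, TRUE)
  d2 <- data.frame(trait = rnorm(n), alcohol = alcohol)
  fit2 <- fitInteraction(d2, prs, "alcohol")
  expect_equal(nrow(fit2$contrasts), 2)
  expect_true(all(grepl("PRS x alcohol\\[", fit2$contrasts$term)))
  expect_false(any(grepl("\\[never\\]", fit2$contrasts$term)))
})

test_that("interaction test is calibrated under the null", {
  set.seed(63)
  hits <- 0L
  reps <- 400
  for (i in seq_len(reps)) {
    n <- 1000
    prs <- rnorm(n)
    e <- rnorm(n)
    d <- data.frame(trait = 0.5 * prs + 0.3 * e + rnorm(n), env = e)
    fit <- fitInteraction(d, prs, "env", standardizePrs = FALSE)
    hits <- hits + (fit$contrasts$pInt < 0.05)
  }
  rate <- hits / reps
  expect_gt(rate, 0.03); expect_lt(rate, 0.07)
})

test_that("interaction estimator is unbiased across effect sizes", {
  set.seed(64)
  for (delta in c(0, 0.1, 0.2)) {
    est <- replicate(60, {
      n <- 2000
      prs <- rnorm(n); e <- rnorm(n)
      d <- data.frame(trait = 0.4 * prs + 0.2 * e + delta * prs * e +
                        rnorm(n), env = e)
      fitInteraction(d, prs, "env", standardizePrs = FALSE)$contrasts$estimate
    })
    mcse <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - delta), 2 * mcse + 0.005)
  }
})

test_that("stratified evaluation detects GxE-driven R2 differences", {
  wins <- 0L
  for (rep in 1:10) {
    n <- 3000
    set.seed(800 + rep)
    prs <- rnorm(n)
    stratum <- rep(c("A", "B"), each = n / 2)
    # stratum B's environment dilutes the genetic effect (delta < 0)
    slope <- ifelse(stratum == "A", 0.5, 0.2)
    d <- data.frame(trait = slope * prs + rnorm(n), region = stratum,
                    age = rnorm(n))
    ev <- stratifiedPrsEval(d, prs, "region", "age")
    r2 <- ev$perStratum$incremental
    wins <- wins + (r2[ev$perStratum$stratum == "B"] <
                      r2[ev$perStratum$stratum == "A"])
  }
  expect_gte(wins, 9)
  # degenerate: single stratum errors
  expect_error(stratifiedPrsEval(data.frame(trait = rnorm(50),
                                            region = "A"),
                                 rnorm(50), "region"), "2 strata")
})

test_that("allele-frequency correlation is symmetric and flip-aware", {
  pA <- quickPanel(n = 400, m = 30, seed = 71, name = "a")
  expect_equal(alleleFreqCorrelation(pA, pA)$r, 1)
  arch <- architectureSpec(500, 10, h2 = 0.3, seed = 72)
  sims <- simulateMultistudy(list(quickSpec("s", fst = 0.01, n = 1500),
                                  quickSpec("w", fst = 0.01, n = 1500)),
                             arch)
  afc <- alleleFreqCorrelation(sims$s$panel, sims$w$panel)
  # near-identical regions keep frequencies highly correlated, and the
  # correlation falls as divergence grows
  expect_gt(afc$r, 0.95)
  simsFar <- simulateMultistudy(list(quickSpec("s", fst = 0.15, n = 1500),
                                     quickSpec("w", fst = 0.15, n = 1500)),
                                arch)
  expect_lt(alleleFreqCorrelation(simsFar$s$panel, simsFar$w$panel)$r, afc$r)
  expect_equal(afc$r, alleleFreqCorrelation(sims$w$panel, sims$s$panel)$r,
               tolerance = 1e-12)
  # swapped ref/alt in one panel: orientation restores the pairing
  pB <- sims$w$panel
  v <- variants(pB)
  tmp <- v$ref; v$ref <- v$alt; v$alt <- tmp
  pFlip <- genotypePanel(2 - dosages(pB), v, populations(pB))
  afc2 <- alleleFreqCorrelation(sims$s$panel, pFlip)
  expect_equal(afc2$r, afc$r, tolerance = 1e-12)
})

test_that("LD decay profile has unit-interval bins and the expected limits", {
  p0 <- quickPanel(n = 1000, m = 60, ldDecayBp = 1, spacingBp = 5000,
                   seed = 73)
  prof <- ldDecayProfile(p0, maxDistance = 100000, bins = 10)
  expect_true(all(prof$meanR2 >= 0 & prof$meanR2 <= 1))
  # independent variants: bin means near the 1/n sampling floor
  expect_true(all(prof$meanR2 < 3 / 1000 + 0.01))
  # duplicated variant at distance ~0 lands r2 = 1 in the first bin
  d <- dosages(p0)[, c(1, 1, 30)]
  v <- variants(p0)[c(1, 1, 30), ]
  v$pos[2] <- v$pos[1] + 1
  v$id <- c("a", "b", "c")
  profDup <- ldDecayProfile(genotypePanel(d, v), maxDistance = 200000,
                            bins = 4)
  expect_equal(max(profDup$meanR2), 1, tolerance = 1e-9)
})
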