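test_that("locus definition applies the 1 Mb greedy separation rule", {
  s <- sumstatTable("1", c(1000000, 1800000, 2100000), c("a", "b", "c"),
                    ea = "A", oa = "C", eaf = 0.5, beta = 1,
                    se = 0.1, p = c(1e-12, 1e-10, 1e-9), n = 1000)
  loci <- defineLoci(s)
  expect_equal(loci$leadPos, c(1000000, 2100000))
  expect_equal(loci$start, c(1, 1100000))
  # no significant variant: zero loci
  s$p <- rep(0.5, 3)
  expect_equal(nrow(defineLoci(s)), 0)
  expect_equal(nrow(defineLoci(s[0, ])), 0)
})

test_that("greedy locus selection agrees with a pairwise-distance oracle", {
  set.seed(41)
  for (rep in 1:5) {
    m <- 500
    s <- sumstatTable(sample(c("1", "2"), m, TRUE),
                      sample.int(50e6, m), paste0("v", 1:m),
                      ea = "A", oa = "C", eaf = 0.5, beta = 1, se = 0.1,
                      p = 10^-runif(m, 8, 30), n = 1000)
    s <- s[order(s$chrom, s$pos), ]
    s <- s[!duplicated(paste(s$chrom, s$pos)), ]
    loci <- defineLoci(s)
    # oracle: simulate the stated rule directly on a sorted copy
    remaining <- s[order(s$p), ]
    expectLeads <- character()
    while (nrow(remaining)) {
      lead <- remaining[1, ]
      expectLeads <- c(expectLeads, lead$id)
      far <- !(remaining$chrom == lead$chrom &
                 abs(remaining$pos - lead$pos) < 1e6)
      remaining <- remaining[far, ]
    }
    expect_setequal(loci$leadId, expectLeads)
    # all leads pairwise >= 1 Mb apart within chromosome
    for (ch in unique(loci$chrom)) {
      p <- sort(loci$leadPos[loci$chrom == ch])
      if (length(p) > 1) expect_true(all(diff(p) >= 1e6))
    }
  }
})

test_that("Bayes factors follow exp[(z^2 - log k)/2]", {
  expect_equal(bayesFactor(0, 1), 1)
  expect_equal(bayesFactor(sqrt(log(4)), 4), 1, tolerance = 1e-12)
  expect_equal(bayesFactor(5.45, 2), 1992053.17, tolerance = 1e-6)
  expect_error(bayesFactor(1, 0), "k")
  expect_error(bayesFactor(Inf, 1), "finite")
  # log form stays finite where the raw form overflows
  expect_equal(bayesFactor(40, 2, log = TRUE), (1600 - log(2)) / 2)
})

test_that("credible sets normalize, rank, and cut at the coverage target", {
  # single variant: the whole posterior
  cs1 <- credibleSet(data.frame(id = "a", pos = 1, z = 3, k = 2))
  expect_equal(setSize(cs1), 1)
  expect_equal(credibleRows(cs1)$posterior, 1)
  # 100 exchangeable variants: uniform posterior, 99-variant set
  rows <- data.frame(id = paste0("v", 1:100), pos = 1:100, z = 2, k = 2)
  cs <- credibleSet(rows)
  expect_equal(credibleRows(cs)$posterior, rep(0.01, 100), tolerance = 1e-12)
  expect_equal(setSize(cs), 99)
  # log-space stability at z^2 > 1400
  big <- credibleSet(data.frame(id = c("a", "b"), pos = 1:2,
                                z = c(40, 38), k = 2))
  expect_equal(sum(credibleRows(big)$posterior), 1, tolerance = 1e-9)
  expect_equal(setSize(big), 1)
  expect_error(credibleSet(rows[0, ]), "empty")
})

test_that("posterior is invariant to a constant shift of z^2 - log k", {
  # multiplying every BF by a constant (k -> k/4 shifts log k by -log 4)
  rows <- data.frame(id = paste0("v", 1:10), pos = 1:10,
                     z = seq(1, 4, length.out = 10), k = 4)
  rows2 <- rows; rows2$k <- 1
  expect_equal(credibleRows(credibleSet(rows))$posterior,
               credibleRows(credibleSet(rows2))$posterior, tolerance = 1e-12)
})

test_that("raising coverage never shrinks the set; a null variant never evicts", {
  set.seed(42)
  rows <- data.frame(id = paste0("v", 1:50), pos = 1:50,
                     z = rnorm(50, 0, 3), k = 2)
  s95 <- credibleSet(rows, 0.95)
  s99 <- credibleSet(rows, 0.99)
  expect_gte(setSize(s99), setSize(s95))
  inSet <- credibleRows(s99)$id[credibleRows(s99)$inSet]
  rowsPlus <- rbind(rows, data.frame(id = "null", pos = 51, z = 0, k = 2))
  inSetPlus <- credibleRows(credibleSet(rowsPlus, 0.99))
  expect_true(all(inSet %in% inSetPlus$id[inSetPlus$inSet]))
})

test_that("credible-set membership matches the brute-force ranking oracle", {
  set.seed(43)
  for (rep in 1:200) {
    m <- sample(2:100, 1)
    z <- rnorm(m, 0, sample(c(1, 5, 15), 1))
    z[sample.int(m, 1)] <- runif(1, -40, 40)  # occasional extreme signal
    k <- sample(2:4, m, replace = TRUE)
    rows <- data.frame(id = paste0("v", 1:m), pos = 1:m, z = z, k = k)
    cs <- credibleRows(credibleSet(rows))
    got <- sort(match(cs$id[cs$inSet], rows$id))
    expect_identical(got, bruteForceCredible(z, k, 1:m))
    expect_equal(sum(cs$posterior), 1, tolerance = 1e-9)
  }
})

test_that("resolution comparison reports medians and single-SNP counts", {
  rows <- data.frame(id = paste0("v", 1:60), pos = 1:60, z = 2, k = 2)
  a <- list(L1 = credibleSet(rows), L2 = credibleSet(rows[1:10, ]))
  expect_error(compareResolution(a, list(Lx = a$L1)), "shared")
  cmp <- compareResolution(a, a)
  expect_equal(cmp$medianA, cmp$medianB)
  expect_true(all(cmp$pairs$sizeA == cmp$pairs$sizeB))
  # single-locus median pair passes straight through (uniform posteriors on
  # m exchangeable variants give a ceil(0.99 m)-variant set)
  one <- compareResolution(list(L = credibleSet(rows[1:59, ], 0.99)),
                           list(L = credibleSet(rows[1:33, ], 0.99)))
  expect_equal(one$medianA, 59)
  expect_equal(one$medianB, 33)
})

test_that("at matched total n, LD diversity alone still shrinks sets in most
           replicates", {
  wins <- 0L
  for (s in 1:12) {
    r <- resolutionExperiment(s, nLoci = 30, matchedN = TRUE)
    wins <- wins + (r$medianMeta <= r$medianSingle)
  }
  expect_gt(wins, 6)
})
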