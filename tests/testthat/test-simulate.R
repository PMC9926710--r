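test_that("configuration is validated", {
  expect_error(crossConfig(nrrFraction = 1), "nrrFraction")
  expect_error(crossConfig(nOffspring = 1), "nOffspring")
  expect_error(crossConfig(genotypeErrorRate = 1), "genotypeErrorRate")
  expect_error(crossConfig(meanDepth = 0), "meanDepth")
})

test_that("zero map length yields unrecombined gametes", {
  cfg <- crossConfig(nChromosomes = 2, chromLengthCM = c(0, 0),
                     nOffspring = 20, variantsPerChromosome = 40,
                     chromBp = rep(2e5, 2), sexChromosome = 1,
                     nrrFraction = 0, genotypeErrorRate = 0, abxabRate = 0,
                     contigsPerChromosome = 3, nChimericContigs = 0, seed = 2)
  sim <- simulateCross(cfg)
  expect_true(all(sim$truth@crossovers$father == 0))
  expect_true(all(sim$truth@crossovers$mother == 0))
})

test_that("same seed reproduces the cross, different seeds differ", {
  cfg <- crossConfig(nChromosomes = 2, nOffspring = 12,
                     variantsPerChromosome = 30, chromBp = rep(2e5, 2),
                     sexChromosome = 1, contigsPerChromosome = 3,
                     nChimericContigs = 0, seed = 4)
  a <- simulateCross(cfg)
  b <- simulateCross(cfg)
  expect_identical(genotypes(a$genotypes), genotypes(b$genotypes))
  expect_identical(a$truth@trueGeno, b$truth@trueGeno)
  cfg2 <- crossConfig(nChromosomes = 2, nOffspring = 12,
                      variantsPerChromosome = 30, chromBp = rep(2e5, 2),
                      sexChromosome = 1, contigsPerChromosome = 3,
                      nChimericContigs = 0, seed = 5)
  c <- simulateCross(cfg2)
  expect_false(identical(a$truth@crossovers, c$truth@crossovers))
})

test_that("true genotypes are Mendelian and male offspring share the Y over the NRR", {
  sim <- smallCross()
  truth <- sim$truth
  tv <- truth@variants
  ## every true genotype must be a sum of one allele from each parent
  pf <- cbind(tv$fatherHap1, tv$fatherHap2)
  pm <- cbind(tv$motherHap1, tv$motherHap2)
  possible <- cbind(pf[, 1] + pm[, 1], pf[, 1] + pm[, 2],
                    pf[, 2] + pm[, 1], pf[, 2] + pm[, 2])
  ok <- vapply(seq_len(nrow(tv)), function(i)
    all(truth@trueGeno[i, ] %in% possible[i, ]), logical(1))
  expect_true(all(ok))

  ## NRR: paternal contribution identical across male offspring (the Y)
  nrr <- which(tv$inNRR & tv$pattern == "paternal" & tv$type != "abxab")
  expect_gt(length(nrr), 5)
  males <- offspringSex(truth) == "male"
  for (i in nrr[1:5]) {
    expect_equal(length(unique(truth@trueGeno[i, males])), 1)
    expect_equal(length(unique(truth@trueGeno[i, !males])), 1)
  }
  ## and no male crossovers can separate NRR variants: codes at NRR variants
  ## are perfectly correlated with sex before error injection
  i <- nrr[1]; j <- nrr[length(nrr)]
  sameAsSex <- function(g) length(unique(g[males])) == 1 &&
    length(unique(g[!males])) == 1
  expect_true(sameAsSex(truth@trueGeno[i, ]) && sameAsSex(truth@trueGeno[j, ]))
})

test_that("adjacent-site recombinant fractions recover Kosambi distances", {
  cfg <- crossConfig(nChromosomes = 1, chromLengthCM = 10, femaleMapFactor = 2,
                     nOffspring = 10000, variantsPerChromosome = 6,
                     chromBp = 1e6, sexChromosome = 1, nrrFraction = 0,
                     genotypeErrorRate = 0, abxabRate = 0, meanDepth = 30,
                     contigsPerChromosome = 2, nChimericContigs = 0, seed = 9)
  sim <- simulateCross(cfg)
  truth <- sim$truth
  tv <- truth@variants
  ord <- order(tv$bp)
  tg <- truth@trueGeno[ord, , drop = FALSE]
  tvo <- tv[ord, ]
  ## recombinants in the maternal meiosis between two maternally informative
  ## sites: offspring switching between matching and mismatching the
  ## maternal alt haplotype
  checkGap <- function(type, gcol) {
    idx <- which(tvo$pattern == type & tvo$type != "abxab")
    if (length(idx) < 2) return(invisible(NULL))
    i <- idx[1]; j <- idx[length(idx)]
    hap1 <- if (type == "maternal") c(tvo$motherHap1[i], tvo$motherHap1[j])
            else c(tvo$fatherHap1[i], tvo$fatherHap1[j])
    ## inherited allele from the informative parent = geno minus the
    ## homozygous parent's contribution
    hom <- if (type == "maternal") tvo$fatherHap1 else tvo$motherHap1
    ai <- tg[i, ] - hom[i]; aj <- tg[j, ] - hom[j]
    inherited1i <- ai == hap1[1]; inherited1j <- aj == hap1[2]
    robs <- mean(inherited1i != inherited1j)
    d <- abs(tvo[[gcol]][j] - tvo[[gcol]][i])
    rexp <- kosambiInverse(d)
    se <- sqrt(rexp * (1 - rexp) / ncol(tg))
    expect_lt(abs(robs - rexp), 4 * se + 1e-9)
  }
  checkGap("maternal", "gFemale")
  checkGap("paternal", "gMale")
})

test_that("crossover counts match map length in Morgans over many meioses", {
  cfg <- crossConfig(nChromosomes = 1, chromLengthCM = 50, femaleMapFactor = 2,
                     nOffspring = 10000, variantsPerChromosome = 120,
                     chromBp = 1e6, sexChromosome = 1, nrrFraction = 0,
                     genotypeErrorRate = 0, abxabRate = 0, meanDepth = 30,
                     contigsPerChromosome = 2, nChimericContigs = 0, seed = 12)
  sim <- simulateCross(cfg)
  xo <- sim$truth@crossovers
  ## male map 0.5 Morgans, female 1.0
  for (want in list(c("father", 0.5), c("mother", 1.0))) {
    counts <- xo[[want[1]]][, 1]
    L <- as.numeric(want[2])
    se <- sd(counts) / sqrt(length(counts))
    expect_lt(abs(mean(counts) - L), 3 * se + 0.02)
  }
})

test_that("depth simulation follows the XY dosage model", {
  sim <- smallCross()
  doc <- simulateDepth(sim$truth, sim$config)
  dm <- normalizeDepth(doc$depth, doc$contigLength)
  X <- normalizedDepth(dm)
  cls <- contigMap(sim$truth)
  cls <- cls[!duplicated(cls$contig), ]
  classOf <- stats::setNames(cls$class, cls$contig)[colnames(X)]
  isMale <- doc$sex == "male"
  auto <- classOf %in% c("autosome", "PAR")
  expect_equal(mean(X[, auto]), 1, tolerance = 0.05)
  ## per-sample normalized median ~ 1
  expect_true(all(abs(apply(X, 1, stats::median) - 1) < 0.15))
  xc <- classOf == "X"
  if (any(xc)) {
    ratio <- mean(X[!isMale, xc]) / mean(X[isMale, xc])
    expect_equal(ratio, 2, tolerance = 0.15)
  }
  yc <- classOf == "Y"
  yGenes <- doc$genes$class == "Y"
  expect_true(all(doc$geneBreadth[yGenes, !isMale] < 0.05))
  expect_true(all(doc$geneBreadth[yGenes, isMale] > 0.9))
})

test_that("expression generator plants recoverable sex-specific genes", {
  sim <- smallCross()
  et <- simulateExpression(sim$truth, sim$config)
  scr <- expressionScreen(et, t1 = 1, t2 = 5)
  expect_setequal(scr$femaleT1, attr(et, "femaleSpecific"))
  expect_setequal(scr$maleT1, attr(et, "maleSpecific"))
  expect_equal(unname(scr$counts["candidates"]),
               length(attr(et, "femaleSpecific")) +
                 length(attr(et, "maleSpecific")))
  ## no designated genes -> no candidates
  cfg0 <- crossConfig(nChromosomes = 4, chromLengthCM = c(50, 45, 40, 35),
                      nOffspring = 10, variantsPerChromosome = 10,
                      chromBp = rep(4e5, 4), sexChromosome = 2,
                      contigsPerChromosome = 5, nFemaleSpecific = 0,
                      nMaleSpecific = 0, seed = 8)
  sim0 <- simulateCross(cfg0)
  et0 <- simulateExpression(sim0$truth, cfg0)
  expect_equal(unname(expressionScreen(et0)$counts["candidates"]), 0L)
})
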