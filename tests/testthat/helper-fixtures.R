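# Shared fixtures, all generated in code.

# Hand-built genotype table. `geno` is a variants x samples matrix of codes
# 0/1/2/NA; read counts default to clean support for the recorded call.
makeGT <- function(geno, adRef = NULL, adAlt = NULL,
                   role = c("father", "mother",
                            rep("offspring", ncol(geno) - 2)),
                   contig = "c1", pos = NULL, isIndel = FALSE,
                   QD = 30, FS = 1, MQ = 60, MQRankSum = 0,
                   ReadPosRankSum = 0, DP = 40) {
  n <- nrow(geno)
  if (is.null(colnames(geno)))
    colnames(geno) <- c("father", "mother",
                        sprintf("off%03d", seq_len(ncol(geno) - 2)))
  if (is.null(adRef)) {
    adRef <- matrix(0L, n, ncol(geno))
    adRef[geno == 0L] <- 20L; adRef[geno == 1L] <- 10L
  }
  if (is.null(adAlt)) {
    adAlt <- matrix(0L, n, ncol(geno))
    adAlt[geno == 2L] <- 20L; adAlt[geno == 1L] <- 10L
  }
  dimnames(adRef) <- dimnames(adAlt) <- dimnames(geno)
  if (is.null(pos)) pos <- seq_len(n) * 10000L
  rc <- function(x) rep_len(x, n)
  GenotypeTable(
    data.frame(contig = rc(contig), pos = pos, ref = rc("A"), alt = rc("C"),
               isIndel = rc(isIndel), QD = rc(QD), FS = rc(FS), MQ = rc(MQ),
               MQRankSum = rc(MQRankSum), ReadPosRankSum = rc(ReadPosRankSum),
               DP = rc(DP)),
    geno, adRef, adAlt, role = role)
}

# A/B code matrix simulated directly as a Markov chain along known cM gaps;
# ground truth for ordering/genoprob tests without the full cross machinery.
makeChainCodes <- function(gapsCM, n, seed = 1, missingRate = 0) {
  set.seed(seed)
  r <- kosambiInverse(gapsCM)
  m <- length(gapsCM) + 1
  h <- matrix(0L, m, n)
  for (j in seq_len(n)) {
    sw <- stats::rbinom(length(r), 1, r)
    h[, j] <- (stats::rbinom(1, 1, 0.5) + cumsum(c(0L, sw))) %% 2
  }
  codes <- matrix(c("A", "B")[h + 1], m, n,
                  dimnames = list(paste0("m", seq_len(m)), NULL))
  if (missingRate > 0)
    codes[matrix(stats::runif(m * n) < missingRate, m, n)] <- NA
  codes
}

# The full-scale synthetic family used by the end-to-end checks. Cached so
# several test files can share one run.
.fixtureCache <- new.env(parent = emptyenv())

fullPipelineRun <- function() {
  if (is.null(.fixtureCache$full)) {
    cfg <- crossConfig(meanDepth = 47, seed = 11)
    .fixtureCache$full <- runPipeline(cfg)
  }
  .fixtureCache$full
}

smallCross <- function() {
  if (is.null(.fixtureCache$small)) {
    cfg <- crossConfig(nChromosomes = 4, chromLengthCM = c(50, 45, 40, 35),
                       nOffspring = 90, variantsPerChromosome = 120,
                       chromBp = rep(4e5, 4), sexChromosome = 2,
                       meanDepth = 47, contigsPerChromosome = 5,
                       nChimericContigs = 1, seed = 7)
    .fixtureCache$small <- c(simulateCross(cfg), list(config = cfg))
  }
  .fixtureCache$small
}
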