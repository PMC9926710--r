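## Synthetic pseudo-testcross family generator.
##
## Meioses are simulated as Poisson crossover processes on the genetic scale
## (no interference); distances are interpreted through the Kosambi map
## function consistently here and in the mapper, so parameter recovery is
## self-consistent and closed-form oracles apply. The male sex chromosome
## recombines only over its pseudoautosomal region: every variant inside the
## non-recombining region (NRR) sits at 0 cM on the male map and co-segregates
## with the inherited paternal haplotype (Y = male).

GENO_LEVELS <- c("0/0", "0/1", "1/1")

## tile a chromosome into contigs with jittered widths; boundary forced at
## the NRR edge on the sex chromosome so no contig straddles it
tileIntervals <- function(bp, nTiles, breakAt = 0) {
  tileOne <- function(lo, hi, k) {
    if (k < 1) k <- 1
    w <- stats::runif(k, 0.85, 1.15)
    w <- w / sum(w) * (hi - lo + 1)
    ends <- lo - 1 + round(cumsum(w))
    ends[k] <- hi
    starts <- c(lo, head(ends, -1) + 1)
    cbind(start = starts, end = ends)
  }
  if (breakAt > 0 && breakAt < bp) {
    kLeft <- max(1L, round(nTiles * breakAt / bp))
    rbind(tileOne(1, breakAt, kLeft), tileOne(breakAt + 1, bp, nTiles - kLeft))
  } else {
    tileOne(1, bp, nTiles)
  }
}

#' Simulate a pseudo-testcross F1 family
#'
#' Generates genotypes with allele read counts and site annotations for the
#' two parents plus \code{nOffspring} offspring of a single outbred cross,
#' together with the full ground truth. Each gamete is generated as a Markov
#' chain along the chromosome's variant sites with switch probability equal
#' to the Kosambi inverse of the adjacent genetic gap, so adjacent-site
#' recombinant fractions recover the configured distances exactly through
#' the map function the mapper uses, and realised crossover counts per
#' chromosome approximate a Poisson draw with mean equal to the map length
#' in Morgans; on the sex chromosome male recombination is restricted to the
#' pseudoautosomal region, so male offspring inherit the paternal Y
#' haplotype intact across the NRR. Read counts are
#' drawn per sample and site (total depth Poisson, alt count binomial with a
#' sequencing-error floor for homozygotes) conditional on the reported
#' genotype call, so that injected miscalls look like read-level artifacts
#' rather than being trivially detectable from the allele depths.
#'
#' @param config a \linkS4class{CrossConfig}.
#' @return list with elements \code{genotypes} (a
#'   \linkS4class{GenotypeTable}) and \code{truth} (a
#'   \linkS4class{TruthSet}).
#' @examples
#' sim <- simulateCross(crossConfig(nChromosomes = 2, nOffspring = 10,
#'                                  variantsPerChromosome = 30, seed = 7))
#' sim$genotypes
#' @export
simulateCross <- function(config) {
  validObject(config)
  set.seed(config@seed)
  C <- config@nChromosomes
  nOff <- config@nOffspring
  maleCM <- config@chromLengthCM
  femCM <- maleCM * config@femaleMapFactor
  bp <- config@chromBp
  sexChrom <- config@sexChromosome
  nrrBp <- ifelse(seq_len(C) == sexChrom, round(config@nrrFraction * bp), 0)

  chromInfo <- data.frame(chrom = seq_len(C), bp = bp, nrrBp = nrrBp,
                          maleCM = maleCM, femaleCM = femCM,
                          isSex = seq_len(C) == sexChrom)

  ## --- contig tiling (sex chromosome tiled more finely so the genome-wide
  ## longest contigs, used for depth normalization, are autosomal)
  contigMap <- do.call(rbind, lapply(seq_len(C), function(ch) {
    nT <- config@contigsPerChromosome + if (ch == sexChrom) 3L else 0L
    iv <- tileIntervals(bp[ch], nT, breakAt = nrrBp[ch])
    data.frame(chrom = ch, start = iv[, "start"], end = iv[, "end"])
  }))
  ## alternate X/Y classes across NRR contigs; PAR behaves autosomally for
  ## coverage since it is present on both X and Y
  contigMap$class <- "autosome"
  sexRows <- which(contigMap$chrom == sexChrom)
  inNRR <- sexRows[contigMap$end[sexRows] <= nrrBp[sexChrom]]
  contigMap$class[sexRows] <- "PAR"
  if (length(inNRR))
    contigMap$class[inNRR] <- rep(c("X", "Y"), length.out = length(inNRR))

  ## chimeric contigs: splice the last tile of one autosome onto the first
  ## tile of another
  autos <- setdiff(seq_len(C), sexChrom)
  nChim <- min(config@nChimericContigs, floor(length(autos) / 2))
  contigMap$fusePartner <- NA_integer_
  if (nChim > 0) {
    for (k in seq_len(nChim)) {
      a <- autos[2 * k - 1]; b <- autos[2 * k]
      ra <- max(which(contigMap$chrom == a))
      rb <- min(which(contigMap$chrom == b))
      contigMap$fusePartner[ra] <- rb
      contigMap$fusePartner[rb] <- ra
    }
  }
  ## assign contig ids; fused interval pairs share one id, the second interval
  ## offset by the length of the first
  contigMap$contig <- NA_character_
  contigMap$contigStart <- 1L
  nextId <- 1L
  for (i in seq_len(nrow(contigMap))) {
    if (!is.na(contigMap$contig[i])) next
    id <- sprintf("ctg%03d", nextId); nextId <- nextId + 1L
    contigMap$contig[i] <- id
    j <- contigMap$fusePartner[i]
    if (!is.na(j) && is.na(contigMap$contig[j])) {
      contigMap$contig[j] <- id
      contigMap$contigStart[j] <- contigMap$end[i] - contigMap$start[i] + 2L
    }
  }
  contigMap$fusePartner <- NULL

  ## --- variant sites
  vars <- do.call(rbind, lapply(seq_len(C), function(ch) {
    v <- config@variantsPerChromosome
    pos <- sort(sample.int(bp[ch], v))
    data.frame(chrom = ch, bp = pos)
  }))
  nV <- nrow(vars)
  typeDraw <- stats::runif(nV)
  vars$type <- ifelse(typeDraw < config@abxabRate, "abxab",
                      ifelse(typeDraw < config@abxabRate +
                               (1 - config@abxabRate) / 2, "maternal", "paternal"))
  vars$pattern <- vars$type
  ab <- vars$type == "abxab"
  vars$pattern[ab] <- sample(c("maternal", "paternal"), sum(ab), replace = TRUE)

  ## map variants to contigs (chromosome-local interval lookup)
  vars$contig <- NA_character_
  vars$pos <- NA_integer_
  for (ch in seq_len(C)) {
    cm <- contigMap[contigMap$chrom == ch, , drop = FALSE]
    idx <- which(vars$chrom == ch)
    iv <- findInterval(vars$bp[idx], cm$start)
    vars$contig[idx] <- cm$contig[iv]
    vars$pos[idx] <- vars$bp[idx] - cm$start[iv] + cm$contigStart[iv]
  }

  ## --- parental haplotypes (father hap 1 = Y on the sex chromosome)
  fH <- matrix(0L, nV, 2); mH <- matrix(0L, nV, 2)
  isMat <- vars$pattern == "maternal" & !ab
  isPat <- vars$pattern == "paternal" & !ab
  pick <- function(n) sample.int(2, n, replace = TRUE)
  mH[cbind(which(isMat), pick(sum(isMat)))] <- 1L
  fH[cbind(which(isPat), pick(sum(isPat)))] <- 1L
  momAlt <- isPat & stats::runif(nV) < 0.25        # mother 1/1 instead of 0/0
  mH[momAlt, ] <- 1L
  fH[cbind(which(ab), pick(sum(ab)))] <- 1L
  mH[cbind(which(ab), pick(sum(ab)))] <- 1L

  ## --- genetic positions of variants
  gFem <- vars$bp / bp[vars$chrom] * femCM[vars$chrom]
  gMale <- vars$bp / bp[vars$chrom] * maleCM[vars$chrom]
  onSex <- vars$chrom == sexChrom
  parBp <- bp[sexChrom] - nrrBp[sexChrom]
  gMale[onSex] <- pmax(0, vars$bp[onSex] - nrrBp[sexChrom]) / parBp * maleCM[sexChrom]

  ## --- meioses: a gamete is a Markov chain along the chromosome's variant
  ## sites, switching haplotype between adjacent sites with probability equal
  ## to the Kosambi inverse of their genetic gap. Adjacent-site recombinant
  ## fractions therefore recover the configured distances exactly through the
  ## same map function the mapper applies, and the NRR (male gap 0) can never
  ## recombine. Switch counts are the realised crossovers.
  trueGeno <- matrix(NA_integer_, nV, nOff)
  sex <- character(nOff)
  xoCount <- list(father = matrix(0L, nOff, C), mother = matrix(0L, nOff, C))
  gamete <- function(r, start) {
    sw <- stats::rbinom(length(r), 1, r)
    list(hap = (start - 1 + cumsum(c(0L, sw))) %% 2 + 1, nxo = sum(sw))
  }
  for (ch in seq_len(C)) {
    idx <- which(vars$chrom == ch)
    rM <- kosambiInverse(diff(gMale[idx]))
    rF <- kosambiInverse(diff(gFem[idx]))
    for (j in seq_len(nOff)) {
      sF <- sample.int(2, 1)
      gF <- gamete(rM, sF)
      fAll <- fH[idx, 1] * (gF$hap == 1) + fH[idx, 2] * (gF$hap == 2)
      sM <- sample.int(2, 1)
      gM <- gamete(rF, sM)
      mAll <- mH[idx, 1] * (gM$hap == 1) + mH[idx, 2] * (gM$hap == 2)
      trueGeno[idx, j] <- fAll + mAll
      xoCount$father[j, ch] <- gF$nxo
      xoCount$mother[j, ch] <- gM$nxo
      if (ch == sexChrom) sex[j] <- if (gF$hap[which.min(gMale[idx])] == 1)
        "male" else "female"
    }
  }

  ## --- called genotypes
  fatherCall <- fH[, 1] + fH[, 2]
  motherCall <- mH[, 1] + mH[, 2]
  ## het x het contamination: the parent that makes the site look like a
  ## testcross is miscalled homozygous reference
  fatherCall[ab & vars$pattern == "maternal"] <- 0L
  motherCall[ab & vars$pattern == "paternal"] <- 0L
  offCall <- trueGeno
  e <- config@genotypeErrorRate
  if (e > 0) {
    hit <- which(matrix(stats::runif(nV * nOff) < e, nV, nOff))
    offCall[hit] <- sample(0:2, length(hit), replace = TRUE)
  }
  geno <- cbind(fatherCall, motherCall, offCall)
  colnames(geno) <- c("father", "mother", sprintf("off%03d", seq_len(nOff)))

  ## --- allele read counts conditional on the reported call
  nS <- ncol(geno)
  depth <- matrix(stats::rpois(nV * nS, config@meanDepth), nV, nS)
  fl <- config@depthErrorRate
  p <- matrix(0.5, nV, nS)
  p[geno == 0L] <- fl
  p[geno == 2L] <- 1 - fl
  alt <- matrix(stats::rbinom(nV * nS, depth, p), nV, nS)
  geno[depth == 0] <- NA_integer_
  adRef <- depth - alt
  adAlt <- alt
  dimnames(adRef) <- dimnames(adAlt) <- dimnames(geno)

  ## --- site annotations with realistic tails
  ref <- sample(c("A", "C", "G", "T"), nV, replace = TRUE)
  altAllele <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                      character(1))
  isIndel <- stats::runif(nV) < config@indelFraction
  ref[isIndel] <- paste0(ref[isIndel], "A")
  variants <- data.frame(
    contig = vars$contig, pos = vars$pos, ref = ref, alt = unname(altAllele),
    isIndel = isIndel,
    QD = pmax(stats::rnorm(nV, 25, 6), 0),
    FS = stats::rexp(nV, 1 / 5),
    MQ = stats::rnorm(nV, 58, 3),
    MQRankSum = stats::rnorm(nV, 0, 2),
    ReadPosRankSum = stats::rnorm(nV, 0, 2),
    DP = rowSums(depth))

  ord <- order(variants$contig, variants$pos)
  gt <- GenotypeTable(variants[ord, ], geno[ord, ], adRef[ord, ], adAlt[ord, ],
                      role = c("father", "mother", rep("offspring", nOff)))

  ## --- gene catalogue (genesPerContig genes spaced along each contig)
  perContig <- contigMap[!duplicated(contigMap$contig), ]
  genes <- do.call(rbind, lapply(seq_len(nrow(perContig)), function(i) {
    len <- perContig$end[i] - perContig$start[i] + 1
    k <- config@genesPerContig
    at <- round(seq(0.1, 0.9, length.out = k) * len)
    data.frame(gene = sprintf("%s.g%d", perContig$contig[i], seq_len(k)),
               contig = perContig$contig[i],
               start = at, end = pmin(at + 999, len),
               class = perContig$class[i])
  }))

  truthVars <- vars[ord, ]
  truthVars$gMale <- gMale[ord]
  truthVars$gFemale <- gFem[ord]
  truthVars$fatherHap1 <- fH[ord, 1]
  truthVars$fatherHap2 <- fH[ord, 2]
  truthVars$motherHap1 <- mH[ord, 1]
  truthVars$motherHap2 <- mH[ord, 2]
  truthVars$inNRR <- onSex[ord] & truthVars$bp <= nrrBp[sexChrom]
  tg <- trueGeno[ord, , drop = FALSE]
  colnames(tg) <- sprintf("off%03d", seq_len(nOff))

  truth <- new("TruthSet", chromInfo = chromInfo,
               contigMap = contigMap[, c("contig", "chrom", "start", "end",
                                         "contigStart", "class")],
               variants = truthVars, trueGeno = tg,
               offspringSex = stats::setNames(sex, colnames(tg)),
               crossovers = xoCount, genes = genes)
  list(genotypes = gt, truth = truth)
}

#' Simulate per-contig depth of coverage and per-gene coverage breadth
#'
#' Mean depth per sample and contig follows the dosage model of an XY system:
#' autosomal and pseudoautosomal contigs have dosage 1 in both sexes, X
#' contigs dosage 1 in females and 0.5 in males, Y contigs dosage 0.5 in
#' males and ~0 in females. Per-gene breadth (fraction of bases covered by at
#' least one read) is generated consistently: Y-linked genes are essentially
#' uncovered in female samples.
#'
#' @param truth a \linkS4class{TruthSet}.
#' @param config the \linkS4class{CrossConfig} used to generate it.
#' @return list with \code{depth} (samples x contigs raw mean depth),
#'   \code{contigLength}, \code{sex} (named sample labels),
#'   \code{geneBreadth} (genes x samples matrix) and \code{genes}.
#' @export
simulateDepth <- function(truth, config) {
  set.seed(config@seed + 1L)
  cm <- truth@contigMap
  perContig <- cm[!duplicated(cm$contig), ]
  lens <- vapply(split(cm$end - cm$start + 1, cm$contig), sum, numeric(1))
  lens <- lens[perContig$contig]
  sex <- c(father = "male", mother = "female", truth@offspringSex)
  nS <- length(sex)
  nCtg <- nrow(perContig)
  dosage <- matrix(1, nS, nCtg, dimnames = list(names(sex), perContig$contig))
  isMale <- sex == "male"
  dosage[isMale, perContig$class == "X"] <- 0.5
  dosage[isMale, perContig$class == "Y"] <- 0.5
  dosage[!isMale, perContig$class == "Y"] <- 0.02
  mu <- config@meanDepth
  depth <- matrix(pmax(stats::rnorm(nS * nCtg, mu * dosage, 0.05 * mu), 0),
                  nS, nCtg, dimnames = dimnames(dosage))

  genes <- truth@genes
  nG <- nrow(genes)
  breadth <- matrix(stats::runif(nG * nS, 0.93, 1), nG, nS,
                    dimnames = list(genes$gene, names(sex)))
  yGene <- genes$class == "Y"
  breadth[yGene, !isMale] <- stats::runif(sum(yGene) * sum(!isMale), 0, 0.04)
  breadth[yGene, isMale] <- stats::runif(sum(yGene) * sum(isMale), 0.92, 1)

  list(depth = depth, contigLength = lens, sex = sex,
       geneBreadth = breadth, genes = genes)
}

#' Simulate a gene x tissue expression table
#'
#' Mean FPKM per gene for three tissue classes (gastrozooid, female
#' gonozooid, male gonozooid). Designated sex-specific genes exceed
#' \code{threshold} only in their own gonozooid class; all remaining genes
#' are either unexpressed or expressed at least as highly in gastrozooids as
#' in either gonozooid class, so they can never classify as sex-specific at
#' any threshold.
#'
#' @param truth a \linkS4class{TruthSet}.
#' @param config the \linkS4class{CrossConfig} used to generate it
#'   (\code{nFemaleSpecific}/\code{nMaleSpecific} set the designated counts).
#' @param threshold FPKM threshold the designated genes are guaranteed to
#'   exceed in their own class (and stay below elsewhere).
#' @return data.frame with columns \code{gene}, \code{gastrozooid},
#'   \code{female_gonozooid}, \code{male_gonozooid}; attributes
#'   \code{femaleSpecific} and \code{maleSpecific} name the designated genes.
#' @export
simulateExpression <- function(truth, config, threshold = 1) {
  set.seed(config@seed + 2L)
  genes <- truth@genes
  nG <- nrow(genes)
  yIdx <- which(genes$class == "Y")
  otherIdx <- setdiff(seq_len(nG), yIdx)
  nMale <- min(config@nMaleSpecific, nG)
  nFem <- min(config@nFemaleSpecific, length(otherIdx))
  maleIdx <- c(yIdx, sample(otherIdx))[seq_len(nMale)]
  femIdx <- sample(setdiff(otherIdx, maleIdx), nFem)

  fpkm <- matrix(stats::runif(nG * 3, 0, 0.4 * threshold), nG, 3,
                 dimnames = list(genes$gene,
                                 c("gastrozooid", "female_gonozooid", "male_gonozooid")))
  ## half the background is broadly expressed, with gastrozooid expression at
  ## the maximum of the three tissues so it can never look sex-specific
  ubiq <- sample(setdiff(seq_len(nG), c(maleIdx, femIdx)),
                 floor((nG - nMale - nFem) / 2))
  for (i in ubiq) {
    v <- threshold * (0.5 + stats::rexp(3, 1 / 3))
    fpkm[i, ] <- c(max(v), sample(v[-which.max(v)]))
  }
  fpkm[femIdx, "female_gonozooid"] <- threshold * (2 + stats::rexp(nFem, 1 / 5))
  fpkm[maleIdx, "male_gonozooid"] <- threshold * (2 + stats::rexp(nMale, 1 / 10))

  out <- data.frame(gene = genes$gene, fpkm, row.names = NULL)
  attr(out, "femaleSpecific") <- genes$gene[femIdx]
  attr(out, "maleSpecific") <- genes$gene[maleIdx]
  out
}
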