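## End-to-end orchestration: simulate (or accept) a genotype table, filter,
## extract pseudo-testcross datasets, build both maps, scan for the sex QTL,
## run the depth-of-coverage analyses and the expression screen, and
## delineate the non-recombining and pseudoautosomal regions.

#' Delineate non-recombining and pseudoautosomal regions
#'
#' On the paternal map (recombination between X and Y), contigs whose
#' markers all sit at the sex-associated position form the non-recombining
#' region (NRR); contigs with recombining paternal markers in the same group
#' are pseudoautosomal (PAR). Contigs placed in only one parent's sex
#' linkage group are listed separately — they may have diverged or simply
#' lack heterozygous variants in the other parent.
#'
#' @param paternalMap,maternalMap \linkS4class{GeneticMap} objects.
#' @param scan paternal scan result from \code{\link{scanBinary}}.
#' @param contigLength named contig lengths in bp (for the summed extents).
#' @return list with the sex group and position, per-region contig tables,
#'   summed bp (\code{nrrBp}, \code{parBp}) and the single-map contig lists;
#'   NULL if no sex-associated group exists (max LOD below 3).
#' @export
delineateSexRegions <- function(paternalMap, maternalMap, scan,
                                contigLength = NULL) {
  peak <- scan[which.max(scan$lod), ]
  if (nrow(peak) == 0 || peak$lod < 3) return(NULL)
  sexGroup <- peak$group
  sexPos <- peak$cM
  ubP <- unbinMap(paternalMap)
  ubM <- unbinMap(maternalMap)
  pat <- ubP[ubP$group == sexGroup, , drop = FALSE]
  atPeak <- abs(pat$cM - sexPos) < 1e-6
  byContig <- split(atPeak, pat$contig)
  nrr <- names(byContig)[vapply(byContig, all, logical(1))]
  par <- setdiff(names(byContig), nrr)

  ## maternal group sharing most contigs with the paternal sex group
  shared <- vapply(split(ubM$contig, ubM$group), function(ctgs)
    length(intersect(unique(ctgs), unique(pat$contig))), integer(1))
  matGroup <- as.integer(names(which.max(shared)))
  matCtgs <- unique(ubM$contig[ubM$group == matGroup])

  bpOf <- function(ctgs) {
    if (is.null(contigLength)) return(NA_real_)
    sum(contigLength[ctgs], na.rm = TRUE)
  }
  list(sexGroup = sexGroup, sexPosition = sexPos, maternalGroup = matGroup,
       nrrContigs = nrr, parContigs = par,
       nrrBp = bpOf(nrr), parBp = bpOf(par),
       maternalOnly = setdiff(matCtgs, unique(pat$contig)),
       paternalOnly = setdiff(unique(pat$contig), matCtgs))
}

ptPrepare <- function(pt, maxMissing = 0.10, segP = 1e-5, thinBp = 5000,
                      distortionAlpha = 0.05) {
  counts <- c(extracted = nVariants(pt))
  pt <- maskUnexpected(pt, maxMissing)
  counts["afterMask"] <- nVariants(pt)
  pt <- segregationFilter(pt, segP)
  counts["afterSegregation"] <- nVariants(pt)
  pt <- thinVariants(pt, thinBp)
  counts["afterThinning"] <- nVariants(pt)
  ms <- binMarkers(pt)
  counts["markers"] <- nMarkers(ms)
  ms <- distortionFilter(ms, distortionAlpha)
  counts["afterDistortion"] <- nMarkers(ms)
  list(markers = ms, counts = counts)
}

withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full inference chain on a simulated family
#'
#' Simulate, filter, extract, map, scan, run the coverage analyses and the
#' expression screen, and delineate sex-chromosome regions. Given the same
#' configuration (including seed) the report is fully reproducible.
#'
#' @param config a \linkS4class{CrossConfig}.
#' @param nPerm permutations for the scan threshold (0 skips it).
#' @param maxRf maximum recombination fraction for linkage grouping.
#' @return a nested report list with the inputs, per-stage record counts,
#'   map statistics, scan peaks, concordance at the paternal peak, the
#'   heterochiasmy comparison, split-contig flags, coverage results,
#'   expression screen counts and region delineation.
#' @export
runPipeline <- function(config, nPerm = 0, maxRf = 0.4) {
  sim <- withStage("simulate", simulateCross(config))
  gt <- sim$genotypes
  truth <- sim$truth
  nSim <- nVariants(gt)

  gt <- withStage("support filter", genotypeSupportFilter(gt))
  nSupport <- nVariants(gt)
  gt <- withStage("hard filter", siteHardFilter(gt))
  nHard <- nVariants(gt)

  pts <- withStage("pseudo-testcross extraction", extractPT(gt))
  prepM <- withStage("maternal marker preparation", ptPrepare(pts$maternal))
  prepP <- withStage("paternal marker preparation", ptPrepare(pts$paternal))

  mapM <- withStage("maternal map", buildMap(prepM$markers, maxRf = maxRf))
  mapP <- withStage("paternal map", buildMap(prepP$markers, maxRf = maxRf))

  sex <- offspringSex(truth)
  scanM <- withStage("maternal scan", scanBinary(mapM, sex))
  scanP <- withStage("paternal scan", scanBinary(mapP, sex))
  peakP <- scanP[which.max(scanP$lod), ]
  thresholds <- if (nPerm > 0)
    withStage("permutation threshold",
              permutationThreshold(mapP, sex, nPerm = nPerm,
                                   seed = config@seed + 3L))
  else NULL
  ## concordance at the peak is assessed on the inferred genotype (posterior
  ## class from the linkage phase), as raw codes still carry genotyping errors
  pB <- attr(scanP, "genoProb")[, peakP$marker]
  conc <- withStage("concordance",
                    concordanceTable(ifelse(pB > 0.5, "B", "A"), sex))

  cmp <- withStage("map comparison", pairMaps(mapM, mapP))
  wilcoxP <- if (length(cmp$gapsMaternal) > 1)
    wilcoxonSignedRank(cmp$gapsMaternal, cmp$gapsPaternal) else NA_real_
  split <- withStage("split contigs",
                     detectSplitContigs(maternal = unbinMap(mapM),
                                        paternal = unbinMap(mapP)))

  doc <- withStage("depth simulation", simulateDepth(truth, config))
  dm <- withStage("depth normalization",
                  normalizeDepth(doc$depth, doc$contigLength))
  grp <- withStage("sex assignment", assignSexGroups(dm))
  flags <- if (grp$status == "ok")
    withStage("contig flags", flagContigs(dm, grp$groups)) else NULL
  screen <- withStage("gene coverage screen",
                      geneCoverageScreen(doc$geneBreadth, doc$sex))

  et <- withStage("expression simulation", simulateExpression(truth, config))
  expr <- withStage("expression screen", expressionScreen(et))

  lenBy <- tapply(truth@contigMap$end - truth@contigMap$start + 1,
                  truth@contigMap$contig, sum)
  lens <- stats::setNames(as.numeric(lenBy), names(lenBy))
  regions <- withStage("region delineation",
                       delineateSexRegions(mapP, mapM, scanP, lens))

  list(
    config = list(seed = config@seed, nChromosomes = config@nChromosomes,
                  nOffspring = config@nOffspring,
                  meanDepth = config@meanDepth,
                  genotypeErrorRate = config@genotypeErrorRate,
                  abxabRate = config@abxabRate),
    sexRatio = c(list(nMale = sum(sex == "male"),
                      nFemale = sum(sex == "female")),
                 sexRatioTest(sum(sex == "male"), sum(sex == "female"))),
    counts = list(simulated = nSim, afterSupportFilter = nSupport,
                  afterHardFilter = nHard,
                  maternal = prepM$counts, paternal = prepP$counts),
    maps = list(maternal = mapStats(mapM), paternal = mapStats(mapP)),
    scan = list(
      maternalPeak = scanM[which.max(scanM$lod), ],
      paternalPeak = peakP,
      thresholds = thresholds,
      concordantAtPeak = conc$perfect,
      discordant = conc$discordant),
    comparison = list(ratio = cmp$ratio, wilcoxonP = wilcoxP,
                      groups = cmp$groups,
                      gapsMaternal = cmp$gapsMaternal,
                      gapsPaternal = cmp$gapsPaternal),
    splitContigs = split,
    depth = list(status = grp$status,
                 groups = grp$groups,
                 flags = flags,
                 femaleDeficit = screen$femaleDeficit,
                 maleDeficit = screen$maleDeficit),
    expression = expr$counts,
    regions = regions,
    maps_objects = list(maternal = mapM, paternal = mapP),
    truth = truth)
}
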