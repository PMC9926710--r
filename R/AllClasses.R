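#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

## Genotype codes used throughout: 0 = hom ref, 1 = het, 2 = hom alt, NA = missing.

#' Cross simulation configuration
#'
#' Parameters of a simulated outbred F1 pseudo-testcross family segregating an
#' XY sex-determination system. Defaults describe a desk-scale family with the
#' structure of a real mapping population: 90 offspring, 15 chromosomes, a
#' female map twice the length of the male map, one sex chromosome whose
#' proximal 38% never recombines in male meiosis, a per-call genotyping error
#' rate of 1.2%, and 5% of pseudo-testcross candidate sites that are truly
#' heterozygous in both parents but miscalled homozygous in one.
#'
#' @slot nChromosomes number of chromosomes.
#' @slot chromLengthCM male genetic length (cM) per chromosome; for the sex
#'   chromosome this is the length of the pseudoautosomal region, since the
#'   non-recombining region contributes 0 cM in male meiosis.
#' @slot femaleMapFactor multiplier applied to male lengths to obtain female
#'   genetic lengths (heterochiasmy).
#' @slot nOffspring number of F1 offspring.
#' @slot variantsPerChromosome simulated variant sites per chromosome.
#' @slot sexChromosome index of the chromosome carrying the sex locus.
#' @slot nrrFraction fraction of the sex chromosome's physical length that
#'   never recombines in male meiosis.
#' @slot chromBp physical length (bp) per chromosome.
#' @slot meanDepth expected sequencing depth per site per sample.
#' @slot depthErrorRate per-read probability that a homozygote shows a read of
#'   the other allele (sequencing-error floor for allele depths).
#' @slot genotypeErrorRate per-call probability that an offspring genotype is
#'   replaced by a uniform draw over the three diploid genotypes.
#' @slot abxabRate fraction of pseudo-testcross candidate sites where both
#'   parents are truly heterozygous but one parent is miscalled homozygous.
#' @slot contigsPerChromosome contigs tiling each autosome (the sex chromosome
#'   is tiled more finely so reference contigs stay autosomal).
#' @slot nChimericContigs contigs spliced from two different chromosomes, to
#'   exercise split-contig detection.
#' @slot indelFraction fraction of sites written as indels rather than SNPs.
#' @slot genesPerContig annotated genes placed on each contig.
#' @slot nFemaleSpecific,nMaleSpecific genes designated female-/male-
#'   gonozooid-specific by the expression generator.
#' @slot seed RNG seed.
#' @export
setClass("CrossConfig", representation(
  nChromosomes = "integer",
  chromLengthCM = "numeric",
  femaleMapFactor = "numeric",
  nOffspring = "integer",
  variantsPerChromosome = "integer",
  sexChromosome = "integer",
  nrrFraction = "numeric",
  chromBp = "numeric",
  meanDepth = "numeric",
  depthErrorRate = "numeric",
  genotypeErrorRate = "numeric",
  abxabRate = "numeric",
  contigsPerChromosome = "integer",
  nChimericContigs = "integer",
  indelFraction = "numeric",
  genesPerContig = "integer",
  nFemaleSpecific = "integer",
  nMaleSpecific = "integer",
  seed = "integer"
))

setValidity("CrossConfig", function(object) {
  msg <- character()
  if (object@nChromosomes < 1L) msg <- c(msg, "nChromosomes must be positive")
  if (length(object@chromLengthCM) != object@nChromosomes)
    msg <- c(msg, "chromLengthCM must have one entry per chromosome")
  if (any(object@chromLengthCM < 0)) msg <- c(msg, "chromLengthCM must be >= 0")
  if (object@femaleMapFactor <= 0) msg <- c(msg, "femaleMapFactor must be > 0")
  if (object@nOffspring < 2L) msg <- c(msg, "nOffspring must be >= 2")
  if (object@nrrFraction < 0 || object@nrrFraction >= 1)
    msg <- c(msg, "nrrFraction must be in [0, 1)")
  if (object@meanDepth <= 0) msg <- c(msg, "meanDepth must be > 0")
  if (object@genotypeErrorRate < 0 || object@genotypeErrorRate >= 1)
    msg <- c(msg, "genotypeErrorRate must be in [0, 1)")
  if (object@abxabRate < 0 || object@abxabRate >= 1)
    msg <- c(msg, "abxabRate must be in [0, 1)")
  if (length(object@chromBp) != object@nChromosomes)
    msg <- c(msg, "chromBp must have one entry per chromosome")
  if (any(object@chromBp <= 0)) msg <- c(msg, "chromBp must be positive")
  if (object@sexChromosome < 1L || object@sexChromosome > object@nChromosomes)
    msg <- c(msg, "sexChromosome out of range")
  if (length(msg)) msg else TRUE
})

#' Construct a CrossConfig
#'
#' @param nChromosomes,chromLengthCM,femaleMapFactor,nOffspring See class slots.
#' @param variantsPerChromosome,sexChromosome,nrrFraction,chromBp See class slots.
#' @param meanDepth,depthErrorRate,genotypeErrorRate,abxabRate See class slots.
#' @param contigsPerChromosome,nChimericContigs,indelFraction See class slots.
#' @param genesPerContig,nFemaleSpecific,nMaleSpecific,seed See class slots.
#' @return A validated \linkS4class{CrossConfig}.
#' @examples
#' cfg <- crossConfig(nChromosomes = 2, nOffspring = 10,
#'                    variantsPerChromosome = 20, seed = 1)
#' @export
crossConfig <- function(nChromosomes = 15L,
                        chromLengthCM = round(seq(55, 30, length.out = nChromosomes), 1),
                        femaleMapFactor = 2.0,
                        nOffspring = 90L,
                        variantsPerChromosome = 360L,
                        sexChromosome = min(4L, nChromosomes),
                        nrrFraction = 0.38,
                        chromBp = rep(1.2e6, nChromosomes),
                        meanDepth = 20,
                        depthErrorRate = 0.002,
                        genotypeErrorRate = 0.012,
                        abxabRate = 0.05,
                        contigsPerChromosome = 8L,
                        nChimericContigs = 1L,
                        indelFraction = 0.15,
                        genesPerContig = 3L,
                        nFemaleSpecific = 9L,
                        nMaleSpecific = 29L,
                        seed = 1L) {
  new("CrossConfig",
      nChromosomes = as.integer(nChromosomes),
      chromLengthCM = as.numeric(chromLengthCM),
      femaleMapFactor = as.numeric(femaleMapFactor),
      nOffspring = as.integer(nOffspring),
      variantsPerChromosome = as.integer(variantsPerChromosome),
      sexChromosome = as.integer(sexChromosome),
      nrrFraction = as.numeric(nrrFraction),
      chromBp = as.numeric(chromBp),
      meanDepth = as.numeric(meanDepth),
      depthErrorRate = as.numeric(depthErrorRate),
      genotypeErrorRate = as.numeric(genotypeErrorRate),
      abxabRate = as.numeric(abxabRate),
      contigsPerChromosome = as.integer(contigsPerChromosome),
      nChimericContigs = as.integer(nChimericContigs),
      indelFraction = as.numeric(indelFraction),
      genesPerContig = as.integer(genesPerContig),
      nFemaleSpecific = as.integer(nFemaleSpecific),
      nMaleSpecific = as.integer(nMaleSpecific),
      seed = as.integer(seed))
}

#' Variants-by-samples genotype table
#'
#' A \linkS4class{SummarizedExperiment} with assays \code{geno} (integer codes
#' 0 = hom ref, 1 = het, 2 = hom alt, NA = missing), \code{adRef} and
#' \code{adAlt} (allele read counts). \code{rowData} carries the site fields
#' (contig, 1-based position, ref/alt alleles, indel flag and the site
#' annotations QD, FS, MQ, MQRankSum, ReadPosRankSum, DP); \code{colData}
#' carries the pedigree \code{role} (father, mother, offspring).
#'
#' @export
setClass("GenotypeTable", contains = "SummarizedExperiment")

setValidity("GenotypeTable", function(object) {
  msg <- character()
  need <- c("geno", "adRef", "adAlt")
  if (!all(need %in% SummarizedExperiment::assayNames(object)))
    return(sprintf("assays must include %s", paste(need, collapse = ", ")))
  g <- SummarizedExperiment::assay(object, "geno")
  if (!all(g[!is.na(g)] %in% 0:2)) msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
  rd <- SummarizedExperiment::rowData(object)
  needCols <- c("contig", "pos", "ref", "alt", "isIndel")
  if (!all(needCols %in% colnames(rd)))
    return(sprintf("rowData must contain %s", paste(needCols, collapse = ", ")))
  if (nrow(rd) > 1) {
    byContig <- split(rd$pos, rd$contig)
    if (any(vapply(byContig, function(p) any(diff(p) <= 0), logical(1))))
      msg <- c(msg, "positions must be strictly increasing within a contig")
  }
  if (any(grepl(",", rd$alt, fixed = TRUE)))
    msg <- c(msg, "multi-allelic records are not allowed")
  if (!"role" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a role column")
  ad <- SummarizedExperiment::assay(object, "adRef") + SummarizedExperiment::assay(object, "adAlt")
  if (any(!is.na(g) & is.na(ad)))
    msg <- c(msg, "allele depths must be present wherever genotype is non-missing")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeTable
#'
#' @param variants a data.frame/DataFrame with columns \code{contig},
#'   \code{pos}, \code{ref}, \code{alt}, \code{isIndel} and optionally the
#'   site annotations \code{QD}, \code{FS}, \code{MQ}, \code{MQRankSum},
#'   \code{ReadPosRankSum}, \code{DP}.
#' @param geno integer matrix of genotype codes (variants x samples).
#' @param adRef,adAlt integer matrices of reference/alternate read counts.
#' @param role character vector, one of \code{"father"}, \code{"mother"},
#'   \code{"offspring"} per sample; defaults to all offspring.
#' @return A \linkS4class{GenotypeTable}.
#' @export
GenotypeTable <- function(variants, geno, adRef, adAlt,
                          role = rep("offspring", ncol(geno))) {
  variants <- S4Vectors::DataFrame(variants)
  variants$pos <- as.integer(variants$pos)
  for (ann in c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "DP"))
    if (!ann %in% colnames(variants)) variants[[ann]] <- rep(NA_real_, nrow(variants))
  storage.mode(geno) <- "integer"
  storage.mode(adRef) <- "integer"
  storage.mode(adAlt) <- "integer"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(geno = geno, adRef = adRef, adAlt = adAlt),
    rowData = variants,
    colData = S4Vectors::DataFrame(role = role, row.names = colnames(geno)))
  new("GenotypeTable", se)
}

#' Pseudo-testcross dataset for one parent
#'
#' Variants informative for one parent's meioses, recoded per offspring to
#' \code{"A"} (the expected homozygote class), \code{"B"} (heterozygote),
#' \code{"U"} (unexpected homozygote, diagnostic of genotyping error) or
#' \code{NA} (missing).
#'
#' @slot parent \code{"mother"} or \code{"father"} (the heterozygous parent).
#' @slot variants DataFrame with \code{id}, \code{contig}, \code{pos} and the
#'   parental genotype \code{pattern}.
#' @slot codes character matrix, variants x offspring.
#' @export
setClass("PTDataset", representation(
  parent = "character",
  variants = "DataFrame",
  codes = "matrix"
))

setValidity("PTDataset", function(object) {
  msg <- character()
  if (!object@parent %in% c("mother", "father"))
    msg <- c(msg, "parent must be 'mother' or 'father'")
  cc <- object@codes
  if (!all(cc[!is.na(cc)] %in% c("A", "B", "U")))
    msg <- c(msg, "codes must be A, B, U or NA")
  if (nrow(object@variants) != nrow(cc))
    msg <- c(msg, "variants and codes must have the same number of rows")
  if (length(msg)) msg else TRUE
})

#' Set of binned markers
#'
#' Variants with identical offspring code vectors collapsed into single
#' markers. Each marker carries a consensus A/B code vector and the list of
#' member variants (id, contig, position, phase flag relative to the
#' consensus).
#'
#' @slot codes character matrix, markers x offspring (\code{"A"}/\code{"B"}/NA).
#' @slot members list of data.frames (one per marker) with columns \code{id},
#'   \code{contig}, \code{pos}, \code{flipped}.
#' @slot parent which parent's meioses the markers segregate through.
#' @export
setClass("MarkerSet", representation(
  codes = "matrix",
  members = "list",
  parent = "character"
))

setValidity("MarkerSet", function(object) {
  if (nrow(object@codes) != length(object@members))
    return("one member table per marker required")
  TRUE
})

#' Sex-specific genetic map
#'
#' Ordered markers in linkage groups with cumulative Kosambi positions.
#'
#' @slot table data.frame with columns \code{group}, \code{marker}, \code{cM}.
#' @slot codes phased character matrix (markers x offspring) aligned so that
#'   adjacent markers share linkage phase along each group.
#' @slot members list of member-variant data.frames, named by marker.
#' @slot parent which parent the map belongs to.
#' @slot unplaced ids of markers that could not be placed confidently.
#' @slot singletons ids of markers that joined no linkage group.
#' @export
setClass("GeneticMap", representation(
  table = "data.frame",
  codes = "matrix",
  members = "list",
  parent = "character",
  unplaced = "character",
  singletons = "character"
))

setValidity("GeneticMap", function(object) {
  tab <- object@table
  if (!all(c("group", "marker", "cM") %in% colnames(tab)))
    return("table must have columns group, marker, cM")
  bad <- vapply(split(tab$cM, tab$group), function(x) any(diff(x) < 0) || (length(x) && x[1] != 0),
                logical(1))
  if (any(bad)) return("positions must start at 0 and be non-decreasing within a group")
  TRUE
})

#' Normalized depth-of-coverage matrix
#'
#' @slot depth raw mean depth, samples x contigs.
#' @slot normalized depth divided by the per-sample scale.
#' @slot contigLength contig lengths in bp.
#' @slot scale per-sample normalization scale (mean raw depth over the
#'   reference contigs).
#' @slot refContigs contigs used for normalization (the longest ones).
#' @export
setClass("DepthMatrix", representation(
  depth = "matrix",
  normalized = "matrix",
  contigLength = "numeric",
  scale = "numeric",
  refContigs = "character"
))

setValidity("DepthMatrix", function(object) {
  msg <- character()
  if (any(object@depth < 0, na.rm = TRUE)) msg <- c(msg, "depths must be >= 0")
  if (ncol(object@depth) != length(object@contigLength))
    msg <- c(msg, "one length per contig required")
  if (nrow(object@depth) != length(object@scale))
    msg <- c(msg, "one scale per sample required")
  if (length(msg)) msg else TRUE
})

#' Simulator ground truth
#'
#' Everything the generator knows that the analysis has to rediscover.
#'
#' @slot chromInfo per-chromosome physical/genetic geometry, including the
#'   non-recombining region (NRR) boundary on the sex chromosome.
#' @slot contigMap contig to chromosome interval assignments (1-based,
#'   inclusive); chimeric contigs own two rows.
#' @slot variants per-site truth: chromosome, bp, contig, contig-relative
#'   position, informative type, parental haplotype assignment.
#' @slot trueGeno integer genotype matrix before error injection.
#' @slot offspringSex \code{"male"}/\code{"female"} per offspring (male =
#'   inherited the paternal Y haplotype over the NRR).
#' @slot crossovers crossover counts per meiosis: list with elements
#'   \code{father} and \code{mother}, each an offspring x chromosome matrix.
#' @slot genes gene catalogue with contig, coordinates and linkage class
#'   (\code{autosome}, \code{X}, \code{Y}, \code{PAR}).
#' @export
setClass("TruthSet", representation(
  chromInfo = "data.frame",
  contigMap = "data.frame",
  variants = "data.frame",
  trueGeno = "matrix",
  offspringSex = "character",
  crossovers = "list",
  genes = "data.frame"
))

setValidity("TruthSet", function(object) {
  cm <- object@contigMap
  ok <- vapply(split(cm, cm$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    all(d$start[-1] > d$end[-nrow(d)])
  }, logical(1))
  if (!all(ok)) return("contig intervals within a chromosome must not overlap")
  TRUE
})
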