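#' @rdname GenotypeTable
#' @export
setMethod("nVariants", "GenotypeTable", function(x) nrow(x))

#' @rdname GenotypeTable
#' @export
setMethod("variantInfo", "GenotypeTable", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname GenotypeTable
#' @export
setMethod("genotypes", "GenotypeTable", function(x)
  SummarizedExperiment::assay(x, "geno"))

#' @rdname GenotypeTable
#' @export
setMethod("alleleDepths", "GenotypeTable", function(x)
  list(ref = SummarizedExperiment::assay(x, "adRef"),
       alt = SummarizedExperiment::assay(x, "adAlt")))

#' @rdname GenotypeTable
#' @export
setMethod("sampleRoles", "GenotypeTable", function(x) {
  r <- SummarizedExperiment::colData(x)$role
  names(r) <- colnames(x)
  r
})

setMethod("show", "GenotypeTable", function(object) {
  cat("GenotypeTable:", nrow(object), "variants x", ncol(object), "samples\n")
  r <- table(SummarizedExperiment::colData(object)$role)
  cat("  roles:", paste(names(r), r, sep = "=", collapse = ", "), "\n")
  cat("  indels:", sum(SummarizedExperiment::rowData(object)$isIndel), "\n")
})

#' @rdname PTDataset
#' @export
setMethod("ptCodes", "PTDataset", function(x) x@codes)

#' @rdname PTDataset
#' @export
setMethod("parentOfInterest", "PTDataset", function(x) x@parent)

#' @rdname PTDataset
#' @export
setMethod("nVariants", "PTDataset", function(x) nrow(x@codes))

#' @rdname PTDataset
#' @export
setMethod("variantInfo", "PTDataset", function(x) as.data.frame(x@variants))

setMethod("show", "PTDataset", function(object) {
  cat("PTDataset (", object@parent, "): ", nrow(object@codes), " variants x ",
      ncol(object@codes), " offspring\n", sep = "")
  cc <- table(factor(object@codes, levels = c("A", "B", "U")), useNA = "always")
  cat("  codes:", paste(c("A", "B", "U", "missing"), as.integer(cc),
                        sep = "=", collapse = ", "), "\n")
})

#' @rdname MarkerSet
#' @export
setMethod("nMarkers", "MarkerSet", function(x) nrow(x@codes))

#' @rdname MarkerSet
#' @export
setMethod("markerCodes", "MarkerSet", function(x) x@codes)

#' @rdname MarkerSet
#' @export
setMethod("markerMembers", "MarkerSet", function(x) x@members)

setMethod("show", "MarkerSet", function(object) {
  sizes <- vapply(object@members, nrow, integer(1))
  cat("MarkerSet (", object@parent, "): ", nrow(object@codes), " markers from ",
      sum(sizes), " variants (largest bin: ", if (length(sizes)) max(sizes) else 0,
      ")\n", sep = "")
})

#' @rdname GeneticMap
#' @export
setMethod("mapTable", "GeneticMap", function(x) x@table)

#' @rdname GeneticMap
#' @export
setMethod("linkageGroups", "GeneticMap", function(x) sort(unique(x@table$group)))

#' @rdname GeneticMap
#' @export
setMethod("nMarkers", "GeneticMap", function(x) nrow(x@table))

#' @rdname GeneticMap
#' @export
setMethod("markerCodes", "GeneticMap", function(x) x@codes)

#' @rdname GeneticMap
#' @export
setMethod("markerMembers", "GeneticMap", function(x) x@members)

setMethod("show", "GeneticMap", function(object) {
  st <- mapStats(object)
  cat("GeneticMap (", object@parent, "): ", st$nMarkers, " markers in ",
      st$nGroups, " linkage groups, ", round(st$totalCM, 1), " cM (avg gap ",
      round(st$avgGap, 2), " cM/marker)\n", sep = "")
})

#' @rdname DepthMatrix
#' @export
setMethod("normalizedDepth", "DepthMatrix", function(x) x@normalized)

#' @rdname DepthMatrix
#' @export
setMethod("contigLengths", "DepthMatrix", function(x) x@contigLength)

setMethod("show", "DepthMatrix", function(object) {
  cat("DepthMatrix:", nrow(object@depth), "samples x", ncol(object@depth),
      "contigs\n  normalization contigs:",
      paste(object@refContigs, collapse = ", "), "\n")
})

#' @rdname TruthSet
#' @export
setMethod("offspringSex", "TruthSet", function(x) x@offspringSex)

#' @rdname TruthSet
#' @export
setMethod("contigMap", "TruthSet", function(x) x@contigMap)

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet:", nrow(object@variants), "variant sites on",
      nrow(object@chromInfo), "chromosomes;",
      sum(object@offspringSex == "male"), "male /",
      sum(object@offspringSex == "female"), "female offspring\n")
})

setMethod("show", "CrossConfig", function(object) {
  cat("CrossConfig:", object@nChromosomes, "chromosomes,",
      object@nOffspring, "offspring,",
      object@variantsPerChromosome, "variants/chromosome\n")
  cat("  sex chromosome", object@sexChromosome,
      sprintf("(NRR fraction %.2f), female map factor %.1f\n",
              object@nrrFraction, object@femaleMapFactor))
  cat(sprintf("  mean depth %.0fx, genotype error %.3f, het x het contamination %.2f, seed %d\n",
              object@meanDepth, object@genotypeErrorRate, object@abxabRate,
              object@seed))
})
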