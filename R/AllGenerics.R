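#' @rdname GenotypeTable
#' @param x a PTXmap object.
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname GenotypeTable
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname GenotypeTable
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GenotypeTable
#' @export
setGeneric("alleleDepths", function(x) standardGeneric("alleleDepths"))

#' @rdname GenotypeTable
#' @export
setGeneric("sampleRoles", function(x) standardGeneric("sampleRoles"))

#' @rdname PTDataset
#' @param x a PTXmap object.
#' @export
setGeneric("ptCodes", function(x) standardGeneric("ptCodes"))

#' @rdname PTDataset
#' @export
setGeneric("parentOfInterest", function(x) standardGeneric("parentOfInterest"))

#' @rdname MarkerSet
#' @param x a PTXmap object.
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname MarkerSet
#' @export
setGeneric("markerCodes", function(x) standardGeneric("markerCodes"))

#' @rdname MarkerSet
#' @export
setGeneric("markerMembers", function(x) standardGeneric("markerMembers"))

#' @rdname GeneticMap
#' @param x a PTXmap object.
#' @export
setGeneric("mapTable", function(x) standardGeneric("mapTable"))

#' @rdname GeneticMap
#' @export
setGeneric("linkageGroups", function(x) standardGeneric("linkageGroups"))

#' @rdname DepthMatrix
#' @param x a PTXmap object.
#' @export
setGeneric("normalizedDepth", function(x) standardGeneric("normalizedDepth"))

#' @rdname DepthMatrix
#' @export
setGeneric("contigLengths", function(x) standardGeneric("contigLengths"))

#' @rdname TruthSet
#' @param x a PTXmap object.
#' @export
setGeneric("offspringSex", function(x) standardGeneric("offspringSex"))

#' @rdname TruthSet
#' @export
setGeneric("contigMap", function(x) standardGeneric("contigMap"))
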