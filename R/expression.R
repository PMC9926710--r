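## Tissue-restricted expression classification at an FPKM threshold.

#' Classify genes by tissue-restricted expression
#'
#' A gene is female-specific when its female-gonozooid FPKM exceeds the
#' threshold while gastrozooid and male-gonozooid FPKM do not (strictly
#' greater than versus at most); male-specific symmetrically; everything
#' else (expressed elsewhere or unexpressed) is "other".
#'
#' @param et data.frame with columns \code{gene}, \code{gastrozooid},
#'   \code{female_gonozooid}, \code{male_gonozooid} (mean FPKM).
#' @param threshold FPKM threshold for "expressed" (> threshold).
#' @return character vector (\code{"female-specific"},
#'   \code{"male-specific"}, \code{"other"}) named by gene.
#' @export
classifyExpression <- function(et, threshold = 1) {
  stopifnot(threshold > 0)
  stopifnot(all(c("gene", "gastrozooid", "female_gonozooid",
                  "male_gonozooid") %in% colnames(et)))
  fem <- et$female_gonozooid > threshold & et$gastrozooid <= threshold &
    et$male_gonozooid <= threshold
  mal <- et$male_gonozooid > threshold & et$gastrozooid <= threshold &
    et$female_gonozooid <= threshold
  out <- rep("other", nrow(et))
  out[fem] <- "female-specific"
  out[mal] <- "male-specific"
  stats::setNames(out, et$gene)
}

#' Two-threshold expression screen
#'
#' Classifies at the strict threshold \code{t1}; genes not sex-specific at
#' \code{t1} are reclassified at the relaxed threshold \code{t2} to pick up
#' genes with high gonozooid but modest gastrozooid expression
#' ("additional" lists). The candidate set is the union of the four lists.
#'
#' @param et expression table as in \code{\link{classifyExpression}}.
#' @param t1,t2 the two FPKM thresholds.
#' @return list with \code{counts} (named vector), the four gene-id lists
#'   (\code{femaleT1}, \code{maleT1}, \code{femaleT2}, \code{maleT2}) and
#'   \code{candidates} (the union).
#' @export
expressionScreen <- function(et, t1 = 1, t2 = 5) {
  cl1 <- classifyExpression(et, t1)
  femaleT1 <- names(cl1)[cl1 == "female-specific"]
  maleT1 <- names(cl1)[cl1 == "male-specific"]
  rest <- et[cl1 == "other", , drop = FALSE]
  cl2 <- classifyExpression(rest, t2)
  femaleT2 <- names(cl2)[cl2 == "female-specific"]
  maleT2 <- names(cl2)[cl2 == "male-specific"]
  candidates <- unique(c(femaleT1, maleT1, femaleT2, maleT2))
  list(counts = c(femaleT1 = length(femaleT1), maleT1 = length(maleT1),
                  femaleT2 = length(femaleT2), maleT2 = length(maleT2),
                  candidates = length(candidates)),
       femaleT1 = femaleT1, maleT1 = maleT1,
       femaleT2 = femaleT2, maleT2 = maleT2,
       candidates = candidates)
}

#' Read a gene x tissue FPKM table
#'
#' @param path TSV with columns gene, gastrozooid, female_gonozooid,
#'   male_gonozooid.
#' @return data.frame suitable for \code{\link{classifyExpression}}.
#' @export
readExpressionTable <- function(path) {
  et <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene", "gastrozooid", "female_gonozooid", "male_gonozooid")
  if (!all(needed %in% colnames(et)))
    stop("expression table must have columns: ", paste(needed, collapse = ", "))
  et
}
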