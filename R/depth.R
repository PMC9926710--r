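## Depth-of-coverage sex assignment and sex-linked contig flagging.
##
## In an XY system, X-linked contigs have twice the depth of coverage (DoC)
## in XX females as in XY males once each sample is normalized to its
## autosomal level, and Y-linked contigs have roughly half depth in males
## and next to none in females. Samples are clustered into homogametic and
## heterogametic groups from the leading axis of DoC variation, and contigs
## with a significant between-group difference are flagged.

#' @importFrom mclust Mclust mclustBIC
NULL

#' Normalize a depth matrix
#'
#' The per-sample scale is the mean raw depth over the \code{nRef} longest
#' contigs (expected to be autosomal in a fragmented assembly); normalized
#' depth is raw depth divided by the scale, so most contigs sit near 1.
#'
#' @param depth raw mean depth matrix, samples x contigs.
#' @param contigLength contig lengths (bp), named or in column order.
#' @param nRef number of longest contigs used for the scale.
#' @return a \linkS4class{DepthMatrix}; samples with zero scale are recorded
#'   in the \code{unusable} attribute.
#' @export
normalizeDepth <- function(depth, contigLength, nRef = 5) {
  stopifnot(ncol(depth) == length(contigLength))
  if (ncol(depth) < nRef) stop("need at least ", nRef, " contigs")
  if (!is.null(names(contigLength)) && !is.null(colnames(depth)))
    contigLength <- contigLength[colnames(depth)]
  ref <- order(-contigLength)[seq_len(nRef)]
  scale <- rowMeans(depth[, ref, drop = FALSE])
  unusable <- rownames(depth)[scale == 0]
  scale[scale == 0] <- NA_real_
  out <- new("DepthMatrix", depth = depth, normalized = depth / scale,
             contigLength = as.numeric(contigLength),
             scale = as.numeric(scale),
             refContigs = colnames(depth)[ref])
  attr(out, "unusable") <- unusable
  out
}

#' Assign samples to homogametic and heterogametic groups
#'
#' Contigs shorter than \code{minLen} are dropped; the sample x contig
#' normalized matrix (contigs optionally weighted by length) is decomposed
#' by PCA and a two-component Gaussian mixture is fitted to the first
#' component (deterministic model-based initialisation). The group with the
#' lower mean normalized depth over the difference-driving contigs is
#' labelled heterogametic (XY males in an XY system, since they carry one X).
#'
#' @param dm a \linkS4class{DepthMatrix}.
#' @param minLen minimum contig length.
#' @param lengthWeighted weight contigs by length in the PCA.
#' @return list with \code{groups} (named character,
#'   \code{"homogametic"}/\code{"heterogametic"}), \code{status}
#'   (\code{"ok"} or \code{"no sex signal"}) and \code{pc1} scores. When no
#'   dosage signal exists the labels are NULL.
#' @export
assignSexGroups <- function(dm, minLen = 2500, lengthWeighted = TRUE) {
  keep <- dm@contigLength >= minLen
  X <- dm@normalized[, keep, drop = FALSE]
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 4) stop("need at least 4 usable samples")
  lens <- dm@contigLength[keep]
  Xc <- sweep(X, 2, colMeans(X))
  if (lengthWeighted) Xc <- sweep(Xc, 2, sqrt(lens / sum(lens)), `*`)
  pc1 <- stats::prcomp(Xc, center = FALSE, scale. = FALSE)$x[, 1]
  fit <- Mclust(pc1, G = 2, verbose = FALSE)
  cls <- fit$classification
  ## dosage signal: contigs whose between-group mean difference is of the
  ## magnitude expected from hemizygosity (~0.5 after normalization)
  g1 <- names(cls)[cls == 1]; g2 <- names(cls)[cls == 2]
  diff <- colMeans(X[g1, , drop = FALSE]) - colMeans(X[g2, , drop = FALSE])
  driving <- abs(diff) > 0.25
  if (!any(driving))
    return(list(groups = NULL, status = "no sex signal", pc1 = pc1))
  m1 <- mean(X[g1, driving, drop = FALSE])
  m2 <- mean(X[g2, driving, drop = FALSE])
  het <- if (m1 < m2) g1 else g2
  groups <- stats::setNames(
    ifelse(rownames(X) %in% het, "heterogametic", "homogametic"), rownames(X))
  list(groups = groups, status = "ok", pc1 = pc1)
}

#' Flag sex-linked contigs
#'
#' Per contig, the normalized depths of the two groups are compared with an
#' unequal-variance t statistic, adjusted across contigs by
#' Benjamini-Hochberg. Significant contigs whose mean difference
#' (homogametic minus heterogametic) falls in \code{window} are flagged
#' X-linked; other significant contigs are flagged sex-linked/abnormal.
#'
#' @param dm a \linkS4class{DepthMatrix}.
#' @param groups named group labels from \code{\link{assignSexGroups}}.
#' @param window mean-difference window for the X-linked call.
#' @param q FDR threshold.
#' @return data.frame with \code{contig}, \code{meanHomogametic},
#'   \code{meanHeterogametic}, \code{difference}, \code{qvalue},
#'   \code{flag}.
#' @export
flagContigs <- function(dm, groups, window = c(0.4, 0.6), q = 0.05) {
  hom <- names(groups)[groups == "homogametic"]
  het <- names(groups)[groups == "heterogametic"]
  if (length(hom) < 2 || length(het) < 2)
    stop("each group needs at least 2 samples")
  X <- dm@normalized
  pvals <- vapply(seq_len(ncol(X)), function(j) {
    a <- X[hom, j]; b <- X[het, j]
    if (stats::sd(a) < 1e-12 && stats::sd(b) < 1e-12)
      return(if (abs(mean(a) - mean(b)) < 1e-12) 1 else 0)
    tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
  }, numeric(1))
  qvals <- stats::p.adjust(pvals, method = "BH")
  mHom <- colMeans(X[hom, , drop = FALSE])
  mHet <- colMeans(X[het, , drop = FALSE])
  diff <- mHom - mHet
  flag <- rep("none", ncol(X))
  sig <- qvals < q
  flag[sig] <- "sex-linked/abnormal"
  flag[sig & diff >= window[1] & diff <= window[2]] <- "X-linked"
  data.frame(contig = colnames(X), meanHomogametic = mHom,
             meanHeterogametic = mHet, difference = diff, qvalue = qvals,
             flag = flag, row.names = NULL)
}

#' Per-gene coverage-breadth screen for sex-limited genes
#'
#' A gene is a female-deficit (candidate Y-linked) gene when its mean
#' coverage breadth is below \code{low} in females and above \code{high} in
#' males; the symmetric male-deficit list is also computed.
#'
#' @param breadth genes x samples matrix of coverage breadth in [0, 1].
#' @param sex named \code{"male"}/\code{"female"} labels for the samples.
#' @param low,high breadth thresholds.
#' @return list with \code{femaleDeficit}, \code{maleDeficit} (gene ids) and
#'   the per-sex mean breadth table \code{means}.
#' @export
geneCoverageScreen <- function(breadth, sex, low = 0.5, high = 0.9) {
  sex <- sex[colnames(breadth)]
  if (!all(c("male", "female") %in% sex)) stop("both sexes must be present")
  fMean <- rowMeans(breadth[, sex == "female", drop = FALSE])
  mMean <- rowMeans(breadth[, sex == "male", drop = FALSE])
  list(femaleDeficit = rownames(breadth)[fMean < low & mMean > high],
       maleDeficit = rownames(breadth)[mMean < low & fMean > high],
       means = data.frame(gene = rownames(breadth), femaleBreadth = fMean,
                          maleBreadth = mMean, row.names = NULL))
}
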