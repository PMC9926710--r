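## Pseudo-testcross extraction and marker preparation.
##
## In a pseudo-testcross, markers heterozygous in one parent and homozygous in
## the other segregate 1:1 in the F1 and map that parent's meioses. Offspring
## are recoded to A (the expected homozygote class), B (heterozygote) and U
## (the unexpected homozygote class, impossible under the recorded parental
## pattern and therefore diagnostic of genotyping error or a miscalled
## het x het parent pair).

codeOffspring <- function(geno, homParentCode) {
  ## homParentCode: 0 when the homozygous parent is 0/0, 2 when it is 1/1
  codes <- matrix(NA_character_, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  hetCode <- 1L
  unexpCode <- 2L - homParentCode
  codes[geno == homParentCode] <- "A"
  codes[geno == hetCode] <- "B"
  codes[geno == unexpCode] <- "U"
  codes
}

#' Extract maternal and paternal pseudo-testcross datasets
#'
#' The maternal dataset holds variants with father 0/0 and mother 0/1; the
#' paternal dataset holds variants with father 0/1 and mother 0/0 or 1/1.
#' Offspring genotypes are recoded to A (same class as the homozygous
#' parent), B (heterozygous), U (the other homozygote) or missing.
#'
#' @param gt a filtered \linkS4class{GenotypeTable}.
#' @param father,mother sample names of the parents.
#' @return list with elements \code{maternal} and \code{paternal}, each a
#'   \linkS4class{PTDataset}.
#' @export
extractPT <- function(gt, father = "father", mother = "mother") {
  g <- genotypes(gt)
  if (!father %in% colnames(g)) stop("father sample '", father, "' not found")
  if (!mother %in% colnames(g)) stop("mother sample '", mother, "' not found")
  fg <- g[, father]
  mg <- g[, mother]
  off <- g[, setdiff(colnames(g), c(father, mother)), drop = FALSE]
  vi <- variantInfo(gt)
  ids <- paste(vi$contig, vi$pos, sep = ":")

  mkDataset <- function(idx, parent, homCode, pattern) {
    codes <- codeOffspring(off[idx, , drop = FALSE], homCode)
    rownames(codes) <- ids[idx]
    new("PTDataset", parent = parent,
        variants = S4Vectors::DataFrame(id = ids[idx],
                                        contig = vi$contig[idx],
                                        pos = vi$pos[idx],
                                        pattern = pattern),
        codes = codes)
  }

  matIdx <- which(!is.na(fg) & !is.na(mg) & fg == 0L & mg == 1L)
  maternal <- mkDataset(matIdx, "mother", 0L, rep("0/0 x 0/1", length(matIdx)))

  patIdx00 <- !is.na(fg) & !is.na(mg) & fg == 1L & mg == 0L
  patIdx11 <- !is.na(fg) & !is.na(mg) & fg == 1L & mg == 2L
  patIdx <- which(patIdx00 | patIdx11)
  patCodes <- matrix(NA_character_, length(patIdx), ncol(off),
                     dimnames = list(ids[patIdx], colnames(off)))
  patCodes[patIdx00[patIdx], ] <- codeOffspring(off[which(patIdx00), , drop = FALSE], 0L)
  patCodes[patIdx11[patIdx], ] <- codeOffspring(off[which(patIdx11), , drop = FALSE], 2L)
  paternal <- new("PTDataset", parent = "father",
                  variants = S4Vectors::DataFrame(
                    id = ids[patIdx], contig = vi$contig[patIdx],
                    pos = vi$pos[patIdx],
                    pattern = ifelse(patIdx00[patIdx], "0/1 x 0/0", "0/1 x 1/1")),
                  codes = patCodes)
  list(maternal = maternal, paternal = paternal)
}

#' Unexpected-homozygote error rates
#'
#' @param pt a \linkS4class{PTDataset}.
#' @return list with \code{perOffspring} and \code{perVariant}: fractions of
#'   non-missing calls coded U.
#' @export
errorRates <- function(pt) {
  cc <- pt@codes
  if (nrow(cc) == 0) stop("empty dataset")
  isU <- cc == "U"
  nonMissing <- !is.na(cc)
  list(perOffspring = colSums(isU, na.rm = TRUE) / colSums(nonMissing),
       perVariant = rowSums(isU, na.rm = TRUE) / rowSums(nonMissing))
}

#' Mask unexpected homozygotes and drop high-missingness variants
#'
#' All U codes become missing; variants whose missing fraction then exceeds
#' \code{maxMissing} (strictly) are removed.
#'
#' @param pt a \linkS4class{PTDataset}.
#' @param maxMissing maximum tolerated missing fraction.
#' @return the masked and filtered \linkS4class{PTDataset}.
#' @export
maskUnexpected <- function(pt, maxMissing = 0.10) {
  cc <- pt@codes
  cc[cc == "U"] <- NA_character_
  missFrac <- rowMeans(is.na(cc))
  keep <- missFrac <= maxMissing
  new("PTDataset", parent = pt@parent,
      variants = pt@variants[keep, , drop = FALSE],
      codes = cc[keep, , drop = FALSE])
}

#' Mendelian segregation filter
#'
#' Chi-square goodness of fit against 1:1 A:B segregation over non-missing
#' offspring (df = 1, no continuity correction); variants with p below
#' \code{pThreshold} are removed.
#'
#' @param pt a masked \linkS4class{PTDataset} (A/B codes only).
#' @param pThreshold removal threshold on the p-value.
#' @return the filtered \linkS4class{PTDataset}.
#' @export
segregationFilter <- function(pt, pThreshold = 1e-5) {
  cc <- pt@codes
  a <- rowSums(cc == "A", na.rm = TRUE)
  b <- rowSums(cc == "B", na.rm = TRUE)
  chi2 <- (a - b)^2 / (a + b)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  keep <- is.na(p) | p >= pThreshold
  new("PTDataset", parent = pt@parent,
      variants = pt@variants[keep, , drop = FALSE],
      codes = cc[keep, , drop = FALSE])
}

#' Physical thinning
#'
#' Greedy per-contig scan from the smallest coordinate: a variant is kept iff
#' it lies at least \code{minBp} beyond the last kept variant on the contig.
#'
#' @param pt a \linkS4class{PTDataset} (variants sorted by contig, position).
#' @param minBp minimum spacing in bp.
#' @return the thinned \linkS4class{PTDataset}.
#' @export
thinVariants <- function(pt, minBp = 5000) {
  v <- pt@variants
  keep <- logical(nrow(v))
  for (idx in split(seq_len(nrow(v)), v$contig)) {
    pos <- v$pos[idx]
    last <- -Inf
    for (k in seq_along(idx)) {
      if (pos[k] - last >= minBp) {
        keep[idx[k]] <- TRUE
        last <- pos[k]
      }
    }
  }
  new("PTDataset", parent = pt@parent,
      variants = v[keep, , drop = FALSE],
      codes = pt@codes[keep, , drop = FALSE])
}

#' Bin variants with identical segregation into markers
#'
#' Variants whose offspring code vectors are exactly equal (missing positions
#' included) are collapsed into a single marker; bins may span contigs. The
#' marker is named after its first member variant.
#'
#' @param pt a \linkS4class{PTDataset}.
#' @return a \linkS4class{MarkerSet}.
#' @export
binMarkers <- function(pt) {
  cc <- pt@codes
  v <- as.data.frame(pt@variants)
  key <- apply(cc, 1, function(x) paste(ifelse(is.na(x), "-", x), collapse = ""))
  groups <- split(seq_len(nrow(cc)), key)
  ## deterministic marker order: by first member's (contig, pos)
  first <- vapply(groups, `[`, integer(1), 1)
  ord <- order(v$contig[first], v$pos[first])
  groups <- groups[ord]
  first <- first[ord]
  codes <- cc[first, , drop = FALSE]
  rownames(codes) <- v$id[first]
  members <- lapply(groups, function(idx)
    data.frame(id = v$id[idx], contig = v$contig[idx], pos = v$pos[idx],
               flipped = FALSE))
  names(members) <- v$id[first]
  new("MarkerSet", codes = codes, members = members, parent = pt@parent)
}

#' Post-binning segregation-distortion filter
#'
#' Recomputes the 1:1 chi-square test per marker and removes markers with
#' p below the Bonferroni-corrected threshold \code{alpha / nMarkers}.
#'
#' @param ms a \linkS4class{MarkerSet}.
#' @param alpha family-wise error rate.
#' @return the filtered \linkS4class{MarkerSet}.
#' @export
distortionFilter <- function(ms, alpha = 0.05) {
  cc <- ms@codes
  a <- rowSums(cc == "A", na.rm = TRUE)
  b <- rowSums(cc == "B", na.rm = TRUE)
  chi2 <- (a - b)^2 / (a + b)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  cut <- alpha / nrow(cc)
  keep <- is.na(p) | p >= cut
  new("MarkerSet", codes = cc[keep, , drop = FALSE],
      members = ms@members[keep], parent = ms@parent)
}
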