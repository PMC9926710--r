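## VCF 4.2 input/output, via vcfR. Only biallelic records with GT and AD are
## representable; the reader drops everything else with a logged count.

fmtNum <- function(x) {
  out <- ifelse(is.na(x), NA_character_, formatC(x, digits = 17, format = "g"))
  out
}

#' Write a GenotypeTable as VCF 4.2
#'
#' Emits a gzipped, standards-compliant VCF 4.2 with GT and AD per sample and
#' the site annotations QD, FS, MQ, MQRankSum, ReadPosRankSum and DP as INFO
#' keys. Positions are 1-based. The file round-trips losslessly through
#' \code{\link{readGenotypeVcf}}.
#'
#' @param gt a \linkS4class{GenotypeTable}.
#' @param path output path (conventionally ending in \code{.vcf.gz}).
#' @return \code{path}, invisibly.
#' @export
writeGenotypeVcf <- function(gt, path) {
  vi <- variantInfo(gt)
  g <- genotypes(gt)
  ad <- alleleDepths(gt)
  n <- nrow(vi)
  meta <- c(
    "##fileformat=VCFv4.2",
    "##source=PTXmap",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Combined depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">")
  keys <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "DP")
  info <- vapply(seq_len(n), function(i) {
    vals <- vapply(keys, function(k) fmtNum(vi[[k]][i]), character(1))
    keep <- !is.na(vals)
    if (!any(keep)) "." else paste(keys[keep], vals[keep], sep = "=", collapse = ";")
  }, character(1))
  fix <- cbind(CHROM = as.character(vi$contig), POS = as.character(vi$pos),
               ID = ".", REF = vi$ref, ALT = vi$alt, QUAL = ".", FILTER = ".",
               INFO = info)
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", colnames(g)), collapse = "\t")
  if (n == 0) {
    con <- gzfile(path, "w")
    on.exit(close(con))
    writeLines(c(meta, header), con)
    return(invisible(path))
  }
  gtStr <- matrix(GENO_LEVELS[g + 1L], nrow(g), ncol(g))
  gtStr[is.na(g)] <- "./."
  body <- matrix(paste0(gtStr, ":", ad$ref, ",", ad$alt),
                 nrow(g), ncol(g), dimnames = dimnames(g))
  vcf <- new("vcfR", meta = meta, fix = fix,
             gt = cbind(FORMAT = rep("GT:AD", n), body))
  vcfR::write.vcf(vcf, file = path)
  invisible(path)
}

#' Read a VCF into a GenotypeTable
#'
#' Parses a VCF 4.2 with GT and AD format fields. Records with more than one
#' alternate allele or without AD are dropped; the number dropped is recorded
#' in the \code{dropped} attribute and reported via \code{message}.
#'
#' @param path VCF path (plain or gzipped).
#' @param father,mother sample names of the two parents; any other sample is
#'   treated as an offspring.
#' @return a \linkS4class{GenotypeTable}.
#' @export
readGenotypeVcf <- function(path, father = "father", mother = "mother") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = length(fix) %/% 7, ncol = 7)
  n <- nrow(vcf@fix)
  multi <- grepl(",", vcf@fix[, "ALT"], fixed = TRUE)
  fmt <- vcf@gt[, "FORMAT"]
  noAD <- !grepl("(^|:)AD(:|$)", fmt)
  drop <- multi | noAD
  nDropped <- sum(drop)
  if (nDropped > 0)
    message(nDropped, " record(s) dropped (multi-allelic or missing AD)")
  vcf <- vcf[!drop, ]
  if (nrow(vcf@fix) == 0) {
    samples <- setdiff(colnames(vcf@gt), "FORMAT")
    empty <- matrix(integer(), 0, length(samples),
                    dimnames = list(NULL, samples))
    out <- GenotypeTable(
      data.frame(contig = character(), pos = integer(), ref = character(),
                 alt = character(), isIndel = logical()),
      empty, empty, empty,
      role = ifelse(samples == father, "father",
                    ifelse(samples == mother, "mother", "offspring")))
    attr(out, "dropped") <- nDropped
    return(out)
  }

  gtRaw <- vcfR::extract.gt(vcf, element = "GT")
  gtRaw <- gsub("|", "/", gtRaw, fixed = TRUE)
  geno <- matrix(NA_integer_, nrow(gtRaw), ncol(gtRaw), dimnames = dimnames(gtRaw))
  geno[gtRaw == "0/0"] <- 0L
  geno[gtRaw %in% c("0/1", "1/0")] <- 1L
  geno[gtRaw == "1/1"] <- 2L

  adRaw <- vcfR::extract.gt(vcf, element = "AD")
  splitAD <- function(k) {
    v <- suppressWarnings(as.integer(vapply(strsplit(ifelse(is.na(adRaw), "0,0", adRaw), ",",
                                                     fixed = TRUE),
                                            `[`, character(1), k)))
    matrix(v, nrow(adRaw), ncol(adRaw), dimnames = dimnames(adRaw))
  }
  adRef <- splitAD(1)
  adAlt <- splitAD(2)

  ref <- vcf@fix[, "REF"]
  alt <- vcf@fix[, "ALT"]
  getInfo <- function(k) suppressWarnings(
    as.numeric(vcfR::extract.info(vcf, element = k)))
  variants <- data.frame(
    contig = vcf@fix[, "CHROM"],
    pos = as.integer(vcf@fix[, "POS"]),
    ref = ref, alt = alt,
    isIndel = nchar(ref) > 1 | nchar(alt) > 1,
    QD = getInfo("QD"), FS = getInfo("FS"), MQ = getInfo("MQ"),
    MQRankSum = getInfo("MQRankSum"),
    ReadPosRankSum = getInfo("ReadPosRankSum"),
    DP = getInfo("DP"))
  samples <- colnames(geno)
  role <- ifelse(samples == father, "father",
                 ifelse(samples == mother, "mother", "offspring"))
  rownames(geno) <- rownames(adRef) <- rownames(adAlt) <- NULL
  out <- GenotypeTable(variants, geno, adRef, adAlt, role = role)
  attr(out, "dropped") <- nDropped
  out
}

#' Read-support genotype filter
#'
#' Keeps only variants where (1) no sample has a missing genotype; (2) every
#' homozygous-reference sample has at most 2 alternate reads and more than 10
#' reference reads; (3) every homozygous-alternate sample has at most 2
#' reference reads and more than 10 alternate reads; and (4) every
#' heterozygous sample has an alternate allele fraction strictly between 0.3
#' and 0.7.
#'
#' @param gt a \linkS4class{GenotypeTable}.
#' @return the filtered \linkS4class{GenotypeTable}; the attribute
#'   \code{removed} holds per-rule removal counts (a variant can fail several
#'   rules).
#' @export
genotypeSupportFilter <- function(gt) {
  g <- genotypes(gt)
  ad <- alleleDepths(gt)
  refN <- ad$ref; altN <- ad$alt
  anyMissing <- rowSums(is.na(g)) > 0

  isHomRef <- !is.na(g) & g == 0L
  badHomRef <- rowSums(isHomRef & (altN > 2 | refN <= 10)) > 0
  isHomAlt <- !is.na(g) & g == 2L
  badHomAlt <- rowSums(isHomAlt & (refN > 2 | altN <= 10)) > 0
  isHet <- !is.na(g) & g == 1L
  frac <- altN / (refN + altN)
  badHet <- rowSums(isHet & (is.na(frac) | frac <= 0.3 | frac >= 0.7)) > 0

  keep <- !(anyMissing | badHomRef | badHomAlt | badHet)
  out <- gt[keep, ]
  attr(out, "removed") <- c(missing = sum(anyMissing),
                            homRefSupport = sum(badHomRef),
                            homAltSupport = sum(badHomAlt),
                            hetBalance = sum(badHet))
  out
}

#' Hard site filters
#'
#' Removes SNPs with QD < 2, FS > 60, MQ < 40, MQRankSum < -12.5,
#' ReadPosRankSum < -8 or DP < 10, and indels with QD < 2, FS > 200 or
#' ReadPosRankSum < -20. Missing annotations are treated as passing (the
#' count of sites with any missing annotation is logged in the
#' \code{missingAnnotation} attribute).
#'
#' @param gt a \linkS4class{GenotypeTable}.
#' @return the filtered \linkS4class{GenotypeTable}; attribute \code{removed}
#'   holds removal counts for SNPs and indels.
#' @export
siteHardFilter <- function(gt) {
  vi <- variantInfo(gt)
  lt <- function(x, cut) !is.na(x) & x < cut
  gtr <- function(x, cut) !is.na(x) & x > cut
  badSnp <- !vi$isIndel & (lt(vi$QD, 2) | gtr(vi$FS, 60) | lt(vi$MQ, 40) |
                             lt(vi$MQRankSum, -12.5) |
                             lt(vi$ReadPosRankSum, -8) | lt(vi$DP, 10))
  badIndel <- vi$isIndel & (lt(vi$QD, 2) | gtr(vi$FS, 200) |
                              lt(vi$ReadPosRankSum, -20))
  keep <- !(badSnp | badIndel)
  out <- gt[keep, ]
  attr(out, "removed") <- c(snp = sum(badSnp), indel = sum(badIndel))
  attr(out, "missingAnnotation") <- sum(rowSums(is.na(
    vi[, c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "DP")])) > 0)
  out
}
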