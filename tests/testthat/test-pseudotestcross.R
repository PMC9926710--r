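test_that("testcross patterns are routed and recoded correctly", {
  ## variants: 1 father 0/0 x mother 0/1 (maternal); 2 father 0/1 x mother 0/1
  ## (neither); 3 father 0/1 x mother 1/1 (paternal); 4 father 0/1 x mother 0/0
  ## (paternal)
  geno <- matrix(c(0L, 1L, 0L, 1L, 2L,
                   1L, 1L, 0L, 1L, 2L,
                   1L, 2L, 1L, 2L, 0L,
                   1L, 0L, 0L, 1L, 2L), 4, 5, byrow = TRUE)
  gt <- makeGT(geno, role = c("father", "mother", rep("offspring", 3)))
  pts <- extractPT(gt)
  expect_equal(nVariants(pts$maternal), 1)
  expect_equal(nVariants(pts$paternal), 2)
  ## maternal 0/0 x 0/1: offspring 0/0 -> A, 0/1 -> B, 1/1 -> U
  expect_equal(unname(ptCodes(pts$maternal)[1, ]), c("A", "B", "U"))
  ## paternal 0/1 x 1/1: offspring 0/1 -> B, 1/1 -> A, 0/0 -> U
  expect_equal(unname(ptCodes(pts$paternal)[1, ]), c("B", "A", "U"))
  ## paternal 0/1 x 0/0: offspring 0/0 -> A, 0/1 -> B, 1/1 -> U
  expect_equal(unname(ptCodes(pts$paternal)[2, ]), c("A", "B", "U"))
  expect_error(extractPT(gt, father = "nope"), "not found")
})

test_that("the two PT datasets partition the informative variants", {
  sim <- smallCross()
  gt <- siteHardFilter(genotypeSupportFilter(sim$genotypes))
  pts <- extractPT(gt)
  expect_length(intersect(variantInfo(pts$maternal)$id,
                          variantInfo(pts$paternal)$id), 0)
})

test_that("unexpected-homozygote rates are computed over non-missing calls", {
  codes <- matrix(c("A", "B", "A", "B",
                    "U", "B", "A", NA,
                    "A", "B", "A", "B"), 3, 4, byrow = TRUE)
  pt <- new("PTDataset", parent = "mother",
            variants = S4Vectors::DataFrame(id = paste0("v", 1:3),
                                            contig = "c1", pos = 1:3 * 10000L,
                                            pattern = "0/0 x 0/1"),
            codes = codes)
  er <- errorRates(pt)
  expect_equal(unname(er$perVariant), c(0, 1 / 3, 0))
  expect_equal(unname(er$perOffspring), c(1 / 3, 0, 0, 0))
  clean <- errorRates(new("PTDataset", parent = "mother",
                          variants = pt@variants[1, , drop = FALSE],
                          codes = codes[1, , drop = FALSE]))
  expect_true(all(clean$perVariant == 0) && all(clean$perOffspring == 0))
})

test_that("a miscalled het x het site shows ~25% unexpected homozygotes", {
  set.seed(31)
  n <- 500; off <- 90
  geno <- cbind(father = rep(0L, n), mother = rep(1L, n),
                matrix(sample(0:2, n * off, replace = TRUE,
                              prob = c(0.25, 0.5, 0.25)), n, off))
  colnames(geno) <- c("father", "mother", sprintf("off%03d", seq_len(off)))
  gt <- makeGT(geno, role = c("father", "mother", rep("offspring", off)))
  er <- errorRates(extractPT(gt)$maternal)
  expect_lt(abs(mean(er$perVariant) - 0.25), 0.01)
})

test_that("per-offspring U rate matches the miscall model expectation e/3", {
  sim <- smallCross()  # genotypeErrorRate 0.012, abxab 0.05
  gt <- sim$genotypes
  pts <- extractPT(gt)
  ## restrict to sites that are genuinely testcross (exclude het x het
  ## contamination, whose U codes reflect the parents, not offspring errors)
  tv <- sim$truth@variants
  tv$id <- paste(tv$contig, tv$pos, sep = ":")
  keepM <- variantInfo(pts$maternal)$id %in% tv$id[tv$type != "abxab"]
  er <- errorRates(new("PTDataset", parent = "mother",
                       variants = pts$maternal@variants[keepM, , drop = FALSE],
                       codes = ptCodes(pts$maternal)[keepM, , drop = FALSE]))
  e3 <- sim$config@genotypeErrorRate / 3
  expect_lt(abs(mean(er$perOffspring) - e3), 0.0015)
})

test_that("masking turns U to missing and applies the strict 10% rule", {
  off <- 90
  mkrow <- function(nU) c(rep("U", nU), rep(c("A", "B"), length.out = off - nU))
  codes <- rbind(mkrow(10), mkrow(9), mkrow(0))
  pt <- new("PTDataset", parent = "mother",
            variants = S4Vectors::DataFrame(id = paste0("v", 1:3),
                                            contig = "c1", pos = 1:3 * 10000L,
                                            pattern = "0/0 x 0/1"),
            codes = codes)
  out <- maskUnexpected(pt)
  expect_equal(variantInfo(out)$id, c("v2", "v3"))   # 10/90 = 11.1% removed
  expect_equal(sum(is.na(ptCodes(out)[1, ])), 9)     # 9/90 = 10% retained
  expect_false(any(ptCodes(out) == "U", na.rm = TRUE))
})

test_that("segregation filter removes only strong distortion", {
  off <- 90
  mkrow <- function(nA) c(rep("A", nA), rep("B", off - nA))
  codes <- rbind(mkrow(45), mkrow(80), mkrow(55))
  pt <- new("PTDataset", parent = "mother",
            variants = S4Vectors::DataFrame(id = paste0("v", 1:3),
                                            contig = "c1", pos = 1:3 * 10000L,
                                            pattern = "0/0 x 0/1"),
            codes = codes)
  out <- segregationFilter(pt)
  ## 80/10: chi2 = 54.4, p ~ 1.6e-13 -> removed; 55/35: chi2 = 4.44 -> kept
  expect_equal(variantInfo(out)$id, c("v1", "v3"))
})

test_that("thinning keeps the greedy >=5 kb spacing per contig", {
  codes <- matrix(rep(c("A", "B"), 4), 4, 2)
  pt <- new("PTDataset", parent = "mother",
            variants = S4Vectors::DataFrame(
              id = paste0("v", 1:4),
              contig = c("c1", "c1", "c1", "c2"),
              pos = c(100L, 3000L, 6000L, 50L),
              pattern = "0/0 x 0/1"),
            codes = codes)
  out <- thinVariants(pt)
  expect_equal(variantInfo(out)$id, c("v1", "v3", "v4"))
  pt2 <- new("PTDataset", parent = "mother",
             variants = S4Vectors::DataFrame(id = c("a", "b"), contig = "c1",
                                             pos = c(100L, 5100L),
                                             pattern = "0/0 x 0/1"),
             codes = codes[1:2, , drop = FALSE])
  expect_equal(nVariants(thinVariants(pt2)), 2)  # 5000 bp satisfies >= 5000
})

test_that("binning collapses exactly-equal code vectors, missing included", {
  codes <- rbind(c("A", "B", "A", NA),
                 c("A", "B", "A", NA),
                 c("A", "B", "A", "A"),
                 c("A", "B", "B", NA))
  pt <- new("PTDataset", parent = "mother",
            variants = S4Vectors::DataFrame(
              id = paste0("v", 1:4),
              contig = c("c1", "c2", "c1", "c1"),
              pos = c(10000L, 500L, 20000L, 30000L),
              pattern = "0/0 x 0/1"),
            codes = codes)
  ms <- binMarkers(pt)
  expect_equal(nMarkers(ms), 3)
  sizes <- vapply(markerMembers(ms), nrow, integer(1))
  expect_equal(sum(sizes), 4)                       # binning is a partition
  big <- markerMembers(ms)[[which(sizes == 2)]]
  expect_setequal(big$id, c("v1", "v2"))            # bin spans two contigs
})

test_that("post-binning distortion filter uses the Bonferroni cut", {
  off <- 90
  mkrow <- function(nA) c(rep("A", nA), rep("B", off - nA))
  nMk <- 977
  codes <- do.call(rbind, c(list(mkrow(55), mkrow(80)),
                            replicate(nMk - 2, mkrow(45), simplify = FALSE)))
  rownames(codes) <- paste0("m", seq_len(nMk))
  members <- lapply(seq_len(nMk), function(i)
    data.frame(id = paste0("m", i), contig = "c1", pos = i * 6000L,
               flipped = FALSE))
  names(members) <- rownames(codes)
  ms <- new("MarkerSet", codes = codes, members = members, parent = "mother")
  out <- distortionFilter(ms)
  ## 55/35 (p = 0.035 > 0.05/977) retained; 80/10 (p ~ 1.6e-13) removed
  expect_equal(nMarkers(out), nMk - 1)
  expect_false("m2" %in% rownames(markerCodes(out)))
})

test_that("het x het contamination surfaces at the configured rate", {
  sim <- smallCross()  # abxabRate 0.05
  gt <- genotypeSupportFilter(sim$genotypes)
  pts <- extractPT(gt)
  for (pt in pts) {
    er <- errorRates(pt)
    tv <- sim$truth@variants
    tv$id <- paste(tv$contig, tv$pos, sep = ":")
    isAb <- variantInfo(pt)$id %in% tv$id[tv$type == "abxab"]
    ## contaminated sites carry ~25% unexpected homozygotes...
    expect_lt(abs(mean(er$perVariant[isAb]) - 0.25), 0.05)
    ## ...and make up about the configured fraction of the dataset
    expect_lt(abs(mean(isAb) - 0.05), 0.035)
  }
})
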