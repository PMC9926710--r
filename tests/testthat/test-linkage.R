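test_that("two-point rf and LOD match the closed forms", {
  x <- rep(c("A", "B"), each = 45)
  same <- twoPoint(x, x)
  expect_equal(same$rf, 0)
  expect_equal(same$lod, 90 * log10(2), tolerance = 1e-9)
  expect_equal(same$phase, "aligned")

  comp <- twoPoint(x, ifelse(x == "A", "B", "A"))
  expect_equal(comp$rf, 0)
  expect_equal(comp$phase, "flipped")
  expect_equal(comp$lod, 90 * log10(2), tolerance = 1e-9)

  y <- x; y[1:9] <- ifelse(y[1:9] == "A", "B", "A")
  r9 <- twoPoint(x, y)
  expect_equal(r9$rf, 0.1)
  expect_equal(r9$lod, 9 * log10(0.1) + 81 * log10(0.9) + 90 * log10(2),
               tolerance = 1e-9)

  few <- twoPoint(c("A", NA, NA), c(NA, "B", NA))
  expect_false(few$valid)
})

test_that("two-point estimates maximise the likelihood over a dense rf grid", {
  grid <- seq(0.001, 0.5, by = 0.001)
  set.seed(17)
  for (rep in 1:20) {
    N <- sample(20:60, 1)
    c1 <- sample(c("A", "B"), N, replace = TRUE)
    flip <- runif(N) < runif(1, 0.05, 0.6)
    c2 <- ifelse(flip, ifelse(c1 == "A", "B", "A"), c1)
    res <- twoPoint(c1, c2)
    Rp <- min(sum(c1 != c2), N - sum(c1 != c2))
    ll <- Rp * log10(grid) + (N - Rp) * log10(1 - grid) + N * log10(2)
    expect_lte(abs(res$rf - grid[which.max(ll)]), 0.001)
    expect_gte(res$lod, max(ll) - 1e-9)
  }
})

test_that("the matrix form agrees with pairwise two-point calls", {
  set.seed(3)
  codes <- matrix(sample(c("A", "B", NA), 6 * 40, replace = TRUE,
                         prob = c(0.45, 0.45, 0.1)), 6, 40)
  rownames(codes) <- paste0("m", 1:6)
  tp <- twoPointMatrix(codes)
  for (i in 1:5) for (j in (i + 1):6) {
    ref <- twoPoint(codes[i, ], codes[j, ])
    if (!ref$valid) {
      expect_true(is.na(tp$rf[i, j]))
    } else {
      expect_equal(tp$rf[i, j], ref$rf)
      expect_equal(tp$lod[i, j], ref$lod)
      expect_equal(unname(tp$flipped[i, j]), ref$phase == "flipped")
    }
  }
})

test_that("the Bonferroni LOD threshold reproduces printed values and is monotone", {
  expect_equal(suggestLod(977), 6.14, tolerance = 0.01)
  expect_equal(suggestLod(487), 5.56, tolerance = 0.01)
  expect_equal(suggestLod(2), stats::qchisq(0.95, 1) / (2 * log(10)),
               tolerance = 1e-9)
  n <- c(2, 10, 100, 1000, 5000)
  expect_true(all(diff(vapply(n, suggestLod, numeric(1))) > 0))
  expect_error(suggestLod(1))
})

test_that("grouping is transitive and isolates unlinked markers", {
  base <- rep(c("A", "B"), each = 45)
  flipAt <- function(x, idx) { x[idx] <- ifelse(x[idx] == "A", "B", "A"); x }
  codes <- rbind(A = base, B = flipAt(base, 1:9), C = flipAt(base, 1:18))
  ## with maxRf 0.15: A-B (0.1) and B-C (0.1) link, A-C (0.2) does not,
  ## yet transitivity joins all three
  grp <- groupMarkers(codes, maxRf = 0.15, minLod = 3)
  expect_length(grp$groups, 1)
  expect_setequal(grp$groups[[1]], c("A", "B", "C"))

  set.seed(9)
  rand <- matrix(sample(c("A", "B"), 4 * 90, replace = TRUE), 4, 90,
                 dimnames = list(paste0("r", 1:4), NULL))
  grp2 <- groupMarkers(rand, maxRf = 0.4, minLod = 6)
  expect_length(grp2$groups, 0)
  expect_length(grp2$singletons, 4)
})

test_that("three linked markers are ordered by brute force", {
  base <- rep(c("A", "B"), each = 50)
  flipAt <- function(x, idx) { x[idx] <- ifelse(x[idx] == "A", "B", "A"); x }
  codes <- rbind(A = base, C = flipAt(base, 1:10), B = flipAt(base, 1:5))
  ## true order A-B-C: rf(A,B) = 0.05, rf(B,C) = 0.05, rf(A,C) = 0.10
  o <- orderGroup(codes, pruneTol = Inf)
  expect_true(identical(o$order, c("A", "B", "C")) ||
                identical(o$order, c("C", "B", "A")))
  ## a zero-length chain stays at 0 cM
  z <- orderGroup(rbind(x = base, y = base, z = base), pruneTol = Inf)
  expect_equal(max(z$cM), 0)
  expect_length(z$unplaced, 0)
})

test_that("simulated marker orders and distances are recovered at n = 2000", {
  codes <- makeChainCodes(gapsCM = rep(5, 7), n = 2000, seed = 42)
  perm <- sample(nrow(codes))
  o <- orderGroup(codes[perm, ])
  expect_true(identical(o$order, rownames(codes)) ||
                identical(o$order, rev(rownames(codes))))
  expect_lt(sqrt(mean((diff(o$cM) - 5)^2)), 1)
})

test_that("phase-complementary co-located markers are deduplicated", {
  base <- rep(c("A", "B"), each = 45)
  flipAll <- ifelse(base == "A", "B", "A")
  codes <- rbind(m1 = base, m2 = flipAll, m3 = base)
  members <- list(
    m1 = data.frame(id = c("m1", "m1b"), contig = "c1",
                    pos = c(10000L, 20000L), flipped = FALSE),
    m2 = data.frame(id = "m2", contig = "c1", pos = 30000L, flipped = FALSE),
    m3 = data.frame(id = "m3", contig = "c9", pos = 1000L, flipped = FALSE))
  ms <- new("MarkerSet", codes = codes, members = members, parent = "mother")
  map <- buildMap(ms, minLod = 3, pruneTol = Inf)
  ## m2 (complement of m1, same contig, same position) is dropped; m3,
  ## identical to m1 but on another contig, survives
  expect_false("m2" %in% mapTable(map)$marker)
  expect_true(all(c("m1", "m3") %in% mapTable(map)$marker))
})

test_that("unbinning conserves variants and propagates positions", {
  sim <- smallCross()
  gt <- siteHardFilter(genotypeSupportFilter(sim$genotypes))
  pt <- thinVariants(segregationFilter(maskUnexpected(extractPT(gt)$maternal)))
  ms <- distortionFilter(binMarkers(pt))
  map <- buildMap(ms, minLod = suggestLod(nMarkers(ms)))
  ub <- unbinMap(map)
  sizes <- vapply(markerMembers(map)[mapTable(map)$marker], nrow, integer(1))
  expect_equal(nrow(ub), sum(sizes))
  one <- mapTable(map)$marker[which.max(sizes)]
  expect_true(all(ub$cM[ub$marker == one] == mapTable(map)$cM[
    mapTable(map)$marker == one]))
})

test_that("map statistics reproduce the average-gap arithmetic", {
  expect_equal(averageGap(1545.5, 590, 15), 2.69, tolerance = 0.005)
  expect_equal(averageGap(827.7, 305, 15), 2.85, tolerance = 0.005)
  expect_equal(averageGap(10, 2, 1), 10)
  expect_equal(averageGap(0, 3, 3), 0)
})

test_that("split contigs are flagged only with two supporting variants per group", {
  ub <- data.frame(
    group = c(1, 1, 2, 2, 1, 1, 1, 2),
    marker = paste0("k", 1:8), cM = 0,
    id = paste0("v", 1:8),
    contig = c("chim", "chim", "chim", "chim", "solid", "solid", "stray", "stray"),
    pos = 1:8)
  out <- detectSplitContigs(main = ub)
  expect_equal(out$contig, "chim")
  expect_equal(out$groups, "1,2")
})

test_that("the chimeric contig of a simulated cross is detected", {
  rep <- fullPipelineRun()
  truthC <- contigMap(rep$truth)
  chim <- names(which(table(truthC$contig) > 1))
  expect_length(chim, 1)
  expect_true(chim %in% rep$splitContigs$contig)
  chromsOf <- sort(unique(truthC$chrom[truthC$contig == chim]))
  expect_length(chromsOf, 2)
})

test_that("physical pairing respects the 5 kb window and contig identity", {
  mkMap <- function(parent, pos, contig = "c1") {
    codes <- matrix(rep(rep(c("A", "B"), each = 45), length(pos)),
                    length(pos), 90, byrow = TRUE)
    rownames(codes) <- paste0(parent, seq_along(pos))
    members <- lapply(seq_along(pos), function(i)
      data.frame(id = rownames(codes)[i], contig = contig, pos = pos[i],
                 flipped = FALSE))
    names(members) <- rownames(codes)
    new("GeneticMap",
        table = data.frame(group = 1L, marker = rownames(codes),
                           cM = c(0, cumsum(rep(1e-9, length(pos) - 1))),
                           flipped = FALSE),
        codes = codes, members = members, parent = parent,
        unplaced = character(), singletons = character())
  }
  near <- pairMaps(mkMap("M", c(1000L, 50000L)), mkMap("P", c(4000L, 57000L)))
  expect_equal(nrow(near$pairs), 1)            # 3000 pairs, 7000 does not
  far <- pairMaps(mkMap("M", 1000L), mkMap("P", 7000L))
  expect_null(far$pairs)
  cross <- pairMaps(mkMap("M", 1000L), mkMap("P", 1500L, contig = "c2"))
  expect_null(cross$pairs)                     # different contig never pairs
})

test_that("heterochiasmy is recovered from rebuilt paired maps", {
  rep <- fullPipelineRun()
  expect_equal(rep$comparison$ratio, 2, tolerance = 0.2)
  expect_lt(rep$comparison$wilcoxonP, 0.05)
  expect_gt(length(rep$comparison$gapsMaternal), 20)
})
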