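## Marker ordering and map construction.
##
## Ordering minimises the sum of adjacent recombination fractions (SARF): a
## seed of the five most informative markers is ordered by exhaustive search,
## and the remaining markers are inserted one by one at the SARF-minimising
## position. The criterion is deterministic, so identical inputs yield
## identical maps.

permAll <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in permAll(n - 1L))
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

#' Order the markers of one linkage group
#'
#' Seeds with the five markers having the most non-missing genotypes (ties
#' broken by marker order), orders the seed exhaustively under the SARF
#' criterion, then inserts the remaining markers one by one in descending
#' order of their best pairwise LOD. A marker whose two best insertion points
#' are genuinely ambiguous (criterion tie not explained by a zero-rf
#' neighbour) is set aside as unplaceable. Adjacent recombination fractions
#' are converted to centimorgans with the Kosambi map function and
#' accumulated from 0.
#'
#' After insertion, the order is curated: a marker that disagrees with both
#' of its flanking markers in more offspring than genuine double crossovers
#' can explain (Poisson rate N * (rf(a,b)/2)^2 across the flanking span,
#' upper predictive bound, with a
#' floor of \code{pruneTol} offspring) carries genotyping errors and is
#' removed as unplaceable, mirroring the rf-graph inspection step usual in
#' testcross mapping.
#'
#' @param codes code matrix of the group's markers (markers x offspring).
#' @param tp optional precomputed \code{\link{twoPointMatrix}} for
#'   \code{codes}.
#' @param pruneTol minimum number of double-disagreeing offspring treated as
#'   evidence of genotyping error; \code{Inf} disables curation.
#' @param binSizes optional member-variant count per marker (in row order of
#'   \code{codes}); when supplied, small terminal bins within 2.5
#'   recombinant-equivalents of a much larger terminal bin are also removed
#'   as error artifacts.
#' @return list with \code{order} (marker names), \code{cM} (cumulative
#'   positions), \code{flipped} (phase relative to the first marker),
#'   \code{codes} (phased code matrix in map order) and \code{unplaced}.
#' @export
orderGroup <- function(codes, tp = NULL, pruneTol = 1, binSizes = NULL) {
  ids <- rownames(codes)
  m <- nrow(codes)
  if (m == 1)
    return(list(order = ids, cM = 0, flipped = FALSE, codes = codes,
                unplaced = character()))
  if (is.null(tp)) tp <- twoPointMatrix(codes)
  rf <- tp$rf
  rf[is.na(rf)] <- 0.5
  rf <- pmin(rf, 0.499)

  sarf <- function(ord) sum(rf[cbind(ord[-length(ord)], ord[-1])])

  nSeed <- min(5L, m)
  info <- rowSums(!is.na(codes))
  seed <- order(-info, seq_len(m))[seq_len(nSeed)]
  best <- NULL; bestC <- Inf
  for (p in permAll(nSeed)) {
    if (nSeed > 1 && p[1] > p[nSeed]) next   # skip mirror orders
    cc <- sarf(seed[p])
    if (cc < bestC - 1e-12) { bestC <- cc; best <- seed[p] }
  }
  ord <- best

  rest <- setdiff(seq_len(m), seed)
  if (length(rest)) {
    bestLod <- apply(tp$lod[rest, , drop = FALSE], 1, function(x)
      max(x[is.finite(x)], -Inf))
    rest <- rest[order(-bestLod, rest)]
  }
  unplaced <- integer()
  for (x in rest) {
    k <- length(ord)
    ## criterion change for inserting x before slot j (j = 1..k+1)
    crit <- numeric(k + 1)
    crit[1] <- rf[x, ord[1]]
    crit[k + 1] <- rf[ord[k], x]
    if (k > 1) {
      a <- ord[-k]; b <- ord[-1]
      crit[2:k] <- rf[cbind(a, rep(x, k - 1))] + rf[cbind(rep(x, k - 1), b)] -
        rf[cbind(a, b)]
    }
    cmin <- min(crit)
    ties <- which(crit - cmin < 1e-6)
    if (length(ties) == 1) {
      slot <- ties
    } else {
      ## ties caused by a zero-rf neighbour are equivalent placements;
      ## anything else is genuinely ambiguous
      consecutive <- all(diff(ties) == 1)
      zeroNbr <- consecutive &&
        all(rf[cbind(rep(x, length(ties) - 1), ord[ties[-length(ties)]])] < 1e-9)
      if (zeroNbr) {
        slot <- ties[1]
      } else {
        unplaced <- c(unplaced, x)
        next
      }
    }
    ord <- append(ord, x, after = slot - 1L)
  }

  ## curation: the local expansion a marker adds beyond rf additivity,
  ## rf(a,x) + rf(x,b) - rf(a,b), equals 2k/N where k counts offspring in
  ## which x disagrees with both flanking markers. Genuine double crossovers
  ## produce k ~ Poisson(N * (rf(a,b)/2)^2); a marker whose k exceeds
  ## both an upper predictive bound of that rate and the pruneTol floor carries
  ## genotyping errors and is removed as not confidently placeable.
  n <- ncol(codes)
  if (is.finite(pruneTol)) {
    repeat {
      k <- length(ord)
      if (k < 3) break
      a <- ord[1:(k - 2)]; x <- ord[2:(k - 1)]; b <- ord[3:k]
      contrib <- rf[cbind(a, x)] + rf[cbind(x, b)] - rf[cbind(a, b)]
      kDbl <- n * contrib / 2
      ## the double-crossover rate is estimated from the spanning distance
      ## rf(a,b), which an error at x cannot inflate; the cut is an upper
      ## predictive bound on k under that rate
      lambda <- n * (rf[cbind(a, b)] / 2)^2
      cut <- pmax(pruneTol, ceiling(lambda + 3.5 * sqrt(lambda)))
      excess <- kDbl - cut
      w <- which.max(excess)
      if (!length(w) || excess[w] < 0) break
      unplaced <- c(unplaced, ord[w + 1])
      ord <- ord[-(w + 1)]
    }
  }

  ## terminal curation: a small bin sitting a couple of recombinant-
  ## equivalents beyond a much larger terminal bin is the signature of a
  ## genotyping-error copy of that bin, not of real terminal map length
  if (!is.null(binSizes)) {
    repeat {
      k <- length(ord)
      if (k < 3) break
      dropHead <- binSizes[ord[1]] <= 2 && binSizes[ord[2]] >= 5 &&
        rf[ord[1], ord[2]] > 0 && rf[ord[1], ord[2]] <= 2.5 / n
      dropTail <- binSizes[ord[k]] <= 2 && binSizes[ord[k - 1]] >= 5 &&
        rf[ord[k], ord[k - 1]] > 0 && rf[ord[k], ord[k - 1]] <= 2.5 / n
      if (!dropHead && !dropTail) break
      if (dropHead) { unplaced <- c(unplaced, ord[1]); ord <- ord[-1] }
      if (dropTail) { k <- length(ord); unplaced <- c(unplaced, ord[k]); ord <- ord[-k] }
    }
  }

  adjRf <- if (length(ord) > 1) rf[cbind(ord[-length(ord)], ord[-1])] else numeric()
  cM <- c(0, cumsum(kosambi(adjRf)))

  flipped <- logical(length(ord))
  for (i in seq_along(ord)[-1])
    flipped[i] <- xor(flipped[i - 1], tp$flipped[ord[i - 1], ord[i]])
  phased <- codes[ord, , drop = FALSE]
  if (any(flipped)) {
    fl <- phased[flipped, , drop = FALSE]
    sw <- fl
    sw[fl == "A"] <- "B"
    sw[fl == "B"] <- "A"
    phased[flipped, ] <- sw
  }
  list(order = ids[ord], cM = cM, flipped = flipped, codes = phased,
       unplaced = ids[unplaced])
}

#' Build a sex-specific genetic map from binned markers
#'
#' Groups markers (\code{\link{groupMarkers}}), orders each group
#' (\code{\link{orderGroup}}), and numbers linkage groups by decreasing
#' genetic length.
#'
#' @param ms a \linkS4class{MarkerSet}.
#' @param maxRf maximum recombination fraction for grouping.
#' @param minLod minimum LOD for grouping; defaults to
#'   \code{\link{suggestLod}} of the marker count.
#' @param dropRedundant remove phase-complementary co-located markers from
#'   the ordered groups (see \code{\link{removeRedundant}}).
#' @param pruneTol curation floor passed to \code{\link{orderGroup}}.
#' @return a \linkS4class{GeneticMap}.
#' @export
buildMap <- function(ms, maxRf = 0.4, minLod = NULL, dropRedundant = TRUE,
                     pruneTol = 1) {
  codes <- markerCodes(ms)
  if (is.null(minLod)) minLod <- suggestLod(nrow(codes))
  tp <- twoPointMatrix(codes)
  grp <- groupMarkers(codes, maxRf = maxRf, minLod = minLod, tp = tp)

  orderings <- lapply(grp$groups, function(idsG) {
    idx <- match(idsG, rownames(codes))
    sub <- lapply(tp[c("rf", "lod", "n", "flipped")],
                  function(mm) mm[idx, idx, drop = FALSE])
    orderGroup(codes[idx, , drop = FALSE], tp = sub, pruneTol = pruneTol,
               binSizes = vapply(ms@members[idsG], nrow, integer(1)))
  })
  lens <- vapply(orderings, function(o) max(o$cM), numeric(1))
  orderings <- orderings[order(-lens)]

  tab <- do.call(rbind, lapply(seq_along(orderings), function(gi) {
    o <- orderings[[gi]]
    data.frame(group = gi, marker = o$order, cM = o$cM, flipped = o$flipped)
  }))
  phased <- do.call(rbind, lapply(orderings, `[[`, "codes"))
  rownames(phased) <- tab$marker
  unplaced <- unlist(lapply(orderings, `[[`, "unplaced"))
  map <- new("GeneticMap", table = tab, codes = phased,
             members = ms@members[tab$marker], parent = ms@parent,
             unplaced = as.character(unplaced),
             singletons = as.character(grp$singletons))
  if (dropRedundant) map <- removeRedundant(map)
  map
}

#' Remove redundant phase-complementary markers
#'
#' Markers placed within \code{tolCM} of each other that share a contig and
#' whose code vectors are exact phase complements of one another carry the
#' same information (the same variants called against opposite alleles); the
#' smaller bin of each such pair is dropped and positions recomputed.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param tolCM co-location tolerance in cM.
#' @return the pruned \linkS4class{GeneticMap}.
#' @export
removeRedundant <- function(map, tolCM = 1e-4) {
  tab <- map@table
  drop <- character()
  for (g in unique(tab$group)) {
    tg <- tab[tab$group == g, , drop = FALSE]
    if (nrow(tg) < 2) next
    for (i in seq_len(nrow(tg) - 1)) {
      for (j in (i + 1):nrow(tg)) {
        if (tg$cM[j] - tg$cM[i] > tolCM) break
        mi <- tg$marker[i]; mj <- tg$marker[j]
        if (mi %in% drop || mj %in% drop) next
        ## phase complements have identical phased codes but opposite flip
        sameCodes <- identical(unname(map@codes[mi, ]), unname(map@codes[mj, ]))
        oppPhase <- tg$flipped[i] != tg$flipped[j]
        shareContig <- length(intersect(map@members[[mi]]$contig,
                                        map@members[[mj]]$contig)) > 0
        if (sameCodes && oppPhase && shareContig) {
          sizes <- c(nrow(map@members[[mi]]), nrow(map@members[[mj]]))
          drop <- c(drop, if (sizes[2] > sizes[1]) mi else mj)
        }
      }
    }
  }
  if (!length(drop)) return(map)
  keep <- !tab$marker %in% drop
  tab <- tab[keep, , drop = FALSE]
  codes <- map@codes[tab$marker, , drop = FALSE]
  ## recompute cumulative positions within each group
  for (g in unique(tab$group)) {
    idx <- which(tab$group == g)
    if (length(idx) > 1) {
      adj <- vapply(seq_len(length(idx) - 1), function(k)
        twoPoint(codes[idx[k], ], codes[idx[k + 1], ])$rf, numeric(1))
      tab$cM[idx] <- c(0, cumsum(kosambi(pmin(adj, 0.499))))
    } else {
      tab$cM[idx] <- 0
    }
  }
  new("GeneticMap", table = tab, codes = codes,
      members = map@members[tab$marker], parent = map@parent,
      unplaced = map@unplaced, singletons = map@singletons)
}

#' Unbin a map to variant level
#'
#' Every member variant inherits its marker's genetic position.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @return data.frame with one row per variant: \code{group}, \code{marker},
#'   \code{cM}, \code{id}, \code{contig}, \code{pos}, sorted by group then
#'   position.
#' @export
unbinMap <- function(map) {
  tab <- map@table
  out <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    mem <- map@members[[tab$marker[i]]]
    data.frame(group = tab$group[i], marker = tab$marker[i], cM = tab$cM[i],
               id = mem$id, contig = mem$contig, pos = mem$pos)
  }))
  out[order(out$group, out$cM, out$contig, out$pos), ]
}

#' Average inter-marker gap
#'
#' @param totalCM total map length in cM.
#' @param nMarkers total marker count.
#' @param nGroups number of linkage groups.
#' @return total cM / (markers - groups); 0 when every marker starts a group.
#' @examples
#' averageGap(1545.5, 590, 15)  # 2.69
#' averageGap(827.7, 305, 15)   # 2.85
#' @export
averageGap <- function(totalCM, nMarkers, nGroups) {
  if (nMarkers <= nGroups) return(0)
  totalCM / (nMarkers - nGroups)
}

#' Map summary statistics
#'
#' @param map a \linkS4class{GeneticMap}.
#' @return list with \code{nMarkers}, \code{nGroups}, \code{totalCM},
#'   \code{avgGap} and the per-group lengths \code{groupCM}.
#' @export
mapStats <- function(map) {
  tab <- map@table
  groupCM <- vapply(split(tab$cM, tab$group), max, numeric(1))
  list(nMarkers = nrow(tab), nGroups = length(groupCM),
       totalCM = sum(groupCM),
       avgGap = averageGap(sum(groupCM), nrow(tab), length(groupCM)),
       groupCM = groupCM)
}

#' Detect contigs split between linkage groups
#'
#' A contig whose variants occupy two or more linkage groups, with at least
#' \code{minSupport} variants in each, is flagged as a candidate misassembly.
#'
#' @param ... one or more variant-level maps from \code{\link{unbinMap}}
#'   (named arguments name the maps in the output).
#' @param minSupport minimum supporting variants per group.
#' @return data.frame with \code{map}, \code{contig} and the supporting
#'   \code{groups} (comma-separated); zero rows when nothing is flagged.
#' @export
detectSplitContigs <- function(..., minSupport = 2) {
  maps <- list(...)
  if (is.null(names(maps)) || any(names(maps) == ""))
    names(maps) <- paste0("map", seq_along(maps))
  out <- list()
  for (nm in names(maps)) {
    ub <- maps[[nm]]
    counts <- table(ub$contig, ub$group)
    supported <- counts >= minSupport
    hits <- rownames(counts)[rowSums(supported) >= 2]
    for (ctg in hits)
      out[[length(out) + 1L]] <- data.frame(
        map = nm, contig = ctg,
        groups = paste(colnames(counts)[supported[ctg, ]], collapse = ","))
  }
  if (!length(out))
    return(data.frame(map = character(), contig = character(),
                      groups = character()))
  do.call(rbind, out)
}

#' Pair markers across maps and compare recombination rates
#'
#' Each maternal variant is greedily paired with the nearest unpaired
#' paternal variant on the same contig within \code{window} bp. Linkage
#' groups are then rebuilt from the paired markers only, and per-group
#' maternal and paternal lengths plus matched gap lists are reported —
#' the basis of the heterochiasmy comparison.
#'
#' @param maternalMap,paternalMap \linkS4class{GeneticMap} objects.
#' @param window maximum physical distance for a pair, in bp.
#' @return list with \code{pairs} (variant-level pairs), \code{groups}
#'   (per-group rebuilt lengths), \code{ratio} (summed maternal / paternal
#'   rebuilt length), and matched \code{gapsMaternal} / \code{gapsPaternal}.
#' @export
pairMaps <- function(maternalMap, paternalMap, window = 5000) {
  ubM <- unbinMap(maternalMap)
  ubP <- unbinMap(paternalMap)
  pairs <- list()
  for (ctg in intersect(ubM$contig, ubP$contig)) {
    vm <- ubM[ubM$contig == ctg, , drop = FALSE]
    vp <- ubP[ubP$contig == ctg, , drop = FALSE]
    used <- logical(nrow(vp))
    for (i in seq_len(nrow(vm))) {
      d <- abs(vp$pos - vm$pos[i])
      d[used] <- Inf
      j <- which.min(d)
      if (length(j) && is.finite(d[j]) && d[j] <= window) {
        used[j] <- TRUE
        pairs[[length(pairs) + 1L]] <- data.frame(
          contig = ctg, posM = vm$pos[i], posP = vp$pos[j],
          markerM = vm$marker[i], markerP = vp$marker[j],
          groupM = vm$group[i], groupP = vp$group[j],
          cMM = vm$cM[i], cMP = vp$cM[j])
      }
    }
  }
  if (!length(pairs))
    return(list(pairs = NULL, groups = NULL, ratio = NA_real_,
                gapsMaternal = numeric(), gapsPaternal = numeric()))
  pairs <- do.call(rbind, pairs)

  ## one row per maternal marker: its modal paternal partner marker
  mk <- pairs[!duplicated(pairs[c("markerM", "markerP")]), ]
  codesM <- markerCodes(maternalMap)
  codesP <- markerCodes(paternalMap)
  groupRows <- list(); gapsM <- numeric(); gapsP <- numeric()
  for (g in sort(unique(mk$groupM))) {
    sub <- mk[mk$groupM == g, , drop = FALSE]
    gp <- as.integer(names(which.max(table(sub$groupP))))
    sub <- sub[sub$groupP == gp, , drop = FALSE]
    sub <- sub[!duplicated(sub$markerM), , drop = FALSE]
    sub <- sub[order(sub$cMM), , drop = FALSE]
    ## collapse runs of identical paternal partners
    keep <- c(TRUE, sub$markerP[-1] != sub$markerP[-nrow(sub)])
    sub <- sub[keep, , drop = FALSE]
    if (nrow(sub) < 2) next
    adjM <- adjP <- numeric(nrow(sub) - 1)
    for (k in seq_len(nrow(sub) - 1)) {
      adjM[k] <- twoPoint(codesM[sub$markerM[k], ], codesM[sub$markerM[k + 1], ])$rf
      adjP[k] <- twoPoint(codesP[sub$markerP[k], ], codesP[sub$markerP[k + 1], ])$rf
    }
    adjM[is.na(adjM)] <- 0.499
    adjP[is.na(adjP)] <- 0.499
    gm <- kosambi(pmin(adjM, 0.499))
    gpv <- kosambi(pmin(adjP, 0.499))
    gapsM <- c(gapsM, gm); gapsP <- c(gapsP, gpv)
    groupRows[[length(groupRows) + 1L]] <- data.frame(
      groupM = g, groupP = gp, nPairs = nrow(sub),
      maternalCM = sum(gm), paternalCM = sum(gpv))
  }
  groups <- if (length(groupRows)) do.call(rbind, groupRows) else NULL
  ratio <- if (!is.null(groups)) sum(groups$maternalCM) / sum(groups$paternalCM)
           else NA_real_
  list(pairs = pairs, groups = groups, ratio = ratio,
       gapsMaternal = gapsM, gapsPaternal = gapsP)
}
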