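## Two-point linkage analysis on testcross markers.

## A/B code matrix -> +1/-1 with 0 for missing
codesToSign <- function(codes) {
  s <- matrix(0, nrow(codes), ncol(codes), dimnames = dimnames(codes))
  s[!is.na(codes) & codes == "A"] <- 1
  s[!is.na(codes) & codes == "B"] <- -1
  s
}

twoPointLod <- function(Rp, N, rf) {
  lod <- ifelse(N > 0 & Rp == 0, N * log10(2),
                Rp * log10(rf) + (N - Rp) * log10(1 - rf) + N * log10(2))
  lod[N == 0] <- NA_real_
  lod
}

#' Two-point test between two markers
#'
#' Over pairwise-complete offspring, counts matches and mismatches of the A/B
#' codes. The linkage phase is chosen so the recombination fraction is at
#' most 0.5: rf = min(R, N - R) / N with R the number of mismatches. The LOD
#' score is the log10 likelihood ratio of linkage at the estimated rf against
#' free recombination (rf = 0.5).
#'
#' @param c1,c2 character vectors of offspring codes ("A"/"B"/NA).
#' @return list with \code{rf}, \code{lod}, \code{phase} ("aligned" or
#'   "flipped"), \code{n} (complete pairs) and \code{valid} (FALSE when fewer
#'   than 2 complete pairs exist).
#' @examples
#' x <- rep(c("A", "B"), each = 45)
#' twoPoint(x, x)  # rf = 0, LOD = 90 * log10(2)
#' @export
twoPoint <- function(c1, c2) {
  ok <- !is.na(c1) & !is.na(c2)
  N <- sum(ok)
  if (N < 2)
    return(list(rf = NA_real_, lod = NA_real_, phase = NA_character_,
                n = N, valid = FALSE))
  R <- sum(c1[ok] != c2[ok])
  flipped <- R > N - R
  Rp <- min(R, N - R)
  rf <- Rp / N
  list(rf = rf, lod = twoPointLod(Rp, N, rf),
       phase = if (flipped) "flipped" else "aligned", n = N, valid = TRUE)
}

#' All-pairs two-point matrices
#'
#' Vectorised two-point analysis over every marker pair of a code matrix.
#'
#' @param codes character matrix (markers x offspring) of "A"/"B"/NA codes.
#' @return list of square matrices \code{rf}, \code{lod}, \code{n} and
#'   logical \code{flipped}.
#' @export
twoPointMatrix <- function(codes) {
  A <- codesToSign(codes)
  S <- tcrossprod(A)               # matches - mismatches
  N <- tcrossprod(abs(A))          # complete pairs
  R <- (N - S) / 2                 # mismatches in the as-coded phase
  flipped <- R > N - R
  Rp <- pmin(R, N - R)
  rf <- ifelse(N > 0, Rp / N, NA_real_)
  lod <- twoPointLod(Rp, N, rf)
  lod[N < 2] <- NA_real_
  rf[N < 2] <- NA_real_
  list(rf = rf, lod = lod, n = N, flipped = flipped)
}

#' Bonferroni-based minimum LOD threshold for linkage grouping
#'
#' The LOD threshold corresponding to a family-wise alpha of 0.05 over all
#' C(n, 2) two-point tests: the chi-square (df = 1) quantile at
#' 1 - 0.05 / C(n, 2), divided by 2 ln 10.
#'
#' @param nMarkers number of markers to be grouped.
#' @param alpha family-wise error rate.
#' @return LOD threshold.
#' @examples
#' suggestLod(977)  # 6.14
#' suggestLod(487)  # 5.56
#' @export
suggestLod <- function(nMarkers, alpha = 0.05) {
  if (nMarkers < 2) stop("need at least 2 markers")
  nTests <- choose(nMarkers, 2)
  stats::qchisq(1 - alpha / nTests, df = 1) / (2 * log(10))
}

#' Form linkage groups
#'
#' Markers are nodes of a graph with an edge wherever rf <= \code{maxRf} and
#' LOD >= \code{minLod}; linkage groups are the connected components.
#'
#' @param codes marker code matrix, or a \linkS4class{MarkerSet}.
#' @param maxRf maximum recombination fraction for an edge.
#' @param minLod minimum LOD for an edge; defaults to
#'   \code{\link{suggestLod}} of the marker count.
#' @param tp optional precomputed \code{\link{twoPointMatrix}} result.
#' @return list with \code{groups} (list of marker-name vectors, largest
#'   first) and \code{singletons}.
#' @export
groupMarkers <- function(codes, maxRf = 0.4, minLod = NULL, tp = NULL) {
  if (is(codes, "MarkerSet")) codes <- markerCodes(codes)
  if (is.null(minLod)) minLod <- suggestLod(nrow(codes))
  if (is.null(tp)) tp <- twoPointMatrix(codes)
  adj <- !is.na(tp$rf) & tp$rf <= maxRf & !is.na(tp$lod) & tp$lod >= minLod
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)
  ids <- rownames(codes)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(codes)))
  byComp <- split(ids, comp$membership)
  sizes <- lengths(byComp)
  groups <- byComp[sizes > 1]
  groups <- groups[order(-lengths(groups))]
  list(groups = unname(groups), singletons = unname(unlist(byComp[sizes == 1])))
}
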