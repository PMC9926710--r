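## Binary-trait QTL scan on a testcross map.
##
## Genotype probabilities come from a two-state hidden chain along each
## ordered linkage group (forward-backward smoothing, transition = Kosambi
## inverse of the cM gap). The scan regresses the binary phenotype on the
## genotype probability at each marker — the binary analogue of Haley-Knott
## regression — with an iteration-capped, probability-clamped IRLS so that
## perfectly separating markers produce the finite saturated-model LOD.

#' Genotype probabilities along a linkage group
#'
#' Two-state forward-backward smoothing per offspring: the transition
#' probability between adjacent markers is the Kosambi inverse of their cM
#' gap; emissions are 1 - \code{errorProb} for the observed class and
#' uniform at missing markers.
#'
#' @param cM marker positions (non-decreasing) of one ordered group.
#' @param codes phased code matrix of the group (markers x offspring).
#' @param errorProb genotyping error probability.
#' @return array markers x offspring x 2 with posterior probabilities of
#'   classes A and B (slices named "A", "B"); each pair sums to 1.
#' @export
calcGenoProb <- function(cM, codes, errorProb = 1e-4) {
  m <- length(cM)
  if (is.unsorted(cM)) stop("group must be ordered (non-decreasing cM)")
  stopifnot(nrow(codes) == m)
  n <- ncol(codes)
  r <- if (m > 1) kosambiInverse(diff(cM)) else numeric()

  emitA <- matrix(1, m, n)  # emission weight for hidden state A
  emitB <- matrix(1, m, n)
  obsA <- !is.na(codes) & codes == "A"
  obsB <- !is.na(codes) & codes == "B"
  emitA[obsA] <- 1 - errorProb; emitB[obsA] <- errorProb
  emitA[obsB] <- errorProb;     emitB[obsB] <- 1 - errorProb

  fA <- matrix(0, m, n); fB <- matrix(0, m, n)
  fA[1, ] <- 0.5 * emitA[1, ]; fB[1, ] <- 0.5 * emitB[1, ]
  sc <- fA[1, ] + fB[1, ]
  fA[1, ] <- fA[1, ] / sc; fB[1, ] <- fB[1, ] / sc
  for (i in seq_len(m - 1)) {
    pA <- fA[i, ] * (1 - r[i]) + fB[i, ] * r[i]
    pB <- fA[i, ] * r[i] + fB[i, ] * (1 - r[i])
    fA[i + 1, ] <- pA * emitA[i + 1, ]
    fB[i + 1, ] <- pB * emitB[i + 1, ]
    sc <- fA[i + 1, ] + fB[i + 1, ]
    fA[i + 1, ] <- fA[i + 1, ] / sc; fB[i + 1, ] <- fB[i + 1, ] / sc
  }
  bA <- matrix(1, m, n); bB <- matrix(1, m, n)
  if (m > 1) {
    for (i in (m - 1):1) {
      nA <- bA[i + 1, ] * emitA[i + 1, ]
      nB <- bB[i + 1, ] * emitB[i + 1, ]
      bA[i, ] <- nA * (1 - r[i]) + nB * r[i]
      bB[i, ] <- nA * r[i] + nB * (1 - r[i])
      sc <- bA[i, ] + bB[i, ]
      bA[i, ] <- bA[i, ] / sc; bB[i, ] <- bB[i, ] / sc
    }
  }
  pA <- fA * bA; pB <- fB * bB
  tot <- pA + pB
  out <- array(c(pA / tot, pB / tot), dim = c(m, n, 2),
               dimnames = list(rownames(codes), colnames(codes), c("A", "B")))
  out
}

## log-likelihood of the intercept-only Bernoulli model
nullLogLik <- function(y) {
  n1 <- sum(y); n0 <- length(y) - n1
  ll <- 0
  if (n1 > 0) ll <- ll + n1 * log(n1 / length(y))
  if (n0 > 0) ll <- ll + n0 * log(n0 / length(y))
  ll
}

## vectorised per-marker logistic IRLS: y (n), X (n x m) of genotype
## probabilities; returns full-model log-likelihood per marker
logisticLogLik <- function(y, X, maxit = 50, clamp = 1e-10) {
  n <- length(y); m <- ncol(X)
  a <- rep(stats::qlogis(mean(y)), m)
  b <- rep(0, m)
  for (it in seq_len(maxit)) {
    eta <- sweep(X * rep(b, each = n), 2, a, `+`)
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, clamp), 1 - clamp)
    w <- pmax(mu * (1 - mu), clamp)
    z <- eta + (y - mu) / w
    sw <- colSums(w); swx <- colSums(w * X); swxx <- colSums(w * X * X)
    swz <- colSums(w * z); swxz <- colSums(w * X * z)
    det <- sw * swxx - swx^2
    det[abs(det) < 1e-12] <- NA
    bNew <- (sw * swxz - swx * swz) / det
    aNew <- (swz - swx * bNew) / sw
    bNew[is.na(bNew)] <- b[is.na(bNew)]
    aNew[is.na(aNew)] <- a[is.na(aNew)]
    delta <- max(abs(bNew - b), abs(aNew - a))
    a <- aNew; b <- bNew
    if (delta < 1e-10) break
  }
  eta <- sweep(X * rep(b, each = n), 2, a, `+`)
  mu <- pmin(pmax(stats::plogis(eta), clamp), 1 - clamp)
  colSums(y * log(mu) + (1 - y) * log(1 - mu))
}

#' Single-locus binary-trait scan
#'
#' Per marker, compares an intercept-only logistic model of the binary
#' phenotype against intercept + genotype probability; LOD is the log10
#' likelihood ratio.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param phenotype named binary vector (e.g. \code{"male"}/\code{"female"}
#'   or 0/1) over the offspring; names must match offspring ids.
#' @param errorProb genotyping error probability for
#'   \code{\link{calcGenoProb}}.
#' @return data.frame with \code{group}, \code{marker}, \code{cM},
#'   \code{lod}; the \code{genoProb} attribute carries the class-B
#'   probability matrix used (offspring x markers).
#' @export
scanBinary <- function(map, phenotype, errorProb = 1e-4) {
  tab <- map@table
  codes <- map@codes
  y <- binarisePhenotype(phenotype, colnames(codes))
  if (length(unique(y)) < 2) stop("phenotype must have two classes")
  X <- matrix(NA_real_, ncol(codes), nrow(tab),
              dimnames = list(colnames(codes), tab$marker))
  for (g in unique(tab$group)) {
    idx <- which(tab$group == g)
    gp <- calcGenoProb(tab$cM[idx], codes[idx, , drop = FALSE], errorProb)
    X[, idx] <- t(gp[, , "B"])
  }
  llNull <- nullLogLik(y)
  llFull <- logisticLogLik(y, X)
  out <- data.frame(group = tab$group, marker = tab$marker, cM = tab$cM,
                    lod = pmax(0, (llFull - llNull) / log(10)))
  attr(out, "genoProb") <- X
  out
}

binarisePhenotype <- function(phenotype, ids) {
  if (!is.null(names(phenotype)) && !is.null(ids)) {
    miss <- setdiff(ids, names(phenotype))
    if (length(miss)) stop("phenotype missing for: ", paste(miss, collapse = ", "))
    phenotype <- phenotype[ids]
  } else if (!is.null(ids) && length(phenotype) != length(ids)) {
    stop("phenotype length must match offspring count")
  }
  if (is.character(phenotype) || is.factor(phenotype)) {
    lev <- sort(unique(as.character(phenotype)))
    if (length(lev) > 2) stop("phenotype must be binary")
    as.integer(as.character(phenotype) == lev[length(lev)])
  } else {
    as.integer(phenotype)
  }
}

#' Permutation threshold for the binary scan
#'
#' Permutes the phenotype \code{nPerm} times, records the genome-wide
#' maximum LOD of each permuted scan, and returns the (1 - alpha) type-7
#' quantiles.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param phenotype binary phenotype as in \code{\link{scanBinary}}.
#' @param nPerm number of permutations.
#' @param alphas significance levels.
#' @param seed RNG seed for the permutations (restored on exit).
#' @param errorProb genotyping error probability.
#' @return named vector of LOD thresholds; the \code{maxLod} attribute
#'   carries the permutation distribution.
#' @export
permutationThreshold <- function(map, phenotype, nPerm = 1000, alphas = 0.05,
                                 seed = 2023, errorProb = 1e-4) {
  if (nPerm < 20 && any(alphas <= 0.05))
    stop("need at least 20 permutations for alpha <= 0.05")
  base <- scanBinary(map, phenotype, errorProb = errorProb)
  X <- attr(base, "genoProb")
  y <- binarisePhenotype(phenotype, rownames(X))
  if (!exists(".Random.seed", envir = .GlobalEnv)) stats::runif(1)
  oldSeed <- get(".Random.seed", envir = .GlobalEnv)
  on.exit(assign(".Random.seed", oldSeed, envir = .GlobalEnv))
  set.seed(seed)
  maxLod <- vapply(seq_len(nPerm), function(i) {
    yp <- sample(y)
    max(pmax(0, (logisticLogLik(yp, X) - nullLogLik(yp)) / log(10)))
  }, numeric(1))
  th <- stats::quantile(maxLod, probs = 1 - alphas, type = 7)
  names(th) <- paste0("alpha", alphas)
  attr(th, "maxLod") <- maxLod
  th
}

#' Genotype-phenotype concordance at a marker
#'
#' Cross-tabulates the marker's A/B codes against the binary phenotype and
#' flags a perfect correlation (zero off-diagonal under one class-to-
#' phenotype assignment).
#'
#' @param codes character vector of offspring codes at one marker.
#' @param phenotype binary phenotype over the same offspring.
#' @return list with \code{table}, \code{discordant} (minimum off-diagonal
#'   count over the two assignments) and \code{perfect}.
#' @export
concordanceTable <- function(codes, phenotype) {
  ok <- !is.na(codes)
  tab <- table(code = codes[ok], phenotype = phenotype[ok])
  if (!all(dim(tab) == c(2, 2))) {
    disc <- 0L
  } else {
    disc <- min(tab[1, 2] + tab[2, 1], tab[1, 1] + tab[2, 2])
  }
  list(table = tab, discordant = disc, perfect = disc == 0)
}
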