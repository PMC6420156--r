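## Vietoris-Rips persistent homology, built from scratch. A k-simplex enters
## the filtration at the largest pairwise distance among its k+1 vertices
## ("pairwise within eps" convention, edges present at eps = distance).
## Dimension-0 intervals come from union-find over edges sorted by length
## (single-linkage merge heights); dimension-1 intervals from the standard
## persistence pairing by column reduction of the boundary matrix over the
## two-element field, on the complex truncated at dimension 2. Intervals use
## the half-open convention [birth, death): b_k(eps) counts intervals with
## birth <= eps < death. An independent per-eps oracle (bettiOracle) computes
## the same Betti numbers from GF(2) ranks of dense boundary matrices and
## shares no code with the persistence path beyond the distance matrix.

.pairwiseEdges <- function(points, maxEps) {
  n <- nrow(points)
  if (n < 2L) return(list(i = integer(), j = integer(), len = numeric()))
  dm <- as.matrix(stats::dist(points))
  idx <- which(upper.tri(dm) & dm <= maxEps, arr.ind = TRUE)
  len <- dm[idx]
  o <- order(len)
  list(i = idx[o, 1], j = idx[o, 2], len = len[o], dm = dm)
}

## single-linkage merge heights via union-find with path halving
.mergeHeights <- function(points, maxEps = Inf) {
  n <- nrow(points)
  e <- .pairwiseEdges(points, maxEps)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  heights <- numeric(0)
  for (k in seq_along(e$len)) {
    ri <- find(e$i[k]); rj <- find(e$j[k])
    if (ri != rj) {
      parent[ri] <- rj
      heights <- c(heights, e$len[k])
      if (length(heights) == n - 1L) break
    }
  }
  heights
}

.symdiff <- function(a, b) {
  x <- c(a, b)
  x <- sort(x)
  x[!(x %in% x[duplicated(x)])]
}

## full reduction up to triangles; returns intervals for dims 0 and 1
.persistencePairs <- function(points, maxEps) {
  n <- nrow(points)
  e <- .pairwiseEdges(points, maxEps)
  nE <- length(e$len)
  edgeIndex <- matrix(0L, n, n)
  for (k in seq_len(nE)) {
    edgeIndex[e$i[k], e$j[k]] <- k
    edgeIndex[e$j[k], e$i[k]] <- k
  }
  ## triangles: all triples whose three edges are in the truncated complex
  ti <- integer(0); tj <- integer(0); tk <- integer(0); tdiam <- numeric(0)
  if (n >= 3L && nE >= 3L) {
    cmb <- utils::combn(n, 3L)
    d12 <- e$dm[cbind(cmb[1, ], cmb[2, ])]
    d13 <- e$dm[cbind(cmb[1, ], cmb[3, ])]
    d23 <- e$dm[cbind(cmb[2, ], cmb[3, ])]
    diam <- pmax(d12, d13, d23)
    keep <- diam <= maxEps
    ti <- cmb[1, keep]; tj <- cmb[2, keep]; tk <- cmb[3, keep]
    tdiam <- diam[keep]
  }
  nT <- length(tdiam)

  m <- n + nE + nT
  sdim <- c(rep(0L, n), rep(1L, nE), rep(2L, nT))
  sdiam <- c(rep(0, n), e$len, tdiam)
  ord <- order(sdiam, sdim)          # stable: faces precede cofaces
  pos <- integer(m); pos[ord] <- seq_len(m)

  boundary <- vector("list", m)
  for (k in seq_len(nE))
    boundary[[pos[n + k]]] <- sort(c(pos[e$i[k]], pos[e$j[k]]))
  for (k in seq_len(nT)) {
    e1 <- edgeIndex[ti[k], tj[k]]
    e2 <- edgeIndex[ti[k], tk[k]]
    e3 <- edgeIndex[tj[k], tk[k]]
    boundary[[pos[n + nE + k]]] <- sort(pos[n + c(e1, e2, e3)])
  }

  diamAt <- sdiam[ord]; dimAt <- sdim[ord]
  lowOwner <- integer(m)
  reduced <- vector("list", m)
  pairedAsBirth <- logical(m)
  births <- integer(0); deaths <- integer(0)
  for (j in seq_len(m)) {
    col <- boundary[[j]]
    while (length(col)) {
      low <- col[length(col)]
      own <- lowOwner[low]
      if (own == 0L) break
      col <- .symdiff(col, reduced[[own]])
    }
    if (length(col)) {
      low <- col[length(col)]
      lowOwner[low] <- j
      reduced[[j]] <- col
      births <- c(births, low); deaths <- c(deaths, j)
      pairedAsBirth[low] <- TRUE
    }
  }
  ## a simplex is positive (creates a class) iff its column reduced to empty
  positive <- vapply(seq_len(m), function(j) is.null(reduced[[j]]), TRUE)
  essential <- which(positive & !pairedAsBirth)

  out <- data.frame(dim = c(dimAt[births], dimAt[essential]),
                    birth = c(diamAt[births], diamAt[essential]),
                    death = c(diamAt[deaths], rep(Inf, length(essential))))
  out[out$dim <= 1L & out$birth < out$death, , drop = FALSE]
}

#' Vietoris-Rips persistence intervals
#'
#' Computes the persistence intervals of the Vietoris-Rips filtration on a
#' Euclidean point cloud, for homology dimensions 0 (and 1 if requested),
#' over the two-element field. The complex is truncated at scale `maxEps`;
#' classes alive beyond it are reported with `death = Inf`, so Betti counts
#' are exact for all scales up to `maxEps`.
#'
#' @param points Numeric M x d matrix (any d; distances are Euclidean).
#' @param maxDim Maximum homology dimension, 0 or 1.
#' @param maxEps Truncation scale (default `Inf`).
#' @return Data frame with columns `dim`, `birth`, `death` (half-open
#'   intervals `[birth, death)`).
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' vrPersistence(sq, maxDim = 1)  # one loop born at 1, dead at sqrt(2)
#' @export
vrPersistence <- function(points, maxDim = 1L, maxEps = Inf) {
  points <- as.matrix(points)
  if (!maxDim %in% c(0L, 1L)) stop("maxDim must be 0 or 1")
  n <- nrow(points)
  if (n == 0L)
    return(data.frame(dim = integer(), birth = numeric(), death = numeric()))
  if (maxDim == 0L) {
    h <- .mergeHeights(points, maxEps)
    deaths <- c(h, rep(Inf, n - length(h)))
    out <- data.frame(dim = 0L, birth = 0, death = deaths)
    return(out[out$birth < out$death, , drop = FALSE])
  }
  .persistencePairs(points, maxEps)
}

#' Betti curves from persistence intervals
#'
#' Evaluates \eqn{b_k(\epsilon)} over a grid by counting persistence
#' intervals with `birth <= eps < death`.
#'
#' @inheritParams vrPersistence
#' @param epsGrid Ascending proximity values.
#' @return Integer matrix with `maxDim + 1` rows (dimensions `0..maxDim`)
#'   and `length(epsGrid)` columns. An empty point cloud gives all zeros.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' ripsBettiCurve(sq, c(0.5, 1, 1.5), maxDim = 1)
#' @export
ripsBettiCurve <- function(points, epsGrid, maxDim = 1L) {
  if (is.unsorted(epsGrid)) stop("epsGrid must be ascending")
  iv <- vrPersistence(points, maxDim = maxDim, maxEps = max(epsGrid))
  out <- matrix(0L, maxDim + 1L, length(epsGrid))
  rownames(out) <- paste0("b", 0:maxDim)
  for (k in 0:maxDim) {
    sub <- iv[iv$dim == k, , drop = FALSE]
    if (nrow(sub))
      out[k + 1L, ] <- vapply(epsGrid, function(eps)
        sum(sub$birth <= eps & eps < sub$death), 0L)
  }
  out
}

#' Rank of a matrix over the two-element field
#'
#' Gaussian elimination with XOR row operations on a 0/1 matrix. Used by the
#' homology oracle; exported for testing.
#'
#' @param M Logical or 0/1 numeric matrix.
#' @return Integer rank.
#' @export
gf2Rank <- function(M) {
  if (length(M) == 0L || nrow(M) == 0L || ncol(M) == 0L) return(0L)
  M <- matrix(as.logical(M), nrow = nrow(M))
  nr <- nrow(M); nc <- ncol(M)
  rank <- 0L; r <- 1L
  for (j in seq_len(nc)) {
    piv <- which(M[r:nr, j])[1]
    if (is.na(piv)) next
    piv <- piv + r - 1L
    if (piv != r) {
      tmp <- M[r, ]; M[r, ] <- M[piv, ]; M[piv, ] <- tmp
    }
    hit <- which(M[, j]); hit <- hit[hit != r]
    if (length(hit))
      M[hit, ] <- xor(M[hit, , drop = FALSE],
                      matrix(M[r, ], length(hit), nc, byrow = TRUE))
    rank <- rank + 1L; r <- r + 1L
    if (r > nr) break
  }
  rank
}

#' Brute-force Betti numbers of a Rips complex at one scale
#'
#' Independent oracle for testing the persistence path: enumerates every
#' vertex, edge and triangle of the Vietoris-Rips complex at scale `eps` and
#' computes \eqn{b_k = n_k - \mathrm{rank}\,\partial_k -
#' \mathrm{rank}\,\partial_{k+1}} over the two-element field
#' (\eqn{\mathrm{rank}\,\partial_0 = 0}). Deliberately naive; refuses clouds
#' larger than 25 points to guard against the combinatorial blow-up.
#'
#' @param points Numeric M x d matrix, M <= 25.
#' @param eps Proximity scale (edges present when distance <= eps).
#' @param k Homology dimension, 0 or 1.
#' @return Integer Betti number.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' bettiOracle(sq, 1, k = 1)  # the square cycle
#' @export
bettiOracle <- function(points, eps, k) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n > 25L) stop("bettiOracle is restricted to clouds of <= 25 points")
  if (!k %in% c(0L, 1L)) stop("k must be 0 or 1")
  if (n == 0L) return(0L)
  if (n == 1L) return(if (k == 0L) 1L else 0L)
  dm <- as.matrix(stats::dist(points))
  pairs <- which(upper.tri(dm) & dm <= eps, arr.ind = TRUE)
  nE <- nrow(pairs)
  d1 <- matrix(FALSE, n, nE)
  if (nE) {
    d1[cbind(pairs[, 1], seq_len(nE))] <- TRUE
    d1[cbind(pairs[, 2], seq_len(nE))] <- TRUE
  }
  r1 <- gf2Rank(d1)
  if (k == 0L) return(n - r1)
  ## triangles: triples pairwise within eps
  edgeId <- matrix(0L, n, n)
  if (nE) {
    edgeId[pairs] <- seq_len(nE)
    edgeId[pairs[, c(2, 1), drop = FALSE]] <- seq_len(nE)
  }
  nT <- 0L; d2 <- matrix(FALSE, nE, 0L)
  if (n >= 3L && nE >= 3L) {
    cmb <- utils::combn(n, 3L)
    ok <- dm[cbind(cmb[1, ], cmb[2, ])] <= eps &
      dm[cbind(cmb[1, ], cmb[3, ])] <= eps &
      dm[cbind(cmb[2, ], cmb[3, ])] <= eps
    tri <- cmb[, ok, drop = FALSE]
    nT <- ncol(tri)
    if (nT) {
      d2 <- matrix(FALSE, nE, nT)
      for (t in seq_len(nT)) {
        d2[edgeId[tri[1, t], tri[2, t]], t] <- TRUE
        d2[edgeId[tri[1, t], tri[3, t]], t] <- TRUE
        d2[edgeId[tri[2, t], tri[3, t]], t] <- TRUE
      }
    }
  }
  (nE - r1) - gf2Rank(d2)
}
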