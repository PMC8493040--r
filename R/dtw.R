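# Dynamic time warping over sets of term vectors, and cosine similarity of
# protein vectors.

as_vector_set <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  storage.mode(v) <- "double"
  v
}

local_dist_matrix <- function(vm, vn, metric) {
  if (metric == "euclidean") {
    d2 <- outer(rowSums(vm^2), rowSums(vn^2), "+") - 2 * tcrossprod(vm, vn)
    d2[d2 < 0] <- 0
    sqrt(d2)
  } else {  # cosine distance 1 - cos
    num <- tcrossprod(vm, vn)
    den <- outer(sqrt(rowSums(vm^2)), sqrt(rowSums(vn^2)))
    if (any(den == 0)) stop("cosine local metric undefined for zero vectors")
    1 - num / den
  }
}

dtw_fill <- function(dl) {
  m <- nrow(dl)
  n <- ncol(dl)
  D <- matrix(0, m, n)
  D[1, 1] <- dl[1, 1]
  if (m > 1) for (i in 2:m) D[i, 1] <- D[i - 1, 1] + dl[i, 1]
  if (n > 1) for (j in 2:n) D[1, j] <- D[1, j - 1] + dl[1, j]
  if (m > 1 && n > 1) {
    for (i in 2:m) {
      for (j in 2:n) {
        D[i, j] <- min(D[i - 1, j] + dl[i, j],
                       D[i, j - 1] + dl[i, j],
                       D[i - 1, j - 1] + 2 * dl[i, j])
      }
    }
  }
  D
}

#' Dynamic time warping distance between two vector sets
#'
#' Fills the cumulative-cost grid with the recurrence in which a vertical or
#' horizontal step adds the local distance once and a diagonal step adds it
#' twice; the first row and column are cumulative sums from cell (1,1). The
#' smaller the value, the more similar the two proteins.
#'
#' @param vm,vn vector sets: numeric matrices (rows = vectors) sharing the
#'   same number of columns; plain vectors are treated as one-column sets.
#' @param metric local point distance: `"euclidean"` or `"cosine"`
#'   (1 - cosine).
#' @return The cumulative cost `D(m, n)`, a non-negative scalar.
#' @export
dtw_distance <- function(vm, vn, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  vm <- as_vector_set(vm)
  vn <- as_vector_set(vn)
  if (nrow(vm) == 0L || nrow(vn) == 0L) stop("empty vector set")
  if (ncol(vm) != ncol(vn)) stop("vector sets differ in dimension")
  D <- dtw_fill(local_dist_matrix(vm, vn, metric))
  D[nrow(D), ncol(D)]
}

#' Full DTW alignment: grids and warping path
#'
#' @inheritParams dtw_distance
#' @return List with the cumulative grid `D`, the pointwise grid `local`,
#'   the total `distance`, and `path`: an integer matrix of grid cells from
#'   (1,1) to (m,n) stepping by (+1,0), (0,+1) or (+1,+1).
#' @export
dtw_alignment <- function(vm, vn, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  vm <- as_vector_set(vm)
  vn <- as_vector_set(vn)
  if (nrow(vm) == 0L || nrow(vn) == 0L) stop("empty vector set")
  if (ncol(vm) != ncol(vn)) stop("vector sets differ in dimension")
  dl <- local_dist_matrix(vm, vn, metric)
  D <- dtw_fill(dl)
  # backtrack
  i <- nrow(D)
  j <- ncol(D)
  path <- list(c(i, j))
  while (i > 1 || j > 1) {
    if (i == 1) {
      j <- j - 1
    } else if (j == 1) {
      i <- i - 1
    } else {
      cand <- c(D[i - 1, j - 1] + 2 * dl[i, j],
                D[i - 1, j] + dl[i, j],
                D[i, j - 1] + dl[i, j])
      k <- which.min(cand)
      if (k == 1) { i <- i - 1; j <- j - 1 }
      else if (k == 2) i <- i - 1
      else j <- j - 1
    }
    path <- c(path, list(c(i, j)))
  }
  path <- do.call(rbind, rev(path))
  colnames(path) <- c("i", "j")
  list(D = D, local = dl, distance = D[nrow(D), ncol(D)], path = path)
}

#' Map a DTW distance to a (0, 1] similarity
#'
#' `s = 1 / (1 + D(m, n) / (m + n))`: strictly decreasing in the
#' length-normalized distance, 1 exactly when the DTW distance is 0. The
#' `m + n` normalization counteracts the bias of longer annotation lists so
#' one threshold applies across proteins.
#'
#' @inheritParams dtw_distance
#' @return Similarity in `(0, 1]`.
#' @export
normalized_dtw_similarity <- function(vm, vn,
                                      metric = c("euclidean", "cosine")) {
  vm <- as_vector_set(vm)
  vn <- as_vector_set(vn)
  d <- dtw_distance(vm, vn, metric)
  1 / (1 + d / (nrow(vm) + nrow(vn)))
}

#' Cosine similarity of two vectors
#'
#' @param wm,wn numeric vectors of equal length.
#' @return Cosine of the angle in `[-1, 1]`, or `NA_real_` for a zero
#'   vector (undefined).
#' @export
cosine_similarity <- function(wm, wn) {
  stopifnot(length(wm) == length(wn))
  nm <- sqrt(sum(wm^2))
  nn <- sqrt(sum(wn^2))
  if (nm == 0 || nn == 0) return(NA_real_)
  sum(wm * wn) / (nm * nn)
}
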