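#' Pairwise voxel similarity
#'
#' Similarity between two retained voxels i and j, each represented
#' by its (vm, vn) group-summary pair:
#' \deqn{\rho = (vm_i - vm_j)^2 + (vn_i - vn_j)^2}
#' i.e. the squared Euclidean distance between the two points in the
#' (disease, control) plane -- no square root is taken. Small rho
#' means near-duplicate voxels; large rho means strongly contrasting
#' voxels.
#'
#' @param p_i,p_j numeric length-2 vectors (vm, vn).
#' @return nonnegative similarity value.
#' @export
pair_similarity <- function(p_i, p_j) {
  if (!all(is.finite(c(p_i, p_j)))) stop("inputs must be finite")
  (p_i[1] - p_j[1])^2 + (p_i[2] - p_j[2])^2
}

## cross-block similarity matrix between two sets of (vm, vn) rows
cross_similarity <- function(A, B) {
  outer(A[, 1], B[, 1], `-`)^2 + outer(A[, 2], B[, 2], `-`)^2
}

block_ranges <- function(n, g) {
  sizes <- rep(n %/% g, g)
  rem <- n %% g
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  Map(function(s, e) s:e, starts, ends)
}

#' Block-partitioned similarity matrices
#'
#' Splits the retained voxel set into \code{g} contiguous,
#' near-equal-sized blocks and computes the similarity matrix for
#' every unordered block pair, including each block against itself:
#' g(g+1)/2 matrices in total (55 for g = 10). Concatenating the
#' blocks reproduces the full dense similarity matrix.
#'
#' @param pairs a \code{voxel_pair_vector}.
#' @param g number of blocks (1 <= g <= number of retained voxels).
#' @return a \code{similarity_block_set}: list with \code{g},
#'   \code{block_ranges} (1-based row ranges into \code{pairs}) and
#'   \code{matrices}, a list of \code{list(block_a, block_b, rho)}.
#' @export
block_similarity <- function(pairs, g) {
  n <- nrow(pairs)
  if (g < 1L) stop("'g' must be at least 1")
  if (g > n) stop("'g' (", g, ") exceeds the number of retained voxels (",
                  n, ")")
  P <- cbind(pairs$vm, pairs$vn)
  ranges <- block_ranges(n, g)
  mats <- list()
  for (a in seq_len(g)) for (b in a:g) {
    mats[[length(mats) + 1L]] <- list(
      block_a = a, block_b = b,
      rho = cross_similarity(P[ranges[[a]], , drop = FALSE],
                             P[ranges[[b]], , drop = FALSE]))
  }
  structure(list(g = g, block_ranges = ranges, matrices = mats,
                 n_voxels = n),
            class = "similarity_block_set")
}

#' Survey-size bounds from similarity extrema
#'
#' Scans every off-diagonal similarity entry for the global minimum
#' and maximum rho, then counts the distinct voxel rows participating
#' in at least one entry tied (within \code{extremum_tol}, relative to
#' the global maximum rho) with each extremum. The count at the
#' minimum is C_min (near-duplicate voxels cluster there, so it is
#' typically the larger count) and the count at the maximum is C_max;
#' the random-survey size l is then drawn from [C_max, C_min]. If the
#' computed counts come out inverted they are swapped with a warning
#' so the interval stays valid.
#'
#' Self-similarities (the within-block diagonal, always 0) are
#' excluded from the scan.
#'
#' @param blocks a \code{similarity_block_set}.
#' @param extremum_tol relative tie tolerance (default 1e-9).
#' @return a \code{feature_bounds}: list with \code{c_max},
#'   \code{c_min}, \code{extremum_tol}, \code{g}, \code{n_voxels},
#'   \code{rho_min}, \code{rho_max}, \code{swapped}.
#' @export
feature_count_bounds <- function(blocks, extremum_tol = 1e-9) {
  if (blocks$n_voxels < 2L)
    stop("need at least 2 voxels to compute bounds")
  rho_min <- Inf; rho_max <- -Inf
  for (m in blocks$matrices) {
    r <- m$rho
    if (m$block_a == m$block_b) diag(r) <- NA
    rho_min <- min(rho_min, r, na.rm = TRUE)
    rho_max <- max(rho_max, r, na.rm = TRUE)
  }
  tol_abs <- extremum_tol * max(abs(rho_max), .Machine$double.xmin)
  rows_at <- function(target) {
    hit <- logical(blocks$n_voxels)
    for (m in blocks$matrices) {
      r <- m$rho
      if (m$block_a == m$block_b) diag(r) <- NA
      w <- which(abs(r - target) <= tol_abs, arr.ind = TRUE)
      if (nrow(w) > 0) {
        hit[blocks$block_ranges[[m$block_a]][w[, 1]]] <- TRUE
        hit[blocks$block_ranges[[m$block_b]][w[, 2]]] <- TRUE
      }
    }
    sum(hit)
  }
  c_min <- rows_at(rho_min)   # ties at the global minimum
  c_max <- rows_at(rho_max)   # ties at the global maximum
  swapped <- FALSE
  if (c_max > c_min) {
    warning("computed C_max (", c_max, ") > C_min (", c_min,
            "); swapping to keep the survey interval valid")
    tmp <- c_max; c_max <- c_min; c_min <- tmp
    swapped <- TRUE
  }
  structure(list(c_max = c_max, c_min = c_min,
                 extremum_tol = extremum_tol, g = blocks$g,
                 n_voxels = blocks$n_voxels,
                 rho_min = rho_min, rho_max = rho_max,
                 swapped = swapped),
            class = "feature_bounds")
}

#' @export
print.feature_bounds <- function(x, ...) {
  cat(sprintf("feature_bounds: survey size l in [C_max = %d, C_min = %d] (g = %d, %d voxels)\n",
              x$c_max, x$c_min, x$g, x$n_voxels))
  invisible(x)
}
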