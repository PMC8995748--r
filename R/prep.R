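#' Weighted per-voxel group summary matrices
#'
#' Collapses each group of maps to a single per-voxel weighted mean
#' vector: M for the disease group and N for the control group. With
#' the default uniform weights this is the voxel-wise group mean.
#'
#' @param cohort a \code{gmd_cohort}.
#' @param weights optional nonnegative per-subject weights, aligned
#'   with \code{cohort$maps}; \code{NULL} means uniform.
#' @return list with elements \code{M} (disease) and \code{N}
#'   (control), each a \code{group_voxel_vector} holding the flattened
#'   summary \code{values}, the group label, dims and flatten order.
#' @export
compute_group_matrices <- function(cohort, weights = NULL) {
  y <- cohort_labels(cohort)
  dims <- cohort_dims(cohort)
  if (is.null(weights)) weights <- rep(1, length(y))
  if (length(weights) != length(y))
    stop("'weights' must have one entry per subject")
  if (any(weights < 0)) stop("'weights' must be nonnegative")
  one <- function(grp) {
    idx <- which(y == grp)
    if (length(idx) == 0L)
      stop("cohort has no subjects with group ", grp)
    w <- weights[idx]
    if (sum(w) <= 0) stop("weights for group ", grp, " sum to zero")
    acc <- 0
    for (i in seq_along(idx))
      acc <- acc + w[i] * as.vector(cohort$maps[[idx[i]]]$data)
    structure(list(values = acc / sum(w), group = grp, dims = dims,
                   flatten_order = FLATTEN_ORDER),
              class = "group_voxel_vector")
  }
  list(M = one(-1L), N = one(+1L))
}

#' Build the voxel-pair vector with equal-voxel deletion
#'
#' Pairs the two group summaries voxel by voxel into (vm, vn) and
#' deletes voxels whose group values are equal (within \code{tol}):
#' such voxels carry no between-group information. The retained
#' entries keep their original linear index and (x, y, z) coordinate.
#'
#' @param M,N \code{group_voxel_vector}s for disease and control.
#' @param tol absolute tolerance for "equal" (exact float equality is
#'   fragile); a voxel is kept iff |vm - vn| > tol.
#' @return a \code{voxel_pair_vector}: data.frame with columns
#'   \code{linear_index} (0-based), \code{x}, \code{y}, \code{z}
#'   (1-based), \code{vm}, \code{vn}; attributes \code{k} (total
#'   voxels), \code{retained}, \code{deleted}, \code{tol},
#'   \code{source_dims}, \code{flatten_order}.
#' @export
build_voxel_pairs <- function(M, N, tol = 1e-12) {
  if (!identical(as.integer(M$dims), as.integer(N$dims)))
    stop("M and N have mismatched dims")
  if (tol < 0) stop("'tol' must be nonnegative")
  k <- length(M$values)
  keep <- which(abs(M$values - N$values) > tol)
  idx0 <- keep - 1L
  co <- linear_to_coord(idx0, M$dims)
  pairs <- data.frame(linear_index = idx0,
                      x = co[, "x"], y = co[, "y"], z = co[, "z"],
                      vm = M$values[keep], vn = N$values[keep])
  structure(pairs, k = k, retained = length(keep),
            deleted = k - length(keep), tol = tol,
            source_dims = as.integer(M$dims),
            flatten_order = FLATTEN_ORDER,
            class = c("voxel_pair_vector", "data.frame"))
}

#' Assemble the subjects-by-retained-voxels feature matrix
#'
#' Gathers every subject's raw density at each retained voxel, giving
#' the initial learning matrix X with labels y (-1 disease, +1
#' control).
#'
#' @param cohort a \code{gmd_cohort}.
#' @param pairs a \code{voxel_pair_vector} built from this cohort's
#'   dims.
#' @return a \code{feature_matrix}: list with \code{X} (subjects x
#'   retained voxels), \code{y}, \code{column_index} (0-based linear
#'   voxel index per column) and \code{subject_id}.
#' @export
assemble_feature_matrix <- function(cohort, pairs) {
  dims <- cohort_dims(cohort)
  if (!identical(as.integer(attr(pairs, "source_dims")),
                 as.integer(dims)))
    stop("pairs were built for different dims than this cohort")
  nv <- prod(dims)
  if (nrow(pairs) > 0 &&
      (min(pairs$linear_index) < 0 || max(pairs$linear_index) >= nv))
    stop("voxel index out of range for cohort dims")
  cols <- pairs$linear_index + 1L
  X <- matrix(unlist(lapply(cohort$maps,
                            function(m) as.vector(m$data)[cols])),
              nrow = length(cohort$maps), ncol = length(cols),
              byrow = TRUE)
  structure(list(X = X, y = cohort_labels(cohort),
                 column_index = pairs$linear_index,
                 subject_id = vapply(cohort$maps, `[[`,
                                     character(1), "subject_id"),
                 dims = dims, flatten_order = FLATTEN_ORDER),
            class = "feature_matrix")
}
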