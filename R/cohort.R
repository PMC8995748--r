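#' @useDynLib rssvm, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd predict
#' @importFrom utils read.csv write.csv
"_PACKAGE"

FLATTEN_ORDER <- "column-major-0-based"

## linear index (0-based, first axis fastest) <-> 1-based (x,y,z)
linear_to_coord <- function(idx, dims) {
  x <- idx %% dims[1]
  y <- (idx %/% dims[1]) %% dims[2]
  z <- idx %/% (dims[1] * dims[2])
  cbind(x = x + 1L, y = y + 1L, z = z + 1L)
}

coord_to_linear <- function(coord, dims) {
  (coord[, 1] - 1L) + (coord[, 2] - 1L) * dims[1] +
    (coord[, 3] - 1L) * dims[1] * dims[2]
}

## separable Gaussian smoothing with replicate padding, sd in voxels
smooth_gaussian_3d <- function(arr, sd) {
  if (sd <= 0) return(arr)
  h <- max(1L, ceiling(3 * sd))
  k <- stats::dnorm(seq(-h, h), sd = sd)
  k <- k / sum(k)
  smooth1 <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], h), v, rep(v[n], h))
    out <- stats::filter(vp, k, sides = 2)
    as.numeric(out[(h + 1):(h + n)])
  }
  d <- dim(arr)
  for (ax in 1:3) {
    arr <- apply(arr, setdiff(1:3, ax), smooth1)
    ## apply() returns the collapsed axis first; rotate back
    arr <- aperm(array(arr, dim = c(d[ax], d[setdiff(1:3, ax)])),
                 order(c(ax, setdiff(1:3, ax))))
  }
  arr
}

## grow a 6-connected contiguous blob by random nearest-neighbour accretion
grow_blob <- function(dims, n_voxels) {
  nv <- prod(dims)
  mask <- array(FALSE, dim = dims)
  start <- arrayInd(sample.int(nv, 1L), dims)
  mask[start] <- TRUE
  coords <- matrix(start, ncol = 3)
  while (sum(mask) < n_voxels) {
    ## frontier: 6-neighbours of current blob not yet included
    nb <- do.call(rbind, lapply(seq_len(nrow(coords)), function(i) {
      p <- coords[i, ]
      rbind(p + c(1, 0, 0), p - c(1, 0, 0), p + c(0, 1, 0),
            p - c(0, 1, 0), p + c(0, 0, 1), p - c(0, 0, 1))
    }))
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nb <- nb[ok, , drop = FALSE]
    nb <- nb[!mask[nb], , drop = FALSE]
    nb <- unique(nb)
    if (nrow(nb) == 0L) break
    pick <- nb[sample.int(nrow(nb), 1L), , drop = FALSE]
    mask[pick] <- TRUE
    coords <- rbind(coords, pick)
  }
  mask
}

#' Generate a synthetic two-group gray-matter-density cohort
#'
#' Emulates a voxel-based-morphometry study of a disease group versus
#' healthy controls: every subject shares one smooth baseline density
#' field; the disease group receives a mean density shift (a loss, by
#' default) at a planted set of "informative" voxels; i.i.d. Gaussian
#' noise is added per subject and voxel; values are clipped to the
#' density range [0, 1]. The planted voxels are returned as a
#' ground-truth mask so feature-selection recovery can be scored.
#'
#' @param n_disease,n_control subjects per group.
#' @param dims integer 3-vector of map dimensions.
#' @param n_informative number of planted informative voxels.
#' @param effect_size magnitude of the group mean density shift at
#'   informative voxels. The disease group is shifted by
#'   \code{-effect_size} (gray-matter loss).
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param baseline_smoothness sd (in voxels) of the separable Gaussian
#'   filter applied to the uniform-random baseline field; the smoothed
#'   field is rescaled to [0.3, 0.7] so a 0.3 shift rarely clips.
#' @param layout \code{"blob"} (contiguous region grown by random
#'   nearest-neighbour accretion, the default: atrophy is spatially
#'   contiguous) or \code{"scattered"} (uniform random voxels).
#' @param seed integer seed; identical parameters and seed reproduce
#'   the cohort bit for bit.
#' @return A \code{gmd_cohort}: list of per-subject maps (each with
#'   \code{subject_id}, \code{group} in \{-1 disease, +1 control\},
#'   and a 3D \code{data} array), the logical \code{truth_mask}, and
#'   \code{gen_params}.
#' @export
generate_cohort <- function(n_disease, n_control, dims,
                            n_informative, effect_size = 0.3,
                            noise_sd = 0.05, baseline_smoothness = 2,
                            layout = c("blob", "scattered"),
                            seed = 1L) {
  layout <- match.arg(layout)
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L))
    stop("'dims' must be three positive integers")
  if (n_disease < 1L || n_control < 1L)
    stop("'n_disease' and 'n_control' must be at least 1")
  nv <- prod(dims)
  if (n_informative > nv)
    stop("'n_informative' (", n_informative,
         ") exceeds the voxel count (", nv, ")")
  if (n_informative < 0L) stop("'n_informative' must be nonnegative")
  if (noise_sd < 0) stop("'noise_sd' must be nonnegative")

  gen_params <- list(n_disease = n_disease, n_control = n_control,
                     dims = dims, n_informative = n_informative,
                     effect_size = effect_size, noise_sd = noise_sd,
                     baseline_smoothness = baseline_smoothness,
                     layout = layout, seed = as.integer(seed))

  withr::with_seed(as.integer(seed), {
    baseline <- array(runif(nv), dim = dims)
    baseline <- smooth_gaussian_3d(baseline, baseline_smoothness)
    rng <- range(baseline)
    if (diff(rng) > 0)
      baseline <- 0.3 + 0.4 * (baseline - rng[1]) / diff(rng)
    else baseline <- array(0.5, dim = dims)

    mask <- if (n_informative == 0L) array(FALSE, dim = dims)
            else if (layout == "blob") grow_blob(dims, n_informative)
            else {
              m <- array(FALSE, dim = dims)
              m[sample.int(nv, n_informative)] <- TRUE
              m
            }

    shift <- array(0, dim = dims)
    shift[mask] <- -effect_size   # density loss in disease

    make_map <- function(id, grp) {
      noise <- array(rnorm(nv, sd = noise_sd), dim = dims)
      dat <- baseline + if (grp == -1L) shift else 0
      dat <- pmin(pmax(dat + noise, 0), 1)
      list(subject_id = id, group = grp,
           data = array(dat, dim = dims))
    }
    maps <- c(
      lapply(seq_len(n_disease),
             function(i) make_map(sprintf("D%03d", i), -1L)),
      lapply(seq_len(n_control),
             function(i) make_map(sprintf("C%03d", i), +1L)))
    structure(list(maps = maps, truth_mask = mask,
                   gen_params = gen_params,
                   flatten_order = FLATTEN_ORDER),
              class = "gmd_cohort")
  })
}

#' @export
print.gmd_cohort <- function(x, ...) {
  g <- vapply(x$maps, `[[`, integer(1), "group")
  cat("gmd_cohort:", sum(g == -1L), "disease +", sum(g == 1L),
      "control subjects, dims",
      paste(x$gen_params$dims, collapse = " x "),
      sprintf("(%d informative voxels)\n", sum(x$truth_mask)))
  invisible(x)
}

cohort_labels <- function(cohort)
  vapply(cohort$maps, `[[`, integer(1), "group")

cohort_dims <- function(cohort) dim(cohort$maps[[1]]$data)

## full-precision text serialization: %.17g round-trips doubles exactly
format_full <- function(x) formatC(x, digits = 17, format = "g")

#' Save a cohort to a plain-text archive directory
#'
#' Writes \code{manifest.json} (generation parameters, dims, flatten
#' order, file list), \code{subjects.csv} (subject_id, group),
#' \code{maps.tsv} (one row per subject, voxels flattened
#' column-major, full double precision) and \code{truth_mask.tsv}.
#'
#' @param cohort a \code{gmd_cohort}.
#' @param path directory to create/write into.
#' @return the manifest path, invisibly.
#' @export
save_cohort <- function(cohort, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  dims <- cohort_dims(cohort)
  subj <- data.frame(
    subject_id = vapply(cohort$maps, `[[`, character(1), "subject_id"),
    group = cohort_labels(cohort))
  write.csv(subj, file.path(path, "subjects.csv"), row.names = FALSE)
  rows <- vapply(cohort$maps, function(m)
    paste(format_full(as.vector(m$data)), collapse = "\t"),
    character(1))
  writeLines(rows, file.path(path, "maps.tsv"))
  writeLines(paste(as.integer(as.vector(cohort$truth_mask)),
                   collapse = "\t"),
             file.path(path, "truth_mask.tsv"))
  manifest <- list(format = "rssvm-cohort/1", dims = dims,
                   flatten_order = cohort$flatten_order,
                   gen_params = cohort$gen_params,
                   files = list(subjects = "subjects.csv",
                                maps = "maps.tsv",
                                truth_mask = "truth_mask.tsv"))
  mp <- file.path(path, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Load a cohort saved by [save_cohort()]
#'
#' @param path archive directory.
#' @return the reconstructed \code{gmd_cohort}.
#' @export
load_cohort <- function(path) {
  mp <- file.path(path, "manifest.json")
  if (!file.exists(mp)) stop("missing manifest: ", mp)
  manifest <- jsonlite::read_json(mp, simplifyVector = TRUE)
  for (f in unlist(manifest$files))
    if (!file.exists(file.path(path, f)))
      stop("cohort archive is missing file: ", f)
  dims <- as.integer(manifest$dims)
  subj <- read.csv(file.path(path, manifest$files$subjects),
                   colClasses = c("character", "integer"))
  rows <- readLines(file.path(path, manifest$files$maps))
  if (length(rows) != nrow(subj))
    stop("maps.tsv has ", length(rows), " rows but subjects.csv lists ",
         nrow(subj), " subjects")
  maps <- lapply(seq_len(nrow(subj)), function(i) {
    v <- as.numeric(strsplit(rows[i], "\t", fixed = TRUE)[[1]])
    if (length(v) != prod(dims))
      stop("map for subject ", subj$subject_id[i],
           " has wrong length (dimension mismatch)")
    list(subject_id = subj$subject_id[i], group = subj$group[i],
         data = array(v, dim = dims))
  })
  mv <- as.integer(strsplit(
    readLines(file.path(path, manifest$files$truth_mask))[1],
    "\t", fixed = TRUE)[[1]])
  gp <- manifest$gen_params
  if (!is.null(gp$dims)) gp$dims <- as.integer(gp$dims)
  structure(list(maps = maps,
                 truth_mask = array(mv == 1L, dim = dims),
                 gen_params = gp,
                 flatten_order = manifest$flatten_order),
            class = "gmd_cohort")
}
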