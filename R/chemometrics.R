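## Hyperspectral-cube chemometrics: additive averaging, NDSI, constrained
## teaching-region sampling, spectral angle mapper, Fisher LDA, and the
## 10-90% edge-response resolution estimator.

#' Additive averaging map
#'
#' Per pixel, `I_ave = S / n` where `S` sums the intensities over the
#' selected bands and `n` is the number of bands.  The mask marks pixels
#' whose `I_ave` lies strictly inside the thresholds.
#'
#' @param cube a [hyperspec_cube()]
#' @param bands integer band indices, or `NULL` to use `wavenumber_range`
#' @param wavenumber_range `c(lo, hi)` in cm^-1 selecting bands by axis
#' @param intensity_thresholds `c(lo, hi)` mask bounds on `I_ave`
#' @return list: `map` (matrix of `I_ave`), `mask`, `bands`
#' @export
additive_averaging <- function(cube, bands = NULL, wavenumber_range = NULL,
                               intensity_thresholds = c(-Inf, Inf)) {
  if (is.null(bands)) {
    if (is.null(wavenumber_range))
      stop("select bands by index or wavenumber_range")
    wn <- cube$wavenumber_cm1
    bands <- which(wn >= min(wavenumber_range) &
                   wn <= max(wavenumber_range))
  }
  if (length(bands) == 0) stop("empty band selection")
  d <- dim(cube$data)
  sub <- cube$data[, , bands, drop = FALSE]
  map <- apply(sub, c(1, 2), mean)
  mask <- map >= intensity_thresholds[1] & map <= intensity_thresholds[2]
  list(map = map, mask = mask, bands = bands)
}

#' Normalized difference spectral index map
#'
#' `NDSI = (I_1 - I_2) / (I_1 + I_2)` per pixel for two selected bands.
#' Pixels with `I_1 + I_2 = 0` are set to 0 and flagged.
#'
#' @param cube a [hyperspec_cube()]
#' @param band_1,band_2 integer band indices
#' @param ndsi_thresholds `c(lo, hi)` mask bounds on the index
#' @return list: `map`, `mask`, `flagged` (zero-denominator pixels)
#' @export
ndsi_map <- function(cube, band_1, band_2,
                     ndsi_thresholds = c(-Inf, Inf)) {
  if (band_1 == band_2)
    warning("identical band indices: NDSI is identically zero")
  d <- dim(cube$data)
  I1 <- matrix(cube$data[, , band_1], d[1], d[2])
  I2 <- matrix(cube$data[, , band_2], d[1], d[2])
  den <- I1 + I2
  flagged <- den == 0
  map <- ifelse(flagged, 0, (I1 - I2) / ifelse(flagged, 1, den))
  mask <- map >= ndsi_thresholds[1] & map <= ndsi_thresholds[2]
  list(map = map, mask = mask, flagged = flagged)
}

#' Region-sampling constraint
#'
#' Strict-inequality bounds on teaching-region side lengths and area, as
#' used when regions are drawn at random from a hyperspectral image:
#' `x_min < width < x_max`, `y_min < height < y_max`,
#' `area_min < width*height < area_max`.
#'
#' @param x_min,x_max exclusive bounds on region width (pixels)
#' @param y_min,y_max exclusive bounds on region height (pixels)
#' @param area_min,area_max exclusive bounds on region area (pixels)
#' @param n_regions number of regions to draw
#' @return an object of class `region_constraint`
#' @export
region_constraint <- function(x_min = 4, x_max = 35, y_min = 3, y_max = 55,
                              area_min = 20, area_max = 720,
                              n_regions = 125) {
  stopifnot(x_min >= 0, x_max > x_min + 1, y_min >= 0, y_max > y_min + 1,
            area_min >= 0, area_max > area_min, n_regions >= 1)
  structure(list(x_min = x_min, x_max = x_max, y_min = y_min,
                 y_max = y_max, area_min = area_min, area_max = area_max,
                 n_regions = as.integer(n_regions)),
            class = "region_constraint")
}

#' Sample non-overlapping teaching regions
#'
#' Rejection-samples axis-aligned rectangles satisfying the strict
#' inequalities of a [region_constraint()], without overlap, reproducibly
#' for a given seed.  With a label map, `n_regions` regions are drawn
#' inside every class (each rectangle entirely within one class); without
#' one, regions are drawn anywhere in the image.  If a cube is supplied,
#' each region's mean spectrum is recorded.
#'
#' @param cube a [hyperspec_cube()], or `NULL` for geometry-only sampling
#' @param constraint a [region_constraint()]
#' @param seed RNG seed
#' @param label_map optional integer matrix of class labels (0 = ignore)
#' @param legend optional named label vector naming the classes
#' @param max_tries_per_region rejection-sampling budget
#' @return a `teaching_set`: `regions` data frame (class, x0, y0, width,
#'   height), `spectra` matrix (one row per region, if a cube was given),
#'   `class_names`, the constraint and seed
#' @export
sample_teaching_regions <- function(cube = NULL, constraint, seed = 1L,
                                    label_map = NULL, legend = NULL,
                                    max_tries_per_region = 500L) {
  stopifnot(inherits(constraint, "region_constraint"))
  if (is.null(cube) && is.null(label_map))
    stop("need a cube or a label map to define the image geometry")
  dims <- if (!is.null(label_map)) dim(label_map) else dim(cube$data)[1:2]
  rows <- dims[1]; cols <- dims[2]
  classes <- if (!is.null(label_map)) {
    sort(unique(label_map[label_map > 0]))
  } else 0L
  class_names <- if (!is.null(legend) && length(legend)) {
    names(legend)[match(classes, legend)]
  } else if (identical(classes, 0L)) "all" else as.character(classes)

  ws <- (constraint$x_min + 1):(constraint$x_max - 1)
  hs <- (constraint$y_min + 1):(constraint$y_max - 1)
  ws <- ws[ws <= cols]; hs <- hs[hs <= rows]
  if (!length(ws) || !length(hs))
    stop("constraint infeasible for this image size")

  occ <- matrix(FALSE, rows, cols)
  out <- list()
  withr::with_seed(seed, {
    for (ci in seq_along(classes)) {
      got <- 0L; tries <- 0L
      budget <- max_tries_per_region * constraint$n_regions
      while (got < constraint$n_regions && tries < budget) {
        tries <- tries + 1L
        w <- sample(ws, 1); h <- sample(hs, 1)
        area <- w * h
        if (!(area > constraint$area_min && area < constraint$area_max))
          next
        if (w > cols || h > rows) next
        x0 <- sample.int(cols - w + 1, 1)
        y0 <- sample.int(rows - h + 1, 1)
        rr <- y0:(y0 + h - 1); cc2 <- x0:(x0 + w - 1)
        if (any(occ[rr, cc2])) next
        if (!is.null(label_map) &&
            !all(label_map[rr, cc2] == classes[ci])) next
        occ[rr, cc2] <- TRUE
        got <- got + 1L
        out[[length(out) + 1L]] <-
          data.frame(class = class_names[ci], x0 = x0, y0 = y0,
                     width = w, height = h)
      }
      if (got < constraint$n_regions)
        stop(sprintf(
          "could only place %d of %d regions for class '%s'",
          got, constraint$n_regions, class_names[ci]))
    }
  })
  regions <- do.call(rbind, out)
  spectra <- NULL
  if (!is.null(cube)) {
    d <- dim(cube$data)
    spectra <- t(vapply(seq_len(nrow(regions)), function(i) {
      rg <- regions[i, ]
      sub <- cube$data[rg$y0:(rg$y0 + rg$height - 1),
                       rg$x0:(rg$x0 + rg$width - 1), , drop = FALSE]
      apply(sub, 3, mean)
    }, numeric(d[3])))
  }
  structure(list(regions = regions, spectra = spectra,
                 class_names = class_names, constraint = constraint,
                 seed = seed),
            class = "teaching_set")
}

#' @export
print.teaching_set <- function(x, ...) {
  cat(sprintf("<teaching_set> %d regions, classes: %s\n",
              nrow(x$regions), paste(x$class_names, collapse = ", ")))
  invisible(x)
}

#' Per-class mean teaching spectra
#'
#' @param teaching a `teaching_set` with spectra
#' @return matrix classes x bands, rownames = class names
#' @export
class_mean_spectra <- function(teaching) {
  if (is.null(teaching$spectra)) stop("teaching set has no spectra")
  cls <- teaching$regions$class
  out <- t(vapply(teaching$class_names, function(cn) {
    colMeans(teaching$spectra[cls == cn, , drop = FALSE])
  }, numeric(ncol(teaching$spectra))))
  rownames(out) <- teaching$class_names
  out
}

.unit_rows <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  list(M = M / ifelse(nrm == 0, 1, nrm), zero = nrm == 0)
}

#' Spectral angle mapper classification
#'
#' Each pixel spectrum and each class teaching spectrum is normalized to
#' unit length; a pixel is assigned the class with the largest inner
#' product (the smallest spectral angle).  Ties go to the lowest class
#' index; zero-norm pixels get label 0.
#'
#' @param cube a [hyperspec_cube()] (or `pixels x bands` matrix)
#' @param teaching a `teaching_set` with spectra, or a matrix of class
#'   spectra (classes x bands, rownames = class names)
#' @return a `class_map`: integer matrix (or vector for matrix input) with
#'   a `legend` attribute
#' @export
sam_classify <- function(cube, teaching) {
  Tm <- if (inherits(teaching, "teaching_set")) class_mean_spectra(teaching)
        else teaching
  if (is.null(rownames(Tm)))
    rownames(Tm) <- paste0("class", seq_len(nrow(Tm)))
  X <- if (inherits(cube, "hyperspec_cube")) cube_spectra(cube) else cube
  if (ncol(X) != ncol(Tm))
    stop("teaching spectra and cube have different band counts")
  un <- .unit_rows(X)
  ut <- .unit_rows(Tm)
  ip <- un$M %*% t(ut$M)
  lab <- max.col(ip, ties.method = "first")
  lab[un$zero] <- 0L
  legend <- stats::setNames(seq_len(nrow(Tm)), rownames(Tm))
  if (inherits(cube, "hyperspec_cube")) {
    d <- dim(cube$data)
    structure(matrix(as.integer(lab), d[1], d[2]),
              legend = legend, class = "class_map")
  } else structure(as.integer(lab), legend = legend)
}

#' Fisher criterion
#'
#' `J(w) = (w' S_B w) / (w' S_W w)`, the ratio of between-class to
#' within-class projected scatter.
#'
#' @param w projection vector
#' @param S_B,S_W between- and within-class scatter matrices
#' @return numeric scalar
#' @export
fisher_criterion <- function(w, S_B, S_W) {
  drop(crossprod(w, S_B %*% w) / crossprod(w, S_W %*% w))
}

#' Train a Fisher linear discriminant model
#'
#' Builds between-class (`S_B`) and within-class (`S_W`) scatter matrices
#' from labelled teaching spectra and solves the generalized eigenproblem
#' `S_B w = J S_W w` for up to `classes - 1` projection vectors; the
#' leading vector maximizes the Fisher criterion.  A ridge term is added
#' to `S_W` when it is singular (always the case when bands outnumber
#' teaching spectra), and its size is recorded.
#'
#' @param x a `teaching_set` with spectra, or a matrix `samples x bands`
#' @param classes class label per row (required for matrix input)
#' @param ridge ridge coefficient relative to `mean(diag(S_W))`; `NULL`
#'   adds one automatically only when `S_W` is numerically singular
#' @return an `lda_model`: projection matrix `w` (bands x k), `S_B`, `S_W`,
#'   projected class `centroids`, `J` of the leading vector, class names,
#'   ridge used
#' @export
lda_train <- function(x, classes = NULL, ridge = NULL) {
  if (inherits(x, "teaching_set")) {
    classes <- x$regions$class
    x <- x$spectra
  }
  if (is.null(classes) || length(classes) != nrow(x))
    stop("need one class label per teaching spectrum")
  cls <- unique(classes)
  if (length(cls) < 2) stop("LDA needs at least two classes")
  counts <- table(factor(classes, levels = cls))
  if (any(counts < 2))
    stop("every class needs at least two teaching spectra")
  p <- ncol(x)
  mu <- colMeans(x)
  S_B <- matrix(0, p, p); S_W <- matrix(0, p, p)
  for (cn in cls) {
    xi <- x[classes == cn, , drop = FALSE]
    mi <- colMeans(xi)
    S_B <- S_B + nrow(xi) * tcrossprod(mi - mu)
    S_W <- S_W + crossprod(sweep(xi, 2, mi))
  }
  lam <- 0
  S_Wr <- S_W
  need_ridge <- is.null(ridge) && rcond(S_W) < 1e-10
  if (!is.null(ridge) || need_ridge) {
    lam <- if (!is.null(ridge)) ridge else 1e-8
    S_Wr <- S_W + lam * mean(diag(S_W)) * diag(p)
    if (need_ridge)
      message(sprintf("lda_train: singular S_W, ridge %g added", lam))
  }
  ev <- eigen(solve(S_Wr, S_B))
  k <- min(length(cls) - 1, p)
  ord <- order(Re(ev$values), decreasing = TRUE)[seq_len(k)]
  w <- Re(ev$vectors[, ord, drop = FALSE])
  w <- sweep(w, 2, sqrt(colSums(w^2)), `/`)
  centroids <- matrix(0, length(cls), k, dimnames = list(cls, NULL))
  for (i in seq_along(cls))
    centroids[i, ] <- colMeans(x[classes == cls[i], , drop = FALSE]) %*% w
  structure(list(w = w, S_B = S_B, S_W = S_W,
                 centroids = centroids,
                 J = fisher_criterion(w[, 1], S_B, S_Wr),
                 class_names = cls, ridge = lam),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d classes, %d bands, J = %.4g\n",
              length(x$class_names), nrow(x$w), x$J))
  invisible(x)
}

#' Classify a cube with a trained LDA model
#'
#' Projects every pixel spectrum with the discriminant vectors and assigns
#' the nearest projected class centroid (ties to the lowest class index).
#'
#' @param cube a [hyperspec_cube()] or `pixels x bands` matrix
#' @param model an `lda_model`
#' @param bands optional band subset matching the model's input space
#' @return a `class_map` with a `legend` attribute
#' @export
lda_classify <- function(cube, model, bands = NULL) {
  X <- if (inherits(cube, "hyperspec_cube")) cube_spectra(cube) else cube
  if (!is.null(bands)) X <- X[, bands, drop = FALSE]
  if (ncol(X) != nrow(model$w))
    stop("band count does not match the trained model")
  proj <- X %*% model$w
  d2 <- outer(rowSums(proj^2), rowSums(model$centroids^2), `+`) -
    2 * proj %*% t(model$centroids)
  lab <- max.col(-d2, ties.method = "first")
  legend <- stats::setNames(seq_along(model$class_names),
                            model$class_names)
  if (inherits(cube, "hyperspec_cube")) {
    d <- dim(cube$data)
    structure(matrix(as.integer(lab), d[1], d[2]),
              legend = legend, class = "class_map")
  } else structure(as.integer(lab), legend = legend)
}

#' 10-90% edge response of a line profile
#'
#' Linear-interpolated distance between the 10% and 90% crossings of the
#' low-to-high plateau span of a monotone edge profile.
#'
#' @param profile numeric intensity profile across one edge
#' @param pixel_pitch_um pixel pitch, um
#' @param tol tolerated non-monotonicity as a fraction of the profile span
#' @return 10-90% distance in um
#' @export
edge_response_resolution <- function(profile, pixel_pitch_um = 1,
                                     tol = 0.02) {
  stopifnot(length(profile) >= 4)
  p <- as.numeric(profile)
  if (p[length(p)] < p[1]) p <- rev(p)
  span <- max(p) - min(p)
  if (span <= 0) stop("profile has no edge")
  if (any(diff(p) < -tol * span))
    stop("profile is not monotone across the edge")
  lo <- min(p); hi <- max(p)
  x <- seq_along(p)
  cross <- function(level) {
    i <- which(p >= level)[1]
    if (i == 1) return(x[1])
    x[i - 1] + (level - p[i - 1]) / (p[i] - p[i - 1])
  }
  (cross(lo + 0.9 * span) - cross(lo + 0.1 * span)) * pixel_pitch_um
}
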