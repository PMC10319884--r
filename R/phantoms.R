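## Phantoms: per-pixel species mixtures plus a broadband transmission
## factor (for opaque structures such as mesh bars and channel walls) and
## integer ground-truth labels.

#' Construct a phantom map
#'
#' @param rows,cols pixel counts (at most 480 x 640)
#' @param pixel_pitch_um pixel pitch at the sample plane, um
#' @param species_names names of the species layers in `mixture`
#' @param mixture array `rows x cols x length(species_names)` of
#'   non-negative optical-depth scales
#' @param transmission matrix of broadband (wavelength-flat) intensity
#'   transmission factors in `[0, 1]`
#' @param labels integer ground-truth label matrix (0 = background)
#' @param legend named integer vector mapping class names to labels
#' @return an object of class `phantom_map`
#' @export
phantom_map <- function(rows, cols, pixel_pitch_um, species_names,
                        mixture, transmission, labels, legend) {
  stopifnot(rows >= 1, cols >= 1, rows <= 480, cols <= 640,
            pixel_pitch_um > 0,
            all(dim(mixture) == c(rows, cols, length(species_names))),
            all(mixture >= 0),
            all(dim(transmission) == c(rows, cols)),
            all(transmission >= 0 & transmission <= 1),
            all(dim(labels) == c(rows, cols)))
  structure(list(rows = rows, cols = cols, pixel_pitch_um = pixel_pitch_um,
                 species_names = species_names, mixture = mixture,
                 transmission = transmission,
                 labels = labels, legend = legend),
            class = "phantom_map")
}

#' @export
print.phantom_map <- function(x, ...) {
  cat(sprintf("<phantom_map> %d x %d px @ %g um, species: %s\n",
              x$rows, x$cols, x$pixel_pitch_um,
              paste(x$species_names, collapse = ", ")))
  invisible(x)
}

.empty_phantom <- function(rows, cols, pitch, species) {
  phantom_map(rows, cols, pitch, species,
              array(0, c(rows, cols, length(species))),
              matrix(1, rows, cols),
              matrix(0L, rows, cols),
              stats::setNames(integer(0), character(0)))
}

#' Generate a test phantom
#'
#' * `"microchannel5"` - five parallel vertical channels etched in a wafer,
#'   each filled with one species; walls transmit a flat fraction.
#' * `"mesh_grid"` - opaque bars of a copper mesh (transmission 0),
#'   for edge-response measurements.
#' * `"flow_sequence"` - frames at multiples of the laser period showing
#'   three water channels; in the middle one a meniscus front (a localized
#'   transmission dip) advances at a set velocity as the water flows.
#' * `"blobs"` - random multi-class discs for classifier tests.
#'
#' @param kind phantom type
#' @param ... parameters of the specific generator, see
#'   [phantom_microchannel5()], [phantom_mesh_grid()],
#'   [phantom_flow_sequence()], [phantom_blobs()]
#' @return a [phantom_map()], or a list of them for `"flow_sequence"`
#'   (with a `times_s` attribute)
#' @export
make_phantom <- function(kind = c("microchannel5", "mesh_grid",
                                  "flow_sequence", "blobs"), ...) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop("unknown phantom kind: ",
                                            kind[1]))
  switch(kind,
         microchannel5 = phantom_microchannel5(...),
         mesh_grid = phantom_mesh_grid(...),
         flow_sequence = phantom_flow_sequence(...),
         blobs = phantom_blobs(...))
}

#' @param rows,cols,pixel_pitch_um phantom geometry
#' @param channel_width_um etched channel width, um
#' @param species the five channel fillings, left to right
#' @param wall_transmission broadband transmission of the wafer walls
#' @param fill_scale optical-depth scale of the channel fillings
#' @rdname make_phantom
#' @export
phantom_microchannel5 <- function(rows = 48, cols = 64,
                                  pixel_pitch_um = 12.5,
                                  channel_width_um = 100,
                                  species = c("glycerin", "glucose",
                                              "albumin", "dopc",
                                              "soybean_oil"),
                                  wall_transmission = 0.25,
                                  fill_scale = 1) {
  stopifnot(length(species) == 5)
  ph <- .empty_phantom(rows, cols, pixel_pitch_um, species)
  ph$transmission[] <- wall_transmission
  half <- max(1, round(channel_width_um / pixel_pitch_um / 2))
  for (k in 1:5) {
    center <- round(cols * (2 * k - 1) / 10)
    cc <- max(1, center - half + 1):min(cols, center + half)
    ph$mixture[, cc, k] <- fill_scale
    ph$transmission[, cc] <- 1
    ph$labels[, cc] <- k
  }
  ph$legend <- stats::setNames(1:5, species)
  ph
}

#' @param bar_width_um mesh bar width, um (0 gives a uniform open map)
#' @param period_um mesh period, um
#' @rdname make_phantom
#' @export
phantom_mesh_grid <- function(rows = 48, cols = 64, pixel_pitch_um = 1.25,
                              bar_width_um = 30, period_um = 120) {
  stopifnot(bar_width_um >= 0, period_um > 0)
  ph <- .empty_phantom(rows, cols, pixel_pitch_um, character(0))
  ph$mixture <- array(0, c(rows, cols, 0))
  if (bar_width_um > 0) {
    xs <- (seq_len(cols) - 0.5) * pixel_pitch_um
    ys <- (seq_len(rows) - 0.5) * pixel_pitch_um
    on_bar <- function(u) (u %% period_um) < bar_width_um
    bar <- outer(on_bar(ys), on_bar(xs), `|`)
    ph$transmission[bar] <- 0
    ph$labels[!bar] <- 1L
  } else {
    ph$labels[] <- 1L
  }
  ph$legend <- c(open = 1L)
  ph
}

#' @param n_frames number of frames
#' @param frame_stride laser shots between stored frames (1 = every shot)
#' @param velocity_mm_s meniscus front velocity, mm/s
#' @param repetition_rate_hz laser repetition rate, Hz
#' @param front_width_um width of the meniscus transmission dip, um
#' @param front_transmission transmission inside the meniscus dip
#' @rdname make_phantom
#' @export
phantom_flow_sequence <- function(rows = 48, cols = 64,
                                  pixel_pitch_um = 18.75,
                                  channel_width_um = 200,
                                  n_frames = 6, frame_stride = 1,
                                  velocity_mm_s = 2.5,
                                  repetition_rate_hz = 5000,
                                  front_width_um = 40,
                                  front_transmission = 0.35) {
  times <- (seq_len(n_frames) - 1) * frame_stride / repetition_rate_hz
  half <- max(1, round(channel_width_um / pixel_pitch_um / 2))
  centers <- round(cols * c(1, 3, 5) / 6)
  y_um <- (seq_len(rows) - 0.5) * pixel_pitch_um
  start_um <- 0.25 * rows * pixel_pitch_um
  frames <- lapply(times, function(tt) {
    ph <- .empty_phantom(rows, cols, pixel_pitch_um, "water")
    for (ci in seq_along(centers)) {
      cc <- max(1, centers[ci] - half + 1):min(cols, centers[ci] + half)
      if (ci != 2) {                        # static full channels
        ph$mixture[, cc, 1] <- 1
        ph$labels[, cc] <- 1L
      } else {                              # draining channel
        front <- start_um + velocity_mm_s * 1000 * tt
        wet <- y_um > front
        ph$mixture[wet, cc, 1] <- 1
        ph$labels[wet, cc] <- 1L
        ph$labels[!wet, cc] <- 3L
        at_front <- abs(y_um - front) <= front_width_um / 2
        ph$transmission[at_front, cc] <- front_transmission
        ph$labels[at_front, cc] <- 2L
      }
    }
    ph$legend <- c(water = 1L, front = 2L, empty = 3L)
    ph
  })
  attr(frames, "times_s") <- times
  frames
}

#' @param n_classes number of species classes
#' @param n_blobs number of discs drawn
#' @param seed RNG seed (reproducible)
#' @param blob_species species used for the classes
#' @param radius_px disc radius range, pixels
#' @rdname make_phantom
#' @export
phantom_blobs <- function(rows = 48, cols = 64, pixel_pitch_um = 12.5,
                          n_classes = 3, n_blobs = 8, seed = 1,
                          blob_species = c("glycerin", "glucose", "albumin",
                                           "dopc", "soybean_oil"),
                          radius_px = c(4, 9)) {
  stopifnot(n_classes >= 1, n_classes <= length(blob_species))
  species <- blob_species[seq_len(n_classes)]
  ph <- .empty_phantom(rows, cols, pixel_pitch_um, species)
  withr::with_seed(seed, {
    for (b in seq_len(n_blobs)) {
      cls <- sample.int(n_classes, 1)
      r0 <- stats::runif(1, 1, rows); c0 <- stats::runif(1, 1, cols)
      rad <- stats::runif(1, radius_px[1], radius_px[2])
      d2 <- outer((seq_len(rows) - r0)^2, (seq_len(cols) - c0)^2, `+`)
      inside <- d2 <= rad^2
      for (k in seq_len(n_classes)) ph$mixture[, , k][inside] <- 0
      ph$mixture[, , cls][inside] <- 1
      ph$labels[inside] <- cls
    }
  })
  ph$legend <- stats::setNames(seq_len(n_classes), species)
  ph
}
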