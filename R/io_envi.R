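## ENVI raster I/O: a plain-text .hdr plus a flat binary file, the lingua
## franca of hyperspectral imagery.  Integer cubes are stored as unsigned
## 16-bit (ENVI data type 12), floating-point cubes as 64-bit (type 5).

.envi_paths <- function(path) {
  base <- sub("\\.(hdr|img)$", "", path)
  list(hdr = paste0(base, ".hdr"), img = paste0(base, ".img"))
}

#' Write a hyperspectral cube in ENVI format
#'
#' Writes `<path>.img` (flat binary, little-endian) and `<path>.hdr`.  The
#' header stores the wavelength list (nm), the derived MIR wavenumber
#' list, and the simulation seed.
#'
#' @param cube a [hyperspec_cube()]
#' @param path output path (extension ignored)
#' @param interleave `"bsq"`, `"bil"`, or `"bip"`
#' @return the header path, invisibly
#' @export
write_envi_cube <- function(cube, path, interleave = c("bsq", "bil", "bip")) {
  interleave <- match.arg(interleave)
  p <- .envi_paths(path)
  d <- dim(cube$data)
  int_data <- is.integer(cube$data) &&
    max(cube$data, na.rm = TRUE) <= 65535 && min(cube$data, na.rm = TRUE) >= 0
  dtype <- if (int_data) 12L else 5L
  perm <- switch(interleave,
                 bsq = c(2, 1, 3), bil = c(2, 3, 1), bip = c(3, 2, 1))
  v <- as.vector(aperm(cube$data, perm))
  con <- file(p$img, "wb")
  on.exit(close(con), add = TRUE)
  if (dtype == 12L) {
    writeBin(as.integer(v), con, size = 2, endian = "little")
  } else {
    writeBin(as.double(v), con, size = 8, endian = "little")
  }
  num_list <- function(x) paste0("{ ", paste(format(x, digits = 10),
                                             collapse = " , "), " }")
  hdr <- c(
    "ENVI",
    "description = { chirpmir hyperspectral cube }",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", dtype),
    paste0("interleave = ", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = ", num_list(cube$wavelength_nm)),
    if (!is.null(cube$wavenumber_cm1))
      paste0("wavenumber = ", num_list(cube$wavenumber_cm1)),
    if (!is.na(cube$seed)) paste0("seed = ", cube$seed)
  )
  writeLines(hdr, p$hdr)
  invisible(p$hdr)
}

.parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  if (!grepl("^ENVI", txt)) stop("malformed header: missing ENVI magic")
  get1 <- function(key, required = TRUE) {
    m <- regmatches(txt, regexpr(paste0("(?mi)^", key,
                                        "\\s*=\\s*([^\\{\\n]+)$"),
                                 txt, perl = TRUE))
    if (!length(m)) {
      if (required) stop("malformed header: missing '", key, "'")
      return(NULL)
    }
    trimws(sub(paste0("(?i)^", key, "\\s*=\\s*"), "", m, perl = TRUE))
  }
  getlist <- function(key) {
    m <- regmatches(txt, regexpr(paste0("(?si)", key,
                                        "\\s*=\\s*\\{(.*?)\\}"),
                                 txt, perl = TRUE))
    if (!length(m)) return(NULL)
    body <- sub(paste0("(?si)", key, "\\s*=\\s*\\{"), "", m, perl = TRUE)
    body <- sub("\\}$", "", body)
    as.numeric(strsplit(trimws(body), "[,\\s]+")[[1]])
  }
  list(samples = as.integer(get1("samples")),
       lines = as.integer(get1("lines")),
       bands = as.integer(get1("bands")),
       dtype = as.integer(get1("data type")),
       interleave = tolower(get1("interleave")),
       byte_order = as.integer(get1("byte order")),
       wavelength = getlist("wavelength"),
       wavenumber = getlist("wavenumber"),
       seed = {
         s <- get1("seed", required = FALSE)
         if (is.null(s)) NA_integer_ else as.integer(s)
       })
}

#' Read an ENVI cube
#'
#' @param path path to the `.hdr` or `.img` file (or their common stem)
#' @return a [hyperspec_cube()]
#' @export
read_envi_cube <- function(path) {
  p <- .envi_paths(path)
  if (!file.exists(p$hdr)) stop("header not found: ", p$hdr)
  if (!file.exists(p$img)) stop("binary not found: ", p$img)
  h <- .parse_envi_header(p$hdr)
  if (!h$interleave %in% c("bsq", "bil", "bip"))
    stop("unsupported interleave: ", h$interleave)
  bytes <- switch(as.character(h$dtype), "12" = 2L, "5" = 8L,
                  stop("unsupported data type: ", h$dtype))
  n <- h$samples * h$lines * h$bands
  expect_size <- n * bytes
  if (file.info(p$img)$size != expect_size)
    stop(sprintf("binary size %d does not match header (%d x %d x %d, %d bytes)",
                 file.info(p$img)$size, h$lines, h$samples, h$bands,
                 expect_size))
  con <- file(p$img, "rb")
  on.exit(close(con), add = TRUE)
  v <- if (bytes == 2L) {
    readBin(con, "integer", n = n, size = 2, signed = FALSE,
            endian = "little")
  } else {
    readBin(con, "double", n = n, size = 8, endian = "little")
  }
  dims <- switch(h$interleave,
                 bsq = c(h$samples, h$lines, h$bands),
                 bil = c(h$samples, h$bands, h$lines),
                 bip = c(h$bands, h$samples, h$lines))
  arr <- array(v, dims)
  data <- switch(h$interleave,
                 bsq = aperm(arr, c(2, 1, 3)),
                 bil = aperm(arr, c(3, 1, 2)),
                 bip = aperm(arr, c(3, 2, 1)))
  if (bytes == 2L) storage.mode(data) <- "integer"
  if (is.null(h$wavelength) || length(h$wavelength) != h$bands)
    stop("header wavelength list missing or inconsistent with band count")
  hyperspec_cube(data, h$wavelength, h$wavenumber, config = NULL,
                 seed = h$seed)
}

#' Write a class map as an indexed PNG plus a JSON legend
#'
#' Label 0 renders black; classes get distinct hues.  The legend JSON maps
#' class names to label values and hex colors.
#'
#' @param map a `class_map` (integer matrix with a `legend` attribute)
#' @param path output stem; writes `<path>.png` and `<path>.json`
#' @return invisible vector of the two paths
#' @export
write_class_map <- function(map, path) {
  base <- sub("\\.(png|json)$", "", path)
  legend <- attr(map, "legend")
  k <- length(legend)
  cols <- grDevices::hcl.colors(max(k, 2), "Dark 3")[seq_len(k)]
  pal <- c("#000000", cols)
  rgb <- grDevices::col2rgb(pal) / 255
  idx <- matrix(match(as.integer(map), c(0L, unname(legend))),
                nrow(map), ncol(map))
  img <- array(0, c(nrow(map), ncol(map), 3))
  for (ch in 1:3) img[, , ch] <- matrix(rgb[ch, idx], nrow(map))
  png::writePNG(img, paste0(base, ".png"))
  jsonlite::write_json(
    list(classes = lapply(seq_along(legend), function(i) {
      list(name = names(legend)[i], label = unname(legend[i]),
           color = cols[i])
    })),
    paste0(base, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paste0(base, ".png"), paste0(base, ".json")))
}

#' Write a two-column spectrum CSV
#'
#' @param wavenumber wavenumber axis, cm^-1
#' @param value spectrum values
#' @param path output CSV path
#' @param value_name column name for the values
#' @return the path, invisibly
#' @export
write_spectrum_csv <- function(wavenumber, value, path,
                               value_name = "value") {
  df <- data.frame(wavenumber_cm1 = wavenumber, v = value)
  names(df)[2] <- value_name
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a two-column spectrum CSV
#'
#' @param path CSV with columns `wavenumber_cm1` and a value column
#' @return data frame
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"wavenumber_cm1" %in% names(df))
    stop("spectrum CSV needs a wavenumber_cm1 column")
  df
}
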