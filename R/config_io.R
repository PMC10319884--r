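## Pipeline configuration (YAML) and run records (JSON).

.pipeline_sections <- function() list(
  optical = names(formals(optical_config)),
  phantom = NULL,                 # free-form: kind + generator parameters
  retrieval = c("xpm", "floor_frac", "n_iter", "gate_cap", "pad_frac"),
  analysis = c("method", "bands", "wavenumbers", "thresholds",
               "constraint", "teaching_seed"),
  seed = NA, output_dir = NA
)

#' Default pipeline configuration
#'
#' @return nested list with `optical`, `phantom`, `retrieval`, `analysis`,
#'   `seed`, and `output_dir` sections
#' @export
default_pipeline_config <- function() {
  list(
    optical = list(full_scale = FALSE),
    phantom = list(kind = "microchannel5"),
    retrieval = list(xpm = TRUE, floor_frac = 0.01, n_iter = 3),
    analysis = list(method = "lda",
                    wavenumbers = c(851, 920, 1030, 1142, 1360, 1427,
                                    1542, 1658, 1089, 1250, 1463, 1747),
                    teaching_seed = 1),
    seed = 1,
    output_dir = "results"
  )
}

#' Read and validate a pipeline configuration
#'
#' Unknown top-level sections or unknown keys inside a checked section are
#' rejected, so typos fail loudly instead of being ignored.
#'
#' @param path YAML file
#' @return validated configuration list
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg configuration list
#' @export
validate_pipeline_config <- function(cfg) {
  sections <- .pipeline_sections()
  unknown <- setdiff(names(cfg), names(sections))
  if (length(unknown))
    stop("unknown configuration section(s): ",
         paste(unknown, collapse = ", "))
  for (sec in names(cfg)) {
    allowed <- sections[[sec]]
    if (is.null(allowed) || all(is.na(allowed))) next
    bad <- setdiff(names(cfg[[sec]]), allowed)
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  cfg
}

#' Write a pipeline configuration to YAML
#'
#' @param cfg configuration list (validated first)
#' @param path output path
#' @return the path, invisibly
#' @export
write_pipeline_config <- function(cfg, path) {
  validate_pipeline_config(cfg)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Record a pipeline run
#'
#' Writes a JSON record of a run: timestamp, package version, seed, the
#' stage names executed, and MD5 hashes of the input and output files that
#' exist.
#'
#' @param stages character vector of stage names
#' @param seed the seed used
#' @param inputs,outputs file paths to hash
#' @param path output JSON path
#' @return the record, invisibly
#' @export
run_record <- function(stages, seed, inputs = character(),
                       outputs = character(), path) {
  hash <- function(fs) {
    fs <- fs[file.exists(fs)]
    if (!length(fs)) return(NULL)
    as.list(tools::md5sum(fs))
  }
  rec <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package = "chirpmir",
    version = as.character(utils::packageVersion("chirpmir")),
    seed = seed,
    stages = as.list(stages),
    input_md5 = hash(inputs),
    output_md5 = hash(outputs)
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(rec)
}
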