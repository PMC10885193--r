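#' Write a movie as multi-page TIFF
#'
#' Frames are written as 16-bit unsigned grayscale, frame-major. Intensities
#' are stored as `counts / scale` (the TIFF holds values in \[0, 1\]);
#' values above `scale` are clipped.
#'
#' @param stack A [movie_stack()].
#' @param path Output path.
#' @param scale Counts mapped to the 16-bit full scale (default 65535, i.e.
#'   intensities are camera counts).
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(stack, path, scale = 65535) {
  d <- dim(stack$frames)
  pages <- lapply(seq_len(d[3]), function(t)
    pmin(pmax(stack$frames[, , t] / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF movie
#'
#' @param path TIFF file.
#' @param pixel_nm,frame_rate_hz Acquisition metadata (not stored in the
#'   TIFF).
#' @param scale Counts at 16-bit full scale (default 65535; must match the
#'   value used when writing).
#' @return A [movie_stack()].
#' @export
read_movie_tiff <- function(path, pixel_nm, frame_rate_hz, scale = 65535) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop_invalid("cannot read TIFF '", path, "': ",
                                   conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, c(dim(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) {
    pg <- pages[[t]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]  # first channel
    frames[, , t] <- pg * scale
  }
  movie_stack(frames, pixel_nm, frame_rate_hz)
}

#' Write a contrast stack as 32-bit TIFF
#'
#' Signed contrast is mapped linearly from `[-range, range]` to `[0, 1]`
#' for storage (TIFF float samples outside `[0, 1]` are not portable);
#' [read_contrast_tiff()] with the same `range` inverts the mapping.
#'
#' @param cstack A `contrast_stack`.
#' @param path Output path.
#' @param range Contrast magnitude mapped to full scale (default 0.5).
#' @return `path`, invisibly.
#' @export
write_contrast_tiff <- function(cstack, path, range = 0.5) {
  d <- dim(cstack$frames)
  pages <- lapply(seq_len(d[3]), function(t) {
    m <- cstack$frames[, , t]
    m[is.na(m)] <- 0
    pmin(pmax((m + range) / (2 * range), 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a 32-bit contrast TIFF written by [write_contrast_tiff()]
#'
#' @param path TIFF file.
#' @param pixel_nm,frame_rate_hz Acquisition metadata.
#' @param range Contrast magnitude at full scale (must match the writer).
#' @param valid_frame_offset 0-based raw-frame index of the first stored
#'   frame (default 0).
#' @return A `contrast_stack`.
#' @export
read_contrast_tiff <- function(path, pixel_nm, frame_rate_hz, range = 0.5,
                               valid_frame_offset = 0L) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop_invalid("cannot read TIFF '", path, "': ",
                                   conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (t in seq_along(pages)) {
    pg <- pages[[t]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    frames[, , t] <- pg * 2 * range - range
  }
  contrast_stack(frames, pixel_nm, frame_rate_hz,
                 valid_frame_offset = as.integer(valid_frame_offset),
                 raw_frame_index = valid_frame_offset + seq_along(pages))
}

#' Write ground truth to CSV
#'
#' Columns: `particle_id`, `frame`, `x_nm`, `y_nm`, `z_nm`, `exited`.
#'
#' @param truth Event list from [sample_events()] or a data frame from
#'   [truth_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  tab <- if (is.data.frame(truth)) truth else truth_table(truth)
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write localizations or trajectories to CSV
#'
#' @param df Data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a localization or trajectory CSV
#'
#' @param path CSV path.
#' @param required Column names that must be present; a missing column
#'   raises a schema error naming it.
#' @return Data frame.
#' @export
read_table_csv <- function(path, required = character(0)) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  df <- read.csv(path)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_invalid("schema error in '", path, "': missing column(s) ",
                 paste(missing, collapse = ", "))
  df
}

#' Read a pipeline configuration file
#'
#' YAML or JSON, recognised by extension; the result is merged over the
#' package defaults by [pipeline_config()].
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop_invalid("config must be .yaml/.yml or .json")
}

# MD5 of the canonical JSON serialisation of a config list.
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Write a run manifest
#'
#' Records what produced a set of outputs: config hash, seed, input file
#' hashes, package version and timestamp.
#'
#' @param path Output JSON path.
#' @param config Configuration list used for the run.
#' @param seed Master seed.
#' @param inputs Character vector of input file paths (hashed if they
#'   exist).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed, inputs = character(0)) {
  input_md5 <- if (length(inputs))
    as.list(tools::md5sum(inputs[file.exists(inputs)])) else list()
  manifest <- list(config_hash = config_hash(config), seed = seed,
                   inputs = input_md5,
                   package = "iscattrack",
                   version = as.character(packageVersion("iscattrack")),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      "%Y-%m-%dT%H:%M:%SZ"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
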