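#' Read annotation or detection boxes
#'
#' The interchange schema has columns `image_id`, `class`, `xmin`, `ymin`,
#' `xmax`, `ymax`, `confidence` (blank/null for human labels). CSV (with a
#' mandatory header row) and a JSON mirror with identical field names are
#' supported; the format is chosen by file extension. Malformed rows are
#' hard errors naming the offending row.
#'
#' @param path path to a `.csv` or `.json` file.
#' @return A box data frame; it is a detection set iff any confidence is
#'   present.
#' @export
read_annotations <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    csv = utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character"),
    json = {
      x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
      if (length(x) == 0L) data.frame() else as.data.frame(x)
    },
    stop("unsupported annotation format: .", ext, call. = FALSE)
  )
  needed <- c("image_id", "class", "xmin", "ymin", "xmax", "ymax")
  missing_cols <- setdiff(needed, names(df))
  assert_that(length(missing_cols) == 0L,
              "%s: missing header column(s): %s", path,
              paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) return(empty_box_set())
  if (is.null(df$confidence)) df$confidence <- NA
  conf <- df$confidence
  conf[conf %in% c("", "NA")] <- NA
  coords <- lapply(c("xmin", "ymin", "xmax", "ymax"), function(cc) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    assert_that(length(bad) == 0L, "%s row %d: non-numeric %s '%s'",
                path, bad[1], cc, df[[cc]][bad[1]])
    v
  })
  out <- data.frame(image_id = as.character(df$image_id),
                    class_label = as.character(df$class),
                    xmin = coords[[1]], ymin = coords[[2]],
                    xmax = coords[[3]], ymax = coords[[4]],
                    confidence = suppressWarnings(as.numeric(conf)),
                    stringsAsFactors = FALSE)
  validate_box_set(out, path)
}

#' Write boxes to CSV or JSON
#'
#' Inverse of [read_annotations()]; a written set reads back identically.
#'
#' @param boxes a box data frame.
#' @param path output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(boxes, path) {
  boxes <- validate_box_set(boxes)
  out <- data.frame(image_id = boxes$image_id, class = boxes$class_label,
                    xmin = boxes$xmin, ymin = boxes$ymin,
                    xmax = boxes$xmax, ymax = boxes$ymax,
                    confidence = boxes$confidence)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(out, path, row.names = FALSE, na = "")
  } else if (ext == "json") {
    jsonlite::write_json(out, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported annotation format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Read an RGB image tile
#'
#' PNG always; TIFF when the `tiff` package is installed.
#'
#' @param path image path.
#' @return Numeric array `[height, width, channels]` in `[0, 1]`; an alpha
#'   channel, if present, is dropped.
#' @export
read_image <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      assert_that(requireNamespace("tiff", quietly = TRUE),
                  "reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(img)) == 3L && dim(img)[3] > 3L) {
    img <- img[, , 1:3, drop = FALSE]
  }
  img
}

#' Write an RGB image tile as PNG
#'
#' @param image numeric array in `[0, 1]`.
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

run_config_keys <- function() {
  c("stains", "candidate_params", "consensus", "filter", "eval_thresholds",
    "seed", "paths")
}

#' Read a run configuration
#'
#' YAML configuration covering stain profiles, candidate-detection
#' parameters, consensus and classifier-filter settings, evaluation IOU
#' thresholds, seed and paths. Unknown top-level keys are rejected so
#' typos cannot silently change a run. The parsed structure round-trips
#' losslessly through [write_run_config()].
#'
#' @param path path to the YAML file.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), run_config_keys())
  assert_that(length(unknown) == 0L, "unknown config key(s): %s",
              paste(unknown, collapse = ", "))
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @param config a `run_config` list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Hash of a configuration
#'
#' MD5 over the canonical YAML serialization; stamped into output files so
#' every result can be traced to the exact configuration that produced it.
#'
#' @param config a `run_config` list (or any serializable list).
#' @return A hex digest string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}
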