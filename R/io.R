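# Reading and writing the standard on-disk formats: multi-page TIFF stacks
# per channel, TSV tables, JSON reports, YAML run configuration.

#' Write a section stack as per-channel multi-page TIFFs
#'
#' Intensity channels are written as 16-bit grayscale, the mask as 8-bit
#' integer labels.
#'
#' @param stack A [section_stack()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_section_stack <- function(stack, dir, prefix = "stack") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ch in c("nuclear", "long", "short")) {
    a <- stack[[ch]]
    if (is.null(a)) next
    pages <- lapply(seq_len(dim(a)[3]), function(s) t(a[, , s]) / 65535)
    p <- file.path(dir, sprintf("%s_%s.tif", prefix, ch))
    tiff::writeTIFF(pages, p, bits.per.sample = 16L)
    paths <- c(paths, p)
  }
  mp <- file.path(dir, sprintf("%s_mask.tif", prefix))
  pages <- lapply(seq_len(dim(stack$mask)[3]), function(s) t(stack$mask[, , s]) / 255)
  tiff::writeTIFF(pages, mp, bits.per.sample = 8L)
  meta <- file.path(dir, sprintf("%s_geometry.json", prefix))
  jsonlite::write_json(list(pixel_size_um = stack$pixel_size_um,
                            section_thickness_um = stack$section_thickness_um),
                       meta, auto_unbox = TRUE)
  invisible(c(paths, mp, meta))
}

#' Read a section stack written by [write_section_stack()]
#'
#' @param dir Directory holding the TIFFs.
#' @param prefix File-name prefix used when writing.
#' @return A [section_stack()].
#' @export
read_section_stack <- function(dir, prefix = "stack") {
  read_stack <- function(path, scale) {
    if (!file.exists(path)) return(NULL)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
    for (s in seq_along(pages)) arr[, , s] <- t(pages[[s]]) * scale
    arr
  }
  meta <- jsonlite::read_json(file.path(dir, sprintf("%s_geometry.json", prefix)))
  section_stack(
    nuclear = read_stack(file.path(dir, sprintf("%s_nuclear.tif", prefix)), 65535),
    long = read_stack(file.path(dir, sprintf("%s_long.tif", prefix)), 65535),
    short = read_stack(file.path(dir, sprintf("%s_short.tif", prefix)), 65535),
    mask = {
      m <- read_stack(file.path(dir, sprintf("%s_mask.tif", prefix)), 255)
      array(as.integer(round(m)), dim(m))
    },
    pixel_size_um = meta$pixel_size_um,
    section_thickness_um = meta$section_thickness_um)
}

#' Write a tibble as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_tsv_table <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a run-manifest JSON
#'
#' Records parameters, seeds and the package version of a pipeline run.
#'
#' @param manifest Named list.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_manifest <- function(manifest, path) {
  manifest$package <- "boxelcycle"
  manifest$version <- as.character(utils::packageVersion("boxelcycle"))
  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a YAML pipeline configuration
#'
#' @param path YAML file.
#' @return Named list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)
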