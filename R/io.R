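# Plain-text readers/writers: CSV data with JSON sidecar metadata, and a
# simple headered text format for volumes/masks (portable, diff-able).

#' Write a photometry session as CSV + JSON sidecar
#'
#' @param session a `septodg_photometry_session`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_photometry_csv <- function(session, path) {
  utils::write.csv(data.frame(time = session$time,
                              F_gcamp = session$F_gcamp,
                              F_mcherry = session$F_mcherry),
                   path, row.names = FALSE)
  meta <- session[c("site", "animal", "genotype", "context", "fs")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a photometry session written by [write_photometry_csv()]
#' @param path CSV path.
#' @return a `septodg_photometry_session`.
#' @export
read_photometry_csv <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(c(list(time = d$time, F_gcamp = d$F_gcamp,
                   F_mcherry = d$F_mcherry), meta),
            class = "septodg_photometry_session")
}

#' Write a behavior track as CSV + JSON sidecar
#' @param track a `septodg_behavior_track`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(track, path) {
  utils::write.csv(data.frame(time = track$time, x = track$x, y = track$y,
                              dir_deg = track$dir_deg),
                   path, row.names = FALSE)
  meta <- list(objects = track$objects, arena_cm = track$arena_cm,
               corner_cm = track$corner_cm, phase = track$phase,
               fs = track$fs, bouts = track$bouts)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a behavior track written by [write_track_csv()]
#' @param path CSV path.
#' @return a `septodg_behavior_track`.
#' @export
read_track_csv <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  meta$objects <- lapply(meta$objects, as.numeric)
  structure(c(list(time = d$time, x = d$x, y = d$y, dir_deg = d$dir_deg),
              meta),
            class = "septodg_behavior_track")
}

#' Write/read a numeric array as a headered text file
#'
#' Line 1: dims; line 2: physical voxel/pixel size; then one value per
#' line.  Deliberately simple and text-only so fixtures stay portable.
#'
#' @param x numeric matrix or array (optionally with a `voxel_um` /
#'   `pixel_um` attribute).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volume_txt <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(dim(x), collapse = " "), con)
  vs <- attr(x, "voxel_um") %||% attr(x, "pixel_um") %||%
    rep(1, length(dim(x)))
  writeLines(paste(vs, collapse = " "), con)
  writeLines(format(as.numeric(x), trim = TRUE), con)
  invisible(path)
}

#' @rdname write_volume_txt
#' @export
read_volume_txt <- function(path) {
  ln <- readLines(path)
  dims <- as.integer(strsplit(ln[1], " ")[[1]])
  vs <- as.numeric(strsplit(ln[2], " ")[[1]])
  x <- array(as.numeric(ln[-(1:2)]), dims)
  attr(x, if (length(dims) == 3) "voxel_um" else "pixel_um") <- vs
  x
}
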