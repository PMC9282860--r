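# Plain-text interchange: kymographs as CSV matrices (rows = bins,
# columns = times, header row of times) with a JSON sidecar of metadata;
# track ensembles as long-format CSV.

#' Write / read a kymograph as CSV (+ JSON sidecar)
#'
#' @param kymo a [kymograph()].
#' @param path CSV path; the sidecar is written next to it as
#'   \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
write_kymograph_csv <- function(kymo, path) {
  stopifnot(inherits(kymo, "kymograph"))
  m <- kymo$mat
  df <- as.data.frame(m)
  names(df) <- format(kymo$times, trim = TRUE)
  utils::write.csv(cbind(angle = kymo$angles, df), path, row.names = FALSE)
  meta <- kymo$meta
  meta$params <- NULL      # closures/objects do not belong in a sidecar
  jsonlite::write_json(list(species = kymo$species, times = kymo$times,
                            angles = kymo$angles, meta = meta),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_kymograph_csv
#' @export
read_kymograph_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  angles <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  side <- paste0(path, ".json")
  species <- "Ep"; meta <- list()
  times <- as.numeric(colnames(m))
  if (file.exists(side)) {
    sc <- jsonlite::read_json(side, simplifyVector = TRUE)
    species <- sc$species %||% species
    if (!is.null(sc$times)) times <- sc$times
    meta <- sc$meta %||% list()
  }
  dimnames(m) <- NULL
  kymograph(m, times, angles, species = species, meta = meta)
}

#' Write / read a track ensemble as long-format CSV
#'
#' Columns: \code{cell_id}, \code{t_min}, \code{x_um}, \code{y_um},
#' \code{phase}.
#'
#' @param ensemble a [track_ensemble()].
#' @param path CSV path.
#' @return \code{path} invisibly (writer); a [track_ensemble()] (reader).
#' @export
write_tracks_csv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "track_ensemble"))
  rows <- lapply(seq_along(ensemble$tracks), function(i) {
    tr <- ensemble$tracks[[i]]
    data.frame(cell_id = i, t_min = tr$t, x_um = tr$x, y_um = tr$y,
               phase = if ("phase" %in% names(tr)) tr$phase else NA)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  df <- utils::read.csv(path)
  ids <- factor(df$cell_id, levels = unique(df$cell_id))
  tracks <- lapply(split(df, ids), function(d)
    data.frame(t = d$t_min, x = d$x_um, y = d$y_um, phase = d$phase))
  names(tracks) <- NULL
  dt <- diff(tracks[[1]]$t)[1]
  track_ensemble(tracks, dt, meta = list(source = path))
}
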