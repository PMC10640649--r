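#' Read a TrackMate model XML file
#'
#' Consumes the `AllSpots`/`AllTracks` sections of a TrackMate XML export:
#' tracks are assembled from edges (`SPOT_SOURCE_ID`/`SPOT_TARGET_ID`), spot
#' positions are taken from `POSITION_X`/`POSITION_Y` and frames from `FRAME`.
#' Gap-closed edges produce non-consecutive frames, which are preserved.
#' The frame interval is read from `Settings/ImageData@timeinterval` unless
#' overridden.
#'
#' @param path path to a TrackMate XML file.
#' @param dt optional frame interval in seconds; overrides the XML metadata.
#' @param cell_id cell label for all tracks (default: file stem).
#' @param condition condition label for all tracks.
#' @return a `perox_trackset` with positions in micrometres.
#' @export
read_trackmate_xml <- function(path, dt = NULL, cell_id = NULL,
                               condition = "default") {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse TrackMate XML: ",
                                           conditionMessage(e), call. = FALSE))
  model <- xml2::xml_find_first(doc, ".//Model")
  if (inherits(model, "xml_missing"))
    stop("no <Model> element: not a TrackMate model file", call. = FALSE)
  units <- xml2::xml_attr(model, "spatialunits")
  if (!is.na(units) && !(tolower(units) %in% c("micron", "microns", "um",
                                               "µm", "μm")))
    stop("spatial unit '", units, "' is not micrometres; convert upstream",
         call. = FALSE)
  if (is.null(dt)) {
    ival <- xml2::xml_attr(xml2::xml_find_first(doc, ".//Settings/ImageData"),
                           "timeinterval")
    if (is.na(ival))
      stop("no frame interval in XML; pass dt explicitly", call. = FALSE)
    dt <- as.numeric(ival)
  }
  if (is.null(cell_id)) cell_id <- sub("\\.[^.]*$", "", basename(path))

  spots <- xml2::xml_find_all(doc, ".//AllSpots//Spot")
  spot_id <- xml2::xml_attr(spots, "ID")
  sx <- as.numeric(xml2::xml_attr(spots, "POSITION_X"))
  sy <- as.numeric(xml2::xml_attr(spots, "POSITION_Y"))
  sframe <- as.integer(xml2::xml_attr(spots, "FRAME"))
  idx <- stats::setNames(seq_along(spot_id), spot_id)

  tracks <- list()
  for (tk in xml2::xml_find_all(doc, ".//AllTracks/Track")) {
    tid <- xml2::xml_attr(tk, "TRACK_ID")
    if (is.na(tid)) tid <- xml2::xml_attr(tk, "name")
    edges <- xml2::xml_find_all(tk, "Edge")
    src <- xml2::xml_attr(edges, "SPOT_SOURCE_ID")
    tgt <- xml2::xml_attr(edges, "SPOT_TARGET_ID")
    ids <- unique(c(src, tgt))
    unknown <- setdiff(ids, names(idx))
    if (length(unknown))
      stop("edge references unknown spot id(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    rows <- idx[ids]
    ord <- order(sframe[rows])
    rows <- rows[ord]
    tracks[[length(tracks) + 1L]] <-
      track(tid, sframe[rows], sx[rows], sy[rows], dt,
            cell_id = cell_id, condition = condition)
  }
  track_set(tracks)
}

#' Write a track set as a minimal TrackMate model XML
#'
#' Emits the subset of the TrackMate schema that [read_trackmate_xml()]
#' consumes (spots, linear edge chains per track, spatial unit micron, frame
#' interval), so `write -> read` round-trips frames and positions.
#'
#' @param ts a `perox_trackset`; all tracks must share one `dt`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trackmate_xml <- function(ts, path) {
  trs <- unclass(ts)
  if (!length(trs)) stop("empty track set", call. = FALSE)
  dts <- unique(vapply(trs, `[[`, 0, "dt"))
  if (length(dts) != 1L) stop("tracks differ in dt", call. = FALSE)

  doc <- xml2::xml_new_root("TrackMate", version = "7.10.2")
  model <- xml2::xml_add_child(doc, "Model", spatialunits = "micron",
                               timeunits = "s")
  all_spots <- xml2::xml_add_child(model, "AllSpots")
  all_tracks <- xml2::xml_add_child(model, "AllTracks")
  filtered <- xml2::xml_add_child(model, "FilteredTracks")

  # spots grouped by frame, with globally unique integer ids
  next_id <- 0L
  spot_ids <- list()
  frame_nodes <- list()
  for (tr in trs) {
    ids <- next_id + seq_along(tr$frames) - 1L
    next_id <- next_id + length(tr$frames)
    spot_ids[[tr$track_id]] <- ids
    for (k in seq_along(tr$frames)) {
      f <- as.character(tr$frames[k])
      if (is.null(frame_nodes[[f]]))
        frame_nodes[[f]] <- xml2::xml_add_child(all_spots, "SpotsInFrame",
                                                frame = f)
      xml2::xml_add_child(frame_nodes[[f]], "Spot",
                          ID = as.character(ids[k]),
                          name = sprintf("ID%d", ids[k]),
                          FRAME = f,
                          POSITION_X = format(tr$x[k], digits = 17),
                          POSITION_Y = format(tr$y[k], digits = 17),
                          POSITION_T = format(tr$frames[k] * tr$dt,
                                              digits = 17))
    }
  }
  xml2::xml_attr(all_spots, "nspots") <- as.character(next_id)
  for (tr in trs) {
    tk <- xml2::xml_add_child(all_tracks, "Track", name = tr$track_id,
                              TRACK_ID = tr$track_id)
    ids <- spot_ids[[tr$track_id]]
    for (k in seq_len(length(ids) - 1L))
      xml2::xml_add_child(tk, "Edge",
                          SPOT_SOURCE_ID = as.character(ids[k]),
                          SPOT_TARGET_ID = as.character(ids[k + 1L]))
    xml2::xml_add_child(filtered, "TrackID", TRACK_ID = tr$track_id)
  }
  settings <- xml2::xml_add_child(doc, "Settings")
  xml2::xml_add_child(settings, "ImageData",
                      timeinterval = format(dts, digits = 17),
                      spatialunits = "micron", timeunits = "s")
  xml2::write_xml(doc, path)
  invisible(path)
}
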