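# I/O for every external artifact the pipeline touches: frame sequences,
# label masks, displacement fields, feature tables, track graphs.
#
# Conventions (used throughout the package):
#   - images are h x w numeric matrices, (row, col) indexing, origin top-left;
#   - gray values are rescaled to [0, 1] on load, whatever the file bit depth;
#   - label masks are integer matrices, 0 = background;
#   - displacement fields are h x w x 2 arrays (slice 1 = row displacement,
#     slice 2 = column displacement, pixel units).

# ---- frames -----------------------------------------------------------------

# Natural-order sort key: "frame2" < "frame10". Splits digit runs and pads.
natural_order <- function(paths) {
  base <- basename(paths)
  keys <- vapply(base, function(s) {
    parts <- regmatches(s, gregexpr("[0-9]+|[^0-9]+", s))[[1]]
    num <- grepl("^[0-9]+$", parts)
    parts[num] <- sprintf("%020d", as.numeric(parts[num]))
    paste(parts, collapse = "")
  }, character(1))
  order(keys, base)
}

read_gray_image <- function(path) {
  lower <- tolower(path)
  px <- if (grepl("\\.png$", lower)) {
    png::readPNG(path)
  } else {
    suppressWarnings(tiff::readTIFF(path))
  }
  if (length(dim(px)) == 3) {
    # collapse color planes to luminance-by-average; sequences here are gray
    px <- apply(px[, , 1:min(3, dim(px)[3]), drop = FALSE], c(1, 2), mean)
  }
  storage.mode(px) <- "double"
  px
}

#' Read an ordered frame sequence
#'
#' Loads all grayscale TIFF/PNG frames matching a directory or glob pattern,
#' sorted by natural filename order, and rescales pixel values to `[0, 1]`
#' (readers divide by the native bit-depth maximum). Every frame must share
#' the same height and width.
#'
#' @param pattern A directory (all `.tif/.tiff/.png` files inside) or a glob
#'   pattern such as `"seq/frame*.tif"`.
#' @return List of frames; each is a list with `pixels` (matrix in `[0, 1]`),
#'   `time_index` (0-based) and `source_path`.
#' @export
read_sequence <- function(pattern) {
  paths <- if (length(pattern) == 1 && dir.exists(pattern)) {
    list.files(pattern, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE,
               full.names = TRUE)
  } else {
    Sys.glob(pattern)
  }
  if (length(paths) == 0) stopf("no frames matched '%s'", paste(pattern, collapse = ", "))
  paths <- paths[natural_order(paths)]
  frames <- vector("list", length(paths))
  ref_dim <- NULL
  for (i in seq_along(paths)) {
    px <- read_gray_image(paths[i])
    if (is.null(ref_dim)) {
      ref_dim <- dim(px)
    } else if (!identical(dim(px), ref_dim)) {
      stopf("frame '%s' has shape %dx%d, expected %dx%d", paths[i],
            nrow(px), ncol(px), ref_dim[1], ref_dim[2])
    }
    frames[[i]] <- new_frame(px, i - 1L, paths[i])
  }
  frames
}

new_frame <- function(pixels, time_index, source_path = NA_character_) {
  stopifnot(is.matrix(pixels))
  list(pixels = pixels, time_index = as.integer(time_index),
       source_path = source_path)
}

# Accept either a frame object or a bare matrix wherever a frame is expected
frame_pixels <- function(frame) {
  if (is.matrix(frame)) return(frame)
  if (is.list(frame) && is.matrix(frame$pixels)) return(frame$pixels)
  stopf("expected an image matrix or a frame with a 'pixels' matrix")
}

#' Write a grayscale frame
#'
#' Stores a `[0, 1]` image as 8-bit (default) or 16-bit grayscale TIFF.
#'
#' @param image Matrix in `[0, 1]` (or a frame object).
#' @param path Output path.
#' @param bits 8 or 16.
#' @return `path`, invisibly.
#' @export
write_frame <- function(image, path, bits = 8L) {
  px <- frame_pixels(image)
  stopifnot(bits %in% c(8L, 16L))
  tiff::writeTIFF(clamp(px, 0, 1), path, bits.per.sample = as.integer(bits))
  invisible(path)
}

# ---- label masks ------------------------------------------------------------

#' Write / read a label mask
#'
#' Masks are stored as single-channel 16-bit TIFF, so the round-trip is
#' bit-exact for labels up to 65535.
#'
#' @param mask Integer matrix, 0 = background.
#' @param path File path.
#' @return `write_label_mask()` returns `path` invisibly; `read_label_mask()`
#'   returns an integer matrix.
#' @export
write_label_mask <- function(mask, path) {
  if (!all(mask == floor(mask)) || any(mask < 0)) {
    stopf("label mask must contain non-negative integers")
  }
  if (max(mask) > 65535) {
    stopf("label %d exceeds 16-bit capacity (65535)", max(mask))
  }
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  px <- suppressWarnings(tiff::readTIFF(path))
  if (length(dim(px)) == 3) px <- px[, , 1]
  m <- round(px * 65535)
  storage.mode(m) <- "integer"
  m
}

# ---- displacement fields ----------------------------------------------------

# Minimal TIFF encoder for 2-channel 32-bit IEEE float images (little-endian,
# uncompressed, one strip). Written by hand because the general-purpose TIFF
# writers in R clamp float samples into [0, 1]; displacement components are
# signed pixel offsets and must round-trip exactly.
write_float_tiff <- function(arr, path) {
  stopifnot(length(dim(arr)) == 3)
  h <- dim(arr)[1]; w <- dim(arr)[2]; ch <- dim(arr)[3]
  con <- file(path, "wb")
  on.exit(close(con))
  data <- as.numeric(aperm(arr, c(3, 2, 1)))  # pixel-interleaved, row-major
  data_offset <- 8L
  data_bytes <- length(data) * 4L
  ifd_offset <- data_offset + data_bytes
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_offset, con, size = 4, endian = "little")
  writeBin(data, con, size = 4, endian = "little")
  tags <- list(                       # tag id, type (3 = short, 4 = long), count, value
    c(256L, 4L, 1L, w),               # ImageWidth
    c(257L, 4L, 1L, h),               # ImageLength
    c(258L, 3L, ch, 32L),             # BitsPerSample
    c(259L, 3L, 1L, 1L),              # Compression: none
    c(262L, 3L, 1L, 1L),              # Photometric: BlackIsZero
    c(273L, 4L, 1L, data_offset),     # StripOffsets
    c(277L, 3L, 1L, ch),              # SamplesPerPixel
    c(278L, 4L, 1L, h),               # RowsPerStrip
    c(279L, 4L, 1L, data_bytes),      # StripByteCounts
    c(339L, 3L, ch, 3L)               # SampleFormat: IEEE float
  )
  writeBin(length(tags), con, size = 2, endian = "little")
  for (tg in tags) {
    writeBin(tg[1], con, size = 2, endian = "little")
    writeBin(tg[2], con, size = 2, endian = "little")
    writeBin(tg[3], con, size = 4, endian = "little")
    if (tg[2] == 3L && tg[3] <= 2L) {
      # shorts packed into the 4-byte value slot
      writeBin(as.integer(rep(tg[4], tg[3])), con, size = 2, endian = "little")
      if (tg[3] == 1L) writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(tg[4], con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little")
  invisible(path)
}

#' Write / read a displacement field
#'
#' Fields are stored as 2-channel 32-bit float TIFF (channel 1 = row
#' displacement, channel 2 = column displacement); the round-trip is exact at
#' 32-bit float precision.
#'
#' @param field `h x w x 2` numeric array with finite entries.
#' @param path File path.
#' @return `write_displacement_field()` returns `path` invisibly;
#'   `read_displacement_field()` returns the `h x w x 2` array.
#' @export
write_displacement_field <- function(field, path) {
  if (length(dim(field)) != 3 || dim(field)[3] != 2) {
    stopf("displacement field must be an h x w x 2 array")
  }
  if (!all(is.finite(field))) stopf("displacement field contains NaN/Inf")
  write_float_tiff(field, path)
}

#' @rdname write_displacement_field
#' @export
read_displacement_field <- function(path) {
  px <- suppressWarnings(tiff::readTIFF(path))
  if (length(dim(px)) != 3 || dim(px)[3] != 2) {
    stopf("'%s' is not a 2-channel displacement field TIFF", path)
  }
  px
}

# ---- feature tables ---------------------------------------------------------

feature_table_columns <- c(
  "frame", "colony_id", "area_px", "elongation", "circularity", "entropy",
  "mean_displacement", "sd_displacement", "centroid_row", "centroid_col"
)

#' Write / read a colony feature table
#'
#' One row per colony per frame, fixed column set (`frame`, `colony_id`,
#' `area_px`, `elongation`, `circularity`, `entropy`, `mean_displacement`,
#' `sd_displacement`, `centroid_row`, `centroid_col`), written as CSV at full
#' precision.
#'
#' @param records Tibble of per-colony records (from [measure_sequence()]).
#' @param path File path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns a tibble.
#' @export
write_feature_table <- function(records, path) {
  if (is.null(records) || nrow(records) == 0) {
    stopf("feature record list is empty")
  }
  missing_cols <- setdiff(feature_table_columns, names(records))
  if (length(missing_cols) > 0) {
    stopf("feature records lack columns: %s", paste(missing_cols, collapse = ", "))
  }
  readr::write_csv(records[feature_table_columns], path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    frame = "i", colony_id = "i", area_px = "i",
                    .default = readr::col_double()))
}

# ---- track graphs -----------------------------------------------------------

node_id <- function(frame, label) sprintf("%d:%d", frame, label)

#' Construct a track graph
#'
#' @param nodes Tibble with columns `frame`, `label`, `centroid_row`,
#'   `centroid_col` (one row per colony per frame).
#' @param edges Tibble with columns `parent_frame`, `parent_label`,
#'   `child_frame`, `child_label`, `event` (one of `continue`, `merge`,
#'   `split`, `appear`; `appear` edges have `NA` parents).
#' @param direction Processing direction the events were detected in.
#' @return A `track_graph` object.
#' @export
track_graph <- function(nodes = NULL, edges = NULL, direction = "forward") {
  nodes <- nodes %||% tibble::tibble(
    frame = integer(), label = integer(),
    centroid_row = numeric(), centroid_col = numeric())
  edges <- edges %||% tibble::tibble(
    parent_frame = integer(), parent_label = integer(),
    child_frame = integer(), child_label = integer(), event = character())
  bad <- setdiff(edges$event, c("continue", "merge", "split", "appear"))
  if (length(bad) > 0) stopf("unknown event type(s): %s", paste(bad, collapse = ", "))
  structure(list(nodes = nodes, edges = edges, direction = direction),
            class = "track_graph")
}

#' @export
print.track_graph <- function(x, ...) {
  cat(sprintf("<track_graph> %d nodes over %d frames, %d edges (%s)\n",
              nrow(x$nodes), length(unique(x$nodes$frame)), nrow(x$edges),
              paste(sprintf("%s: %d", names(table(x$edges$event)),
                            as.integer(table(x$edges$event))), collapse = ", ")))
  invisible(x)
}

#' Write / read a track graph as JSON
#'
#' Nodes carry `id` (`"frame:label"`), `frame`, `label` and centroid; edges
#' carry `parent`, `child` (node ids; `appear` edges have `null` parents) and
#' `event`. The round-trip is isomorphic.
#'
#' @param graph A [track_graph()].
#' @param path File path.
#' @return `write_track_graph()` returns `path` invisibly;
#'   `read_track_graph()` returns a `track_graph`.
#' @export
write_track_graph <- function(graph, path) {
  stopifnot(inherits(graph, "track_graph"))
  nodes <- graph$nodes
  edges <- graph$edges
  out <- list(
    direction = graph$direction,
    nodes = if (nrow(nodes) == 0) list() else
      purrr::pmap(nodes, function(frame, label, centroid_row, centroid_col, ...) {
        list(id = node_id(frame, label), frame = frame, label = label,
             centroid_row = centroid_row, centroid_col = centroid_col)
      }),
    edges = if (nrow(edges) == 0) list() else
      purrr::pmap(edges, function(parent_frame, parent_label, child_frame,
                                  child_label, event, ...) {
        list(
          parent = if (is.na(parent_label)) NULL else node_id(parent_frame, parent_label),
          child = node_id(child_frame, child_label),
          event = event)
      })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_track_graph
#' @export
read_track_graph <- function(path) {
  raw <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stopf("malformed track graph JSON: %s", conditionMessage(e)))
  parse_id <- function(id) as.integer(strsplit(id, ":", fixed = TRUE)[[1]])
  nodes <- if (length(raw$nodes) == 0) NULL else
    purrr::map_dfr(raw$nodes, function(n) tibble::tibble(
      frame = as.integer(n$frame), label = as.integer(n$label),
      centroid_row = as.numeric(n$centroid_row %||% NA),
      centroid_col = as.numeric(n$centroid_col %||% NA)))
  edges <- if (length(raw$edges) == 0) NULL else
    purrr::map_dfr(raw$edges, function(e) {
      p <- if (is.null(e$parent)) c(NA_integer_, NA_integer_) else parse_id(e$parent)
      ch <- parse_id(e$child)
      tibble::tibble(parent_frame = p[1], parent_label = p[2],
                     child_frame = ch[1], child_label = ch[2],
                     event = e$event)
    })
  track_graph(nodes, edges, direction = raw$direction %||% "forward")
}
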