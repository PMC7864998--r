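#' Compartment codes
#'
#' The four anatomical compartments of a retinal OCT B-scan, in top-to-bottom
#' order: vitreous (0), retina (1), choroid (2), sclera (3). Label maps store
#' these integer codes; row 0 of a map is the image top (vitreous side).
#'
#' @format A named integer vector of length four.
#' @export
COMPARTMENTS <- c(vitreous = 0L, retina = 1L, choroid = 2L, sclera = 3L)

#' Display palette for compartment codes
#'
#' Colors used when rendering label maps: vitreous orange, retina blue,
#' choroid yellow, sclera gray. Visualization only; files store codes.
#'
#' @format A character vector of four colors named by compartment.
#' @export
COMPARTMENT_PALETTE <- c(vitreous = "#FFA500", retina = "#0000FF",
                         choroid = "#FFFF00", sclera = "#808080")

compartment_code <- function(compartment) {
  if (is.numeric(compartment)) {
    code <- as.integer(compartment)
  } else {
    code <- COMPARTMENTS[match(tolower(as.character(compartment)),
                               names(COMPARTMENTS))]
  }
  if (length(code) != 1L || is.na(code) || !code %in% COMPARTMENTS)
    stop("unknown compartment: ", paste(compartment, collapse = ", "),
         " (expected one of ", paste(names(COMPARTMENTS), collapse = ", "),
         " or codes 0-3)", call. = FALSE)
  code
}

#' Construct a compartment label map
#'
#' A label map is an integer matrix of compartment codes (see
#' [COMPARTMENTS]) with a scan identifier and a grading identifier (e.g.
#' `"g1"` for a human grader or `"cnn"` for a model).
#'
#' @param labels Integer matrix with all values in `{0,1,2,3}`.
#' @param scan_id,grading_id Identifier strings (no commas).
#' @return An object of class `labelmap`: the matrix with `scan_id` and
#'   `grading_id` attributes.
#' @export
labelmap <- function(labels, scan_id = "scan", grading_id = "grading") {
  if (!is.matrix(labels) || nrow(labels) < 1L || ncol(labels) < 1L)
    stop("labels must be a matrix with at least one row and column")
  storage.mode(labels) <- "integer"
  bad <- !(labels %in% COMPARTMENTS)
  if (any(bad))
    stop("invalid compartment codes in label map: ",
         paste(sort(unique(labels[bad])), collapse = ", "))
  check_id(scan_id); check_id(grading_id)
  structure(labels, scan_id = scan_id, grading_id = grading_id,
            class = c("labelmap", "matrix", "array"))
}

check_id <- function(id) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || grepl(",", id))
    stop("identifiers must be single strings without commas: ",
         deparse(substitute(id)))
  invisible(id)
}

#' @export
print.labelmap <- function(x, ...) {
  cat(sprintf("<labelmap %s/%s: %d x %d>\n", attr(x, "scan_id"),
              attr(x, "grading_id"), nrow(x), ncol(x)))
  tab <- tabulate(as.integer(x) + 1L, nbins = 4L)
  cat("  pixels per compartment:",
      paste(sprintf("%s=%d", names(COMPARTMENTS), tab), collapse = " "), "\n")
  invisible(x)
}

#' Construct a boundary set
#'
#' Three per-column boundary lines partition a B-scan into four compartments:
#' the inner limiting membrane (ILM), the inner choriocapillaris border
#' (CCi), and the choroid-sclera interface (CSI). Row positions are 0-based;
#' a boundary row belongs to the compartment below the line, so the vitreous
#' is strictly above the ILM.
#'
#' @param ilm,cci,csi Numeric vectors of equal length `W` giving, for each
#'   column, the row position of the boundary. Must satisfy
#'   `0 <= ilm <= cci <= csi` in every column.
#' @return An object of class `boundary_set` (a list with elements `ilm`,
#'   `cci`, `csi`).
#' @export
boundary_set <- function(ilm, cci, csi) {
  w <- length(ilm)
  if (length(cci) != w || length(csi) != w)
    stop(sprintf("boundary length mismatch: ilm=%d cci=%d csi=%d",
                 w, length(cci), length(csi)))
  if (w < 1L) stop("boundaries must have at least one column")
  b <- list(ilm = as.numeric(ilm), cci = as.numeric(cci), csi = as.numeric(csi))
  bad <- which(b$ilm < 0 | b$cci < b$ilm | b$csi < b$cci)
  if (length(bad))
    stop(sprintf("crossing or negative boundaries at column %d (0-based %d): ilm=%g cci=%g csi=%g",
                 bad[1], bad[1] - 1L, b$ilm[bad[1]], b$cci[bad[1]], b$csi[bad[1]]))
  structure(b, class = "boundary_set")
}

#' @export
print.boundary_set <- function(x, ...) {
  cat(sprintf("<boundary_set: %d columns>\n", length(x$ilm)))
  for (nm in c("ilm", "cci", "csi"))
    cat(sprintf("  %s: rows %g-%g\n", nm, min(x[[nm]]), max(x[[nm]])))
  invisible(x)
}

#' Rasterize boundary lines into a compartment label map
#'
#' Pixels between two lines are labeled as the compartment between them,
#' with half-open intervals: pixel `(r, c)` (0-based rows, row 0 at the top)
#' is vitreous iff `r < ilm[c]`, retina iff `ilm[c] <= r < cci[c]`, choroid
#' iff `cci[c] <= r < csi[c]`, and sclera iff `r >= csi[c]`.
#'
#' @param b A [boundary_set()] whose vectors have length `width` and values
#'   at most `height`.
#' @param height,width Output grid size in pixels.
#' @inheritParams labelmap
#' @return A [labelmap()] of size `height` x `width`.
#' @export
lines_to_labelmap <- function(b, height, width, scan_id = "scan",
                              grading_id = "grading") {
  stopifnot(inherits(b, "boundary_set"))
  if (length(b$ilm) != width)
    stop(sprintf("boundary length %d does not match width %d",
                 length(b$ilm), width))
  if (any(b$csi > height))
    stop("boundary rows exceed image height")
  r <- matrix(seq_len(height) - 1L, nrow = height, ncol = width)
  ilm <- matrix(b$ilm, nrow = height, ncol = width, byrow = TRUE)
  cci <- matrix(b$cci, nrow = height, ncol = width, byrow = TRUE)
  csi <- matrix(b$csi, nrow = height, ncol = width, byrow = TRUE)
  lab <- (r >= ilm) + (r >= cci) + (r >= csi)
  labelmap(matrix(as.integer(lab), height, width), scan_id, grading_id)
}

#' Binary membership map for one compartment
#'
#' Treats a segmentation as a binary map where a pixel either does or does
#' not belong to the given compartment. The four binary maps of a label map
#' sum to one at every pixel.
#'
#' @param m A [labelmap()].
#' @param compartment Compartment name or code (see [COMPARTMENTS]).
#' @return An integer 0/1 matrix of the same shape.
#' @export
labelmap_to_binary <- function(m, compartment) {
  code <- compartment_code(compartment)
  out <- matrix(as.integer(unclass(m) == code), nrow(m), ncol(m))
  out
}

#' Read and write label-map PNGs
#'
#' Label maps are stored as 8-bit PNGs holding the compartment codes 0-3:
#' either single-channel grayscale files whose byte values are the codes, or
#' paletted files whose palette indices are the codes (indices are recovered
#' from the file's PLTE chunk, so decoding does not depend on the display
#' colors). `write_labelmap` writes grayscale codes; with `palette = TRUE`
#' it writes an RGB rendering using [COMPARTMENT_PALETTE] (for display only;
#' such files are not round-trippable by index).
#'
#' @param path PNG file path.
#' @param m A [labelmap()].
#' @inheritParams labelmap
#' @return `read_labelmap` returns a [labelmap()]; `write_labelmap` returns
#'   `path` invisibly. Reading then writing (or vice versa) is bit-exact on
#'   the code matrix.
#' @export
read_labelmap <- function(path, scan_id = "scan", grading_id = "grading") {
  img <- tryCatch(png::readPNG(path), error = function(e)
    stop("not a readable PNG: ", path, " (", conditionMessage(e), ")",
         call. = FALSE))
  pal <- read_png_palette(path)
  if (!is.null(pal)) {
    # paletted file: readPNG expanded indices to RGB; invert via the PLTE chunk
    codes <- rgb_to_palette_index(img, pal)
  } else {
    if (length(dim(img)) == 3L) {
      if (dim(img)[3] >= 3L &&
          (any(img[, , 1] != img[, , 2]) || any(img[, , 1] != img[, , 3])))
        stop("PNG is RGB with non-gray pixels and no palette; cannot infer codes: ",
             path)
      img <- img[, , 1]
    }
    codes <- round(img * 255)
  }
  bad <- !(codes %in% COMPARTMENTS)
  if (any(bad))
    stop("PNG pixel values outside {0,1,2,3}: ",
         paste(sort(unique(codes[bad])), collapse = ", "), " in ", path)
  labelmap(matrix(as.integer(codes), nrow(codes), ncol(codes)),
           scan_id, grading_id)
}

#' @rdname read_labelmap
#' @param palette If `TRUE`, write an RGB visualization instead of raw codes.
#' @export
write_labelmap <- function(m, path, palette = FALSE) {
  stopifnot(inherits(m, "labelmap"))
  if (palette) {
    cols <- grDevices::col2rgb(COMPARTMENT_PALETTE) / 255
    arr <- array(0, dim = c(nrow(m), ncol(m), 3L))
    for (ch in 1:3)
      arr[, , ch] <- matrix(cols[ch, unclass(m) + 1L], nrow(m), ncol(m))
    png::writePNG(arr, path)
  } else {
    png::writePNG(unclass(m) / 255, path)
  }
  invisible(path)
}

# Scan the PNG chunk stream for a PLTE chunk and return the palette as an
# N x 3 integer matrix, or NULL when the file has no palette. Chunk framing
# only (length / type / data / crc); pixel data is never touched here.
read_png_palette <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  if (length(raw) < 8L || !identical(raw[1:8], sig))
    stop("not a PNG file: ", path, call. = FALSE)
  pos <- 9L
  while (pos + 8L <= length(raw)) {
    len <- sum(as.integer(raw[pos:(pos + 3L)]) * c(2^24, 2^16, 2^8, 1))
    type <- rawToChar(raw[(pos + 4L):(pos + 7L)])
    if (type == "PLTE") {
      dat <- as.integer(raw[(pos + 8L):(pos + 7L + len)])
      return(matrix(dat, ncol = 3L, byrow = TRUE))
    }
    if (type == "IDAT" || type == "IEND") return(NULL)
    pos <- pos + 12L + len
  }
  NULL
}

rgb_to_palette_index <- function(img, pal) {
  if (length(dim(img)) == 2L) {
    # grayscale-rendered palette (all entries gray); match on one channel
    rgb255 <- round(img * 255)
    key <- pal[, 1]
  } else {
    rgb255 <- round(img[, , 1] * 255) * 2^16 +
      round(img[, , 2] * 255) * 2^8 + round(img[, , 3] * 255)
    key <- pal[, 1] * 2^16 + pal[, 2] * 2^8 + pal[, 3]
  }
  idx <- match(as.vector(rgb255), key) - 1L
  if (anyNA(idx))
    stop("pixel colors not present in the PNG palette; corrupt file?")
  matrix(idx, nrow(rgb255), ncol(rgb255))
}

#' Read and write boundary-line CSV files
#'
#' Boundary annotations are exchanged as UTF-8 CSV with header
#' `scan_id,grading_id,column,ilm,cci,csi` and one row per image column
#' (0-based `column` index). Round trips are value-exact.
#'
#' @param path CSV file path.
#' @return `read_boundaries` returns a data frame with one row per
#'   `(scan_id, grading_id)` and a list-column `boundaries` of
#'   [boundary_set()] objects. `write_boundaries` returns `path` invisibly.
#' @export
read_boundaries <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("scan_id", "grading_id", "column", "ilm", "cci", "csi")
  if (!all(need %in% names(df)))
    stop("boundary CSV must have columns ", paste(need, collapse = ","))
  keys <- unique(df[c("scan_id", "grading_id")])
  sets <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- df[df$scan_id == keys$scan_id[i] & df$grading_id == keys$grading_id[i], ]
    sub <- sub[order(sub$column), ]
    if (!identical(as.integer(sub$column), seq_len(nrow(sub)) - 1L))
      stop(sprintf("missing or duplicated columns for (%s, %s)",
                   keys$scan_id[i], keys$grading_id[i]))
    sets[[i]] <- boundary_set(sub$ilm, sub$cci, sub$csi)
  }
  keys$boundaries <- sets
  rownames(keys) <- NULL
  keys
}

#' @rdname read_boundaries
#' @param boundaries A data frame as returned by [read_boundaries()], or a
#'   named list of [boundary_set()] (names become `scan_id`, with a single
#'   `grading_id`).
#' @param grading_id Grading identifier used when `boundaries` is a plain list.
#' @export
write_boundaries <- function(boundaries, path, grading_id = "grading") {
  if (!is.data.frame(boundaries)) {
    ids <- names(boundaries)
    if (is.null(ids)) ids <- paste0("scan", seq_along(boundaries))
    sets <- unname(boundaries)
    boundaries <- data.frame(scan_id = ids, grading_id = grading_id,
                             stringsAsFactors = FALSE)
    boundaries$boundaries <- sets
  }
  rows <- lapply(seq_len(nrow(boundaries)), function(i) {
    b <- boundaries$boundaries[[i]]
    data.frame(scan_id = boundaries$scan_id[i],
               grading_id = boundaries$grading_id[i],
               column = seq_along(b$ilm) - 1L,
               ilm = b$ilm, cci = b$cci, csi = b$csi,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Assemble a grading ensemble
#'
#' A grading ensemble holds one label map per `(scan_id, grading_id)` pair
#' over a complete block design: every grading must be present for every
#' scan, as in a test set where each B-scan is labeled by all graders and
#' the model. All maps must share one grid size.
#'
#' @param maps A list of [labelmap()] objects.
#' @param grader_ids Character vector of human-grader identifiers, in display
#'   order. Defaults to all grading ids except `model_id`.
#' @param model_id Optional identifier of the model grading, or `NULL`.
#' @return An object of class `grading_ensemble`.
#' @export
grading_ensemble <- function(maps, grader_ids = NULL, model_id = NULL) {
  stopifnot(is.list(maps), length(maps) > 0L)
  scan <- vapply(maps, attr, "", "scan_id")
  grad <- vapply(maps, attr, "", "grading_id")
  dims <- vapply(maps, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all maps in an ensemble must share one (height, width)")
  key <- paste(scan, grad, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate map for (scan, grading): ",
         sub("\r", ", ", key[duplicated(key)][1]))
  scan_ids <- unique(scan)
  grading_ids <- unique(grad)
  missing <- outer(scan_ids, grading_ids, function(s, g)
    !(paste(s, g, sep = "\r") %in% key))
  if (any(missing)) {
    w <- which(missing, arr.ind = TRUE)[1, ]
    stop(sprintf("incomplete block design: no map for (%s, %s)",
                 scan_ids[w[1]], grading_ids[w[2]]))
  }
  if (is.null(grader_ids)) grader_ids <- setdiff(grading_ids, model_id)
  if (!all(grader_ids %in% grading_ids))
    stop("grader_ids not present in maps: ",
         paste(setdiff(grader_ids, grading_ids), collapse = ", "))
  if (!is.null(model_id) && !model_id %in% grading_ids)
    stop("model_id not present in maps: ", model_id)
  names(maps) <- key
  empties <- vapply(maps, function(m) any(tabulate(unclass(m) + 1L, 4L) == 0L),
                    logical(1))
  if (any(empties))
    warning(sprintf("%d map(s) lack at least one compartment; analyses assume all four compartments are displayed",
                    sum(empties)))
  structure(list(maps = maps, scan_ids = scan_ids,
                 grader_ids = grader_ids, model_id = model_id,
                 height = dims[1, 1], width = dims[2, 1]),
            class = "grading_ensemble")
}

#' @export
print.grading_ensemble <- function(x, ...) {
  cat(sprintf("<grading_ensemble: %d scans x %d gradings (%d x %d pixels)>\n",
              length(x$scan_ids), length(x$grader_ids) + !is.null(x$model_id),
              x$height, x$width))
  cat("  graders:", paste(x$grader_ids, collapse = ", "),
      if (!is.null(x$model_id)) paste0("| model: ", x$model_id) else "", "\n")
  invisible(x)
}

ensemble_map <- function(e, scan_id, grading_id) {
  m <- e$maps[[paste(scan_id, grading_id, sep = "\r")]]
  if (is.null(m))
    stop(sprintf("no map for (%s, %s) in ensemble", scan_id, grading_id))
  m
}
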