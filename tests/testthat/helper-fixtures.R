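# Shared fixture builders. Everything is generated in code; the only stored
# bytes are a tiny synthetic paletted PNG (base64, below), since the png
# package cannot write palette chunks.

# random valid label map
rand_labelmap <- function(h, w, scan_id = "s1", grading_id = "g1", seed = 1) {
  m <- trex:::local_seed(seed,
    matrix(sample(0:3, h * w, replace = TRUE), h, w))
  labelmap(m, scan_id, grading_id)
}

# random monotone boundary set on a height-h grid
rand_boundaries <- function(h, w, seed = 1) {
  trex:::local_seed(seed, {
    m <- apply(matrix(sample(0:h, 3 * w, replace = TRUE), 3, w), 2, sort)
    boundary_set(m[1, ], m[2, ], m[3, ])
  })
}

flat_boundaries <- function(ilm, cci, csi, w) {
  boundary_set(rep(ilm, w), rep(cci, w), rep(csi, w))
}

# small ensemble of flat-boundary gradings with known per-grader offsets
offset_ensemble <- function(offsets, h = 64, w = 32, base = c(16, 32, 44),
                            n_scans = 2, model_offset = NULL) {
  maps <- list()
  scans <- sprintf("s%d", seq_len(n_scans))
  for (s in scans) {
    for (g in names(offsets)) {
      b <- flat_boundaries(base[1] + offsets[[g]][1], base[2] + offsets[[g]][2],
                           base[3] + offsets[[g]][3], w)
      maps[[length(maps) + 1L]] <- lines_to_labelmap(b, h, w, s, g)
    }
    if (!is.null(model_offset)) {
      b <- flat_boundaries(base[1] + model_offset[1], base[2] + model_offset[2],
                           base[3] + model_offset[3], w)
      maps[[length(maps) + 1L]] <- lines_to_labelmap(b, h, w, s, "cnn")
    }
  }
  grading_ensemble(maps, grader_ids = names(offsets),
                   model_id = if (is.null(model_offset)) NULL else "cnn")
}

# hand-build a distance_table from a data frame spec
make_table <- function(df) {
  class(df) <- c("distance_table", "data.frame")
  df
}

# synthetic 8x6 paletted PNG (indices 0..3 in row bands of two; palette:
# orange, blue, yellow, gray). Generated once with Pillow; inlined because
# binary fixtures cannot be stored.
paletted_png_fixture <- function() {
  b64 <- paste0(
    "iVBORw0KGgoAAAANSUhEUgAAAAYAAAAIAgMAAACnqGarAAAADFBMVEX/pQAAAP//",
    "/wCAgIAIQnZiAAAAHklEQVR4nGNgAAHG0N9MDAwsod+YGBgY/39kYmAAACvtBJg4",
    "MfhiAAAAAElFTkSuQmCC")
  path <- tempfile(fileext = ".png")
  writeBin(jsonlite::base64_dec(b64), path)
  path
}
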