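#' Non-overlapping tile decomposition of a whole-slide image
#'
#' A whole-slide image (WSI) is processed as a grid of non-overlapping
#' square tiles (1536 x 1536 px by default, the field-of-view size of the
#' workflow). Partial tiles at the right/bottom margins of a WSI whose
#' dimensions are not multiples of the tile size are dropped, so the grid
#' covers the largest prefix rectangle of the WSI.
#'
#' @param wsi_width,wsi_height WSI dimensions in pixels.
#' @param tile_size tile side length in pixels (default 1536).
#' @return An object of class `tile_grid`: a list with `wsi_width`,
#'   `wsi_height`, `tile_size` and `tiles`, a data frame with columns
#'   `row`, `col`, `x_offset`, `y_offset` (offsets are multiples of
#'   `tile_size`). A WSI smaller than one tile yields an empty grid with a
#'   warning.
#' @examples
#' tile_grid(4608, 3072)          # 3 x 2 = 6 tiles
#' tile_grid(4000, 4000, 1536)    # 2 x 2, 928-px margins dropped
#' @export
tile_grid <- function(wsi_width, wsi_height, tile_size = 1536) {
  assert_that(wsi_width > 0 && wsi_height > 0 && tile_size > 0,
              "dimensions and tile size must be positive")
  n_cols <- floor(wsi_width / tile_size)
  n_rows <- floor(wsi_height / tile_size)
  if (n_cols == 0L || n_rows == 0L) {
    warning(sprintf("WSI %dx%d smaller than tile size %d: empty grid",
                    wsi_width, wsi_height, tile_size), call. = FALSE)
    tiles <- data.frame(row = integer(0), col = integer(0),
                        x_offset = numeric(0), y_offset = numeric(0))
  } else {
    tiles <- expand.grid(col = seq_len(n_cols) - 1L, row = seq_len(n_rows) - 1L)
    tiles <- data.frame(row = tiles$row, col = tiles$col,
                        x_offset = tiles$col * tile_size,
                        y_offset = tiles$row * tile_size)
  }
  structure(list(wsi_width = wsi_width, wsi_height = wsi_height,
                 tile_size = tile_size, tiles = tiles),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid> %d x %d px WSI, tile %d px, %d tiles\n",
              x$wsi_width, x$wsi_height, x$tile_size, nrow(x$tiles)))
  invisible(x)
}

#' Translate tile-local boxes to WSI coordinates
#'
#' @param boxes a box data frame in tile-local coordinates.
#' @param tile one row of a [tile_grid()] `tiles` data frame, or any list
#'   with `x_offset` and `y_offset`.
#' @return The boxes with offsets added.
#' @export
to_wsi_coords <- function(boxes, tile) {
  boxes <- validate_box_set(boxes)
  boxes$xmin <- boxes$xmin + tile$x_offset
  boxes$xmax <- boxes$xmax + tile$x_offset
  boxes$ymin <- boxes$ymin + tile$y_offset
  boxes$ymax <- boxes$ymax + tile$y_offset
  boxes
}
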