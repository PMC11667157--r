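#' Electrode montage layout on a rectangular scalp grid
#'
#' A montage layout places each EEG channel at one cell of a coarse
#' rectangular grid approximating the 2D projection of the scalp. The
#' default layout positions the 64 channels of the international 10-10
#' system (as recorded by the BCI2000 amplifier at 160 Hz) on a
#' 10-row x 11-column grid: row 1 is the prefrontal line (Fp1, Fpz, Fp2)
#' and row 5 the full temporal-central line (T9, T7, C5 ... C6, T8, T10).
#' Cells without an electrode are zero-cells.
#'
#' @param placement data.frame with columns `channel` (1-based index into
#'   the channel order of a recording), `name` (electrode label), `row`,
#'   `col` (1-based grid cell).
#' @param grid_shape integer vector `c(rows, cols)`.
#' @return An object of class `montage_layout`.
#' @seealso [default_montage()], [build_topology()]
#' @export
montage_layout <- function(placement, grid_shape = c(10L, 11L)) {
  stopifnot(is.data.frame(placement),
            all(c("channel", "name", "row", "col") %in% names(placement)))
  placement <- placement[order(placement$channel), , drop = FALSE]
  if (!identical(as.integer(placement$channel), seq_len(nrow(placement))))
    stop("placement must contain each channel index 1..n exactly once")
  if (any(placement$row < 1L | placement$row > grid_shape[1]) ||
      any(placement$col < 1L | placement$col > grid_shape[2]))
    stop("placement contains cells outside the grid")
  cell <- paste(placement$row, placement$col)
  if (anyDuplicated(cell))
    stop("two channels share a grid cell: ", cell[duplicated(cell)][1])
  structure(list(placement = placement,
                 grid_shape = as.integer(grid_shape)),
            class = "montage_layout")
}

#' @export
print.montage_layout <- function(x, ...) {
  cat(sprintf("<montage_layout> %d channels on a %d x %d grid\n",
              nrow(x$placement), x$grid_shape[1], x$grid_shape[2]))
  invisible(x)
}

#' Read a montage layout from a CSV placement table
#'
#' The placement table is deliberately an editable plain-text file so that
#' montages can be corrected or remapped without code changes.
#'
#' @param path CSV file with columns channel, name, row, col.
#' @inheritParams montage_layout
#' @return A `montage_layout`.
#' @export
read_montage <- function(path, grid_shape = c(10L, 11L)) {
  montage_layout(utils::read.csv(path, stringsAsFactors = FALSE), grid_shape)
}

#' Default 64-channel 10-10 montage
#'
#' @return The packaged 64-channel layout on the 10 x 11 grid.
#' @export
default_montage <- function() {
  read_montage(system.file("extdata", "montage_64_1010.csv",
                           package = "mi3dnet", mustWork = TRUE))
}

#' Channel names of a montage, in channel order
#' @param layout a `montage_layout`.
#' @return Character vector of electrode labels.
#' @export
montage_channels <- function(layout) {
  stopifnot(inherits(layout, "montage_layout"))
  layout$placement$name
}

# Normalize electrode labels for matching: strip trailing dots (as used in
# some EDF exports) and case-fold.
normalize_ch_names <- function(x) toupper(gsub("[. ]+$", "", x))
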