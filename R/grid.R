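#' Construct a rectangular electrode array
#'
#' Builds the geometry of a single rows x cols electrode array with
#' row-major channel numbering. Row 1 is taken as the dorsal edge of
#' the array; users whose physical layout is flipped can relabel rows
#' before constructing the grid.
#'
#' @param rows,cols array dimensions (positive integers).
#' @param pitch centre-to-centre electrode distance in mm (default 2.5).
#' @param arrayId label of the array (e.g. "TC", "dmPFC").
#' @param location per-channel "surface"/"sulcal" flag, recycled.
#' @param region per-channel free-text region label, recycled.
#' @return an [ElectrodeGrid-class].
#' @examples
#' makeGrid(8, 16, arrayId = "TC")     # 128-channel temporal array
#' makeGrid(8, 8, arrayId = "dmPFC")   # 64-channel prefrontal array
#' @export
makeGrid <- function(rows, cols, pitch = 2.5, arrayId = "A",
                     location = "surface", region = arrayId) {
  if (length(rows) != 1L || length(cols) != 1L || rows < 1 || cols < 1 ||
      rows != round(rows) || cols != round(cols))
    stop("rows and cols must be positive integers")
  n <- rows * cols
  ch <- data.frame(
    channel = seq_len(n),
    row = rep(seq_len(rows), each = cols),
    col = rep(seq_len(cols), times = rows),
    array = arrayId,
    location = rep_len(location, n),
    region = rep_len(region, n),
    stringsAsFactors = FALSE)
  new("ElectrodeGrid", channels = ch, pitch = pitch)
}

#' Combine electrode arrays into one session grid
#'
#' Concatenates the channel tables of several arrays, renumbering
#' channels consecutively. Array ids must be distinct.
#'
#' @param ... [ElectrodeGrid-class] objects with equal pitch.
#' @return a combined [ElectrodeGrid-class].
#' @examples
#' g <- combineGrids(makeGrid(8, 16, arrayId = "TC"),
#'                   makeGrid(8, 8, arrayId = "dmPFC"))
#' nChannels(g)  # 192
#' @export
combineGrids <- function(...) {
  grids <- list(...)
  stopifnot(length(grids) >= 1L)
  pitch <- grids[[1]]@pitch
  tabs <- lapply(grids, function(g) {
    stopifnot(is(g, "ElectrodeGrid"))
    if (abs(g@pitch - pitch) > 1e-9) stop("all arrays must share the same pitch")
    g@channels
  })
  ids <- unlist(lapply(tabs, function(t) unique(t$array)))
  if (anyDuplicated(ids)) stop("array ids must be distinct across grids")
  ch <- do.call(rbind, tabs)
  ch$channel <- seq_len(nrow(ch))
  new("ElectrodeGrid", channels = ch, pitch = pitch)
}

#' Default two-array session geometry
#'
#' The stock recording layout emulated by the synthetic generator: an
#' 8 x 16 temporal-cortex array plus an 8 x 8 dorsomedial prefrontal
#' array at 2.5 mm pitch, 192 channels in total.
#'
#' @return an [ElectrodeGrid-class] with arrays "TC" and "dmPFC".
#' @export
defaultSessionGrid <- function() {
  combineGrids(makeGrid(8, 16, arrayId = "TC"),
               makeGrid(8, 8, arrayId = "dmPFC"))
}

# Channel id at (array, row, col), or NA when off the array.
gridChannelAt <- function(grid, array, row, col) {
  ch <- grid@channels
  hit <- ch$channel[ch$array == array & ch$row == row & ch$col == col]
  if (length(hit)) hit[1] else NA_integer_
}

# 4-neighbourhood (same array) of a channel; used for topography peaks.
gridNeighbors <- function(grid, channel) {
  ch <- grid@channels
  me <- ch[ch$channel == channel, ]
  if (nrow(me) != 1L) stop("unknown channel: ", channel)
  nb <- c(gridChannelAt(grid, me$array, me$row - 1L, me$col),
          gridChannelAt(grid, me$array, me$row + 1L, me$col),
          gridChannelAt(grid, me$array, me$row, me$col - 1L),
          gridChannelAt(grid, me$array, me$row, me$col + 1L))
  nb[!is.na(nb)]
}
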