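# Plain-text serialization of the epoch container: a CSV matrix of
# the voltage data plus a JSON sidecar carrying sampling, labels,
# grid geometry and provenance.

#' Write trial epochs to a text container
#'
#' Stores the voltage array as `<stem>_data.csv` (one row per
#' (trial, channel), samples across columns) and everything else --
#' dimensions, sampling rate, epoch window, labels, grid table, pitch
#' and provenance -- as `<stem>_meta.json`.
#'
#' @param epochs a [TrialEpochs-class].
#' @param stem file path stem (without extension).
#' @return the stem, invisibly.
#' @export
writeEpochs <- function(epochs, stem) {
  stopifnot(is(epochs, "TrialEpochs"))
  d <- dim(epochs@data)
  flat <- matrix(aperm(epochs@data, c(3, 2, 1)), nrow = d[1] * d[2],
                 ncol = d[3], byrow = TRUE)
  data.table::fwrite(data.table::as.data.table(flat),
                     paste0(stem, "_data.csv"), col.names = FALSE)
  meta <- list(
    dims = d, fs = epochs@fs, t0 = epochs@times[1],
    labels = as.character(epochs@labels),
    labelLevels = levels(epochs@labels),
    provenance = epochs@provenance)
  if (!is.null(epochs@grid)) {
    meta$grid <- channelTable(epochs@grid)
    meta$pitch <- epochs@grid@pitch
  }
  jsonlite::write_json(meta, paste0(stem, "_meta.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(stem)
}

#' Read trial epochs from a text container
#'
#' @param stem file path stem used by [writeEpochs()].
#' @return a [TrialEpochs-class].
#' @export
readEpochs <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"),
                              simplifyVector = TRUE)
  d <- as.integer(meta$dims)
  flat <- as.matrix(data.table::fread(paste0(stem, "_data.csv"),
                                      header = FALSE))
  dat <- aperm(array(t(flat), c(d[3], d[2], d[1])), c(3, 2, 1))
  grid <- NULL
  if (!is.null(meta$grid)) {
    tab <- as.data.frame(meta$grid, stringsAsFactors = FALSE)
    grid <- new("ElectrodeGrid", channels = tab, pitch = meta$pitch)
  }
  new("TrialEpochs", data = dat, fs = meta$fs,
      times = meta$t0 + (seq_len(d[3]) - 1L) / meta$fs,
      labels = factor(meta$labels, levels = meta$labelLevels),
      grid = grid, provenance = as.character(meta$provenance))
}
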