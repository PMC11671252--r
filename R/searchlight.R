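# Spatially resolved decoding: sliding 2 x 2 electrode regions of
# interest over each array, voltage-domain feature construction and
# per-ROI accuracy maps with bootstrap significance.

#' Enumerate 2 x 2 searchlight regions of interest
#'
#' All contiguous 2 x 2 electrode blocks of every array, stride 1, in
#' row-major order; an array of r x c electrodes yields
#' (r - 1) x (c - 1) ROIs. ROIs never straddle arrays.
#'
#' @param grid an [ElectrodeGrid-class].
#' @return data.frame with `array`, `roiRow`, `roiCol` (top-left
#'   corner), member channels `ch1`..`ch4` and the ROI centre in grid
#'   units (`centerRow`, `centerCol`).
#' @export
enumerateRois <- function(grid) {
  stopifnot(is(grid, "ElectrodeGrid"))
  tab <- channelTable(grid)
  rois <- list()
  for (a in unique(tab$array)) {
    sub <- tab[tab$array == a, ]
    R <- max(sub$row); C <- max(sub$col)
    if (R < 2 || C < 2)
      stop(sprintf("array '%s' is smaller than 2 x 2: no searchlight ROI", a))
    for (r in seq_len(R - 1)) for (cc in seq_len(C - 1)) {
      rois[[length(rois) + 1L]] <- data.frame(
        array = a, roiRow = r, roiCol = cc,
        ch1 = gridChannelAt(grid, a, r, cc),
        ch2 = gridChannelAt(grid, a, r, cc + 1L),
        ch3 = gridChannelAt(grid, a, r + 1L, cc),
        ch4 = gridChannelAt(grid, a, r + 1L, cc + 1L),
        centerRow = r + 0.5, centerCol = cc + 0.5,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rois)
}

#' Voltage features of one searchlight ROI
#'
#' Per trial, the raw voltage samples of the four member channels
#' inside the window are concatenated (window endpoints inclusive).
#' The default window -100 ms to 2000 ms at 500 Hz gives
#' 4 x 1051 = 4204 features per trial.
#'
#' @param epochs a [TrialEpochs-class].
#' @param members integer(4) member channel ids.
#' @param window numeric(2) feature window in seconds.
#' @return trials x features numeric matrix.
#' @export
roiFeatures <- function(epochs, members, window = c(-0.1, 2)) {
  stopifnot(is(epochs, "TrialEpochs"))
  idx <- timesInWindow(epochs@times, window)
  if (!length(idx) || window[1] < epochs@times[1] - 0.5 / epochs@fs ||
      window[2] > epochs@times[length(epochs@times)] + 0.5 / epochs@fs)
    stop("feature window lies outside the epoch")
  nt <- dim(epochs@data)[1]
  feats <- matrix(0, nt, length(members) * length(idx))
  for (k in seq_along(members)) {
    feats[, (k - 1) * length(idx) + seq_along(idx)] <-
      epochs@data[, members[k], idx]
  }
  feats
}

#' Searchlight decoding map over the electrode grids
#'
#' Decodes the trial category from each ROI's voltage features with a
#' stratified 5-fold linear SVM, attaches bootstrap significance per
#' ROI, adjusts p-values by FDR over all ROIs of all arrays jointly,
#' and highlights ROIs whose accuracy exceeds the per-array 95th
#' percentile (linear interpolation between order statistics; ties at
#' the threshold are included).
#'
#' @param epochs a [TrialEpochs-class] with a grid.
#' @param window feature window in seconds.
#' @param nBoot bootstrap iterations per ROI (0 = no inference).
#' @param nFolds folds for the observed accuracy.
#' @param q FDR level.
#' @param topPercentile per-array highlight percentile (default 0.95).
#' @param seed RNG seed.
#' @return data.frame (the ROI table of [enumerateRois()]) extended
#'   with `accuracy`, `p`, `padj`, `significant` and `top` columns.
#' @export
searchlightDecode <- function(epochs, window = c(-0.1, 2), nBoot = 1000L,
                              nFolds = 5L, q = 0.05, topPercentile = 0.95,
                              seed = NULL) {
  stopifnot(is(epochs, "TrialEpochs"))
  if (is.null(epochs@grid)) stop("an electrode grid is required")
  rois <- enumerateRois(epochs@grid)
  labels <- epochs@labels
  n <- nrow(rois)
  rois$accuracy <- NA_real_
  rois$p <- NA_real_
  # one seeded fold/split assignment shared by every ROI, so that maps
  # are comparable across ROIs and equivariant to grid relabeling
  for (r in seq_len(n)) {
    members <- unlist(rois[r, c("ch1", "ch2", "ch3", "ch4")])
    feats <- roiFeatures(epochs, members, window)
    rois$accuracy[r] <- decodePoint(feats, labels, nFolds, seed = seed)$accuracy
    if (nBoot > 0) {
      bs <- bootstrapSignificance(feats, labels, nBoot = nBoot,
                                  nFolds = nFolds, seed = seed)
      rois$p[r] <- bs$p
    }
  }
  if (nBoot > 0) {
    adj <- fdrBH(rois$p, q)
    rois$padj <- adj$padj
    rois$significant <- adj$significant
  } else {
    rois$padj <- NA_real_
    rois$significant <- NA
  }
  rois$top <- FALSE
  for (a in unique(rois$array)) {
    sel <- rois$array == a
    thr <- quantile(rois$accuracy[sel], topPercentile, type = 7)
    rois$top[sel] <- rois$accuracy[sel] >= thr
  }
  rois
}
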