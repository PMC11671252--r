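# Signal conditioning: zero-phase band-limiting, resampling,
# high-pass, common-average re-referencing and bipolar derivation.
# All offline filters are zero-phase FIR (windowed-sinc applied
# forward and backward); causal-filter phase shifts would bias the
# directed-connectivity stage downstream.

#' Filtering specification for the conditioning chain
#'
#' @param lowpassPreHz anti-alias low-pass cutoff applied at the input
#'   rate (default 220 Hz).
#' @param resampleToHz target sampling rate (default 500 Hz).
#' @param highpassHz high-pass cutoff applied after resampling
#'   (default 1 Hz).
#' @param notchHz optional line-noise notch frequency (NULL = off; the
#'   synthetic generator produces no line noise by default).
#' @return a list of class `"filterSpec"`.
#' @export
filterSpec <- function(lowpassPreHz = 220, resampleToHz = 500,
                       highpassHz = 1, notchHz = NULL) {
  stopifnot(lowpassPreHz > 0, resampleToHz > 0, highpassHz >= 0)
  if (lowpassPreHz >= resampleToHz)
    stop("low-pass cutoff must lie below the target sampling rate")
  structure(list(lowpassPreHz = lowpassPreHz, resampleToHz = resampleToHz,
                 highpassHz = highpassHz, notchHz = notchHz),
            class = "filterSpec")
}

# Small rational approximation p/q of a resampling ratio.
rationalRatio <- function(x, maxDen = 10000L) {
  for (q in seq_len(maxDen)) {
    p <- x * q
    if (abs(p - round(p)) < 1e-9) return(c(as.integer(round(p)), q))
  }
  stop("resampling ratio has no small rational approximation")
}

# Zero-phase FIR filtering of a trials x channels x samples array.
# `type` and `w` as in signal::fir1 (normalized cutoff(s), 0..1).
firFiltfilt <- function(dat, order, w, type) {
  b <- signal::fir1(order, w, type = type)
  ns <- dim(dat)[3]
  if (ns <= 3 * (order + 1))
    stop(sprintf("epoch (%d samples) shorter than the filter warm-up (%d taps, zero-phase)",
                 ns, order + 1))
  nt <- dim(dat)[1]; nch <- dim(dat)[2]
  out <- dat
  for (tr in seq_len(nt)) for (ch in seq_len(nch))
    out[tr, ch, ] <- signal::filtfilt(b, dat[tr, ch, ])
  out
}

#' Condition raw epochs: band-limit, resample, high-pass
#'
#' Applies the offline signal-conditioning chain: a zero-phase FIR
#' low-pass at `lowpassPreHz` at the input rate, resampling to
#' `resampleToHz` (plain decimation for integer ratios, polyphase
#' resampling otherwise), a zero-phase FIR high-pass at `highpassHz`,
#' and an optional IIR notch. Passband content is preserved within
#' about 1 dB; the processing log is appended to the provenance.
#'
#' @param epochs a [TrialEpochs-class].
#' @param spec a [filterSpec()].
#' @return conditioned [TrialEpochs-class] at the target rate.
#' @export
conditionSignal <- function(epochs, spec = filterSpec()) {
  stopifnot(is(epochs, "TrialEpochs"), inherits(spec, "filterSpec"))
  fs <- epochs@fs
  if (fs < 2 * spec$lowpassPreHz)
    stop("input sampling rate must be at least twice the anti-alias cutoff")
  dat <- epochs@data
  # anti-alias low-pass at the input rate
  lpOrder <- 2L * floor(3.3 / (100 / fs) / 2)     # ~100 Hz transition band
  lpOrder <- min(lpOrder, 2L * floor((dim(dat)[3] - 2) / 6))
  dat <- firFiltfilt(dat, lpOrder, spec$lowpassPreHz / (fs / 2), "low")
  # resample
  target <- spec$resampleToHz
  if (abs(fs - target) > 1e-9) {
    if (abs(fs / target - round(fs / target)) < 1e-9) {
      q <- as.integer(round(fs / target))
      keep <- seq(1L, dim(dat)[3], by = q)
      dat <- dat[, , keep, drop = FALSE]
    } else {
      pq <- rationalRatio(target / fs)
      ns2 <- floor(dim(dat)[3] * pq[1] / pq[2])
      out <- array(0, c(dim(dat)[1], dim(dat)[2], ns2))
      for (tr in seq_len(dim(dat)[1])) for (ch in seq_len(dim(dat)[2]))
        out[tr, ch, ] <- signal::resample(dat[tr, ch, ], pq[1], pq[2])[seq_len(ns2)]
      dat <- out
    }
  }
  times <- epochs@times[1] + (seq_len(dim(dat)[3]) - 1L) / target
  # high-pass at the output rate
  if (spec$highpassHz > 0) {
    hpOrder <- min(800L, 2L * floor((dim(dat)[3] - 2) / 6))
    dat <- firFiltfilt(dat, hpOrder, spec$highpassHz / (target / 2), "high")
  }
  if (!is.null(spec$notchHz)) {
    w <- spec$notchHz / (target / 2)
    bt <- signal::butter(2, c(w * 0.96, w * 1.04), type = "stop")
    for (tr in seq_len(dim(dat)[1])) for (ch in seq_len(dim(dat)[2]))
      dat[tr, ch, ] <- signal::filtfilt(bt, dat[tr, ch, ])
  }
  new("TrialEpochs", data = dat, fs = target, times = times,
      labels = epochs@labels, grid = epochs@grid,
      provenance = c(epochs@provenance,
                     sprintf("conditionSignal(lp=%g, fs=%g->%g, hp=%g%s)",
                             spec$lowpassPreHz, fs, target, spec$highpassHz,
                             if (is.null(spec$notchHz)) ""
                             else sprintf(", notch=%g", spec$notchHz))))
}

#' Common-average re-referencing per array
#'
#' Subtracts, per array, sample and trial, the mean across that
#' array's channels. Arrays are independent: re-referencing one leaves
#' the others untouched. Idempotent.
#'
#' @param epochs a [TrialEpochs-class] with a grid.
#' @param grid optional [ElectrodeGrid-class] overriding the epochs' grid.
#' @return re-referenced [TrialEpochs-class].
#' @export
rereferenceCommonAverage <- function(epochs, grid = NULL) {
  stopifnot(is(epochs, "TrialEpochs"))
  grid <- grid %||% epochs@grid
  if (is.null(grid)) stop("an electrode grid is required")
  tab <- channelTable(grid)
  dat <- epochs@data
  for (a in unique(tab$array)) {
    chs <- tab$channel[tab$array == a]
    if (length(chs) < 2)
      stop(sprintf("array '%s' has a single channel: average reference undefined", a))
    avg <- apply(dat[, chs, , drop = FALSE], c(1, 3), mean)
    for (ch in chs) dat[, ch, ] <- dat[, ch, ] - avg
  }
  new("TrialEpochs", data = dat, fs = epochs@fs, times = epochs@times,
      labels = epochs@labels, grid = grid,
      provenance = c(epochs@provenance, "rereferenceCommonAverage()"))
}

#' Vertical bipolar derivation at selected sites
#'
#' Derives, for each selected site, the difference between the site
#' and its immediately dorsal electrode in the same column ("lane") of
#' its array; a site at the dorsal end of a column (row 1) is instead
#' referenced to its immediately ventral electrode. The derived
#' channels inherit the site's grid position.
#'
#' @param epochs a [TrialEpochs-class] with a grid.
#' @param sites channel ids to derive.
#' @param grid optional [ElectrodeGrid-class] overriding the epochs' grid.
#' @return a [TrialEpochs-class] with one derived channel per site.
#' @export
bipolarDerive <- function(epochs, sites, grid = NULL) {
  stopifnot(is(epochs, "TrialEpochs"))
  grid <- grid %||% epochs@grid
  if (is.null(grid)) stop("an electrode grid is required")
  tab <- channelTable(grid)
  nt <- dim(epochs@data)[1]; ns <- dim(epochs@data)[3]
  out <- array(0, c(nt, length(sites), ns))
  neighbors <- integer(length(sites))
  for (s in seq_along(sites)) {
    me <- tab[tab$channel == sites[s], ]
    if (nrow(me) != 1L) stop("unknown site channel: ", sites[s])
    if (max(tab$row[tab$array == me$array]) < 2)
      stop(sprintf("array '%s' has a single row: no same-column neighbour", me$array))
    nb <- if (me$row > 1L) gridChannelAt(grid, me$array, me$row - 1L, me$col)
          else gridChannelAt(grid, me$array, me$row + 1L, me$col)
    if (is.na(nb)) stop("no same-column neighbour for site ", sites[s])
    neighbors[s] <- nb
    out[, s, ] <- epochs@data[, sites[s], ] - epochs@data[, nb, ]
  }
  siteTab <- tab[match(sites, tab$channel), ]
  siteTab$channel <- seq_along(sites)
  siteTab$region <- sprintf("%s-bipolar", siteTab$region)
  rownames(siteTab) <- NULL
  # positions are kept for reference; the derived table is not a full
  # rectangular array, so it is attached as metadata rather than a grid
  derived <- new("TrialEpochs", data = out, fs = epochs@fs,
                 times = epochs@times, labels = epochs@labels, grid = NULL,
                 provenance = c(epochs@provenance,
                                sprintf("bipolarDerive(sites=%s; refs=%s)",
                                        paste(sites, collapse = ","),
                                        paste(neighbors, collapse = ","))))
  attr(derived, "sites") <- sites
  attr(derived, "references") <- neighbors
  attr(derived, "siteTable") <- siteTab
  derived
}
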