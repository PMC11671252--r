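# Accessor generics and show methods.

#' Number of channels
#' @param x an object with channels
#' @return integer channel count
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Number of trials
#' @param x an object with trials
#' @return integer trial count
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' Channel metadata table
#' @param x an object carrying electrode geometry
#' @return data.frame with one row per channel
#' @export
setGeneric("channelTable", function(x) standardGeneric("channelTable"))

#' Trial category labels
#' @param x an object with per-trial labels
#' @return factor of labels
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))

#' Sampling rate in Hz
#' @param x an object with a time base
#' @return numeric sampling rate
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Time axis in seconds
#' @param x an object with a time base
#' @return numeric vector of times
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))

#' Raw data array
#' @param x a data container
#' @return the underlying array
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' Electrode grid reference
#' @param x a container carrying a grid
#' @return an [ElectrodeGrid-class] or NULL
#' @export
setGeneric("electrodeGrid", function(x) standardGeneric("electrodeGrid"))

#' @describeIn ElectrodeGrid channel count
#' @param x object
#' @export
setMethod("nChannels", "ElectrodeGrid", function(x) nrow(x@channels))

#' @describeIn ElectrodeGrid channel metadata table
#' @export
setMethod("channelTable", "ElectrodeGrid", function(x) x@channels)

#' @describeIn TrialEpochs channel count
#' @export
setMethod("nChannels", "TrialEpochs", function(x) dim(x@data)[2])

#' @describeIn TrialEpochs trial count
#' @export
setMethod("nTrials", "TrialEpochs", function(x) dim(x@data)[1])

#' @describeIn TrialEpochs per-trial labels
#' @export
setMethod("trialLabels", "TrialEpochs", function(x) x@labels)

#' @describeIn TrialEpochs sampling rate
#' @export
setMethod("samplingRate", "TrialEpochs", function(x) x@fs)

#' @describeIn TrialEpochs time axis
#' @export
setMethod("epochTimes", "TrialEpochs", function(x) x@times)

#' @describeIn TrialEpochs trials x channels x samples array
#' @export
setMethod("epochData", "TrialEpochs", function(x) x@data)

#' @describeIn TrialEpochs electrode grid
#' @export
setMethod("electrodeGrid", "TrialEpochs", function(x) x@grid)

setMethod("show", "ElectrodeGrid", function(object) {
  ch <- object@channels
  cat(sprintf("ElectrodeGrid: %d channels, pitch %.2f mm\n",
              nrow(ch), object@pitch))
  for (a in unique(ch$array)) {
    sub <- ch[ch$array == a, ]
    cat(sprintf("  array '%s': %d x %d (%d channels)\n",
                a, max(sub$row), max(sub$col), nrow(sub)))
  }
})

setMethod("show", "TrialEpochs", function(object) {
  d <- dim(object@data)
  cat(sprintf("TrialEpochs: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], object@fs))
  cat(sprintf("  time %.3f .. %.3f s; labels: %s\n",
              object@times[1], object@times[length(object@times)],
              paste(sprintf("%s=%d", levels(object@labels),
                            tabulate(object@labels)), collapse = ", ")))
  if (length(object@provenance))
    cat("  provenance:", paste(object@provenance, collapse = " | "), "\n")
})

setMethod("show", "SpectralPerturbation", function(object) {
  d <- dim(object@power)
  kind <- if (object@normalized) "normalized (dB)" else "raw"
  cat(sprintf("SpectralPerturbation (%s): %s; %d freqs x %d times\n",
              kind, paste(d, collapse = " x "),
              length(object@freqs), length(object@times)))
  cat(sprintf("  freq %.2f .. %.2f Hz; time %.3f .. %.3f s\n",
              min(object@freqs), max(object@freqs),
              min(object@times), max(object@times)))
})

setMethod("show", "ICDecomposition", function(object) {
  cat(sprintf("ICDecomposition: %d components x %d channels, %d epochs of %d samples\n",
              nrow(object@unmixing), ncol(object@unmixing),
              object@nTrials, length(object@times)))
})

setMethod("show", "CrossSpectralDensity", function(object) {
  cat(sprintf("CrossSpectralDensity: %d sites, %d frequencies (0 .. %g Hz), %d tapers, %d epochs\n",
              length(object@sites), length(object@freqs),
              max(object@freqs), object@nTapers, object@nEpochs))
})

setMethod("show", "SpectralFactorization", function(object) {
  cat(sprintf("SpectralFactorization: %d sites, %d frequencies; %d iterations, residual %.2e\n",
              dim(object@H)[1], length(object@freqs),
              object@iterations, object@residual))
})

setMethod("show", "GCSpectra", function(object) {
  cat(sprintf("GCSpectra: %d sites (%s), %d frequencies %.1f .. %.1f Hz\n",
              length(object@sites), paste(object@sites, collapse = ", "),
              length(object@freqs), min(object@freqs), max(object@freqs)))
  if (length(object@threshold))
    cat(sprintf("  permutation thresholds from %d permutations\n", object@nPerm))
})
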