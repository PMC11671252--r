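# Linear classification of trial category from spectral (or voltage)
# features, with bootstrap and false-discovery-rate inference.
# Classifier: linear support-vector machine with the implementation's
# default regularization, trained on non-standardized features.

svmFit <- function(x, y) {
  e1071::svm(x = x, y = y, kernel = "linear", scale = FALSE)
}

svmAccuracy <- function(model, x, y) {
  mean(predict(model, x) == y)
}

# Proportion of the bootstrap distribution below chance. Held-out
# accuracies are quantized (multiples of 1/nTest), so values exactly
# at chance are split half-and-half (mid-p) instead of counting as
# evidence against the null.
bootP <- function(boot, chance = 0.5) {
  mean(boot < chance) + 0.5 * mean(boot == chance)
}

checkFeatures <- function(features, labels) {
  features <- as.matrix(features)
  labels <- droplevels(as.factor(labels))
  if (nrow(features) != length(labels))
    stop("one label per feature row is required")
  if (anyNA(features)) stop("features must not contain missing values")
  if (nlevels(labels) < 2) stop("both classes must be present")
  if (min(table(labels)) < 2) stop("at least 2 trials per class are required")
  list(features = features, labels = labels)
}

#' Cross-validated decoding accuracy at one feature set
#'
#' Trains a linear SVM in stratified k-fold cross-validation and
#' returns the mean held-out accuracy. Chance level is 0.5 for the
#' balanced two-class design; class imbalance triggers a warning but
#' no reweighting.
#'
#' @param features trials x features numeric matrix.
#' @param labels per-trial class labels (2 classes).
#' @param nFolds number of folds (default 5).
#' @param seed optional RNG seed controlling the fold assignment.
#' @return list with `accuracy`, per-fold `fold` accuracies, `nFolds`
#'   and `chance` (0.5).
#' @export
decodePoint <- function(features, labels, nFolds = 5L, seed = NULL) {
  chk <- checkFeatures(features, labels)
  features <- chk$features; labels <- chk$labels
  if (nFolds < 2) stop("nFolds must be at least 2")
  counts <- table(labels)
  if (max(counts) / min(counts) > 1.5)
    warning("classes are imbalanced; the 0.5 chance level assumes balance")
  folds <- withSeed(seed, stratifiedFolds(labels, nFolds))
  acc <- vapply(seq_len(nFolds), function(f) {
    tr <- folds != f
    if (nlevels(droplevels(labels[tr])) < 2) return(NA_real_)
    m <- svmFit(features[tr, , drop = FALSE], labels[tr])
    svmAccuracy(m, features[!tr, , drop = FALSE], labels[!tr])
  }, numeric(1))
  list(accuracy = mean(acc, na.rm = TRUE), fold = acc,
       nFolds = as.integer(nFolds), chance = 0.5)
}

#' Decoding accuracy at every time-frequency point
#'
#' Applies [decodePoint()] independently per (frequency, time) point
#' of a raw multitaper decomposition, using the non-normalized power
#' of all channels at that point as the feature vector.
#'
#' @param tfr a raw [SpectralPerturbation-class] (per-trial power).
#' @param labels per-trial class labels.
#' @param channels optional channel subset (e.g. one array).
#' @param nFolds folds for [decodePoint()].
#' @param seed RNG seed (fold assignment, fixed across points).
#' @return list with `accuracy` (freqs x times matrix), `freqs`, `times`.
#' @export
decodeTimeFreqMap <- function(tfr, labels, channels = NULL, nFolds = 5L,
                              seed = NULL) {
  stopifnot(is(tfr, "SpectralPerturbation"))
  if (tfr@normalized || length(dim(tfr@power)) != 4L)
    stop("a raw per-trial decomposition is required")
  pw <- tfr@power
  if (!is.null(channels)) pw <- pw[, channels, , , drop = FALSE]
  nf <- length(tfr@freqs); ntm <- length(tfr@times)
  acc <- matrix(NA_real_, nf, ntm, dimnames = list(NULL, NULL))
  for (f in seq_len(nf)) for (w in seq_len(ntm)) {
    feats <- pw[, , f, w]
    if (is.null(dim(feats))) feats <- matrix(feats, ncol = 1L)
    acc[f, w] <- decodePoint(feats, labels, nFolds, seed)$accuracy
  }
  list(accuracy = acc, freqs = tfr@freqs, times = tfr@times)
}

#' Bootstrap significance of decoding accuracy
#'
#' Splits trials into a stratified 80/20 train/test partition; per
#' iteration, resamples the training trials with replacement, trains
#' the classifier, and records its accuracy on the fixed held-out test
#' set. The p-value is the proportion of the bootstrap distribution
#' below the 0.5 chance level.
#'
#' @param features trials x features matrix.
#' @param labels per-trial class labels.
#' @param nBoot bootstrap iterations (default 1000; below 100 warns).
#' @param trainFrac training fraction of the initial split.
#' @param nFolds folds for the observed cross-validated accuracy and
#'   the optional per-iteration CV statistic.
#' @param statistic "test" records the held-out-test accuracy per
#'   iteration; "cv" records the mean k-fold CV accuracy on the
#'   resampled training set instead.
#' @param seed RNG seed.
#' @return list with observed `accuracy` (k-fold CV on all trials),
#'   bootstrap `median`, `ci` (95%), `p`, `boot` values and `chance`.
#' @export
bootstrapSignificance <- function(features, labels, nBoot = 1000L,
                                  trainFrac = 0.8, nFolds = 5L,
                                  statistic = c("test", "cv"),
                                  seed = NULL) {
  statistic <- match.arg(statistic)
  chk <- checkFeatures(features, labels)
  features <- chk$features; labels <- chk$labels
  if (nBoot < 100) warning("nBoot < 100: bootstrap CI will be unstable")
  observed <- decodePoint(features, labels, nFolds, seed)$accuracy
  res <- withSeed(seed, {
    test <- integer(0)
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      nTest <- max(1L, round(length(idx) * (1 - trainFrac)))
      test <- c(test, sample(idx, nTest))
    }
    train <- setdiff(seq_along(labels), test)
    boot <- numeric(nBoot)
    for (b in seq_len(nBoot)) {
      repeat {
        res <- sample(train, length(train), replace = TRUE)
        if (nlevels(droplevels(labels[res])) == 2) break
      }
      boot[b] <- if (statistic == "test") {
        m <- svmFit(features[res, , drop = FALSE], labels[res])
        svmAccuracy(m, features[test, , drop = FALSE], labels[test])
      } else {
        decodePoint(features[res, , drop = FALSE], labels[res], nFolds)$accuracy
      }
    }
    boot
  })
  ci <- if (nBoot >= 2) unname(quantile(res, c(0.025, 0.975))) else c(NA_real_, NA_real_)
  if (nBoot < 2) warning("degenerate bootstrap (nBoot < 2): CI undefined")
  list(accuracy = observed, median = median(res), ci = ci,
       p = bootP(res), boot = res, chance = 0.5)
}

#' Frequency-band decoding with bootstrap inference
#'
#' Decomposes the epochs with a longer window (default 0.5 s, step
#' 0.35 s), then, for each analysis window and frequency band, decodes
#' each (frequency, time) point inside the band and window and
#' summarizes the band by the median accuracy across those points.
#' With `nBoot > 0`, a per-band bootstrap (resampling the 80% training
#' trials, testing on the fixed 20%) yields a median, 95% CI and
#' p-value per band, FDR-adjusted across all bands and windows.
#'
#' @param epochs a [TrialEpochs-class].
#' @param bands named list of Hz intervals (default [frequencyBands()]).
#' @param windows named list of analysis windows in seconds; defaults
#'   to the transient (-98 to 602 ms) and sustained (1652 to 2352 ms)
#'   periods.
#' @param windowS,stepS,nTapers,timeBandwidth,freqRange decomposition
#'   parameters (defaults: 0.5 s window, 0.35 s step, 6 tapers at
#'   time-bandwidth 4, 1.5-150 Hz).
#' @param channels optional channel subset.
#' @param nBoot bootstrap iterations per band (0 = point estimate only).
#' @param nFolds folds for the observed accuracies.
#' @param q FDR level for the adjusted p-values.
#' @param seed RNG seed.
#' @return data.frame with one row per (window, band): median
#'   `accuracy`, bootstrap `median`, `ciLow`, `ciHigh`, `p`, `padj`,
#'   `nPoints`.
#' @export
bandDecoding <- function(epochs, bands = frequencyBands(),
                         windows = list(transient = c(-0.098, 0.602),
                                        sustained = c(1.652, 2.352)),
                         windowS = 0.5, stepS = 0.35, nTapers = 6L,
                         timeBandwidth = 4, freqRange = c(1.5, 150),
                         channels = NULL, nBoot = 1000L, nFolds = 5L,
                         q = 0.05, seed = NULL) {
  stopifnot(is(epochs, "TrialEpochs"))
  tfr <- multitaperTFR(epochs, windowS, stepS, nTapers, timeBandwidth,
                       freqRange, channels = channels)
  labels <- droplevels(as.factor(epochs@labels))
  pw <- tfr@power
  tol <- 1 / epochs@fs   # printed window bounds may sit a sample off-grid
  rows <- list()
  bootAcc <- list()
  withSeed(seed, {
    # one stratified 80/20 split shared across bands
    test <- integer(0)
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      test <- c(test, sample(idx, max(1L, round(length(idx) * 0.2))))
    }
    train <- setdiff(seq_along(labels), test)
    for (wn in names(windows)) {
      tidx <- timesInWindow(tfr@times, windows[[wn]], tol = tol)
      for (bn in names(bands)) {
        bw <- bands[[bn]]
        fidx <- which(tfr@freqs >= bw[1] & tfr@freqs <= bw[2])
        if (!length(fidx))
          stop(sprintf("band '%s' has no frequency points on the grid", bn))
        pts <- expand.grid(f = fidx, w = tidx)
        ptAcc <- vapply(seq_len(nrow(pts)), function(r) {
          decodePoint(pw[, , pts$f[r], pts$w[r]], labels, nFolds)$accuracy
        }, numeric(1))
        boot <- NULL
        if (nBoot > 0) {
          boot <- vapply(seq_len(nBoot), function(b) {
            repeat {
              res <- sample(train, length(train), replace = TRUE)
              if (nlevels(droplevels(labels[res])) == 2) break
            }
            median(vapply(seq_len(nrow(pts)), function(r) {
              feats <- pw[, , pts$f[r], pts$w[r]]
              m <- svmFit(feats[res, , drop = FALSE], labels[res])
              svmAccuracy(m, feats[test, , drop = FALSE], labels[test])
            }, numeric(1)))
          }, numeric(1))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          window = wn, band = bn, accuracy = median(ptAcc),
          median = if (is.null(boot)) NA_real_ else median(boot),
          ciLow = if (is.null(boot)) NA_real_ else unname(quantile(boot, 0.025)),
          ciHigh = if (is.null(boot)) NA_real_ else unname(quantile(boot, 0.975)),
          p = if (is.null(boot)) NA_real_ else bootP(boot),
          nPoints = nrow(pts), stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, rows)
  out$padj <- if (all(is.na(out$p))) NA_real_ else fdrBH(out$p, q)$padj
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up procedure; adjusted p-values are monotone and a
#' test is significant when its adjusted p-value is at most `q`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list with `padj` and logical `significant`.
#' @export
fdrBH <- function(p, q = 0.05) {
  if (!length(p)) return(list(padj = numeric(0), significant = logical(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  padj <- p.adjust(p, method = "BH")
  list(padj = padj, significant = !is.na(padj) & padj <= q)
}
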