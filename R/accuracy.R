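## accuracy_roc: TPR/FDR/ADR metrics, threshold sweeps, optimal and pooled
## cutoffs, summary ROC, chi-squared accuracy comparison.

#' Accuracy metrics from confusion counts
#'
#' TPR = tp/(tp+fn) (the agreement between histology and the image),
#' FDR = fp/(tp+fp) (the disagreement), and the agreement-disagreement
#' ratio ADR = tp/(fp+fn). ADR is Inf when there is no disagreement at all,
#' and FDR is 0 when nothing is predicted.
#'
#' @param c a \linkS4class{ConfusionCounts}.
#' @return named numeric c(tpr, fdr, adr).
#' @export
accuracyMetrics <- function(c) {
  tp <- tpCount(c); fp <- fpCount(c); fn <- fnCount(c)
  if (tp + fn == 0) stop("empty reference: tp + fn = 0")
  c(tpr = tp / (tp + fn),
    fdr = if (tp + fp == 0) 0 else fp / (tp + fp),
    adr = if (fp + fn == 0) Inf else tp / (fp + fn))
}

#' Agreement-disagreement ratio from the two rates
#'
#' For positive counts the ADR is determined by (TPR, FDR) alone:
#' ADR = 1 / (FDR/(1-FDR) + (1-TPR)/TPR). Scale-invariant in the
#' underlying pixel counts. Returns 0 at TPR = 0 or FDR = 1.
#'
#' @param tpr true positive rate in (0, 1].
#' @param fdr false discovery rate in [0, 1).
#' @return the ADR.
#' @export
adrFromRates <- function(tpr, fdr) {
  ifelse(tpr <= 0 | fdr >= 1, 0,
         1 / (fdr / (1 - fdr) + (1 - tpr) / tpr))
}

#' Threshold sweep: accuracy metrics at every integer threshold
#'
#' Repeats isolate-overlay-count for every integer threshold from 1 to the
#' image maximum, producing the raw material of the ROC analysis.
#'
#' @param image an \linkS4class{ImageGrid} (already co-registered with the
#'   reference, i.e. both in the CT frame).
#' @param referenceAligned binary matrix of the aligned histology mask.
#' @param seedXY region-growing seed (x, y).
#' @param connectivity 4 or 8.
#' @param ablationId identifier recorded on the sweep.
#' @return A \linkS4class{ThresholdSweep}.
#' @export
thresholdSweep <- function(image, referenceAligned, seedXY,
                           connectivity = 8, ablationId = "ablation") {
  if (!all(dim(gridValues(image)) == dim(referenceAligned)))
    stop("image and reference must have the same shape")
  v <- gridValues(image)
  vmax <- max(v[is.finite(v) & v != .MARKER_SENTINEL])
  thresholds <- seq_len(max(1L, as.integer(floor(vmax))))
  ref <- referenceAligned != 0
  refN <- sum(ref)
  rows <- vector("list", length(thresholds))
  for (i in seq_along(thresholds)) {
    iso <- isolateAblation(image, thresholds[i], seedXY, connectivity)
    p <- iso$mask != 0
    tp <- sum(p & ref); fp <- sum(p) - tp; fn <- refN - tp
    rows[[i]] <- c(thresholds[i], tp, fp, fn)
  }
  tb <- as.data.frame(do.call(rbind, rows))
  names(tb) <- c("threshold", "tp", "fp", "fn")
  tb$tpr <- tb$tp / (tb$tp + tb$fn)
  tb$fdr <- ifelse(tb$tp + tb$fp == 0, 0, tb$fp / (tb$tp + tb$fp))
  tb$adr <- ifelse(tb$fp + tb$fn == 0, Inf, tb$tp / (tb$fp + tb$fn))
  new("ThresholdSweep", ablationId = as.character(ablationId),
      modality = modality(image), table = tb)
}

#' Optimal display threshold of one sweep
#'
#' The threshold maximizing the agreement-disagreement ratio - the study's
#' own composite of agreement vs disagreement (specificity-based criteria
#' are unavailable without true negatives). Ties break toward the smallest
#' threshold.
#'
#' @param sweep a \linkS4class{ThresholdSweep}.
#' @return list(threshold, tpr, fdr, adr, found); \code{found = FALSE}
#'   (flagged no-optimum) when every threshold produced an empty mask.
#' @export
optimalThreshold <- function(sweep) {
  tb <- sweepTable(sweep)
  if (nrow(tb) == 0L) stop("empty sweep")
  if (all(tb$tp + tb$fp == 0))
    return(list(threshold = NA_real_, tpr = NA_real_, fdr = NA_real_,
                adr = NA_real_, found = FALSE))
  i <- which.max(tb$adr)
  list(threshold = tb$threshold[i], tpr = tb$tpr[i], fdr = tb$fdr[i],
       adr = tb$adr[i], found = TRUE)
}

#' Pool per-ablation metrics into a single row
#'
#' macro: unweighted mean of the per-ablation rates (each ablation counts
#' equally - this reproduces the published pooled rows); micro: metrics of
#' the summed pixel counts (each pixel counts equally).
#'
#' @param perAblation data.frame (or list) with columns/elements tpr, fdr,
#'   adr.
#' @param mode "macro" or "micro".
#' @param counts list of \linkS4class{ConfusionCounts}, required for micro.
#' @return named numeric c(tpr, fdr, adr).
#' @export
poolMetrics <- function(perAblation, mode = c("macro", "micro"),
                        counts = NULL) {
  mode <- match.arg(mode)
  if (is.list(perAblation) && !is.data.frame(perAblation))
    perAblation <- as.data.frame(do.call(rbind, perAblation))
  if (nrow(perAblation) == 0L) stop("no per-ablation metrics to pool")
  if (mode == "macro") {
    c(tpr = mean(perAblation$tpr), fdr = mean(perAblation$fdr),
      adr = mean(perAblation$adr))
  } else {
    if (is.null(counts)) stop("micro pooling requires the pixel counts")
    tot <- ConfusionCounts(sum(vapply(counts, tpCount, 0)),
                           sum(vapply(counts, fpCount, 0)),
                           sum(vapply(counts, fnCount, 0)))
    accuracyMetrics(tot)
  }
}

#' Pooled cutoff across the sweeps of one modality
#'
#' Selects the single threshold maximizing the macro-mean ADR across
#' ablations (evaluated on the intersection of the sweeps' threshold
#' ranges; ties toward the smallest threshold) and reports the pooled
#' metrics at that cutoff under both pooling modes.
#'
#' @param sweeps list of \linkS4class{ThresholdSweep} for one modality.
#' @return list(threshold, macro, micro, perAblation) where perAblation is
#'   a data.frame of each sweep's metrics at the pooled cutoff.
#' @export
pooledCutoff <- function(sweeps) {
  stopifnot(length(sweeps) >= 1L)
  mods <- unique(vapply(sweeps, function(s) s@modality, ""))
  if (length(mods) > 1L)
    stop("sweeps mix modalities (threshold units differ): ",
         paste(mods, collapse = ", "))
  grids <- lapply(sweeps, function(s) sweepTable(s)$threshold)
  common <- Reduce(intersect, grids)
  if (length(common) == 0L) stop("sweeps have disjoint threshold ranges")
  common <- sort(common)

  tabs <- lapply(sweeps, sweepTable)
  adrMat <- vapply(tabs, function(tb)
    tb$adr[match(common, tb$threshold)], numeric(length(common)))
  adrMat <- matrix(adrMat, nrow = length(common))
  objective <- rowMeans(adrMat)
  i <- which.max(objective)
  thr <- common[i]

  at <- lapply(tabs, function(tb) tb[tb$threshold == thr, , drop = FALSE])
  per <- do.call(rbind, at)
  per <- data.frame(ablation_id = vapply(sweeps, function(s) s@ablationId, ""),
                    per[, c("threshold", "tp", "fp", "fn", "tpr", "fdr",
                            "adr")],
                    row.names = NULL)
  counts <- lapply(at, function(r) ConfusionCounts(r$tp, r$fp, r$fn))
  list(threshold = thr,
       macro = poolMetrics(per, "macro"),
       micro = poolMetrics(per, "micro", counts = counts),
       perAblation = per)
}

#' Summary ROC across ablations
#'
#' Builds each ablation's empirical ROC in (FDR, TPR) space - the monotone
#' upper envelope of its achieved operating points, anchored at (0, 0) and
#' (1, 1), linearly interpolated - then vertically averages the curves on
#' a fixed FDR grid. The AUC is the trapezoidal area under the averaged
#' curve. Per-ablation operating points at their own optimal cutoffs are
#' recorded alongside.
#'
#' @param sweeps list of at least two \linkS4class{ThresholdSweep}.
#' @param fdrGrid grid on [0, 1] for the vertical averaging.
#' @return A \linkS4class{SummaryROC}.
#' @export
summaryROC <- function(sweeps, fdrGrid = seq(0, 1, by = 0.01)) {
  stopifnot(length(sweeps) >= 2L)
  curves <- vapply(sweeps, function(s) {
    tb <- sweepTable(s)
    pts <- rbind(c(0, 0), as.matrix(tb[, c("fdr", "tpr")]), c(1, 1))
    pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
    ## monotone upper envelope: best TPR achieved at or below each FDR
    env <- cummax(pts[, 2])
    keep <- !duplicated(pts[, 1], fromLast = TRUE)
    stats::approx(pts[keep, 1], env[keep], xout = fdrGrid,
                  rule = 2)$y
  }, numeric(length(fdrGrid)))
  meanTpr <- cummax(rowMeans(curves))
  auc <- pracma::trapz(fdrGrid, meanTpr)
  pts <- do.call(rbind, lapply(sweeps, function(s) {
    o <- optimalThreshold(s)
    data.frame(ablation_id = s@ablationId, threshold = o$threshold,
               fdr = o$fdr, tpr = o$tpr)
  }))
  new("SummaryROC", fdrGrid = fdrGrid, meanTpr = meanTpr,
      auc = min(max(auc, 0), 1), points = pts)
}

#' Chi-squared comparison of two modalities' pooled accuracies
#'
#' Builds the 2x2 table [correct = tp, error = fp + fn] per modality and
#' applies Pearson's chi-squared test without continuity correction
#' (1 df).
#'
#' @param countsA,countsB pooled \linkS4class{ConfusionCounts} of the two
#'   modalities.
#' @return named numeric c(statistic, p.value).
#' @export
compareAccuracy <- function(countsA, countsB) {
  tab <- rbind(c(tpCount(countsA), fpCount(countsA) + fnCount(countsA)),
               c(tpCount(countsB), fpCount(countsB) + fnCount(countsB)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in the 2x2 accuracy table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  c(statistic = unname(ct$statistic), p.value = unname(ct$p.value))
}
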