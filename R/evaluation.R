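#' One-vs-rest ROC AUC per category
#'
#' Treats each category in turn as positive against all others and
#' computes the area under the ROC curve of its probability (or score)
#' column, with ties handled by the trapezoidal rule. The macro AUC is
#' the mean over categories present in the labels.
#'
#' @param scores n x C numeric matrix (or data.frame) of per-sample
#'   scores; column names are the categories.
#' @param labels length-n character vector of true categories.
#' @return List with \code{per_category} (named AUC vector; \code{NA}
#'   for categories missing a positive or negative sample) and
#'   \code{macro}.
#' @export
rocAUC <- function(scores, labels) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) stop("scores must have category column names")
  if (nrow(scores) != length(labels))
    stop("one label per score row is required")
  auc <- vapply(colnames(scores), function(cl) {
    y <- as.integer(labels == cl)
    if (length(unique(y)) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(y, scores[, cl], quiet = TRUE,
                                   direction = "<")))
  }, numeric(1))
  list(per_category = auc, macro = mean(auc, na.rm = TRUE))
}

#' Positive predictive value (precision) per category
#'
#' @param predictions length-n character vector of predicted categories.
#' @param labels length-n character vector of true categories.
#' @return Named numeric vector TP/(TP+FP) per category; \code{NA} (with
#'   a warning) for categories never predicted.
#' @export
ppv <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("predictions and labels must have the same length")
  cats <- sort(unique(c(predictions, labels)))
  out <- vapply(cats, function(cl) {
    np <- sum(predictions == cl)
    if (np == 0) return(NA_real_)
    sum(predictions == cl & labels == cl) / np
  }, numeric(1))
  if (anyNA(out))
    warning(sprintf("no positive predictions for: %s",
                    paste(cats[is.na(out)], collapse = ", ")))
  out
}

.iou <- function(a0, a1, b0, b1) {
  inter <- max(0, min(a1, b1) - max(a0, b0))
  union <- (a1 - a0) + (b1 - b0) - inter
  if (union <= 0) return(0)
  inter / union
}

#' Segmental F1 at overlap threshold k
#'
#' Temporal-action-segmentation F1: predicted segments are greedily
#' matched (by decreasing IoU) one-to-one to ground-truth segments of
#' the same category with intersection-over-union at least
#' \code{overlapFrac}; matched pairs are true positives, unmatched
#' predictions false positives, unmatched truths false negatives, and
#' F1 = 2TP / (2TP + FP + FN), reported on a 0-100 scale. The commonly
#' reported F1@10 uses \code{overlapFrac = 0.10}.
#'
#' @param predEvents,trueEvents data.frames with columns
#'   \code{category}, \code{start_s}, \code{end_s}; per-category events
#'   must be non-overlapping.
#' @param overlapFrac IoU threshold in (0, 1] (default 0.10).
#' @return F1 score in [0, 100].
#' @export
segmentalF1 <- function(predEvents, trueEvents, overlapFrac = 0.10) {
  if (overlapFrac <= 0 || overlapFrac > 1)
    stop("overlapFrac must be in (0, 1]")
  tp <- 0L
  cats <- unique(c(predEvents$category, trueEvents$category))
  for (cl in cats) {
    p <- predEvents[predEvents$category == cl, , drop = FALSE]
    g <- trueEvents[trueEvents$category == cl, , drop = FALSE]
    if (!nrow(p) || !nrow(g)) next
    M <- outer(seq_len(nrow(p)), seq_len(nrow(g)),
               Vectorize(function(i, j)
                 .iou(p$start_s[i], p$end_s[i], g$start_s[j], g$end_s[j])))
    M <- rbind(M)
    while (TRUE) {
      best <- which(M == max(M), arr.ind = TRUE)[1, , drop = TRUE]
      if (M[best[1], best[2]] < overlapFrac) break
      tp <- tp + 1L
      M[best[1], ] <- -1
      M[, best[2]] <- -1
      if (all(M < 0)) break
    }
  }
  fp <- nrow(predEvents) - tp
  fn <- nrow(trueEvents) - tp
  if (tp + fp + fn == 0) return(100)
  100 * 2 * tp / (2 * tp + fp + fn)
}

#' Aggregate a metric over cross-validation folds
#'
#' @param values numeric vector of per-fold metric values.
#' @return List with \code{mean}, \code{sd} and \code{per_fold}.
#' @export
foldSummary <- function(values) {
  list(mean = mean(values), sd = stats::sd(values), per_fold = values)
}

#' Cross-validated metric report
#'
#' Runs [predictFold()] for every fold and summarizes one-vs-rest AUC
#' (per category and macro) and PPV across folds as mean and standard
#' deviation.
#'
#' @param samples list of labelled [VideoSample-class] objects.
#' @param splits output of [makeSplits()].
#' @param models list of trained [ActivityDecoder-class] objects (one
#'   per fold).
#' @return List with \code{auc_macro}, \code{auc_per_category},
#'   \code{ppv} fold summaries and the per-fold prediction tables.
#' @export
metricReport <- function(samples, splits, models) {
  stopifnot(length(splits) == length(models))
  cats <- models[[1]]@categories
  perFold <- lapply(seq_along(splits), function(f)
    predictFold(samples, splits[[f]], models[[f]]))
  aucs <- lapply(perFold, function(df)
    rocAUC(as.matrix(df[, cats, drop = FALSE]), df$label))
  ppvs <- lapply(perFold, function(df) {
    pred <- cats[max.col(as.matrix(df[, cats, drop = FALSE]),
                         ties.method = "first")]
    suppressWarnings(mean(ppv(pred, df$label), na.rm = TRUE))
  })
  aucCat <- t(vapply(aucs, function(a) a$per_category, numeric(length(cats))))
  colnames(aucCat) <- cats
  list(
    auc_macro = foldSummary(vapply(aucs, function(a) a$macro, numeric(1))),
    auc_per_category = apply(aucCat, 2, foldSummary, simplify = FALSE),
    ppv = foldSummary(unlist(ppvs)),
    predictions = perFold
  )
}
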