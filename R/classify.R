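#' Leave-one-out one-nearest-neighbor prediction
#'
#' Each record is assigned the class of its nearest neighbor in the distance
#' matrix, excluding itself. Distance ties are broken by the smallest matrix
#' index, so predictions are deterministic.
#'
#' @param d Symmetric labeled distance matrix (e.g. from [pcnv_dist()]).
#' @param labels Named character vector: record id -> true class. Must cover
#'   every matrix label.
#' @return Named character vector of predicted classes, in matrix order.
#' @export
one_nn_predict <- function(d, labels) {
  d <- validate_distmat(d)
  ids <- rownames(d)
  if (length(ids) < 2L) abort_input("need at least 2 records")
  missing <- setdiff(ids, names(labels))
  if (length(missing) > 0L)
    abort_input("no class label for: %s", paste(missing, collapse = ", "))
  truth <- labels[ids]
  if (length(unique(truth)) < 2L)
    abort_input("need at least 2 classes among the records")
  singles <- names(which(table(truth) == 1L))
  if (length(singles) > 0L)
    warning(sprintf(
      "class(es) with a single member cannot be self-predicted: %s",
      paste(singles, collapse = ", ")), call. = FALSE)
  pred <- vapply(seq_along(ids), function(i) {
    row <- d[i, ]
    row[i] <- Inf
    truth[[which.min(row)]]  # which.min takes the first (lowest-index) tie
  }, character(1L))
  stats::setNames(pred, ids)
}

#' One-vs-rest confusion counts per class
#'
#' @param truth,predicted Named character vectors over the same ids.
#' @return Data frame with columns `class`, `n` (true members), `TP`, `FN`,
#'   `FP`, `TN`, one row per class occurring in either vector.
#' @export
confusion_counts <- function(truth, predicted) {
  if (is.null(names(truth)) || is.null(names(predicted)))
    abort_input("truth and predicted must be named by record id")
  if (!setequal(names(truth), names(predicted)))
    abort_input("id mismatch between truth and predictions: %s",
                paste(union(setdiff(names(truth), names(predicted)),
                            setdiff(names(predicted), names(truth))),
                      collapse = ", "))
  predicted <- predicted[names(truth)]
  classes <- sort(unique(c(truth, predicted)))
  total <- length(truth)
  rows <- lapply(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    fp <- sum(truth != cl & predicted == cl)
    data.frame(class = cl, n = tp + fn, TP = tp, FN = fn, FP = fp,
               TN = total - tp - fn - fp)
  })
  do.call(rbind, rows)
}

#' Sensitivity, specificity and accuracy report
#'
#' Per class: sensitivity = TP/(TP+FN), specificity = TN/(FP+TN), and
#' accuracy = the fraction of the class's members predicted correctly (equal
#' to sensitivity under one-vs-rest tabulation). An `Ave.` row holds the
#' unweighted mean over classes; classes with no true members yield `NA`
#' metrics and are excluded from the averages with a warning. Values are kept
#' as proportions in [0, 1]; rounding to display percentages happens only in
#' [write_report()].
#'
#' @param counts Data frame from [confusion_counts()].
#' @return Data frame with columns `class`, `n`, `sensitivity`,
#'   `specificity`, `accuracy`; attribute `overall_accuracy` holds total
#'   correct / total records.
#' @export
classification_metrics <- function(counts) {
  need <- c("class", "n", "TP", "FN", "FP", "TN")
  if (!all(need %in% colnames(counts))) abort_input("invalid confusion counts")
  sens <- ifelse(counts$TP + counts$FN > 0, counts$TP / (counts$TP + counts$FN), NA_real_)
  spec <- ifelse(counts$FP + counts$TN > 0, counts$TN / (counts$FP + counts$TN), NA_real_)
  if (anyNA(sens))
    warning("class(es) with no true members excluded from averages: ",
            paste(counts$class[is.na(sens)], collapse = ", "), call. = FALSE)
  rep <- data.frame(class = counts$class, n = counts$n,
                    sensitivity = sens, specificity = spec, accuracy = sens)
  ave <- data.frame(class = "Ave.", n = sum(counts$n),
                    sensitivity = mean(sens, na.rm = TRUE),
                    specificity = mean(spec, na.rm = TRUE),
                    accuracy = mean(sens, na.rm = TRUE))
  out <- rbind(rep, ave)
  attr(out, "overall_accuracy") <- sum(counts$TP) / sum(counts$n)
  out
}

#' Classify a labeled dataset end to end
#'
#' Composes [compute_pcnv_matrix()], [pcnv_dist()], [one_nn_predict()],
#' [confusion_counts()] and [classification_metrics()].
#'
#' @param dataset A [pcnv_dataset] with labels.
#' @param strict Passed to [compute_pcnv_matrix()].
#' @return The metrics data frame, with the predictions in attribute
#'   `predicted`.
#' @export
classify_dataset <- function(dataset, strict = FALSE) {
  if (is.null(dataset$labels)) abort_input("dataset has no labels")
  d <- pcnv_dist(compute_pcnv_matrix(dataset, strict = strict))
  pred <- one_nn_predict(d, dataset$labels)
  truth <- dataset$labels[rownames(d)]
  out <- classification_metrics(confusion_counts(truth, pred))
  attr(out, "predicted") <- pred
  out
}

#' Write a classification report
#'
#' Writes a delimited table with columns Type, Number, Sens, Spec, Acc
#' (metrics as percentages rounded to 1 decimal place) and, when `json` is
#' given, a machine-readable JSON twin keeping full precision.
#'
#' @param metrics Data frame from [classification_metrics()].
#' @param path Output path for the delimited table.
#' @param json Optional output path for the JSON variant.
#' @param sep Field delimiter.
#' @return Invisibly, `path`.
#' @export
write_report <- function(metrics, path, json = NULL, sep = "\t") {
  pct <- function(x) ifelse(is.na(x), "NA", sprintf("%.1f", 100 * x))
  tab <- data.frame(Type = metrics$class, Number = metrics$n,
                    Sens = pct(metrics$sensitivity),
                    Spec = pct(metrics$specificity),
                    Acc = pct(metrics$accuracy))
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(json)) {
    payload <- list(classes = metrics,
                    overall_accuracy = attr(metrics, "overall_accuracy"))
    jsonlite::write_json(payload, json, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}
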