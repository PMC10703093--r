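#' Classification metrics from a confusion matrix
#'
#' Computes overall accuracy (trace / total) and macro-averaged
#' one-vs-rest sensitivity, specificity, precision and F1 from a K x K
#' count matrix with rows = true class and columns = predicted class.
#' Per-class F1 is the harmonic mean of that class's precision and
#' recall; macro values are unweighted means over classes (classes with
#' an undefined ratio, e.g. no predicted positives, contribute 0).
#'
#' @param cm square numeric count matrix, rows = truth.
#' @return list with `acc`, `sen`, `spe`, `pre`, `f1` and a `perClass`
#'   data.frame.
#' @examples
#' cm <- matrix(c(8, 0, 1, 1, 9, 0, 1, 1, 9), 3, 3)
#' confusionMetrics(cm)$acc  # 26/30
#' @export
confusionMetrics <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stopShape("confusion matrix must be square")
  if (any(cm < 0)) stopShape("confusion matrix counts must be >= 0")
  total <- sum(cm)
  if (total == 0) stopDegenerate("confusion matrix is empty")
  K <- nrow(cm)
  safe <- function(num, den) ifelse(den > 0, num / den, 0)
  per <- data.frame(class = if (!is.null(rownames(cm))) rownames(cm)
                            else paste0("class", seq_len(K)))
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  per$sen <- safe(tp, tp + fn)
  per$spe <- safe(tn, tn + fp)
  per$pre <- safe(tp, tp + fp)
  per$f1 <- safe(2 * per$pre * per$sen, per$pre + per$sen)
  list(acc = sum(tp) / total, sen = mean(per$sen), spe = mean(per$spe),
       pre = mean(per$pre), f1 = mean(per$f1), perClass = per)
}

#' One-vs-rest ROC curves and macro AUC
#'
#' Builds a per-class ROC curve (that class against the rest) from
#' predicted class probabilities, using pROC, and macro-averages the AUC.
#'
#' @param probs (N, K) matrix of class probabilities, columns named by
#'   class.
#' @param labels character vector of true labels, length N.
#' @return list with `curves` (named list of data.frames with columns
#'   `fpr`, `tpr`) and `auc` (macro one-vs-rest AUC).
#' @export
rocCurves <- function(probs, labels) {
  classes <- colnames(probs)
  stopifnot(!is.null(classes), length(labels) == nrow(probs))
  curves <- list()
  aucs <- numeric(0)
  for (cl in classes) {
    resp <- factor(ifelse(labels == cl, "pos", "neg"),
                   levels = c("neg", "pos"))
    if (length(unique(resp)) < 2L) next
    r <- pROC::roc(resp, probs[, cl], quiet = TRUE, direction = "<",
                   levels = c("neg", "pos"))
    curves[[cl]] <- data.frame(fpr = rev(1 - r$specificities),
                               tpr = rev(r$sensitivities))
    aucs <- c(aucs, as.numeric(pROC::auc(r)))
  }
  list(curves = curves, auc = if (length(aucs)) mean(aucs) else NA_real_)
}

# Assemble an AmsfMetrics object from truth, predictions, probabilities.
buildMetrics <- function(truth, pred, probs, classes) {
  cm <- table(factor(truth, levels = classes),
              factor(pred, levels = classes))
  cm <- matrix(as.integer(cm), length(classes), length(classes),
               dimnames = list(truth = classes, predicted = classes))
  met <- confusionMetrics(cm)
  roc <- if (!is.null(probs)) rocCurves(probs, truth)
         else list(curves = list(), auc = NA_real_)
  new("AmsfMetrics", confusion = cm, acc = met$acc, sen = met$sen,
      spe = met$spe, pre = met$pre, f1 = met$f1, perClass = met$perClass,
      roc = roc$curves, auc = roc$auc)
}
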