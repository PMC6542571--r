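# Evaluation: macro-averaged multiclass measures over a 6-class confusion
# matrix and the per-sample class probability graph for expert review.

#' Class colour map of the probability graph
#'
#' Classes 0 to 5 are drawn in black, red, yellow, green, light blue and
#' dark blue.
#' @return named character vector of hex colours.
#' @export
classColours <- function() {
  c(class0 = "#000000", class1 = "#D62728", class2 = "#F2C700",
    class3 = "#2CA02C", class4 = "#77C8F0", class5 = "#1F3A93")
}

#' Score every sample of a manifest
#'
#' Materialises each augmented sample, scales it to [0, 1], and runs the
#' model in evaluation mode; output order preserves manifest order.
#'
#' @param model a trained \linkS4class{DenseNetModel}.
#' @param manifest a \linkS4class{DatasetManifest} matching the model input
#'   side.
#' @param batchSize inference batch size.
#' @return data.frame: the manifest's provenance columns plus
#'   \code{class0..class5} probability columns and \code{predicted}
#'   (argmax; ties break toward the lower class index).
#' @export
scoreSet <- function(model, manifest, batchSize = 16L) {
  if (length(manifest) == 0) {
    out <- cbind(manifest@samples,
                 matrix(numeric(0), 0, 7,
                        dimnames = list(NULL, c(paste0("class", 0:5),
                                                "predicted"))))
    return(out)
  }
  if (manifest@sidePx != model@spec@inputSide)
    stop("manifest side does not match network input side")
  x <- materializeAll(manifest)
  probs <- predictScores(model, x, batchSize = batchSize)
  out <- cbind(manifest@samples, as.data.frame(probs))
  out$predicted <- apply(probs, 1, which.max) - 1L
  out
}

#' Confusion matrix over the six classes
#'
#' @param true,predicted integer vectors of labels in 0..5.
#' @return 6 x 6 integer matrix; rows are true classes, columns predicted.
#' @export
confusionSummary <- function(true, predicted) {
  stopifnot(length(true) == length(predicted))
  tab <- table(factor(true, levels = 0:5), factor(predicted, levels = 0:5))
  m <- matrix(as.integer(tab), 6, 6,
              dimnames = list(true = paste0("class", 0:5),
                              predicted = paste0("class", 0:5)))
  m
}

#' Macro-averaged performance measures
#'
#' Computes, per class c, one-vs-rest accuracy (TP + TN) / total, precision
#' TP / (TP + FP) and recall TP / (TP + FN), and reports their unweighted
#' means over all six classes in percent: average per-class accuracy,
#' macro precision and macro recall. A class that is never predicted
#' contributes precision 0 to the macro mean (conservative convention); a
#' class absent from the truth contributes recall 0.
#'
#' @param confusion 6 x 6 confusion matrix (rows true, columns predicted).
#' @return list with \code{avgPerClassAccuracy}, \code{macroPrecision},
#'   \code{macroRecall} (percent) and a \code{perClass} data.frame.
#' @examples
#' cm <- confusionSummary(rep(0:5, each = 4), rep(0:5, each = 4))
#' computeMetrics(cm)$avgPerClassAccuracy   # 100
#' @export
computeMetrics <- function(confusion) {
  total <- sum(confusion)
  if (total == 0) stop("confusion matrix is empty")
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  tn <- total - tp - fp - fn
  acc <- (tp + tn) / total
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  list(avgPerClassAccuracy = 100 * mean(acc),
       macroPrecision = 100 * mean(prec),
       macroRecall = 100 * mean(rec),
       perClass = data.frame(class = 0:5, tp = tp, fp = fp, fn = fn,
                             tn = tn, accuracy = acc, precision = prec,
                             recall = rec, row.names = NULL))
}

#' Partition predictions into correct, neighbour and distant errors
#'
#' T-tubule development is continuous, so a cell may carry features of two
#' adjacent stages; confusing stage i with stage i +/- 1 (both >= 1) is a
#' questionable, reviewable error, while any other confusion -- including
#' every confusion involving the reject class 0 -- is a distant error
#' (stage 5 and class 0 are not neighbours).
#'
#' @param confusion 6 x 6 confusion matrix.
#' @return named integer vector: \code{correct}, \code{neighbour},
#'   \code{distant}; the three partition the sample count.
#' @export
neighbourErrorSummary <- function(confusion) {
  correct <- sum(diag(confusion))
  neighbour <- 0L
  for (i in 1:5) for (j in 1:5) {
    if (abs(i - j) == 1) neighbour <- neighbour + confusion[i + 1, j + 1]
  }
  c(correct = as.integer(correct), neighbour = as.integer(neighbour),
    distant = as.integer(sum(confusion) - correct - neighbour))
}

#' Class probability graph
#'
#' Displays the softmax scores of every sample in an evaluation set as a
#' bar of fixed height, coloured from the top down starting with class 0.
#' Bars are organised by source image (sorted by class, then source id,
#' top to bottom), by rotation angle (ascending within a row) and split
#' into non-flipped and flipped columns; each source row is annotated with
#' its true class colour. The machine-readable bar table (one row per
#' sample with the six segment heights) is returned alongside the plot.
#'
#' @param scored data.frame from \code{\link{scoreSet}} (provenance columns
#'   plus class0..class5 probabilities).
#' @param barHeight bar height in plot units.
#' @return list with \code{plot} (a ggplot) and \code{barTable}
#'   (data.frame: provenance, row/column position, six segment heights
#'   summing to \code{barHeight}).
#' @export
classProbabilityGraph <- function(scored, barHeight = 1) {
  need <- c("sample_id", "source_id", "class_label", "flip", "angle_rad",
            paste0("class", 0:5))
  miss <- setdiff(need, names(scored))
  if (length(miss) > 0)
    stop("scored table is missing provenance columns: ",
         paste(miss, collapse = ", "))

  # canonical ordering: sources by class then id; samples by angle; flips split
  srcTab <- unique(scored[, c("source_id", "class_label")])
  srcTab <- srcTab[order(srcTab$class_label, srcTab$source_id), ]
  srcTab$row <- seq_len(nrow(srcTab))
  df <- merge(scored, srcTab[, c("source_id", "row")], by = "source_id")
  df <- df[order(df$row, df$flip, df$angle_rad), ]
  ang <- sort(unique(df$angle_rad))
  df$angleIdx <- match(df$angle_rad, ang)
  nAng <- length(ang)
  df$col <- df$angleIdx + ifelse(df$flip, nAng + 1L, 0L)  # 1-col gutter

  probs <- as.matrix(df[, paste0("class", 0:5)])
  heights <- probs * barHeight
  bt <- data.frame(df[, c("sample_id", "source_id", "class_label", "flip",
                          "angle_rad", "row", "col")],
                   heights)
  names(bt)[8:13] <- paste0("h", 0:5)

  # long format for stacked drawing, class 0 segment at the top
  segs <- do.call(rbind, lapply(0:5, function(cl) {
    data.frame(row = df$row, col = df$col,
               class = cl,
               top = rowSums(heights[, seq_len(cl), drop = FALSE]) *
                 (if (cl == 0) 0 else 1),
               h = heights[, cl + 1])
  }))
  if (nrow(segs) > 0) {
    segs$ymax <- -(segs$row - 1) * (barHeight * 1.3) - segs$top
    segs$ymin <- segs$ymax - segs$h
  }
  cols <- classColours()
  p <- ggplot2::ggplot(segs) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$col - 0.45, xmax = .data$col + 0.45,
      ymin = .data$ymin, ymax = .data$ymax,
      fill = factor(.data$class, levels = 0:5))) +
    ggplot2::geom_tile(
      data = data.frame(row = srcTab$row, class = srcTab$class_label),
      ggplot2::aes(x = -1, width = 0.9,
                   y = -(.data$row - 1) * (barHeight * 1.3) - barHeight / 2,
                   height = barHeight,
                   fill = factor(.data$class, levels = 0:5))) +
    ggplot2::scale_fill_manual(values = unname(cols), breaks = 0:5,
                               name = "class", drop = FALSE) +
    ggplot2::scale_x_continuous(
      breaks = c(seq_len(nAng), nAng + 1 + seq_len(nAng)),
      labels = rep(round(ang * 180 / pi), 2), position = "top") +
    ggplot2::labs(x = "rotation (degrees); non-flipped | flipped columns",
                  y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(size = 5, angle = 90),
                   panel.grid = ggplot2::element_blank())
  list(plot = p, barTable = bt)
}
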