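#' ROC curve and AUC for positive vs. decoy scores
#'
#' Ranks the pooled scores and computes the receiver operating characteristic
#' curve together with its area. The AUC is computed from the Mann-Whitney
#' rank statistic, so ties between a positive and a decoy score contribute
#' half credit — the natural convention here because the aggregation rule
#' produces exact-zero ties whenever any desirability is non-positive.
#'
#' @param pos_scores Numeric scores of the positive set (non-empty).
#' @param neg_scores Numeric scores of the negative/decoy set (non-empty).
#' @return A `qea_roc` object with elements `points` (tibble of `fpr`, `tpr`
#'   from (0,0) to (1,1)), `auc`, `n_pos`, `n_neg`.
#' @examples
#' roc_auc(c(0.9, 0.8), c(0.7, 0.85))$auc  # 0.75
#' @export
roc_auc <- function(pos_scores, neg_scores) {
  pos_scores <- as.numeric(pos_scores)
  neg_scores <- as.numeric(neg_scores)
  if (length(pos_scores) == 0 || length(neg_scores) == 0) {
    stop("both score sets must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(c(pos_scores, neg_scores)))) {
    stop("scores must be finite", call. = FALSE)
  }
  n_pos <- length(pos_scores)
  n_neg <- length(neg_scores)

  # Mann-Whitney via midranks: U = sum(rank(pos)) - n_pos(n_pos+1)/2
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  u <- sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2
  auc <- u / (n_pos * n_neg)

  # Curve: sweep the threshold down through unique score values.
  thresholds <- sort(unique(c(pos_scores, neg_scores)), decreasing = TRUE)
  tpr <- vapply(thresholds, function(t) mean(pos_scores >= t), numeric(1))
  fpr <- vapply(thresholds, function(t) mean(neg_scores >= t), numeric(1))
  points <- tibble::tibble(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  points <- dplyr::distinct(points)

  structure(
    list(points = points, auc = auc, n_pos = n_pos, n_neg = n_neg),
    class = "qea_roc"
  )
}

#' @method print qea_roc
#' @export
print.qea_roc <- function(x, ...) {
  cat(sprintf("<qea_roc> AUC = %.4f (%d positives vs %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @method tidy qea_roc
#' @export
tidy.qea_roc <- function(x, ...) x$points

#' @method glance qea_roc
#' @export
glance.qea_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Plot a ROC curve
#'
#' @param object A `qea_roc` object.
#' @param ... Unused.
#' @return A ggplot of the ROC curve with the chance diagonal.
#' @method autoplot qea_roc
#' @export
autoplot.qea_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(colour = "#d95f02") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Write ROC results to disk
#'
#' Writes the curve points as CSV and a one-line JSON summary
#' (`auc`, `n_pos`, `n_neg`) next to it.
#'
#' @param roc A `qea_roc` object.
#' @param path Output CSV path for the curve points; the JSON summary goes to
#'   the same path with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_roc <- function(roc, path) {
  readr::write_csv(roc$points, path, progress = FALSE)
  json_path <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(list(auc = roc$auc, n_pos = roc$n_pos,
                            n_neg = roc$n_neg),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Sample a decoy set from a compound pool
#'
#' Uniform sample without replacement, reproducible for a fixed seed and
#' isolated from the session's random-number state.
#'
#' @param pool Compound tibble (or any data frame) to sample rows from.
#' @param k Number of decoys to draw (`k <= nrow(pool)`).
#' @param seed Integer seed controlling the draw.
#' @return A tibble of `k` sampled rows.
#' @export
sample_decoys <- function(pool, k, seed) {
  if (!is.data.frame(pool)) stop("pool must be a data frame", call. = FALSE)
  k <- as.integer(k)
  if (k > nrow(pool)) {
    stop("k (", k, ") exceeds pool size (", nrow(pool), ")", call. = FALSE)
  }
  idx <- withr::with_seed(seed, sample.int(nrow(pool), k))
  dplyr::as_tibble(pool[idx, , drop = FALSE])
}
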