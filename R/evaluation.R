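#' Label predictions as hits or misses
#'
#' A prediction is a hit when it shares at least one residue with an
#' annotated NLS of the same sequence (abutting intervals do not count);
#' an annotated NLS is covered when some prediction overlaps it.
#'
#' @param predictions data.frame with \code{seq_id}, \code{start},
#'   \code{end} (1-based inclusive).
#' @param annotations data.frame with \code{seq_id}, \code{start},
#'   \code{end}.
#' @param seq_ids Optional character vector of known sequence ids;
#'   predictions on other ids raise an error.
#' @return List: \code{hit} (logical per prediction), \code{covered}
#'   (logical per annotation).
#' @export
classify_hits <- function(predictions, annotations, seq_ids = NULL) {
  if (!is.null(seq_ids)) {
    unknown <- setdiff(predictions$seq_id, seq_ids)
    if (length(unknown))
      stop("prediction(s) reference unknown sequence id(s): ",
           paste(unknown, collapse = ", "))
  }
  overlaps <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1
  hit <- vapply(seq_len(nrow(predictions)), function(i) {
    a <- annotations[annotations$seq_id == predictions$seq_id[i], ]
    nrow(a) > 0 && any(overlaps(predictions$start[i], predictions$end[i],
                                a$start, a$end))
  }, logical(1))
  covered <- vapply(seq_len(nrow(annotations)), function(j) {
    p <- predictions[predictions$seq_id == annotations$seq_id[j], ]
    nrow(p) > 0 && any(overlaps(p$start, p$end, annotations$start[j],
                                annotations$end[j]))
  }, logical(1))
  list(hit = hit, covered = covered)
}

#' Amino-acid performance coefficient
#'
#' Residue-level accuracy of a prediction against a true NLS:
#' \code{aTP / (aTP + aFP + aFN)} where aTP is the number of shared
#' residues, aFP the predicted residues outside the NLS and aFN the NLS
#' residues missed.
#'
#' @param pred_start,pred_end,nls_start,nls_end 1-based inclusive bounds
#'   on the same sequence.
#' @return Numeric in [0, 1]; 1 iff the intervals are identical.
#' @export
#' @examples
#' apc(10, 19, 15, 24)  # 5/15
apc <- function(pred_start, pred_end, nls_start, nls_end) {
  atp <- max(0L, min(pred_end, nls_end) - max(pred_start, nls_start) + 1L)
  afp <- (pred_end - pred_start + 1L) - atp
  afn <- (nls_end - nls_start + 1L) - atp
  atp / (atp + afp + afn)
}

#' Evaluate predictions against annotated NLSs
#'
#' Overlap-hit metrics: precision = hits / predictions, recall = covered
#' NLSs / NLSs, F1 their harmonic mean, and the mean amino-acid
#' performance coefficient over hit predictions only. A hit overlapping
#' several NLSs contributes the aPC against the NLS that maximizes it.
#'
#' @param predictions Match/prediction data.frame (\code{seq_id},
#'   \code{start}, \code{end}).
#' @param annotations Annotation data.frame.
#' @param merge_first Merge overlapping predictions before evaluating
#'   (useful for external predictors); default \code{FALSE} — the
#'   package's own predictors already emit disjoint predictions.
#' @return An \code{nls_eval} list: n_hits, n_miss, n_nls,
#'   n_nls_covered, precision, recall, f1, apc (per hit prediction),
#'   mean_apc.
#' @export
evaluate_predictions <- function(predictions, annotations,
                                 merge_first = FALSE) {
  if (nrow(annotations) == 0L)
    stop("no annotated NLSs: recall is undefined")
  if (merge_first && nrow(predictions))
    predictions <- merge_matches(predictions)
  cls <- classify_hits(predictions, annotations)
  n_hits <- sum(cls$hit)
  n_miss <- sum(!cls$hit)
  n_nls <- nrow(annotations)
  n_cov <- sum(cls$covered)
  if (nrow(predictions) == 0L)
    warning("no predictions: precision reported as 0")
  precision <- if (nrow(predictions)) n_hits / nrow(predictions) else 0
  recall <- n_cov / n_nls
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  apcs <- vapply(which(cls$hit), function(i) {
    a <- annotations[annotations$seq_id == predictions$seq_id[i], ]
    max(vapply(seq_len(nrow(a)), function(j)
      apc(predictions$start[i], predictions$end[i], a$start[j], a$end[j]),
      numeric(1)))
  }, numeric(1))
  structure(list(n_hits = n_hits, n_miss = n_miss, n_nls = n_nls,
                 n_nls_covered = n_cov, precision = precision,
                 recall = recall, f1 = f1, apc = apcs,
                 mean_apc = if (length(apcs)) mean(apcs) else NA_real_),
            class = "nls_eval")
}

#' @export
print.nls_eval <- function(x, ...) {
  cat(sprintf(
    "NLS evaluation: %d hits / %d predictions, %d of %d NLSs covered\n",
    x$n_hits, x$n_hits + x$n_miss, x$n_nls_covered, x$n_nls))
  cat(sprintf("  precision %.3f  recall %.3f  F1 %.3f  mean aPC %s\n",
              x$precision, x$recall, x$f1,
              ifelse(is.na(x$mean_apc), "NA",
                     sprintf("%.3f", x$mean_apc))))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive
#' score exceeds a random negative score, ties counting one half.
#'
#' @param scores_pos,scores_neg Numeric score vectors (at least one
#'   each).
#' @return AUC in [0, 1].
#' @export
#' @examples
#' roc_auc(c(0.9, 0.4), c(0.5, 0.1))  # 0.75
roc_auc <- function(scores_pos, scores_neg) {
  stopifnot(length(scores_pos) >= 1, length(scores_neg) >= 1)
  np <- length(scores_pos)
  nn <- length(scores_neg)
  r <- rank(c(scores_pos, scores_neg), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}
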