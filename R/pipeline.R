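#' Sequence-based NLS predictor
#'
#' Scans the queries with the sequential patterns and (unless disabled)
#' the bipartite consensus, removes pattern matches whose enrichment
#' score is below \code{es_cutoff} (bipartite matches are never
#' removed), and merges overlapping survivors until disjoint.
#'
#' @param seqs Named character vector of query sequences.
#' @param patterns Pattern data.frame.
#' @param config A [scoring_config()].
#' @return An \code{nls_predictions} object: \code{mode},
#'   \code{predictions} (disjoint, 1-based inclusive), \code{config},
#'   \code{log} (per-stage counts).
#' @export
predict_sequence_based <- function(seqs, patterns,
                                   config = scoring_config()) {
  raw <- scan_sequences(seqs, patterns, config)
  keep <- raw$source == "bipartite" | raw$e_s >= config$es_cutoff
  kept <- raw[keep, , drop = FALSE]
  merged <- merge_matches(kept)
  new_predictions("sequence_based", merged, config,
                  list(raw = nrow(raw), filtered = sum(!keep),
                       merged = nrow(merged)))
}

#' Integrated NLS predictor
#'
#' Scan, then score every match: the linear motif score \eqn{S_L} from
#' the disorder tracks and the final score combining it with the
#' normalized enrichment. Matches below \code{final_cutoff} are removed,
#' survivors merged until disjoint, and (when conservation tracks are
#' supplied) the merged predictions are IRLC-masked.
#'
#' @param seqs Named character vector of query sequences.
#' @param patterns Pattern data.frame.
#' @param model A [train_linear_motif_model()] model.
#' @param tracks Named list of per-residue disorder vectors; every query
#'   with a match must be covered.
#' @param config A [scoring_config()].
#' @param conservation Optional named list of conservation vectors; if
#'   given, IRLC masking is applied.
#' @param irlc An [irlc_config()].
#' @param rsa_tracks Optional RSA tracks when the model uses RSA.
#' @return An \code{nls_predictions} object.
#' @export
predict_integrated <- function(seqs, patterns, model, tracks,
                               config = scoring_config(),
                               conservation = NULL,
                               irlc = irlc_config(), rsa_tracks = NULL) {
  raw <- scan_sequences(seqs, patterns, config)
  if (nrow(raw)) {
    missing <- setdiff(unique(raw$seq_id), names(tracks))
    if (length(missing))
      stop("no disorder track for sequence(s): ",
           paste(missing, collapse = ", "))
    raw$s_l <- linear_motif_score(model, raw, tracks, rsa_tracks)
    raw$final_score <- final_score(raw$e_s, raw$s_l, raw$source, config)
  }
  keep <- raw$final_score >= config$final_cutoff
  kept <- raw[keep, , drop = FALSE]
  merged <- merge_matches(kept)
  n_masked <- 0L
  if (!is.null(conservation) && nrow(merged)) {
    before <- nrow(merged)
    merged <- apply_irlc_mask(merged, conservation, irlc)
    n_masked <- before - nrow(merged)
  }
  new_predictions("integrated", merged, config,
                  list(raw = nrow(raw), filtered = sum(!keep),
                       merged = nrow(merged) + n_masked,
                       masked = n_masked))
}

new_predictions <- function(mode, predictions, config, log) {
  rownames(predictions) <- NULL
  structure(list(mode = mode, predictions = predictions,
                 config = config, log = log),
            class = "nls_predictions")
}

#' @export
print.nls_predictions <- function(x, ...) {
  cat("NLS predictions (", x$mode, " mode): ", nrow(x$predictions),
      " prediction(s) on ", length(unique(x$predictions$seq_id)),
      " sequence(s)\n", sep = "")
  cat("  stages: ", paste(names(x$log), unlist(x$log), sep = "=",
                          collapse = ", "), "\n", sep = "")
  if (nrow(x$predictions)) print(head(x$predictions, 10))
  invisible(x)
}

#' Write predictions to a TSV
#'
#' Columns: seq_id, start, end (1-based inclusive), mode, e_s, s_l,
#' final_score, irlc, provenance.
#'
#' @param pred An \code{nls_predictions} object.
#' @param path Output path.
#' @export
write_predictions <- function(pred, path) {
  df <- pred$predictions
  df$mode <- pred$mode
  if (is.null(df$irlc)) df$irlc <- NA_real_
  write.table(df[, c("seq_id", "start", "end", "mode", "e_s", "s_l",
                     "final_score", "irlc", "provenance")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sweep a cutoff grid and tabulate performance
#'
#' Runs the chosen predictor at each cutoff (enrichment-score cutoff in
#' \code{sequence_based} mode, final-score cutoff in \code{integrated}
#' mode) and evaluates against the annotations. Recall is non-increasing
#' in the cutoff.
#'
#' @param seqs Named character vector of query sequences.
#' @param patterns Pattern data.frame.
#' @param annotations Annotation data.frame.
#' @param cutoffs Numeric vector of cutoffs.
#' @param mode \code{"sequence_based"} or \code{"integrated"}.
#' @param config A [scoring_config()] (its cutoff field is overridden
#'   per grid point).
#' @param ... Passed to [predict_integrated()] (model, tracks,
#'   conservation, ...).
#' @return data.frame: cutoff, n_predictions, precision, recall, f1,
#'   mean_apc.
#' @export
sweep_cutoffs <- function(seqs, patterns, annotations, cutoffs,
                          mode = c("sequence_based", "integrated"),
                          config = scoring_config(), ...) {
  mode <- match.arg(mode)
  rows <- lapply(cutoffs, function(ct) {
    cfg <- config
    if (mode == "sequence_based") cfg$es_cutoff <- ct
    else cfg$final_cutoff <- ct
    ps <- if (mode == "sequence_based")
      predict_sequence_based(seqs, patterns, cfg)
    else predict_integrated(seqs, patterns, config = cfg, ...)
    ev <- suppressWarnings(
      evaluate_predictions(ps$predictions, annotations))
    data.frame(cutoff = ct, n_predictions = ev$n_hits + ev$n_miss,
               precision = ev$precision, recall = ev$recall,
               f1 = ev$f1, mean_apc = ev$mean_apc)
  })
  do.call(rbind, rows)
}
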