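#' Scoring and mining configuration
#'
#' Bundles every threshold and weight used by the miner, the scanners and
#' the two predictors. Defaults are the published operating point of the
#' method.
#'
#' @param e_k Enrichment saturation threshold \eqn{E_K}: raw enrichment
#'   scores at or above this value map to a normalized enrichment of 1.
#'   Default 1.62, the point past which raising the enrichment-score
#'   cutoff no longer improves precision.
#' @param min_score Minimal possible enrichment score of a collected
#'   pattern (the floor of the normalization ramp). Default 1.0, equal to
#'   the pattern collection threshold.
#' @param alpha Weight of the normalized enrichment score in the final
#'   score; the linear motif score gets \code{1 - alpha}. Default 0.8.
#' @param beta Discount applied to the linear motif score of
#'   sequential-pattern matches (bipartite matches are undiscounted
#'   because their boundaries are more accurate). Default 0.6.
#' @param final_cutoff Final-score cutoff of the integrated predictor.
#'   Default 0.85.
#' @param es_cutoff Enrichment-score cutoff of the sequence-based
#'   predictor. Default 1.62.
#' @param es_collect Enrichment-score threshold for collecting a word-list
#'   as a sequential pattern at mining time. Default 1.0.
#' @param max_gap Maximum number of residues allowed between consecutive
#'   words of a qualified match. Default 2.
#' @param min_support Minimum positive-corpus support of a frequent
#'   word-set. Default 3.
#' @param max_set_size Maximum word-set size. Default 4.
#' @param word_length Word length in residues. Default 2 (dipeptides).
#' @param enrichment Enrichment formula: \code{"log2_ratio"} (default),
#'   \code{log2((n_p1/n_p) / ((n_b1+1)/(n_b+1)))}, or
#'   \code{"plain_ratio"}, the same ratio without the log.
#' @param use_rsa Use median relative surface area as a second
#'   linear-motif feature. Default \code{FALSE}: disorder alone performs
#'   as well, RSA is redundant with it.
#' @param use_bipartite Include the bipartite-NLS consensus in scans.
#'   Default \code{TRUE}.
#' @param spacer Allowed bipartite spacer length(s). Default 10.
#'
#' @return An object of class \code{nls_config} (a named list).
#' @export
#' @examples
#' cfg <- scoring_config()
#' cfg$e_k
scoring_config <- function(e_k = 1.62, min_score = 1.0, alpha = 0.8,
                           beta = 0.6, final_cutoff = 0.85,
                           es_cutoff = 1.62, es_collect = 1.0,
                           max_gap = 2L, min_support = 3L,
                           max_set_size = 4L, word_length = 2L,
                           enrichment = c("log2_ratio", "plain_ratio"),
                           use_rsa = FALSE, use_bipartite = TRUE,
                           spacer = 10L) {
  enrichment <- match.arg(enrichment)
  stopifnot(alpha > 0, alpha < 1, beta > 0, beta <= 1, e_k > min_score,
            max_gap >= 0, min_support >= 1, max_set_size >= 1,
            word_length >= 1, all(spacer >= 0))
  structure(list(e_k = e_k, min_score = min_score, alpha = alpha,
                 beta = beta, final_cutoff = final_cutoff,
                 es_cutoff = es_cutoff, es_collect = es_collect,
                 max_gap = as.integer(max_gap),
                 min_support = as.integer(min_support),
                 max_set_size = as.integer(max_set_size),
                 word_length = as.integer(word_length),
                 enrichment = enrichment, use_rsa = use_rsa,
                 use_bipartite = use_bipartite,
                 spacer = as.integer(spacer)),
            class = "nls_config")
}

#' IRLC masking configuration
#'
#' @param flank Number of residues on each side of a prediction that count
#'   as flanking residues. Default 5.
#' @param threshold_t Masking cutoff \eqn{T}: predictions with IRLC
#'   strictly greater than \eqn{T} are removed. Default 1.7, chosen so
#'   that essentially no true NLS is masked.
#' @param on_missing What to do when a sequence has no conservation
#'   track: \code{"skip"} (default; keep the prediction, warn) or
#'   \code{"error"}.
#' @return An object of class \code{irlc_config}.
#' @export
irlc_config <- function(flank = 5L, threshold_t = 1.7,
                        on_missing = c("skip", "error")) {
  on_missing <- match.arg(on_missing)
  stopifnot(flank >= 1, is.finite(threshold_t))
  structure(list(flank = as.integer(flank), threshold_t = threshold_t,
                 on_missing = on_missing),
            class = "irlc_config")
}
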