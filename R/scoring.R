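#' Median track score over a segment
#'
#' The per-segment disorder (or RSA) score is the median of the
#' per-residue scores inside the segment; an even-length segment uses the
#' mean of the two central values.
#'
#' @param values Numeric vector of per-residue scores for one sequence.
#' @param start,end 1-based inclusive segment bounds.
#' @return Numeric scalar.
#' @export
segment_median <- function(values, start, end) {
  if (start > end) stop("empty segment [", start, ", ", end, "]")
  if (start < 1L || end > length(values))
    stop("segment [", start, ", ", end, "] outside track of length ",
         length(values))
  median(values[start:end])
}

segment_features <- function(segments, tracks, rsa_tracks = NULL) {
  med <- function(trk, what) {
    vapply(seq_len(nrow(segments)), function(i) {
      v <- trk[[segments$seq_id[i]]]
      if (is.null(v))
        stop("no ", what, " track for segment ", segments$seq_id[i], ":",
             segments$start[i], "-", segments$end[i])
      segment_median(v, segments$start[i], segments$end[i])
    }, numeric(1))
  }
  x <- cbind(disorder = med(tracks, "disorder"))
  if (!is.null(rsa_tracks)) x <- cbind(x, rsa = med(rsa_tracks, "rsa"))
  x
}

#' Train the linear motif model
#'
#' A probabilistic binary classifier over segment features (median
#' disorder; optionally median RSA) separating NLS segments from
#' length-matched non-NLS segments. The model is an RBF-kernel
#' (Gaussian) kernel logistic regression with a ridge penalty, fitted by
#' Newton iterations; its output is directly a class probability, the
#' linear motif score \eqn{S_L}. Deterministic given the training data;
#' \code{seed} is recorded in the metadata for provenance.
#'
#' @param pos_segments,neg_segments data.frames with \code{seq_id},
#'   \code{start}, \code{end} (1-based inclusive), at least 2 rows each.
#' @param tracks Named list of per-residue disorder vectors covering
#'   every segment.
#' @param config A [scoring_config()]; \code{use_rsa} adds the RSA
#'   feature.
#' @param seed Integer recorded in the model metadata.
#' @param rsa_tracks Named list of RSA vectors (needed iff
#'   \code{use_rsa}).
#' @param gamma RBF kernel width \code{exp(-gamma * d^2)}; default 2.
#' @param lambda Ridge penalty on the kernel coefficients; default 0.1.
#' @return An object of class \code{nls_lm_model}.
#' @export
train_linear_motif_model <- function(pos_segments, neg_segments, tracks,
                                     config = scoring_config(), seed = 1L,
                                     rsa_tracks = NULL, gamma = 2,
                                     lambda = 0.1) {
  stopifnot(nrow(pos_segments) >= 2, nrow(neg_segments) >= 2)
  rsa <- if (isTRUE(config$use_rsa)) rsa_tracks else NULL
  if (isTRUE(config$use_rsa) && is.null(rsa_tracks))
    stop("use_rsa is TRUE but no rsa_tracks supplied")
  xp <- segment_features(pos_segments, tracks, rsa)
  xn <- segment_features(neg_segments, tracks, rsa)
  x <- rbind(xp, xn)
  y <- c(rep(1, nrow(xp)), rep(0, nrow(xn)))
  K <- rbf_kernel(x, x, gamma)
  n <- nrow(x)
  # penalized IRLS for f = K a + b, penalty lambda * a' K a
  a <- rep(0, n)
  b <- 0
  for (it in 1:50) {
    f <- drop(K %*% a) + b
    p <- plogis(f)
    w <- pmax(p * (1 - p), 1e-6)
    z <- f + (y - p) / w
    # solve weighted penalized system for [a; b]
    A <- rbind(cbind(K * w + diag(lambda, n), w),
               c(w %*% K, sum(w)))
    rhs <- c(w * z, sum(w * z))
    sol <- tryCatch(solve(A, rhs), error = function(e)
      solve(A + diag(1e-8, n + 1L), rhs))
    a_new <- sol[seq_len(n)]
    b_new <- sol[n + 1L]
    if (max(abs(c(a_new - a, b_new - b))) < 1e-8) {
      a <- a_new; b <- b_new; break
    }
    a <- a_new; b <- b_new
  }
  structure(list(alpha = a, bias = b, x = x, gamma = gamma,
                 lambda = lambda, features = colnames(x),
                 meta = list(seed = seed, n_pos = nrow(xp),
                             n_neg = nrow(xn), kernel = "rbf")),
            class = "nls_lm_model")
}

rbf_kernel <- function(x, centers, gamma) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") -
    2 * tcrossprod(x, centers)
  exp(-gamma * pmax(d2, 0))
}

#' @export
print.nls_lm_model <- function(x, ...) {
  cat("RBF kernel logistic regression (linear motif model)\n",
      " features: ", paste(x$features, collapse = ", "), "\n",
      " training: ", x$meta$n_pos, " NLS vs ", x$meta$n_neg,
      " non-NLS segments; gamma=", x$gamma, ", lambda=", x$lambda,
      ", seed=", x$meta$seed, "\n", sep = "")
  invisible(x)
}

# probability for a feature matrix
predict_lm_model <- function(model, x) {
  x <- as.matrix(x)
  K <- rbf_kernel(x, model$x, model$gamma)
  plogis(drop(K %*% model$alpha) + model$bias)
}

#' Linear motif score of matches
#'
#' \eqn{S_L}: the model probability that each match interval is an NLS,
#' given its median disorder (and RSA when the model uses it).
#'
#' @param model A trained [train_linear_motif_model()] model.
#' @param matches Match data.frame.
#' @param tracks Named list of disorder vectors.
#' @param rsa_tracks Named list of RSA vectors (if the model was trained
#'   with RSA).
#' @return Numeric vector of probabilities in [0, 1], one per match.
#' @export
linear_motif_score <- function(model, matches, tracks, rsa_tracks = NULL) {
  if (!nrow(matches)) return(numeric())
  rsa <- if ("rsa" %in% model$features) rsa_tracks else NULL
  if ("rsa" %in% model$features && is.null(rsa_tracks))
    stop("model uses RSA but no rsa_tracks supplied")
  x <- segment_features(matches, tracks, rsa)
  predict_lm_model(model, x)
}

#' Normalized enrichment score
#'
#' Maps raw enrichment onto the [0, 1] scale of the linear motif score:
#' a linear ramp from \code{min_score} (the minimal possible collected
#' score, 1.0) to the saturation threshold \eqn{E_K} (1.62), clamped at
#' both ends. The bipartite \code{Inf} sentinel maps to 1. Past
#' \eqn{E_K}, raising the raw score cannot improve precision, hence the
#' saturation.
#'
#' @param e_s Numeric vector of raw enrichment scores (may contain
#'   \code{Inf}).
#' @param config A [scoring_config()].
#' @return Numeric vector in [0, 1].
#' @export
#' @examples
#' normalized_enrichment(c(1.0, 1.31, 1.62, 5, Inf))
normalized_enrichment <- function(e_s, config = scoring_config()) {
  out <- (e_s - config$min_score) / (config$e_k - config$min_score)
  out[is.infinite(e_s) & e_s > 0] <- 1
  pmin(pmax(out, 0), 1)
}

#' Final score of a match
#'
#' Convex combination of the normalized enrichment score and the linear
#' motif score: \code{alpha * Normalized(E_S) + (1 - alpha) * beta * S_L}
#' for sequential-pattern matches and \code{alpha * Normalized(E_S) +
#' (1 - alpha) * S_L} for bipartite matches (whose boundaries are more
#' accurate, so their \eqn{S_L} is undiscounted). With the default
#' weights any match with \eqn{E_S \ge E_K} scores at least 0.8.
#'
#' @param e_s Raw enrichment score(s).
#' @param s_l Linear motif score(s) in [0, 1].
#' @param source \code{"pattern"} or \code{"bipartite"} (vectorized).
#' @param config A [scoring_config()].
#' @return Numeric vector in [0, 1].
#' @export
final_score <- function(e_s, s_l, source = "pattern",
                        config = scoring_config()) {
  stopifnot(all(s_l >= 0 & s_l <= 1))
  ne <- normalized_enrichment(e_s, config)
  disc <- ifelse(source == "bipartite", 1, config$beta)
  config$alpha * ne + (1 - config$alpha) * disc * s_l
}
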