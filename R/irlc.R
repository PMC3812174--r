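#' Inverse relative local conservation score of one prediction
#'
#' Linear motifs tend to be more conserved than their flanks, so a
#' flanking residue that is far more conserved than the interior of a
#' prediction argues against it. With \eqn{M} the mean conservation of
#' the residues inside the prediction and \eqn{\sigma} the population
#' standard deviation of conservation over the whole sequence, each
#' flanking residue j (within \code{flank} residues of either boundary,
#' truncated at the sequence ends) scores
#' \eqn{IRLC_j = (C_j - M)/\sigma}, and the prediction's IRLC is the
#' maximum over its flanking residues. A flat track (\eqn{\sigma = 0})
#' or a prediction with no flanking residues scores 0: no
#' relative-conservation evidence.
#'
#' @param start,end 1-based inclusive prediction bounds.
#' @param conservation Numeric vector of per-residue conservation scores
#'   for the whole sequence (e.g. from [conservation_from_pssm()]).
#' @param config An [irlc_config()].
#' @return List with \code{m}, \code{sigma}, \code{irlc}, \code{masked}
#'   (\code{irlc > threshold_t}, strict).
#' @export
irlc_score <- function(start, end, conservation,
                       config = irlc_config()) {
  L <- length(conservation)
  if (start < 1L || end > L || start > end)
    stop("prediction [", start, ", ", end,
         "] outside conservation track of length ", L)
  m <- mean(conservation[start:end])
  sigma <- sqrt(mean((conservation - mean(conservation))^2))
  flank <- c(if (start > 1L) max(1L, start - config$flank):(start - 1L),
             if (end < L) (end + 1L):min(L, end + config$flank))
  irlc <- if (sigma == 0 || !length(flank)) 0 else
    max((conservation[flank] - m) / sigma)
  list(m = m, sigma = sigma, irlc = irlc,
       masked = irlc > config$threshold_t)
}

#' Mask predictions by IRLC
#'
#' Removes every prediction whose IRLC score is strictly greater than
#' the cutoff \eqn{T}. Sequences without a conservation track are, by
#' default, left unmasked with a warning.
#'
#' @param matches Match data.frame of final predictions.
#' @param conservation Named list of per-residue conservation vectors.
#' @param config An [irlc_config()].
#' @return The surviving matches, with an \code{irlc} column added;
#'   removals are reported via \code{message()}.
#' @export
apply_irlc_mask <- function(matches, conservation,
                            config = irlc_config()) {
  if (!nrow(matches)) {
    matches$irlc <- numeric()
    return(matches)
  }
  irlc <- rep(NA_real_, nrow(matches))
  for (i in seq_len(nrow(matches))) {
    trk <- conservation[[matches$seq_id[i]]]
    if (is.null(trk)) {
      if (config$on_missing == "error")
        stop("no conservation track for sequence ", matches$seq_id[i])
      warning("no conservation track for sequence ", matches$seq_id[i],
              "; prediction not masked")
      next
    }
    irlc[i] <- irlc_score(matches$start[i], matches$end[i], trk,
                          config)$irlc
  }
  matches$irlc <- irlc
  drop <- !is.na(irlc) & irlc > config$threshold_t
  if (any(drop))
    message("IRLC-masked ", sum(drop), " prediction(s): ",
            paste(sprintf("%s:%d-%d (IRLC %.2f)",
                          matches$seq_id[drop], matches$start[drop],
                          matches$end[drop], irlc[drop]),
                  collapse = ", "))
  out <- matches[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}
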