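# -- low-level word position index ------------------------------------------

# named list: word -> sorted 1-based start positions within seq.
# Words containing X are excluded (X matches no pattern position).
word_index <- function(seq, word_length = 2L) {
  n <- nchar(seq) - word_length + 1L
  if (n < 1L) return(structure(list(), names = character()))
  w <- substring(seq, 1:n, word_length:nchar(seq))
  keep <- !grepl("X", w, fixed = TRUE)
  split(which(keep), w[keep])
}

# existence of an ordered placement with inter-word gaps in [0, max_gap].
# Reachable-set propagation: a position p of word k+1 is reachable iff some
# reachable position q of word k satisfies p - (q + wlen) in [0, max_gap].
has_ordered_match <- function(idx, wordlist, wlen, max_gap) {
  cur <- idx[[wordlist[1]]]
  if (is.null(cur)) return(FALSE)
  for (w in wordlist[-1]) {
    nxt <- idx[[w]]
    if (is.null(nxt)) return(FALSE)
    lo <- cur + wlen
    hi <- cur + wlen + max_gap
    cur <- nxt[vapply(nxt, function(p) any(lo <= p & p <= hi), logical(1))]
    if (!length(cur)) return(FALSE)
  }
  TRUE
}

#' Qualified matches of one word-list on one sequence
#'
#' Enumerates every distinct interval realizable by placing the words in
#' order, non-overlapping, with each inter-word gap between 0 and
#' \code{max_gap} residues. The interval runs from the start of the first
#' word to the end of the last word (1-based inclusive). Identical spans
#' reached through different internal placements are reported once.
#'
#' @param seq Character scalar (one protein sequence).
#' @param wordlist Character vector of words in match order.
#' @param max_gap Maximum residues between consecutive words, default 2.
#' @param seq_id Identifier used in the result, default \code{"seq"}.
#' @param e_s Enrichment score to attach to the matches.
#' @return Match data.frame (seq_id, start, end, source, e_s, s_l,
#'   final_score, provenance).
#' @export
#' @examples
#' match_wordlist("MATQRKKL", c("AT", "KK"))  # one match, residues 2-7
match_wordlist <- function(seq, wordlist, max_gap = 2L, seq_id = "seq",
                           e_s = NA_real_) {
  stopifnot(length(wordlist) >= 1, max_gap >= 0)
  wlen <- nchar(wordlist[1])
  stopifnot(all(nchar(wordlist) == wlen))
  idx <- word_index(seq, wlen)
  starts <- idx[[wordlist[1]]]
  if (is.null(starts)) return(empty_matches())
  nw <- length(wordlist)
  memo <- new.env(parent = emptyenv())
  # reach(k, p): ends (position of last word) reachable when word k sits at p
  reach <- function(k, p) {
    if (k == nw) return(p)
    key <- paste0(k, ":", p)
    if (!is.null(got <- memo[[key]])) return(got)
    nxt <- idx[[wordlist[k + 1L]]]
    ends <- integer()
    if (!is.null(nxt)) {
      ok <- nxt[nxt >= p + wlen & nxt <= p + wlen + max_gap]
      for (q in ok) ends <- c(ends, reach(k + 1L, q))
    }
    ends <- unique(ends)
    memo[[key]] <- ends
    ends
  }
  spans <- list()
  for (s in starts) {
    ends <- reach(1L, s)
    for (e in ends)
      spans[[length(spans) + 1L]] <- c(s, e + wlen - 1L)
  }
  if (!length(spans)) return(empty_matches())
  sp <- unique(do.call(rbind, spans))
  sp <- sp[order(sp[, 1], sp[, 2]), , drop = FALSE]
  as_match_df(seq_id, sp[, 1], sp[, 2], "pattern", e_s,
              paste(wordlist, collapse = "-"))
}

#' Bipartite-NLS consensus matches
#'
#' Finds every 17-residue window matching (K/R)(K/R)X10(K/R)3/5: two
#' basic residues, a spacer of exactly 10 arbitrary residues, then 5
#' residues of which at least 3 are K or R. The enrichment score of a
#' bipartite match is the \code{Inf} sentinel ("arbitrarily large"), so
#' it always survives enrichment-score cutoffs. Spacer lengths other than
#' 10 can be allowed via \code{spacer}. Residue X satisfies no K/R
#' position and does not count toward the 3-of-5 tally; wildcard spacer
#' positions impose no constraint.
#'
#' @param seq Character scalar.
#' @param seq_id Identifier for the result.
#' @param spacer Integer vector of allowed spacer lengths, default 10.
#' @return Match data.frame with \code{source = "bipartite"},
#'   \code{e_s = Inf}.
#' @export
#' @examples
#' match_bipartite(paste0("KK", strrep("A", 10), "KKKAA"))
match_bipartite <- function(seq, seq_id = "seq", spacer = 10L) {
  L <- nchar(seq)
  out <- list()
  basic <- strsplit(seq, "")[[1]] %in% c("K", "R")
  cs <- c(0L, cumsum(basic))
  for (sp in spacer) {
    win <- 2L + sp + 5L
    if (L < win) next
    w <- seq_len(L - win + 1L)
    head_ok <- basic[w] & basic[w + 1L]
    tail_cnt <- cs[w + win] - cs[w + win - 5L]
    hit <- w[head_ok & tail_cnt >= 3L]
    if (length(hit))
      out[[length(out) + 1L]] <- as_match_df(seq_id, hit, hit + win - 1L,
                                             "bipartite", Inf, "bipartite")
  }
  if (!length(out)) return(empty_matches())
  res <- unique(do.call(rbind, out))
  res <- res[order(res$start, res$end), ]
  rownames(res) <- NULL
  res
}

#' Merge overlapping matches
#'
#' Repeatedly replaces every pair of overlapping matches (sharing at
#' least one residue; abutting intervals do not overlap) on the same
#' sequence with their union until all matches are pairwise disjoint.
#' A merged match carries \code{source = "merged"}, the maximum of each
#' score field over its constituents, and the union of their provenance.
#'
#' @param matches Match data.frame (may span several sequences).
#' @return Match data.frame with pairwise-disjoint intervals per
#'   sequence, ordered by seq_id then start.
#' @export
merge_matches <- function(matches) {
  if (!nrow(matches)) return(matches)
  pieces <- lapply(split(matches, matches$seq_id), function(m) {
    m <- m[order(m$start, m$end), ]
    grp <- integer(nrow(m))
    g <- 1L
    grp[1] <- g
    cur_end <- m$end[1]
    for (i in seq_len(nrow(m))[-1]) {
      if (m$start[i] <= cur_end) {       # 1-based inclusive: overlap
        grp[i] <- g
        cur_end <- max(cur_end, m$end[i])
      } else {
        g <- g + 1L
        grp[i] <- g
        cur_end <- m$end[i]
      }
    }
    do.call(rbind, lapply(split(m, grp), function(x) {
      if (nrow(x) == 1L) return(x)
      data.frame(seq_id = x$seq_id[1], start = min(x$start),
                 end = max(x$end), source = "merged",
                 e_s = suppressWarnings(max(x$e_s, na.rm = TRUE)),
                 s_l = max_or_na(x$s_l),
                 final_score = max_or_na(x$final_score),
                 provenance = paste(unique(unlist(
                   strsplit(x$provenance, ";", fixed = TRUE))),
                   collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$seq_id, out$start), ]
  rownames(out) <- NULL
  out
}

max_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) NA_real_ else max(x)
}

#' Scan sequences with a pattern set and the bipartite consensus
#'
#' Raw scan shared by both predictors: every qualified match of every
#' sequential pattern plus (unless disabled) every bipartite-consensus
#' match. A span matched by several patterns is reported once with the
#' maximum enrichment score and the provenance of all contributing
#' patterns.
#'
#' @param seqs Named character vector of query sequences.
#' @param patterns Pattern data.frame from [collect_patterns()] /
#'   [read_patterns()].
#' @param config A [scoring_config()].
#' @return Match data.frame.
#' @export
scan_sequences <- function(seqs, patterns, config = scoring_config()) {
  wlen <- config$word_length
  out <- list()
  wordlists <- strsplit(patterns$words, "-", fixed = TRUE)
  for (id in names(seqs)) {
    seq <- seqs[[id]]
    idx <- word_index(seq, wlen)
    for (k in seq_along(wordlists)) {
      wl <- wordlists[[k]]
      if (!has_ordered_match(idx, wl, wlen, config$max_gap)) next
      out[[length(out) + 1L]] <-
        match_wordlist(seq, wl, config$max_gap, id, patterns$e_s[k])
    }
    if (config$use_bipartite)
      out[[length(out) + 1L]] <- match_bipartite(seq, id, config$spacer)
  }
  if (!length(out)) return(empty_matches())
  m <- do.call(rbind, out)
  # deduplicate identical spans: keep max e_s, union provenance
  key <- paste(m$seq_id, m$start, m$end, m$source)
  dd <- do.call(rbind, lapply(split(m, key), function(x) {
    if (nrow(x) == 1L) return(x)
    x$e_s[1] <- max(x$e_s)
    x$provenance[1] <- paste(unique(x$provenance), collapse = ";")
    x[1, ]
  }))
  dd <- dd[order(dd$seq_id, dd$start, dd$end), ]
  rownames(dd) <- NULL
  dd
}
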