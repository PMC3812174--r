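#' Assemble a training corpus
#'
#' @param positives Named character vector of NLS peptides.
#' @param negatives Named character vector of non-NLS peptides; the
#'   reference corpus uses non-overlapping peptides of length 40 (about
#'   the longest training NLS), so other lengths trigger a warning, not
#'   an error.
#' @return A list with \code{positives}, \code{negatives}, \code{n_p},
#'   \code{n_b}, class \code{nls_corpus}.
#' @export
training_corpus <- function(positives, negatives) {
  validate_sequences(positives)
  validate_sequences(negatives)
  if (length(negatives) && any(nchar(negatives) != 40L))
    warning("negative peptides are expected to have length 40; ",
            sum(nchar(negatives) != 40L), " deviate")
  structure(list(positives = positives, negatives = negatives,
                 n_p = length(positives), n_b = length(negatives)),
            class = "nls_corpus")
}

#' Distinct words of a sequence
#'
#' A word is a fixed-length amino-acid substring; presence is counted
#' once per sequence no matter how often the word occurs (itemset
#' transaction semantics). Words containing \code{X} are dropped.
#'
#' @param seq Character scalar.
#' @param word_length Word length, default 2.
#' @return Character vector of distinct words (empty if the sequence is
#'   shorter than \code{word_length}).
#' @export
#' @examples
#' extract_words("ATKK")   # "AT" "TK" "KK"
extract_words <- function(seq, word_length = 2L) {
  stopifnot(word_length >= 1)
  n <- nchar(seq) - word_length + 1L
  if (n < 1L) return(character())
  w <- unique(substring(seq, 1:n, word_length:nchar(seq)))
  w[!grepl("X", w, fixed = TRUE)]
}

#' Mine frequent word-sets from the positive corpus
#'
#' Apriori-style level-wise search over word presence: a word-set is
#' frequent when all its words co-occur in at least \code{min_support}
#' positive sequences and the set has at most \code{max_set_size} words.
#' Anti-monotonicity (every subset of a frequent set is frequent) prunes
#' the candidate space.
#'
#' @param corpus An [training_corpus()] object (only positives are used).
#' @param min_support Minimum support count, default 3.
#' @param max_set_size Maximum set size, default 4.
#' @param word_length Word length, default 2.
#' @return data.frame with columns \code{words} (dash-joined, words in
#'   sorted order), \code{size}, \code{support}, ordered by size then
#'   words.
#' @export
mine_frequent_wordsets <- function(corpus, min_support = 3L,
                                   max_set_size = 4L, word_length = 2L) {
  stopifnot(min_support >= 1, max_set_size >= 1)
  empty <- data.frame(words = character(), size = integer(),
                      support = integer(), stringsAsFactors = FALSE)
  tx <- lapply(unname(corpus$positives), extract_words,
               word_length = word_length)
  if (!length(tx)) return(empty)
  vocab <- sort(unique(unlist(tx)))
  if (!length(vocab)) return(empty)
  # presence matrix: vocab x transactions
  pres <- vapply(tx, function(t) vocab %in% t, logical(length(vocab)))
  pres <- matrix(pres, nrow = length(vocab))
  supp_of <- function(idx) sum(colSums(pres[idx, , drop = FALSE]) ==
                                 length(idx))
  l1 <- which(rowSums(pres) >= min_support)
  if (!length(l1)) return(empty)
  levels <- list(lapply(l1, identity))
  supports <- list(as.integer(rowSums(pres)[l1]))
  k <- 1L
  while (k < max_set_size && length(levels[[k]]) > 1L) {
    prev <- levels[[k]]
    prev_keys <- vapply(prev, paste, "", collapse = ",")
    cands <- list()
    # join step: two k-sets sharing their first k-1 items
    if (k == 1L) {
      items <- sort(unlist(prev))
      n <- length(items)
      for (a in seq_len(n - 1L))
        for (b in (a + 1L):n)
          cands[[length(cands) + 1L]] <- c(items[a], items[b])
    } else {
      ord <- order(prev_keys)
      prev <- prev[ord]
      pref <- vapply(prev, function(s) paste(s[-k], collapse = ","), "")
      for (grp in split(seq_along(prev), pref)) {
        if (length(grp) < 2L) next
        last <- sort(vapply(grp, function(i) prev[[i]][k], integer(1)))
        base <- prev[[grp[1]]][-k]
        n <- length(last)
        for (a in seq_len(n - 1L))
          for (b in (a + 1L):n)
            cands[[length(cands) + 1L]] <- sort(c(base, last[a], last[b]))
      }
    }
    if (!length(cands)) break
    # prune step: every k-subset must be frequent
    keyset <- new.env(parent = emptyenv())
    for (key in prev_keys) assign(key, TRUE, envir = keyset)
    next_sets <- list()
    next_supp <- integer()
    for (cand in cands) {
      subs_ok <- all(vapply(seq_along(cand), function(d)
        exists(paste(cand[-d], collapse = ","), envir = keyset,
               inherits = FALSE), logical(1)))
      if (!subs_ok) next
      s <- supp_of(cand)
      if (s >= min_support) {
        next_sets[[length(next_sets) + 1L]] <- cand
        next_supp <- c(next_supp, s)
      }
    }
    if (!length(next_sets)) break
    k <- k + 1L
    levels[[k]] <- next_sets
    supports[[k]] <- next_supp
  }
  out <- do.call(rbind, lapply(seq_along(levels), function(kk) {
    if (!length(levels[[kk]])) return(NULL)
    data.frame(words = vapply(levels[[kk]], function(s)
      paste(vocab[s], collapse = "-"), ""),
      size = kk, support = supports[[kk]], stringsAsFactors = FALSE)
  }))
  out <- out[order(out$size, out$words), ]
  rownames(out) <- NULL
  out
}

#' All orderings of a word-set
#'
#' @param words Character vector of distinct words (a frequent word-set).
#' @return List of character vectors, all \code{length(words)!} distinct
#'   orderings.
#' @export
permute_wordlists <- function(words) {
  n <- length(words)
  if (n <= 1L) return(list(words))
  out <- list()
  for (i in seq_len(n)) {
    rest <- permute_wordlists(words[-i])
    for (r in rest) out[[length(out) + 1L]] <- c(words[i], r)
  }
  out
}

#' Sequences containing an ordered, gap-bounded match of a word-list
#'
#' Counts sequences (at most once each) containing a qualified match of
#' the word-list: words in the given order, non-overlapping, with at most
#' \code{max_gap} residues between consecutive words — the same rule as
#' [match_wordlist()].
#'
#' @param wordlist Character vector of words, in order.
#' @param seqs Character vector of sequences.
#' @param max_gap Maximum inter-word gap, default 2.
#' @return Integer count.
#' @export
count_ordered_support <- function(wordlist, seqs, max_gap = 2L) {
  stopifnot(length(wordlist) >= 1)
  wlen <- nchar(wordlist[1])
  sum(vapply(seqs, function(s)
    has_ordered_match(word_index(s, wlen), wordlist, wlen, max_gap),
    logical(1)))
}

#' Enrichment score of a word-list
#'
#' Over-representation of the word-list in the positive NLS corpus
#' relative to the negative peptide corpus. The default form is
#' \code{log2((n_p1/n_p) / ((n_b1 + 1)/(n_b + 1)))}; the +1 pseudocount
#' on the negative side keeps the score finite when the word-list never
#' occurs among the negatives. \code{plain_ratio} drops the log.
#'
#' @param n_p1 Positive sequences containing the word-list (ordered
#'   match); must be >= 1.
#' @param n_p Positive corpus size.
#' @param n_b1 Negative peptides containing the word-list.
#' @param n_b Negative corpus size.
#' @param method \code{"log2_ratio"} (default) or \code{"plain_ratio"}.
#' @return Numeric enrichment score (vectorized over n_p1/n_b1).
#' @export
#' @examples
#' enrichment_score(12, 108, 100, 26772)  # ~ 4.88
enrichment_score <- function(n_p1, n_p, n_b1, n_b,
                             method = c("log2_ratio", "plain_ratio")) {
  method <- match.arg(method)
  stopifnot(all(n_p1 >= 1), all(n_p1 <= n_p), all(n_b1 >= 0),
            all(n_b1 <= n_b))
  ratio <- (n_p1 / n_p) / ((n_b1 + 1) / (n_b + 1))
  if (method == "log2_ratio") log2(ratio) else ratio
}

#' Mine the sequential-pattern set end to end
#'
#' Frequent word-sets are permuted into ordered word-lists, ordered
#' supports are counted in both corpus sides under the qualified-match
#' gap rule, each word-list is scored for enrichment, and word-lists with
#' at least one positive occurrence and enrichment score at or above the
#' collection threshold (default 1.0) are kept as sequential patterns.
#'
#' @param corpus An [training_corpus()] object.
#' @param config A [scoring_config()]; uses \code{min_support},
#'   \code{max_set_size}, \code{word_length}, \code{max_gap},
#'   \code{es_collect} and \code{enrichment}.
#' @return data.frame with columns \code{words} (dash-joined, in match
#'   order), \code{n_words}, \code{n_p1}, \code{n_b1}, \code{e_s},
#'   ordered lexicographically by \code{words}.
#' @export
collect_patterns <- function(corpus, config = scoring_config()) {
  fs <- mine_frequent_wordsets(corpus, config$min_support,
                               config$max_set_size, config$word_length)
  if (!nrow(fs)) return(data.frame(words = character(),
                                   n_words = integer(), n_p1 = integer(),
                                   n_b1 = integer(), e_s = numeric(),
                                   stringsAsFactors = FALSE))
  wlen <- config$word_length
  pos_idx <- lapply(unname(corpus$positives), word_index, wlen)
  neg_idx <- lapply(unname(corpus$negatives), word_index, wlen)
  pos_pres <- presence_map(pos_idx)
  neg_pres <- presence_map(neg_idx)
  rows <- vector("list", 0L)
  for (i in seq_len(nrow(fs))) {
    words <- strsplit(fs$words[i], "-", fixed = TRUE)[[1]]
    cand_pos <- Reduce(intersect, pos_pres[words])
    cand_neg <- Reduce(intersect, neg_pres[words])
    if (is.null(cand_pos) || !length(cand_pos)) next
    for (perm in permute_wordlists(words)) {
      n_p1 <- sum(vapply(cand_pos, function(j)
        has_ordered_match(pos_idx[[j]], perm, wlen, config$max_gap),
        logical(1)))
      if (n_p1 < 1L) next  # unscorable and unsupported in this order
      n_b1 <- if (is.null(cand_neg) || !length(cand_neg)) 0L else
        sum(vapply(cand_neg, function(j)
          has_ordered_match(neg_idx[[j]], perm, wlen, config$max_gap),
          logical(1)))
      e_s <- enrichment_score(n_p1, corpus$n_p, n_b1, corpus$n_b,
                              config$enrichment)
      if (e_s >= config$es_collect)
        rows[[length(rows) + 1L]] <- data.frame(
          words = paste(perm, collapse = "-"),
          n_words = length(perm), n_p1 = n_p1, n_b1 = n_b1, e_s = e_s,
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(words = character(), n_words = integer(),
               n_p1 = integer(), n_b1 = integer(), e_s = numeric(),
               stringsAsFactors = FALSE)
  out <- out[order(out$words), ]
  rownames(out) <- NULL
  out
}

# word -> indices of sequences whose index contains the word
presence_map <- function(idx_list) {
  pairs <- lapply(seq_along(idx_list), function(j)
    setNames(rep(j, length(idx_list[[j]])), names(idx_list[[j]])))
  all_w <- unlist(pairs)
  if (!length(all_w)) return(list())
  split(unname(all_w), names(all_w))
}

#' Write / read a pattern store
#'
#' Tab-separated with header: words (dash-joined, match order), n_p1,
#' n_b1, e_s.
#'
#' @param patterns Pattern data.frame from [collect_patterns()].
#' @param path File path.
#' @return \code{read_patterns} returns the pattern data.frame.
#' @export
write_patterns <- function(patterns, path) {
  write.table(patterns[, c("words", "n_p1", "n_b1", "e_s")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$n_words <- lengths(strsplit(df$words, "-", fixed = TRUE))
  df[, c("words", "n_words", "n_p1", "n_b1", "e_s")]
}
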