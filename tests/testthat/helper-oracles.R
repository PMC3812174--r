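# Independent oracles, deliberately naive and separate from the package's
# code paths.

# exhaustive subset enumeration of frequent word-sets. Only words that are
# themselves frequent can belong to a frequent set (support is monotone in
# the subset relation by definition), which keeps full enumeration feasible.
oracle_frequent_sets <- function(seqs, min_support, max_set_size,
                                 word_length = 2L) {
  words_of <- function(s) {
    n <- nchar(s) - word_length + 1L
    if (n < 1L) return(character())
    unique(substring(s, 1:n, word_length:nchar(s)))
  }
  tx <- lapply(unname(seqs), words_of)
  vocab <- sort(unique(unlist(tx)))
  supp <- function(set) sum(vapply(tx, function(t) all(set %in% t),
                                   logical(1)))
  vocab <- vocab[vapply(vocab, function(w) supp(w) >= min_support,
                        logical(1))]
  rows <- list()
  for (k in seq_len(max_set_size)) {
    if (length(vocab) < k) break
    for (comb in utils::combn(vocab, k, simplify = FALSE)) {
      s <- supp(comb)
      if (s >= min_support)
        rows[[length(rows) + 1L]] <- data.frame(
          words = paste(comb, collapse = "-"), size = k, support = s,
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(words = character(), size = integer(),
               support = integer(), stringsAsFactors = FALSE)
  out[order(out$size, out$words), ]
}

# brute-force enumeration of every placement of a word-list with inter-word
# gaps in [0, max_gap]; returns the distinct (start, end) spans.
oracle_spans <- function(seq, wordlist, max_gap = 2L) {
  wlen <- nchar(wordlist[1])
  occ <- lapply(wordlist, function(w) {
    n <- nchar(seq) - wlen + 1L
    if (n < 1L) return(integer())
    which(substring(seq, 1:n, wlen:nchar(seq)) == w)
  })
  spans <- list()
  rec <- function(k, prev_end, first) {
    if (k > length(wordlist)) {
      spans[[length(spans) + 1L]] <<- c(first, prev_end)
      return(invisible())
    }
    for (p in occ[[k]]) {
      if (k == 1L) rec(2L, p + wlen - 1L, p)
      else {
        gap <- p - prev_end - 1L
        if (gap >= 0L && gap <= max_gap) rec(k + 1L, p + wlen - 1L, first)
      }
    }
  }
  rec(1L, NA_integer_, NA_integer_)
  if (!length(spans)) return(matrix(integer(), 0, 2))
  sp <- unique(do.call(rbind, spans))
  sp[order(sp[, 1], sp[, 2]), , drop = FALSE]
}

# random peptide over a restricted alphabet (rich word overlap)
rand_pep <- function(n, alphabet = c("A", "K", "R", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
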