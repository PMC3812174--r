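# Shared in-code fixtures.

# the worked mining example: 12 positives containing both AT and KK,
# 8 background positives containing neither word.
worked_example_corpus <- function() {
  pos <- c(vapply(1:12, function(i) "MATQQKKLV", character(1)),
           vapply(1:8, function(i) "MLVQSEDHG", character(1)))
  names(pos) <- sprintf("p%02d", 1:20)
  neg <- setNames(vapply(1:5, function(i) strrep("G", 40), character(1)),
                  sprintf("n%d", 1:5))
  suppressWarnings(training_corpus(pos, neg))
}

# small corpus with one strongly planted ordered word-list (KR, KK)
planted_corpus <- function(n_pos = 12, n_neg = 60, seed = 42) {
  set.seed(seed)
  pos <- vapply(seq_len(n_pos), function(i) {
    gap <- strrep("Q", sample(0:2, 1))
    paste0(rand_pep(4, LETTERS20()), "KR", gap, "KK",
           rand_pep(4, LETTERS20()))
  }, character(1))
  names(pos) <- sprintf("p%02d", seq_len(n_pos))
  neg <- vapply(seq_len(n_neg), function(i) rand_pep(40, LETTERS20()),
                character(1))
  names(neg) <- sprintf("n%02d", seq_len(n_neg))
  training_corpus(pos, neg)
}

LETTERS20 <- function() c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
                          "I", "L", "K", "M", "F", "P", "S", "T", "W",
                          "Y", "V")

# constant-mean disorder worlds for classifier tests: one pseudo-sequence
# per segment
lm_training_fixture <- function(n = 30, mean_pos = 0.63, mean_neg = 0.39,
                                sd = 0.05, len = 11, seed = 11) {
  set.seed(seed)
  mk <- function(prefix, mu) {
    ids <- sprintf("%s%02d", prefix, seq_len(n))
    tracks <- setNames(lapply(seq_len(n), function(i)
      pmin(pmax(rnorm(len, mu, sd), 0), 1)), ids)
    segs <- data.frame(seq_id = ids, start = 1L, end = len,
                       stringsAsFactors = FALSE)
    list(tracks = tracks, segs = segs)
  }
  p <- mk("hi", mean_pos)
  n_ <- mk("lo", mean_neg)
  list(pos = p$segs, neg = n_$segs, tracks = c(p$tracks, n_$tracks))
}

trained_lm_model <- function(...) {
  fx <- lm_training_fixture(...)
  train_linear_motif_model(fx$pos, fx$neg, fx$tracks, seed = 3L)
}
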