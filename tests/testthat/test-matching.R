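test_that("match_wordlist places words in order within the gap bound", {
  m <- match_wordlist("MATQRKKL", c("AT", "KK"))
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(2L, 7L))  # AT at 2-3, gap QR, KK at 6-7
  # gap of three exceeds the default bound
  expect_equal(nrow(match_wordlist("MATQQRKKL", c("AT", "KK"))), 0L)
  expect_equal(nrow(match_wordlist("MATQQRKKL", c("AT", "KK"),
                                   max_gap = 3)), 1L)
  # singleton word-list: two distinct overlapping spans
  m <- match_wordlist("KKK", "KK")
  expect_equal(m$start, c(1L, 2L))
  expect_equal(m$end, c(2L, 3L))
  # words may not overlap each other
  expect_equal(nrow(match_wordlist("AKA", c("AK", "KA"))), 0L)
})

test_that("scanner agrees with the naive placement enumerator", {
  set.seed(13)
  lists <- list("KK", c("AT", "KK"), c("KR", "KK"), c("KA", "AK", "KT"),
                c("AA", "TT", "KK", "RR"))
  for (rep in 1:25) {
    seq <- rand_pep(sample(10:50, 1))
    wl <- lists[[sample(length(lists), 1)]]
    gap <- sample(0:3, 1)
    got <- match_wordlist(seq, wl, gap)
    want <- oracle_spans(seq, wl, gap)
    expect_equal(cbind(got$start, got$end), unname(want),
                 ignore_attr = TRUE,
                 info = paste(seq, paste(wl, collapse = "-"), gap))
  }
})

test_that("bipartite consensus requires 2 basic, exact spacer, 3 of 5", {
  hit <- match_bipartite(paste0("KK", strrep("A", 10), "KKKAA"))
  expect_equal(nrow(hit), 1L)
  expect_equal(c(hit$start, hit$end), c(1L, 17L))
  expect_equal(hit$e_s, Inf)
  # spacer must be exactly 10 by default; the basic cluster here is
  # interleaved so a shifted 5-residue window sees only 2 of K/R
  expect_equal(nrow(match_bipartite(
    paste0("KK", strrep("A", 11), "KAKAK"))), 0L)
  expect_equal(nrow(match_bipartite(
    paste0("KK", strrep("A", 11), "KAKAK"), spacer = c(10L, 11L))), 1L)
  # RK head, K/R scattered in the last window: 3 basic among 5
  expect_equal(nrow(match_bipartite(paste0("RK", strrep("A", 10),
                                           "KRAKA"))), 1L)
  expect_equal(nrow(match_bipartite(paste0("RK", strrep("A", 10),
                                           "KRAAA"))), 0L)
  # X satisfies no basic position
  expect_equal(nrow(match_bipartite(paste0("XK", strrep("A", 10),
                                           "KKKAA"))), 0L)
  expect_equal(nrow(match_bipartite(paste0("KK", strrep("A", 10),
                                           "KKXAA"))), 0L)
})

test_that("merging unions overlaps and reaches a disjoint fixed point", {
  m <- as.data.frame(rbind(
    data.frame(seq_id = "s", start = 1L, end = 7L),
    data.frame(seq_id = "s", start = 5L, end = 12L)))
  m$source <- "pattern"; m$e_s <- c(2, 3); m$s_l <- NA_real_
  m$final_score <- NA_real_; m$provenance <- c("a", "b")
  out <- merge_matches(m)
  expect_equal(c(out$start, out$end), c(1L, 12L))
  expect_equal(out$e_s, 3)                 # max over constituents
  expect_equal(out$source, "merged")
  expect_setequal(strsplit(out$provenance, ";")[[1]], c("a", "b"))

  # disjoint and abutting matches stay separate (end == start-1 abuts)
  m2 <- m; m2$start <- c(1L, 8L); m2$end <- c(7L, 12L)
  expect_equal(nrow(merge_matches(m2)), 2L)

  # transitive chain collapses to one interval
  m3 <- do.call(rbind, lapply(list(c(1, 4), c(4, 6), c(6, 9)),
    function(iv) data.frame(seq_id = "s", start = iv[1], end = iv[2],
                            source = "pattern", e_s = 1, s_l = NA_real_,
                            final_score = NA_real_, provenance = "x")))
  out3 <- merge_matches(m3)
  expect_equal(c(out3$start, out3$end), c(1, 9))
})

test_that("merge is idempotent, order-independent, and disjoint", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    start <- sample(1:40, n, replace = TRUE)
    m <- data.frame(seq_id = sample(c("a", "b"), n, replace = TRUE),
                    start = start, end = start + sample(1:10, n, TRUE),
                    source = "pattern", e_s = runif(n), s_l = NA_real_,
                    final_score = NA_real_,
                    provenance = as.character(seq_len(n)),
                    stringsAsFactors = FALSE)
    once <- merge_matches(m)
    expect_equal(merge_matches(once)[, c("seq_id", "start", "end")],
                 once[, c("seq_id", "start", "end")])
    shuf <- merge_matches(m[sample(n), ])
    expect_equal(shuf[, c("seq_id", "start", "end", "e_s")],
                 once[, c("seq_id", "start", "end", "e_s")])
    for (id in unique(once$seq_id)) {
      x <- once[once$seq_id == id, ]
      if (nrow(x) > 1)
        expect_true(all(x$start[-1] > x$end[-nrow(x)]))
    }
  }
})

test_that("scan_sequences dedupes spans and keeps the max enrichment", {
  pat <- data.frame(words = c("KR-KK", "KR"), n_words = c(2L, 1L),
                    n_p1 = c(10L, 10L), n_b1 = c(0L, 5L),
                    e_s = c(5, 2), stringsAsFactors = FALSE)
  seqs <- c(q1 = "AAKRQKKAAA")
  m <- scan_sequences(seqs, pat, scoring_config(use_bipartite = FALSE))
  # KR-KK spans 3-7; KR alone spans 3-4
  expect_equal(nrow(m), 2L)
  expect_equal(m$e_s[m$start == 3 & m$end == 7], 5)
  # identical span matched by two patterns appears once with max e_s
  pat2 <- rbind(pat[1, ], data.frame(words = "KR-KK", n_words = 2L,
                                     n_p1 = 3L, n_b1 = 10L, e_s = 1.2))
  m2 <- scan_sequences(seqs, pat2, scoring_config(use_bipartite = FALSE))
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$e_s, 5)
})
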