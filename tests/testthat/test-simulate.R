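test_that("generators are deterministic under the spec seed", {
  spec <- simulation_spec(seed = 77, n_pos = 10, n_neg = 20, n_query = 4)
  a <- simulate_training_corpus(spec)
  b <- simulate_training_corpus(spec)
  expect_identical(a, b)
  qa <- simulate_query_set(spec)
  qb <- simulate_query_set(spec)
  expect_identical(qa, qb)
  # a different seed changes the world
  expect_false(identical(
    a$corpus$positives,
    simulate_training_corpus(simulation_spec(seed = 78, n_pos = 10,
                                             n_neg = 20))$corpus$positives))
})

test_that("forced planting yields full word-set support", {
  spec <- simulation_spec(seed = 2, n_pos = 30, n_neg = 10,
                          planted_wordlists = list(c("KR", "KK")),
                          plant_prob = 1.0)
  tc <- simulate_training_corpus(spec)
  expect_equal(tc$truth$n_planted, 30L)
  fs <- mine_frequent_wordsets(tc$corpus)
  expect_equal(fs$support[fs$words == "KK-KR"], 30L)
  expect_equal(count_ordered_support(c("KR", "KK"),
                                     tc$corpus$positives), 30L)
})

test_that("with no planting no word-list is frequent above chance", {
  for (seed in c(100, 200, 300)) {
    spec <- simulation_spec(seed = seed, n_pos = 20, n_neg = 10,
                            plant_prob = 0)
    tc <- simulate_training_corpus(spec)
    expect_equal(nrow(tc$truth), 0L)
    fs <- mine_frequent_wordsets(tc$corpus, min_support = 3,
                                 max_set_size = 2)
    # the designated word-lists do not reach min_support by chance
    expect_false(any(c("KK-KR", "RK-RR") %in% fs$words))
  }
})

test_that("negatives are length-40 background peptides", {
  tc <- simulate_training_corpus(simulation_spec(seed = 3, n_pos = 5,
                                                 n_neg = 25))
  expect_true(all(nchar(tc$corpus$negatives) == 40L))
  expect_equal(tc$corpus$n_b, 25L)
})

test_that("query tracks carry the stated disorder contrast", {
  spec <- simulation_spec(seed = 11, n_query = 15)
  sim <- simulate_query_set(spec)
  ins <- outs <- numeric(0)
  for (i in seq_len(nrow(sim$annotations))) {
    a <- sim$annotations[i, ]
    d <- sim$disorder[[a$seq_id]]
    ins <- c(ins, d[a$start:a$end])
    outs <- c(outs, d[-(max(1, a$start - 10):min(length(d),
                                                 a$end + 10))])
  }
  expect_gt(mean(ins) - mean(outs),
            0.7 * (spec$disorder_in - spec$disorder_out))
  expect_true(all(ins >= 0 & ins <= 1))
})

test_that("planted bipartite intervals are found by the matcher", {
  sim <- simulate_query_set(simulation_spec(seed = 21, n_query = 25,
                                            bipartite_rate = 1.0))
  for (i in seq_len(nrow(sim$annotations))) {
    a <- sim$annotations[i, ]
    m <- match_bipartite(sim$sequences[[a$seq_id]], a$seq_id)
    expect_true(any(m$start == a$start & m$end == a$end),
                info = paste(a$seq_id, a$start))
  }
})

test_that("planted word-list intervals are matched by their pattern", {
  spec <- simulation_spec(seed = 31, n_query = 15, bipartite_rate = 0)
  sim <- simulate_query_set(spec)
  wl_keys <- vapply(spec$planted_wordlists, paste, "", collapse = "-")
  for (i in seq_len(nrow(sim$annotations))) {
    a <- sim$annotations[i, ]
    found <- any(vapply(spec$planted_wordlists, function(wl) {
      m <- match_wordlist(sim$sequences[[a$seq_id]], wl, 2, a$seq_id)
      nrow(m) > 0 && any(m$start == a$start & m$end == a$end)
    }, logical(1)))
    expect_true(found, info = paste(a$seq_id, a$start, a$label))
  }
})

test_that("planted motifs are more conserved than their flanks", {
  sims <- lapply(c(41, 42, 43), function(s)
    simulate_query_set(simulation_spec(seed = s, n_query = 20)))
  irlc_true <- irlc_rand <- numeric(0)
  set.seed(99)
  for (sim in sims) {
    for (i in seq_len(nrow(sim$annotations))) {
      a <- sim$annotations[i, ]
      cons <- sim$conservation[[a$seq_id]]
      irlc_true <- c(irlc_true, irlc_score(a$start, a$end, cons)$irlc)
      len <- a$end - a$start + 1L
      at <- sample(length(cons) - len, 1L)
      irlc_rand <- c(irlc_rand, irlc_score(at, at + len - 1L,
                                           cons)$irlc)
    }
  }
  expect_lt(mean(irlc_true), mean(irlc_rand))
})

test_that("generated files round-trip through the io layer", {
  spec <- simulation_spec(seed = 55, n_pos = 6, n_neg = 8, n_query = 3)
  tc <- simulate_training_corpus(spec)
  sim <- simulate_query_set(spec)
  d <- withr::local_tempdir()
  write_fasta(sim$sequences, file.path(d, "q.fasta"))
  expect_equal(read_fasta(file.path(d, "q.fasta")), sim$sequences)
  write_annotations(sim$annotations, file.path(d, "nls.tsv"))
  back <- read_annotations(file.path(d, "nls.tsv"))
  expect_equal(back$start, sim$annotations$start)
  write_track(sim$disorder, file.path(d, "dis.tsv"))
  expect_equal(read_track(file.path(d, "dis.tsv"), "disorder"),
               sim$disorder, ignore_attr = TRUE, tolerance = 1e-10)
  # toy PSSMs reproduce the conservation track exactly
  paths <- write_simulated_pssms(sim, file.path(d, "pssms"))
  id <- names(sim$sequences)[1]
  pssm <- read_pssm(paths[[id]], id)
  expect_equal(conservation_from_pssm(pssm), sim$conservation[[id]])
})

test_that("negative segments are length-matched and NLS-free", {
  spec <- simulation_spec(seed = 61, n_query = 10)
  sim <- simulate_query_set(spec)
  neg <- sample_negative_segments(sim$sequences, sim$annotations,
                                  seed = 8)
  expect_equal(nrow(neg), nrow(sim$annotations))
  expect_equal(neg$end - neg$start, sim$annotations$end -
                 sim$annotations$start)
  for (i in seq_len(nrow(neg))) {
    own <- sim$annotations[sim$annotations$seq_id == neg$seq_id[i], ]
    expect_false(any(neg$start[i] <= own$end & own$start <= neg$end[i]))
  }
  expect_identical(neg, sample_negative_segments(sim$sequences,
                                                 sim$annotations,
                                                 seed = 8))
})
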