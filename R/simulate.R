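#' Specification of a synthetic NLS world
#'
#' States the conditions the generators emulate. Defaults mirror the
#' reference training setup where a value is published: negatives are
#' length-40 peptides; mean disorder 0.632 inside NLSs vs 0.386 outside;
#' mean RSA 0.393 vs 0.299. Where no value is published a realistic one
#' is fixed here once: query proteins of 200-600 residues, NLS-like
#' positives of 12-25 residues, inter-word gaps uniform on {0, 1, 2},
#' uniform background composition, and a conservation boost of 4
#' log-odds units inside planted motifs over a noise floor of sd 1.5.
#'
#' @param seed Integer seed; all generators are deterministic under it.
#' @param n_pos,n_neg,n_query Corpus and query sizes.
#' @param planted_wordlists List of character vectors: the word-lists
#'   planted into positives and query NLSs.
#' @param plant_prob Probability that a positive peptide receives a
#'   planted word-list.
#' @param bipartite_rate Fraction of query NLSs planted as bipartite
#'   consensus instances rather than word-list instances.
#' @param background \code{"uniform"} over the 20 letters or
#'   \code{"kr_enriched"} (K and R at 3x weight, as in basic NLS
#'   neighbourhoods).
#' @param pos_length,query_length Integer ranges (min, max).
#' @param disorder_in,disorder_out,disorder_sd Disorder track model.
#' @param rsa_in,rsa_out,rsa_sd RSA track model.
#' @param cons_boost,cons_sd Conservation model: planted motifs are
#'   \code{cons_boost} units above the zero-mean background noise.
#' @param smooth Moving-average window for disorder/RSA tracks, so
#'   segment medians behave like real predictor output.
#' @return A \code{sim_spec} list.
#' @export
simulation_spec <- function(seed = 1L, n_pos = 30L, n_neg = 500L,
                            n_query = 40L,
                            planted_wordlists = list(c("KR", "KK"),
                                                     c("RK", "RR")),
                            plant_prob = 1.0, bipartite_rate = 0.3,
                            background = c("uniform", "kr_enriched"),
                            pos_length = c(12L, 25L),
                            query_length = c(200L, 600L),
                            disorder_in = 0.632, disorder_out = 0.386,
                            disorder_sd = 0.1,
                            rsa_in = 0.393, rsa_out = 0.299,
                            rsa_sd = 0.1,
                            cons_boost = 4, cons_sd = 1.5,
                            smooth = 5L) {
  background <- match.arg(background)
  stopifnot(plant_prob >= 0, plant_prob <= 1,
            bipartite_rate >= 0, bipartite_rate <= 1)
  structure(as.list(environment()), class = "sim_spec")
}

bg_freqs <- function(spec) {
  w <- rep(1, 20)
  if (spec$background == "kr_enriched")
    w[match(c("K", "R"), AA20)] <- 3
  w / sum(w)
}

random_peptide <- function(n, freqs) {
  paste(sample(AA20, n, replace = TRUE, prob = freqs), collapse = "")
}

# build a word-list instance with sampled gaps; returns the string
wordlist_instance <- function(wordlist, freqs, max_gap = 2L) {
  gaps <- if (length(wordlist) > 1L)
    sample(0:max_gap, length(wordlist) - 1L, replace = TRUE) else integer()
  parts <- character()
  for (k in seq_along(wordlist)) {
    parts <- c(parts, wordlist[k])
    if (k < length(wordlist) && gaps[k] > 0L)
      parts <- c(parts, random_peptide(gaps[k], freqs))
  }
  paste(parts, collapse = "")
}

bipartite_instance <- function(freqs) {
  head2 <- paste(sample(c("K", "R"), 2, replace = TRUE), collapse = "")
  spacer <- random_peptide(10L, freqs)
  tail5 <- sample(AA20[!AA20 %in% c("K", "R")], 5, replace = TRUE)
  tail5[sample(5L, 3L)] <- sample(c("K", "R"), 3L, replace = TRUE)
  paste0(head2, spacer, paste(tail5, collapse = ""))
}

splice_in <- function(seq, insert, at) {
  # overwrite residues at..at+nchar(insert)-1
  paste0(substr(seq, 1L, at - 1L), insert,
         substr(seq, at + nchar(insert), nchar(seq)))
}

#' Simulate a training corpus with planted word-lists
#'
#' Positives are background peptides of 12-25 residues, each receiving
#' (with probability \code{plant_prob}) one planted word-list instance
#' with gaps sampled on {0,...,max_gap}; negatives are pure background
#' peptides of length 40. Deterministic under the spec seed.
#'
#' @param spec A [simulation_spec()].
#' @return List: \code{corpus} (an [training_corpus()]),
#'   \code{truth} (data.frame of planted word-lists, dash-joined, and
#'   how often each was planted).
#' @export
simulate_training_corpus <- function(spec = simulation_spec()) {
  freqs <- bg_freqs(spec)
  with_seed(spec$seed, {
    planted <- character(spec$n_pos)
    positives <- character(spec$n_pos)
    for (i in seq_len(spec$n_pos)) {
      n <- sample(spec$pos_length[1]:spec$pos_length[2], 1L)
      s <- random_peptide(n, freqs)
      if (runif(1) <= spec$plant_prob) {
        wl <- spec$planted_wordlists[[
          sample(length(spec$planted_wordlists), 1L)]]
        inst <- wordlist_instance(wl, freqs)
        if (nchar(inst) > n)
          stop("planted word-list instance longer than peptide (",
               nchar(inst), " > ", n, ")")
        at <- sample(n - nchar(inst) + 1L, 1L)
        s <- splice_in(s, inst, at)
        planted[i] <- paste(wl, collapse = "-")
      }
      positives[i] <- s
    }
    names(positives) <- sprintf("pos%03d", seq_len(spec$n_pos))
    negatives <- vapply(seq_len(spec$n_neg), function(i)
      random_peptide(40L, freqs), character(1))
    names(negatives) <- sprintf("neg%04d", seq_len(spec$n_neg))
    tbl <- table(planted[planted != ""])
    truth <- data.frame(words = names(tbl),
                        n_planted = as.integer(tbl),
                        stringsAsFactors = FALSE)
    list(corpus = training_corpus(positives, negatives), truth = truth)
  })
}

smooth_track <- function(x, window) {
  if (window <= 1L) return(x)
  k <- rep(1 / window, window)
  as.numeric(stats::filter(c(rep(x[1], window), x, rep(x[length(x)],
                                                       window)),
                           k, sides = 2))[(window + 1):(window +
                                                          length(x))]
}

make_track <- function(L, inside, mean_in, mean_out, sd, window) {
  mu <- rep(mean_out, L)
  mu[inside] <- mean_in
  pmin(pmax(smooth_track(mu + rnorm(L, 0, sd), window), 0), 1)
}

#' Simulate query proteins with planted NLSs and score tracks
#'
#' Each query protein (200-600 residues of background) carries one
#' planted NLS: a bipartite-consensus instance with probability
#' \code{bipartite_rate}, otherwise a planted word-list instance.
#' Disorder and RSA tracks are elevated inside the planted interval
#' (means per the spec) and smoothed; conservation is integer
#' noise boosted inside the interval, so planted motifs are more
#' conserved than their flanks. Deterministic under the spec seed.
#'
#' @param spec A [simulation_spec()].
#' @return List: \code{sequences} (named character), \code{annotations}
#'   (seq_id, start, end, label in {wordlist, bipartite}),
#'   \code{disorder}, \code{rsa}, \code{conservation} (named lists of
#'   numeric vectors).
#' @export
simulate_query_set <- function(spec = simulation_spec()) {
  freqs <- bg_freqs(spec)
  with_seed(spec$seed + 1L, {
    ids <- sprintf("query%03d", seq_len(spec$n_query))
    seqs <- character(spec$n_query)
    ann <- vector("list", spec$n_query)
    disorder <- rsa <- conservation <- vector("list", spec$n_query)
    for (i in seq_len(spec$n_query)) {
      L <- sample(spec$query_length[1]:spec$query_length[2], 1L)
      s <- random_peptide(L, freqs)
      if (runif(1) <= spec$bipartite_rate) {
        inst <- bipartite_instance(freqs)
        label <- "bipartite"
      } else {
        wl <- spec$planted_wordlists[[
          sample(length(spec$planted_wordlists), 1L)]]
        inst <- wordlist_instance(wl, freqs)
        label <- "wordlist"
      }
      at <- sample(L - nchar(inst) + 1L, 1L)
      s <- splice_in(s, inst, at)
      seqs[i] <- s
      ann[[i]] <- data.frame(seq_id = ids[i], start = at,
                             end = at + nchar(inst) - 1L, label = label,
                             stringsAsFactors = FALSE)
      inside <- at:(at + nchar(inst) - 1L)
      disorder[[i]] <- make_track(L, inside, spec$disorder_in,
                                  spec$disorder_out, spec$disorder_sd,
                                  spec$smooth)
      rsa[[i]] <- make_track(L, inside, spec$rsa_in, spec$rsa_out,
                             spec$rsa_sd, spec$smooth)
      cons <- round(rnorm(L, 0, spec$cons_sd))
      cons[inside] <- cons[inside] + spec$cons_boost
      conservation[[i]] <- cons
    }
    names(seqs) <- names(disorder) <- names(rsa) <-
      names(conservation) <- ids
    list(sequences = seqs, annotations = do.call(rbind, ann),
         disorder = disorder, rsa = rsa, conservation = conservation)
  })
}

#' Length-matched negative segments for linear-motif training
#'
#' For each annotated NLS, samples one random segment of the same length
#' in the same parent protein that does not overlap any annotated NLS —
#' the construction used for the non-NLS half of the linear-motif
#' training set.
#'
#' @param seqs Named character vector of parent sequences.
#' @param annotations Annotation data.frame.
#' @param seed Integer seed.
#' @return data.frame of negative segments (seq_id, start, end).
#' @export
sample_negative_segments <- function(seqs, annotations, seed = 1L) {
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(annotations)), function(i) {
      id <- annotations$seq_id[i]
      L <- nchar(seqs[[id]])
      len <- annotations$end[i] - annotations$start[i] + 1L
      own <- annotations[annotations$seq_id == id, ]
      for (try in 1:200) {
        at <- sample(L - len + 1L, 1L)
        if (!any(at <= own$end & own$start <= at + len - 1L))
          return(data.frame(seq_id = id, start = at, end = at + len - 1L,
                            stringsAsFactors = FALSE))
      }
      NULL  # pathological: NLSs tile the protein; skip
    })
    do.call(rbind, rows)
  })
}

#' Emit toy PSSM files for a simulated query set
#'
#' Writes one PSI-BLAST ASCII PSSM per sequence in which the
#' own-residue column equals the simulated conservation score and every
#' other column is -1, so [conservation_from_pssm()] recovers the
#' simulated track exactly.
#'
#' @param sim A [simulate_query_set()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_simulated_pssms <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(sim$sequences), function(id) {
    res <- strsplit(sim$sequences[[id]], "")[[1]]
    scores <- matrix(-1L, length(res), 20L)
    col <- match(res, PSSM_COLS)
    scores[cbind(seq_along(res), col)] <-
      as.integer(sim$conservation[[id]])
    p <- file.path(dir, paste0(id, ".pssm"))
    write_pssm(sim$sequences[[id]], scores, p)
    p
  }, character(1))
  invisible(paths)
}
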