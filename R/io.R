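#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased and identifiers are taken from the header up
#' to the first whitespace. Residues outside the 20-letter amino-acid
#' alphabet other than \code{X} are rejected; \code{X} is permitted but
#' flagged with a warning (it never matches any word or consensus
#' position downstream).
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences, names are the ids.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  validate_sequences(seqs)
  seqs
}

validate_sequences <- function(seqs) {
  if (anyDuplicated(names(seqs))) {
    dup <- unique(names(seqs)[duplicated(names(seqs))])
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
  }
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for id(s): ",
         paste(names(seqs)[nchar(seqs) == 0L], collapse = ", "))
  bad <- grepl(paste0("[^", paste(AA20, collapse = ""), "X]"), seqs)
  if (any(bad))
    stop("non amino-acid characters in sequence(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  if (any(grepl("X", seqs, fixed = TRUE)))
    warning("sequence(s) contain residue X; X matches no pattern position")
  invisible(seqs)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read NLS annotations
#'
#' Tab-separated columns: seq_id, start, end (1-based inclusive), and an
#' optional label. A header line is detected automatically.
#'
#' @param path Path to the annotation TSV.
#' @return A data.frame with columns \code{seq_id}, \code{start},
#'   \code{end} and (if present) \code{label}.
#' @export
read_annotations <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  header <- length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[2])))
  df <- read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("annotation table needs >= 3 columns")
  names(df)[1:3] <- c("seq_id", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "label"
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(is.na(df$start)) || any(is.na(df$end)) ||
      any(df$start < 1L) || any(df$start > df$end))
    stop("invalid annotation interval(s): need 1 <= start <= end")
  df
}

#' Write NLS annotations
#' @param ann Data frame with seq_id, start, end (1-based inclusive).
#' @param path Output path.
#' @export
write_annotations <- function(ann, path) {
  write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read per-residue score tracks
#'
#' Tab-separated columns without header: seq_id, 1-based position, score.
#' Positions must be contiguous from 1 within each sequence. Disorder and
#' RSA tracks must lie in [0, 1]; conservation is unbounded (PSSM
#' log-odds).
#'
#' @param path Path to the track TSV.
#' @param kind One of \code{"disorder"}, \code{"rsa"},
#'   \code{"conservation"}.
#' @return A named list of numeric vectors (one per sequence), with
#'   attribute \code{kind}.
#' @export
read_track <- function(path, kind = c("disorder", "rsa", "conservation")) {
  kind <- match.arg(kind)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("seq_id", "pos", "score"))
  df$pos <- as.integer(df$pos)
  tracks <- lapply(split(df, df$seq_id), function(d) {
    d <- d[order(d$pos), ]
    expect <- seq_len(nrow(d))
    if (!identical(d$pos, expect)) {
      gap <- setdiff(seq_len(max(d$pos)), d$pos)
      stop("track for '", d$seq_id[1], "' has missing position(s): ",
           paste(head(gap, 5), collapse = ", "))
    }
    d$score
  })
  if (kind %in% c("disorder", "rsa")) {
    bad <- vapply(tracks, function(v) any(v < 0 | v > 1), logical(1))
    if (any(bad))
      stop(kind, " scores outside [0,1] for: ",
           paste(names(tracks)[bad], collapse = ", "))
  }
  structure(tracks, kind = kind)
}

#' Write per-residue score tracks
#' @param tracks Named list of numeric vectors.
#' @param path Output path.
#' @export
write_track <- function(tracks, path) {
  df <- do.call(rbind, lapply(names(tracks), function(id) {
    data.frame(seq_id = id, pos = seq_along(tracks[[id]]),
               score = tracks[[id]], stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the \code{-out_ascii_pssm} dialect: after the header lines, one
#' row per residue with a position index, the residue, 20 integer
#' log-odds columns (used) and 20 weighted-percentage columns (ignored).
#'
#' @param path Path to the PSSM file.
#' @param seq_id Identifier to attach; defaults to the file base name.
#' @return A list with \code{seq_id}, \code{residues} (string) and
#'   \code{scores} (n x 20 integer matrix, columns in PSI-BLAST order
#'   A R N D C Q E G H I L K M F P S T W Y V), class \code{nls_pssm}.
#' @export
read_pssm <- function(path, seq_id = NULL) {
  lines <- readLines(path)
  is_row <- grepl("^\\s*\\d+\\s+[A-Za-z]", lines)
  if (!any(is_row)) stop("no PSSM rows found in ", path)
  rows <- which(is_row)
  n <- length(rows)
  scores <- matrix(NA_integer_, n, 20L, dimnames = list(NULL, PSSM_COLS))
  residues <- character(n)
  for (k in seq_len(n)) {
    tok <- strsplit(trimws(lines[rows[k]]), "\\s+")[[1]]
    if (length(tok) < 22L)
      stop("malformed PSSM row at line ", rows[k], ": expected >= 22 ",
           "fields, got ", length(tok))
    residues[k] <- toupper(tok[2])
    vals <- suppressWarnings(as.integer(tok[3:22]))
    if (any(is.na(vals)))
      stop("non-numeric log-odds in PSSM row at line ", rows[k])
    scores[k, ] <- vals
  }
  structure(list(seq_id = seq_id %||% sub("\\.[^.]*$", "", basename(path)),
                 residues = paste(residues, collapse = ""),
                 scores = scores),
            class = "nls_pssm")
}

#' Conservation track from a PSSM
#'
#' The conservation score of residue i is the PSSM log-odds entry in row
#' i at the column of the sequence's own residue at that position.
#' Residue \code{X} has no own column and scores 0 (with a warning).
#'
#' @param pssm A parsed PSSM from [read_pssm()].
#' @return Numeric vector of per-residue conservation scores, length
#'   equal to the sequence length.
#' @export
conservation_from_pssm <- function(pssm) {
  stopifnot(inherits(pssm, "nls_pssm"))
  res <- strsplit(pssm$residues, "")[[1]]
  col <- match(res, PSSM_COLS)
  if (anyNA(col))
    warning("residue(s) without PSSM column (e.g. X) scored 0 in ",
            pssm$seq_id)
  vals <- numeric(length(res))
  ok <- !is.na(col)
  vals[ok] <- pssm$scores[cbind(which(ok), col[ok])]
  vals
}

#' Write a toy PSSM in the PSI-BLAST ASCII dialect
#'
#' Emits a file that [read_pssm()] parses back; used by the synthetic
#' data generator so the parser is exercised end-to-end.
#'
#' @param seq Amino-acid sequence (character scalar).
#' @param scores n x 20 integer matrix, PSI-BLAST column order.
#' @param path Output path.
#' @export
write_pssm <- function(seq, scores, path) {
  res <- strsplit(seq, "")[[1]]
  stopifnot(nrow(scores) == length(res), ncol(scores) == 20L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed",
               paste0("      ", paste(sprintf("%3s", c(PSSM_COLS, PSSM_COLS)),
                                      collapse = ""))), con)
  pct <- rep(0L, 20L)
  for (i in seq_along(res)) {
    writeLines(paste0(sprintf("%5d %s ", i, res[i]),
                      paste(sprintf("%3d", scores[i, ]), collapse = ""),
                      paste(sprintf("%4d", pct), collapse = "")), con)
  }
  invisible(path)
}
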