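# Consensus-sequence scanning: ungapped Hamming-similarity search of a
# fixed-length operator consensus against both strands of a genome.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

check_iupac <- function(x, what) {
  chars <- strsplit(toupper(x), "")[[1]]
  bad <- which(!chars %in% names(IUPAC_SETS))
  if (length(bad)) {
    stop(what, " contains non-IUPAC characters at position(s) ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  chars
}

#' The 22-bp operator consensus sequence
#'
#' The semi-palindromic consensus element recognized by gamma-butyrolactone
#' receptor regulators, used as the default search string by [scan_motif()].
#'
#' @return A character scalar, 5' to 3'.
#' @export
consensus_cs <- function() "ACATACGGGACGCCCCGTTTAT"

#' Score a window against an IUPAC consensus
#'
#' Counts the positions at which the window base is compatible with the
#' consensus IUPAC code (ungapped Hamming similarity).
#'
#' @param consensus IUPAC consensus string.
#' @param window Candidate sequence of equal length.
#' @return Integer match count in `[0, nchar(consensus)]`.
#' @export
score_window <- function(consensus, window) {
  cc <- check_iupac(consensus, "consensus")
  wc <- check_iupac(window, "window")
  if (length(cc) != length(wc)) {
    stop("consensus and window lengths differ (", length(cc), " vs ",
         length(wc), ")", call. = FALSE)
  }
  sum(vapply(seq_along(cc), function(i) wc[i] %in% IUPAC_SETS[[cc[i]]], logical(1)))
}

# Score every window of the genome against the consensus, vectorized over
# windows (one pass per consensus position).
scan_scores <- function(genome_chars, cons_chars) {
  L <- length(cons_chars)
  n_win <- length(genome_chars) - L + 1
  scores <- integer(n_win)
  idx <- seq_len(n_win)
  for (p in seq_len(L)) {
    ok <- genome_chars[idx + p - 1] %in% IUPAC_SETS[[cons_chars[p]]]
    scores <- scores + ok
  }
  scores
}

#' Scan a genome for consensus-sequence matches
#'
#' Slides the consensus over every window of the plus strand and, when
#' `both_strands`, also matches the reverse-complemented consensus against
#' the same windows (reporting those hits on the minus strand). Coordinates
#' are 1-based inclusive on the plus strand regardless of hit strand; the
#' matched subsequence is reported as read 5' to 3' on its own strand.
#' Overlapping hits are retained.
#'
#' @param genome Genome sequence: a character string, or a named character
#'   vector / `Biostrings::DNAStringSet` of records.
#' @param consensus IUPAC consensus string (default [consensus_cs()]).
#' @param min_score Minimum match count to report.
#' @param both_strands Scan the minus strand too (default TRUE).
#' @return A tibble sorted by descending score then ascending position:
#'   `record`, `start`, `end`, `strand`, `score`, `subsequence`.
#' @export
scan_motif <- function(genome, consensus = consensus_cs(), min_score,
                       both_strands = TRUE) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  if (is.null(names(genome))) names(genome) <- rep("seq", length(genome))
  cons <- toupper(consensus)
  cc <- check_iupac(cons, "consensus")
  L <- length(cc)
  if (missing(min_score)) stop("min_score is required (no endorsed default)",
                               call. = FALSE)
  out <- purrr::map_dfr(seq_along(genome), function(g) {
    gc <- check_iupac(genome[[g]], paste0("genome record ", names(genome)[g]))
    if (length(gc) < L) stop("genome record shorter than the consensus",
                             call. = FALSE)
    gstr <- paste(gc, collapse = "")
    plus <- scan_scores(gc, cc)
    res <- tibble::tibble(
      record = names(genome)[g],
      start = which(plus >= min_score),
      strand = "+"
    )
    res$score <- plus[res$start]
    if (both_strands) {
      rc <- check_iupac(revcomp(cons), "reverse-complemented consensus")
      minus <- scan_scores(gc, rc)
      res2 <- tibble::tibble(
        record = names(genome)[g],
        start = which(minus >= min_score),
        strand = "-"
      )
      res2$score <- minus[res2$start]
      res <- dplyr::bind_rows(res, res2)
    }
    res$end <- res$start + L - 1L
    res$subsequence <- if (nrow(res)) substring(gstr, res$start, res$end) else character(0)
    minus <- which(res$strand == "-")
    if (length(minus)) {
      res$subsequence[minus] <- vapply(res$subsequence[minus], revcomp, character(1))
    }
    res
  })
  out <- dplyr::arrange(out, dplyr::desc(.data$score), .data$start, .data$strand)
  out[, c("record", "start", "end", "strand", "score", "subsequence")]
}

#' Column-wise conservation annotation of an alignment
#'
#' Per column of the (equal-length, ungapped) alignment: `*` when all
#' sequences agree, `:` when at least two agree but not all, space otherwise.
#'
#' @param sequences Character vector of at least two equal-length sequences.
#' @return A list with `sequences` (uppercase) and `annotation` (a string of
#'   `*`, `:` and spaces of the alignment length).
#' @export
annotate_conservation <- function(sequences) {
  if (length(sequences) < 2) stop("need at least 2 sequences", call. = FALSE)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1) {
    stop("sequences have ragged lengths: ", paste(lens, collapse = ", "),
         call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(toupper(sequences), ""))
  ann <- apply(mat, 2, function(col) {
    tab <- table(col)
    if (length(tab) == 1) "*" else if (max(tab) >= 2) ":" else " "
  })
  list(sequences = toupper(sequences), annotation = paste(ann, collapse = ""))
}

#' Read and write FASTA sequence files
#'
#' Thin wrappers around Biostrings for plain DNA FASTA.
#'
#' @param path File path.
#' @param sequences Named character vector of sequences.
#' @return `read_fasta` returns a named character vector.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  ss <- Biostrings::DNAStringSet(unlist(sequences))
  names(ss) <- names(sequences) %||% paste0("seq", seq_along(sequences))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
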