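#' Generate a random genome with planted degenerate motif copies
#'
#' Draws a background sequence with the requested GC content and overwrites
#' it at the requested positions with copies of a motif carrying exactly the
#' requested number of mismatches (mismatch positions and substituted bases
#' chosen by the seeded generator). Minus-strand plants are inserted as the
#' reverse complement. Deterministic for a fixed seed and independent of the
#' global RNG state.
#'
#' @param length Genome length in bp.
#' @param gc_fraction Background GC content in `[0, 1]` (default 0.5).
#' @param plants Optional tibble/data frame with columns `motif`, `position`
#'   (1-based start on the plus strand), `strand` (`"+"`/`"-"`) and
#'   `mismatches` (non-negative integer).
#' @param seed Integer seed.
#' @return A character string of A/C/G/T.
#' @export
#' @examples
#' g <- generate_genome(500, plants = tibble::tibble(
#'   motif = consensus_cs(), position = 101, strand = "+", mismatches = 0
#' ), seed = 3)
#' substr(g, 101, 122)
generate_genome <- function(length, gc_fraction = 0.5, plants = NULL, seed = 1) {
  stopifnot(length >= 1, gc_fraction >= 0, gc_fraction <= 1)
  probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
             G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  chars <- with_local_seed(seed, {
    bg <- sample(names(probs), length, replace = TRUE, prob = probs)
    if (!is.null(plants) && nrow(plants) > 0) {
      plants <- tibble::as_tibble(plants)
      need <- c("motif", "position", "strand", "mismatches")
      if (!all(need %in% names(plants))) {
        stop("plants needs columns: ", paste(need, collapse = ", "), call. = FALSE)
      }
      iv <- cbind(plants$position, plants$position + nchar(plants$motif) - 1)
      if (any(iv[, 1] < 1) || any(iv[, 2] > length)) {
        stop("planted motif extends outside the genome", call. = FALSE)
      }
      ord <- order(iv[, 1])
      if (nrow(plants) > 1 &&
          any(iv[ord, 1][-1] <= iv[ord, 2][-nrow(plants)])) {
        stop("planted motifs overlap", call. = FALSE)
      }
      for (k in seq_len(nrow(plants))) {
        motif <- toupper(plants$motif[k])
        if (plants$strand[k] == "-") motif <- revcomp(motif)
        mc <- strsplit(motif, "")[[1]]
        if (!all(mc %in% c("A", "C", "G", "T"))) {
          stop("planted motifs must be A/C/G/T", call. = FALSE)
        }
        mm <- plants$mismatches[k]
        if (mm < 0 || mm > base::length(mc)) {
          stop("mismatch count out of range for plant ", k, call. = FALSE)
        }
        if (mm > 0) {
          pos <- sample(seq_along(mc), mm)
          for (p in pos) mc[p] <- sample(setdiff(c("A", "C", "G", "T"), mc[p]), 1)
        }
        bg[plants$position[k]:(plants$position[k] + base::length(mc) - 1)] <- mc
      }
    }
    bg
  })
  paste(chars, collapse = "")
}
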