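#' Build an ideal or deformed B-form DNA duplex
#'
#' Constructs a two-chain duplex by stacking standard-geometry base-pair
#' templates along a fiber model: base-pair frames are propagated with the
#' requested helical twist and rise (and, optionally, per-step roll and tilt)
#' using the mid-step-triad construction, so that [step_parameters()] on the
#' result reproduces the requested values to numerical precision. Strand I is
#' chain `A` numbered 1..N in the 5' to 3' direction of `sequence`; strand II
#' (chain `B`) is the reverse complement, numbered 5' to 3' on its own strand.
#'
#' @param sequence Strand-I sequence, 5' to 3'; A/C/G/T only, length >= 2.
#' @param twist_per_step Helical twist in degrees; scalar or one value per
#'   step (default 36.0).
#' @param rise_per_step Helical rise in angstrom; scalar or per step
#'   (default 3.38).
#' @param roll_profile Optional per-step roll in degrees (scalar or length
#'   `nchar(sequence) - 1`); default 0.
#' @param tilt_profile Optional per-step tilt in degrees; default 0.
#' @param chain_ids Two chain identifiers, default `c("A", "B")`.
#' @return A `tetr_structure` tibble of the duplex.
#' @export
#' @examples
#' dup <- build_ideal_bdna("ACGTACGT")
#' nrow(pair_duplex(dup, "A", "B"))
build_ideal_bdna <- function(sequence, twist_per_step = 36.0, rise_per_step = 3.38,
                             roll_profile = NULL, tilt_profile = NULL,
                             chain_ids = c("A", "B")) {
  seq_chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(seq_chars) < 2) {
    stop("duplex sequence must contain at least 2 bases", call. = FALSE)
  }
  bad <- setdiff(unique(seq_chars), c("A", "C", "G", "T"))
  if (length(bad)) {
    stop("invalid characters in duplex sequence: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- length(seq_chars)
  n_steps <- n - 1
  expand <- function(x, default) {
    if (is.null(x)) x <- default
    if (length(x) == 1) x <- rep(x, n_steps)
    if (length(x) != n_steps) {
      stop("per-step parameter must have length 1 or ", n_steps, call. = FALSE)
    }
    x
  }
  twist <- expand(twist_per_step, 36.0)
  rise <- expand(rise_per_step, 3.38)
  roll <- expand(roll_profile, 0)
  tilt <- expand(tilt_profile, 0)

  frames <- vector("list", n)
  frames[[1]] <- list(R = diag(3), o = c(0, 0, 0))
  for (s in seq_len(n_steps)) {
    frames[[s + 1]] <- apply_step(frames[[s]]$R, frames[[s]]$o,
                                  0, 0, rise[s], tilt[s], roll[s], twist[s])
  }

  flip <- diag(c(1, -1, -1))
  place <- function(template, R, o) {
    sweep(template %*% t(R), 2, o, "+")
  }
  rows <- vector("list", 2 * n)
  for (i in seq_len(n)) {
    tmpl <- nucleotide_template(seq_chars[i])
    xyz <- place(tmpl, frames[[i]]$R, frames[[i]]$o)
    rows[[i]] <- tibble::tibble(
      chain = chain_ids[1], resno = i, resid = paste0("D", seq_chars[i]),
      elety = rownames(tmpl), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
    )
  }
  comp <- unname(COMPLEMENT[seq_chars])
  for (j in seq_len(n)) {
    level <- n + 1 - j                      # strand II residue j pairs level n+1-j
    tmpl <- nucleotide_template(comp[level])
    xyz <- place(tmpl, frames[[level]]$R %*% flip, frames[[level]]$o)
    rows[[n + j]] <- tibble::tibble(
      chain = chain_ids[2], resno = j, resid = paste0("D", comp[level]),
      elety = rownames(tmpl), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
    )
  }
  atoms <- dplyr::bind_rows(rows)
  atoms$elesy <- toupper(substr(gsub("[0-9']", "", atoms$elety), 1, 1))
  new_structure(atoms, id = paste0("bdna_", n, "bp"))
}

#' Reverse-complement a DNA sequence string
#'
#' @param sequence Character string over the IUPAC DNA alphabet.
#' @return The reverse complement, uppercase.
#' @export
revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(sequence))))
}
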