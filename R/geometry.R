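# Base-pair reference frames, step parameters, bend and groove geometry.
#
# Conventions follow the 3DNA family of tools: base frames are obtained by
# least-squares superposition of standard-geometry bases onto the observed
# ring atoms (the standard reference frame), pair frames average the two base
# frames after flipping the complementary strand, and step parameters come
# from the mid-step-triad decomposition (roll about y, tilt about x, twist
# about z).

#' Reference frame of a single base
#'
#' Superposes the standard-geometry base of the residue's type onto the
#' observed ring atoms (Kabsch least squares) and returns the fitted frame.
#'
#' @param structure A structure tibble.
#' @param chain Chain identifier.
#' @param resno Residue number.
#' @return A list with `origin` (3-vector, angstrom), `axes` (3x3 rotation,
#'   columns x/y/z), `rmsd` (fit RMSD, angstrom) and `base`.
#' @export
base_frame <- function(structure, chain, resno) {
  res <- structure[structure$chain == chain & structure$resno == resno &
                     !structure$water, ]
  if (nrow(res) == 0) stop("residue not found: ", chain, " ", resno, call. = FALSE)
  base <- normalize_base(res$resid[1])
  ring <- base_ring_atoms(base)
  missing <- setdiff(ring, res$elety)
  if (length(missing)) {
    stop("residue ", chain, " ", resno, " is missing ring atoms: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tmpl <- base_template(base)[ring, , drop = FALSE]
  obs <- do.call(rbind, lapply(ring, function(a) get_atom(res, chain, resno, a)))
  fit_frame(tmpl, obs, base)
}

# Kabsch superposition: observed = R %*% template + t.
fit_frame <- function(tmpl, obs, base = NA_character_) {
  tm <- colMeans(tmpl); om <- colMeans(obs)
  H <- t(sweep(tmpl, 2, tm)) %*% sweep(obs, 2, om)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  origin <- as.vector(om - R %*% tm)
  fitted <- sweep(tmpl %*% t(R), 2, origin, "+")
  rmsd <- sqrt(mean(rowSums((fitted - obs)^2)))
  list(origin = origin, axes = R, rmsd = rmsd, base = base)
}

# Base-pair frames for the Watson-Crick pairs of a duplex, in level order.
pair_frames <- function(structure, pairs) {
  wc <- pairs[pairs$pair_type == "watson-crick", ]
  lapply(seq_len(nrow(wc)), function(k) {
    fa <- base_frame(structure, wc$chain_i[k], wc$resno_i[k])
    fb <- base_frame(structure, wc$chain_ii[k], wc$resno_ii[k])
    Rb <- fb$axes %*% diag(c(1, -1, -1))   # flip complementary strand
    R <- project_rotation(fa$axes + Rb)
    list(R = R, o = (fa$origin + fb$origin) / 2,
         level = k, resno_i = wc$resno_i[k], resno_ii = wc$resno_ii[k])
  })
}

wc_pairs <- function(structure, chain_a, chain_b, pairs = NULL) {
  if (is.null(pairs)) pairs <- pair_duplex(structure, chain_a, chain_b)
  pairs[pairs$pair_type == "watson-crick", ]
}

#' Base-pair step parameters of a duplex
#'
#' Computes the six rigid-body step parameters (shift, slide, rise, tilt,
#' roll, twist) between consecutive Watson-Crick base-pair frames via the
#' mid-step-triad construction. Unpaired overhangs are skipped.
#'
#' @param structure A structure tibble containing the duplex.
#' @param chain_a,chain_b Strand chain identifiers.
#' @param pairs Optional precomputed [pair_duplex()] table.
#' @return A tibble with one row per step: `step` (1-based, 5' to 3' on
#'   strand I), `resno_i` (strand-I residue starting the step), `shift`,
#'   `slide`, `rise` (angstrom), `tilt`, `roll`, `twist` (degrees).
#' @export
#' @examples
#' dup <- build_ideal_bdna("ACGTACG")
#' step_parameters(dup, "A", "B")
step_parameters <- function(structure, chain_a, chain_b, pairs = NULL) {
  wc <- wc_pairs(structure, chain_a, chain_b, pairs)
  if (nrow(wc) < 2) {
    stop("step parameters need at least 2 consecutive Watson-Crick pairs",
         call. = FALSE)
  }
  fr <- pair_frames(structure, wc)
  purrr::map_dfr(seq_len(length(fr) - 1), function(s) {
    st <- extract_step(fr[[s]]$R, fr[[s]]$o, fr[[s + 1]]$R, fr[[s + 1]]$o)
    tibble::tibble(
      step = s, resno_i = wc$resno_i[s],
      shift = st$shift, slide = st$slide, rise = st$rise,
      tilt = st$tilt, roll = st$roll, twist = st$twist
    )
  })
}

#' Mean and standard deviation of step parameters
#'
#' @param steps A [step_parameters()] tibble.
#' @return A tibble with columns `parameter`, `mean`, `sd` (sample SD; 0 for
#'   a single step).
#' @export
average_params <- function(steps) {
  if (is.null(steps) || nrow(steps) == 0) {
    stop("no steps to average", call. = FALSE)
  }
  long <- tidyr::pivot_longer(
    steps[, c("shift", "slide", "rise", "tilt", "roll", "twist")],
    cols = dplyr::everything(), names_to = "parameter", values_to = "value"
  )
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$parameter),
    mean = mean(.data$value),
    sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
    .groups = "drop"
  )
  out[match(c("shift", "slide", "rise", "tilt", "roll", "twist"), out$parameter), ]
}

# Local helical-axis direction fitted to three consecutive pair frames: the
# normalized mean of their helix-advance (z) axes. Exact for a uniform
# segment; a local estimate for curved DNA.
segment_axis <- function(f1, f2, f3) {
  unitize(f1$R[, 3] + f2$R[, 3] + f3$R[, 3])
}

#' Global bend of a DNA duplex
#'
#' End-to-end bend: the angle between the helical-axis direction of the first
#' three base pairs and that of the last three (`method = "end_axes"`, the
#' default). `method = "cumulative"` instead sums the per-step bending
#' magnitudes `sqrt(roll^2 + tilt^2)`.
#'
#' @inheritParams step_parameters
#' @param method `"end_axes"` or `"cumulative"`.
#' @return Bend angle in degrees, in `[0, 180)`.
#' @export
global_bend <- function(structure, chain_a, chain_b, pairs = NULL,
                        method = c("end_axes", "cumulative")) {
  method <- match.arg(method)
  wc <- wc_pairs(structure, chain_a, chain_b, pairs)
  if (nrow(wc) < 4) {
    stop("global bend needs at least 4 consecutive Watson-Crick pairs",
         call. = FALSE)
  }
  if (method == "cumulative") {
    st <- step_parameters(structure, chain_a, chain_b, pairs = wc)
    return(sum(sqrt(st$roll^2 + st$tilt^2)))
  }
  fr <- pair_frames(structure, wc)
  n <- length(fr)
  a1 <- segment_axis(fr[[1]], fr[[2]], fr[[3]])
  a2 <- segment_axis(fr[[n - 2]], fr[[n - 1]], fr[[n]])
  rad2deg(acos(max(-1, min(1, sum(a1 * a2)))))
}

#' Major- and minor-groove widths of a duplex
#'
#' Groove widths follow the direct phosphate convention: at each base-pair
#' level the minimal cross-strand P-P distance is taken over a fixed window
#' of partner-strand levels bracketing the canonical register of each groove,
#' and 5.8 angstrom (two phosphate-group radii) is subtracted. The windows
#' (major: partner levels l-1..l+3; minor: l-6..l-3, in strand-I level
#' coordinates) are calibrated so that the default ideal fiber duplex
#' reports the canonical ideal-B widths of 11.7 (major) and 5.7 (minor)
#' angstrom. Levels whose window leaves the duplex, or lacking phosphates,
#' are flagged not measurable (`NA`).
#'
#' @inheritParams step_parameters
#' @return A tibble with `level`, `major_width`, `minor_width` (angstrom,
#'   `NA` when not measurable) and `definition_tag`.
#' @export
groove_widths <- function(structure, chain_a, chain_b, pairs = NULL) {
  wc <- wc_pairs(structure, chain_a, chain_b, pairs)
  n <- nrow(wc)
  if (n < 7) {
    stop("groove widths need at least 7 consecutive Watson-Crick pairs",
         call. = FALSE)
  }
  p_i <- lapply(seq_len(n), function(l) {
    tryCatch(get_atom(structure, wc$chain_i[l], wc$resno_i[l], "P"),
             error = function(e) NULL)
  })
  p_ii <- lapply(seq_len(n), function(l) {
    tryCatch(get_atom(structure, wc$chain_ii[l], wc$resno_ii[l], "P"),
             error = function(e) NULL)
  })
  if (all(vapply(p_i, is.null, logical(1))) || all(vapply(p_ii, is.null, logical(1)))) {
    stop("no phosphorus atoms found on the duplex strands", call. = FALSE)
  }
  width_at <- function(l, partner_levels) {
    if (any(partner_levels < 1) || any(partner_levels > n)) return(NA_real_)
    if (is.null(p_i[[l]])) return(NA_real_)
    ds <- vapply(partner_levels, function(m) {
      if (is.null(p_ii[[m]])) return(NA_real_)
      vnorm(p_i[[l]] - p_ii[[m]])
    }, numeric(1))
    if (anyNA(ds)) return(NA_real_)
    min(ds) - 5.8
  }
  tibble::tibble(
    level = seq_len(n),
    major_width = vapply(seq_len(n), function(l) width_at(l, (l - 1):(l + 3)), numeric(1)),
    minor_width = vapply(seq_len(n), function(l) width_at(l, (l - 6):(l - 3)), numeric(1)),
    definition_tag = "min cross-strand P-P minus 5.8 A (major window l-1..l+3, minor l-6..l-3)"
  )
}
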