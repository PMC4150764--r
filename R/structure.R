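#' Atom-table representation of a macromolecular structure
#'
#' Structures are carried as tibbles with one row per atom and columns
#' `type` (ATOM/HETATM), `eleno`, `elety` (atom name, PDB convention),
#' `resid` (residue name), `chain`, `resno`, `insert`, `x`, `y`, `z`
#' (angstrom), `o` (occupancy), `b` (B-factor), `elesy` (element) and
#' `water` (logical flag). Row order is file order and is meaningful.
#'
#' @param atoms A data frame with the columns above (missing ones are filled
#'   with defaults).
#' @param id Optional structure identifier stored as an attribute.
#' @return A tibble of class `tetr_structure`.
#' @export
#' @examples
#' s <- new_structure(tibble::tibble(
#'   elety = "P", resid = "DA", chain = "A", resno = 1,
#'   x = 0, y = 0, z = 0, elesy = "P"
#' ))
#' nrow(s)
new_structure <- function(atoms, id = "structure") {
  atoms <- tibble::as_tibble(atoms)
  defaults <- list(
    type = "ATOM", eleno = NA_integer_, elety = NA_character_,
    resid = NA_character_, chain = "A", resno = NA_integer_, insert = "",
    x = NA_real_, y = NA_real_, z = NA_real_, o = 1, b = 0,
    elesy = NA_character_, water = NA
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(atoms)) atoms[[nm]] <- defaults[[nm]]
  }
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$elety <- gsub("\\*", "'", atoms$elety)
  atoms$water <- toupper(atoms$resid) %in% c("HOH", "WAT", "DOD", "H2O")
  if (any(is.na(atoms$eleno))) atoms$eleno <- seq_len(nrow(atoms))
  if (any(is.na(atoms$elesy))) {
    guess <- toupper(substr(gsub("[0-9' ]", "", atoms$elety), 1, 1))
    atoms$elesy[is.na(atoms$elesy)] <- guess[is.na(atoms$elesy)]
  }
  atoms <- atoms[, names(defaults)]
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)), all(is.finite(atoms$z)))
  out <- tibble::new_tibble(atoms, id = id, class = "tetr_structure")
  out
}

#' @export
#' @rdname new_structure
structure_id <- function(structure) attr(structure, "id") %||% "structure"

#' Read a structure from a PDB file
#'
#' Parses fixed-width ATOM/HETATM records through bio3d. Alternate locations
#' are resolved to the highest-occupancy conformer (ties broken by file
#' order); waters are retained and flagged in the `water` column.
#'
#' @param path Path to a PDB-format text file.
#' @param model 1-based model index (for multi-model files); default first.
#' @return A `tetr_structure` tibble.
#' @export
read_structure <- function(path, model = 1) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path, call. = FALSE)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("not a readable PDB file (", conditionMessage(e), "): ",
                             path, call. = FALSE)
  )
  at <- tibble::as_tibble(pdb$atom)
  if (nrow(at) == 0) stop("format error: no ATOM/HETATM records in ", path, call. = FALSE)
  if (model > 1) {
    if (is.null(pdb$xyz) || nrow(pdb$xyz) < model) {
      stop("model index ", model, " not present in ", path, call. = FALSE)
    }
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # altloc policy: highest occupancy wins, ties by file order
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  keep <- rep(TRUE, nrow(at))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    best <- idx[which.max(at$o[idx])]
    keep[setdiff(idx, best)] <- FALSE
  }
  at <- at[keep, ]
  new_structure(at, id = sub("\\.(pdb|ent)$", "", basename(path)))
}

#' Write a structure to a PDB file
#'
#' The inverse of [read_structure()]: `read_structure(write_structure(s))`
#' reproduces atom names, numbering and coordinates to the 0.001-angstrom
#' precision of the fixed-width PDB format, and writing a re-read structure
#' reproduces the ATOM block byte for byte.
#'
#' @param structure A `tetr_structure` or compatible data frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(structure, path) {
  if (nrow(structure) == 0) stop("refusing to write an empty structure", call. = FALSE)
  if (nrow(structure) > 99999) {
    stop("overflow: fixed-width PDB serial field cannot hold > 99999 atoms", call. = FALSE)
  }
  if (any(nchar(trimws(structure$chain)) > 1)) {
    stop("format error: PDB chain identifiers must be a single character", call. = FALSE)
  }
  ok <- tryCatch({
    bio3d::write.pdb(
      pdb = NULL, file = path,
      xyz = as.vector(t(as.matrix(structure[, c("x", "y", "z")]))),
      type = structure$type, resno = structure$resno, resid = structure$resid,
      eleno = seq_len(nrow(structure)), elety = structure$elety,
      chain = structure$chain, insert = structure$insert,
      o = structure$o, b = structure$b, elesy = structure$elesy
    )
    TRUE
  }, error = function(e) stop("cannot write PDB file ", path, " (",
                              conditionMessage(e), ")", call. = FALSE))
  invisible(path)
}

#' Select atoms by chain, residue range and atom name
#'
#' @param structure A structure tibble.
#' @param chains Character vector of chain ids (NULL = all).
#' @param resno Integer vector of residue numbers (NULL = all).
#' @param elety Character vector of atom names (NULL = all).
#' @param heavy_only Drop hydrogens and deuteriums.
#' @param drop_waters Drop flagged water molecules.
#' @return The filtered structure tibble.
#' @export
select_atoms <- function(structure, chains = NULL, resno = NULL, elety = NULL,
                         heavy_only = TRUE, drop_waters = TRUE) {
  out <- structure
  if (!is.null(chains)) out <- out[out$chain %in% chains, ]
  if (!is.null(resno)) out <- out[out$resno %in% resno, ]
  if (!is.null(elety)) out <- out[out$elety %in% elety, ]
  if (heavy_only) out <- out[!toupper(out$elesy) %in% c("H", "D"), ]
  if (drop_waters) out <- out[!out$water, ]
  out
}

#' Apply a rigid-body transformation to a structure
#'
#' @param structure A structure tibble.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation vector (angstrom).
#' @return The transformed structure.
#' @export
transform_structure <- function(structure, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- as.matrix(structure[, c("x", "y", "z")]) %*% t(rotation)
  structure$x <- xyz[, 1] + translation[1]
  structure$y <- xyz[, 2] + translation[2]
  structure$z <- xyz[, 3] + translation[3]
  structure
}

atom_xyz <- function(structure) {
  unname(as.matrix(structure[, c("x", "y", "z")]))
}

# Retrieve the coordinates of a single named atom; error if absent/ambiguous.
get_atom <- function(structure, chain, resno, elety) {
  hit <- structure[structure$chain == chain & structure$resno == resno &
                     structure$elety == elety, ]
  if (nrow(hit) == 0) {
    stop("atom not found: chain ", chain, " residue ", resno, " atom ", elety,
         call. = FALSE)
  }
  c(hit$x[1], hit$y[1], hit$z[1])
}

# Residue table for a chain, in file order.
chain_residues <- function(structure, chain) {
  sub <- structure[structure$chain == chain & !structure$water, ]
  key <- paste(sub$resno, sub$insert, sep = "\r")
  idx <- !duplicated(key)
  tibble::tibble(
    chain = chain,
    resno = sub$resno[idx],
    insert = sub$insert[idx],
    resid = sub$resid[idx]
  )
}

#' Identify Watson-Crick pairing between two DNA strands
#'
#' A pair is called when (i) the bases are complementary (A-T, G-C), (ii) the
#' C1'-C1' distance lies in 8.9-11.9 angstrom, and (iii) the glycosidic-face
#' heavy-atom hydrogen-bond distance (purine N1 to pyrimidine N3) is at most
#' 3.5 angstrom. Each residue joins at most one pair; unpaired terminal
#' nucleotides are reported as overhangs. The result is ordered 5' to 3'
#' along `chain_a`.
#'
#' @param structure A structure tibble containing both strands.
#' @param chain_a,chain_b Chain identifiers of the two strands.
#' @return A tibble with one row per strand-I residue (plus strand-II
#'   overhangs): `chain_i`, `resno_i`, `base_i`, `chain_ii`, `resno_ii`,
#'   `base_ii`, `pair_type` (`"watson-crick"` or `"overhang"`), `c1_dist`,
#'   `hbond_dist`.
#' @export
pair_duplex <- function(structure, chain_a, chain_b) {
  res_a <- chain_residues(structure, chain_a)
  res_b <- chain_residues(structure, chain_b)
  if (nrow(res_a) == 0 || nrow(res_b) == 0) {
    stop("chain not present or empty", call. = FALSE)
  }
  if (!all(is_nucleotide_resid(res_a$resid)) || !all(is_nucleotide_resid(res_b$resid))) {
    stop("pair_duplex requires two nucleotide chains", call. = FALSE)
  }
  base_a <- vapply(res_a$resid, normalize_base, character(1))
  base_b <- vapply(res_b$resid, normalize_base, character(1))

  glyco <- function(base) if (base %in% c("A", "G")) "N1" else "N3"
  cand <- NULL
  for (i in seq_len(nrow(res_a))) {
    for (j in seq_len(nrow(res_b))) {
      if (COMPLEMENT[[base_a[i]]] != base_b[j]) next
      c1a <- tryCatch(get_atom(structure, chain_a, res_a$resno[i], "C1'"),
                      error = function(e) NULL)
      c1b <- tryCatch(get_atom(structure, chain_b, res_b$resno[j], "C1'"),
                      error = function(e) NULL)
      if (is.null(c1a) || is.null(c1b)) next
      dc1 <- vnorm(c1a - c1b)
      if (dc1 < 8.9 || dc1 > 11.9) next
      ga <- tryCatch(get_atom(structure, chain_a, res_a$resno[i], glyco(base_a[i])),
                     error = function(e) NULL)
      gb <- tryCatch(get_atom(structure, chain_b, res_b$resno[j], glyco(base_b[j])),
                     error = function(e) NULL)
      if (is.null(ga) || is.null(gb)) next
      dh <- vnorm(ga - gb)
      if (dh > 3.5) next
      cand <- rbind(cand, c(i, j, dc1, dh))
    }
  }
  used_a <- logical(nrow(res_a)); used_b <- logical(nrow(res_b))
  pairs <- NULL
  if (!is.null(cand)) {
    cand <- cand[order(cand[, 4]), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      pairs <- rbind(pairs, cand[r, ])
    }
  }
  out <- tibble::tibble(
    chain_i = character(), resno_i = integer(), base_i = character(),
    chain_ii = character(), resno_ii = integer(), base_ii = character(),
    pair_type = character(), c1_dist = numeric(), hbond_dist = numeric()
  )
  rows <- list()
  for (i in seq_len(nrow(res_a))) {
    if (used_a[i]) {
      j <- pairs[pairs[, 1] == i, 2]
      rows[[length(rows) + 1]] <- tibble::tibble(
        chain_i = chain_a, resno_i = res_a$resno[i], base_i = base_a[i],
        chain_ii = chain_b, resno_ii = res_b$resno[j], base_ii = base_b[j],
        pair_type = "watson-crick",
        c1_dist = pairs[pairs[, 1] == i, 3], hbond_dist = pairs[pairs[, 1] == i, 4]
      )
    } else {
      rows[[length(rows) + 1]] <- tibble::tibble(
        chain_i = chain_a, resno_i = res_a$resno[i], base_i = base_a[i],
        chain_ii = NA_character_, resno_ii = NA_integer_, base_ii = NA_character_,
        pair_type = "overhang", c1_dist = NA_real_, hbond_dist = NA_real_
      )
    }
  }
  for (j in which(!used_b)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      chain_i = NA_character_, resno_i = NA_integer_, base_i = NA_character_,
      chain_ii = chain_b, resno_ii = res_b$resno[j], base_ii = base_b[j],
      pair_type = "overhang", c1_dist = NA_real_, hbond_dist = NA_real_
    )
  }
  dplyr::bind_rows(out, rows)
}
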