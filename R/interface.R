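# Polar-contact inventories and apo/bound interface differencing.

# Donor/acceptor capability of a single atom given its residue context.
atom_roles <- function(resid, elety) {
  resid <- toupper(trimws(resid))
  if (resid %in% AMINO_ACIDS) {
    donor <- elety %in% PROTEIN_DONORS$backbone ||
      elety %in% (PROTEIN_DONORS[[resid]] %||% character())
    acceptor <- elety %in% PROTEIN_ACCEPTORS$backbone ||
      elety %in% (PROTEIN_ACCEPTORS[[resid]] %||% character())
  } else if (is_nucleotide_resid(resid)) {
    base <- normalize_base(resid)
    donor <- elety %in% DNA_DONORS[[base]]
    acceptor <- elety %in% DNA_ACCEPTORS$backbone ||
      elety %in% DNA_ACCEPTORS[[base]]
  } else {
    donor <- FALSE; acceptor <- FALSE
  }
  c(donor = donor, acceptor = acceptor)
}

is_protein_resid <- function(resid) toupper(trimws(resid)) %in% AMINO_ACIDS

resolve_selection <- function(structure, sel) {
  if (is.data.frame(sel)) return(sel)
  if (is.character(sel)) sel <- list(chains = sel)
  select_atoms(structure, chains = sel$chains, resno = sel$resno,
               heavy_only = TRUE, drop_waters = TRUE)
}

atom_key <- function(df) {
  paste(df$chain, df$resno, df$insert, df$elety, sep = ":")
}

#' Find polar contacts between two atom selections
#'
#' Enumerates all donor-acceptor heavy-atom pairs (one atom from each
#' selection) within the cutoff, using fixed chemical dictionaries of
#' hydrogen-bond donors and acceptors for the 20 amino acids and the 4
#' deoxynucleotides. No hydrogen positions or angular criteria are used, as
#' appropriate for moderate-resolution crystal structures. Histidine and
#' amide nitrogens that are ambiguous without hydrogens are treated as both
#' donor and acceptor.
#'
#' @param structure A structure tibble.
#' @param sel1,sel2 Selections: a character vector of chain ids, a list with
#'   `chains`/`resno`, or an atom tibble. Must be disjoint.
#' @param cutoff Heavy-atom distance cutoff in angstrom (default 3.5).
#' @return A tibble with one row per contact: donor and acceptor identities
#'   (`*_chain`, `*_resno`, `*_resid`, `*_atom`), `distance` and `category`
#'   (`protein-protein`, `protein-DNA-base`, `protein-DNA-backbone`,
#'   `DNA-DNA`).
#' @export
find_polar_contacts <- function(structure, sel1, sel2, cutoff = 3.5) {
  a1 <- resolve_selection(structure, sel1)
  a2 <- resolve_selection(structure, sel2)
  if (nrow(a1) == 0 || nrow(a2) == 0) stop("empty selection", call. = FALSE)
  if (length(intersect(atom_key(a1), atom_key(a2)))) {
    stop("selections overlap; they must be disjoint", call. = FALSE)
  }
  roles1 <- t(mapply(atom_roles, a1$resid, a1$elety))
  roles2 <- t(mapply(atom_roles, a2$resid, a2$elety))
  keep1 <- roles1[, 1] | roles1[, 2]
  keep2 <- roles2[, 1] | roles2[, 2]
  a1 <- a1[keep1, ]; roles1 <- roles1[keep1, , drop = FALSE]
  a2 <- a2[keep2, ]; roles2 <- roles2[keep2, , drop = FALSE]
  if (nrow(a1) == 0 || nrow(a2) == 0) return(empty_contacts())
  d <- sqrt(outer(a1$x, a2$x, "-")^2 + outer(a1$y, a2$y, "-")^2 +
              outer(a1$z, a2$z, "-")^2)
  hits <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty_contacts())
  rows <- lapply(seq_len(nrow(hits)), function(r) {
    i <- hits[r, 1]; j <- hits[r, 2]
    ok_12 <- roles1[i, 1] && roles2[j, 2]   # sel1 donates
    ok_21 <- roles2[j, 1] && roles1[i, 2]   # sel2 donates
    if (!ok_12 && !ok_21) return(NULL)
    don <- if (ok_12) a1[i, ] else a2[j, ]
    acc <- if (ok_12) a2[j, ] else a1[i, ]
    tibble::tibble(
      donor_chain = don$chain, donor_resno = don$resno,
      donor_resid = don$resid, donor_atom = don$elety,
      acceptor_chain = acc$chain, acceptor_resno = acc$resno,
      acceptor_resid = acc$resid, acceptor_atom = acc$elety,
      distance = d[i, j],
      category = contact_category(don$resid, don$elety, acc$resid, acc$elety)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(empty_contacts())
  dplyr::arrange(out, .data$distance)
}

empty_contacts <- function() {
  tibble::tibble(
    donor_chain = character(), donor_resno = integer(),
    donor_resid = character(), donor_atom = character(),
    acceptor_chain = character(), acceptor_resno = integer(),
    acceptor_resid = character(), acceptor_atom = character(),
    distance = numeric(), category = character()
  )
}

dna_atom_is_backbone <- function(elety) {
  grepl("'", elety, fixed = TRUE) | elety %in% DNA_BACKBONE_ATOMS
}

contact_category <- function(resid1, atom1, resid2, atom2) {
  p1 <- is_protein_resid(resid1); p2 <- is_protein_resid(resid2)
  n1 <- is_nucleotide_resid(resid1); n2 <- is_nucleotide_resid(resid2)
  if (p1 && p2) return("protein-protein")
  if (n1 && n2) return("DNA-DNA")
  dna_atom <- if (n1) atom1 else atom2
  if (dna_atom_is_backbone(dna_atom)) "protein-DNA-backbone" else "protein-DNA-base"
}

#' Classify protein-DNA contacts as base or backbone
#'
#' DNA atoms whose names carry a prime or belong to the phosphate group are
#' counted as backbone; ring and exocyclic base atoms as base. Returns totals
#' and a per-protein-residue breakdown suitable for contact-map summaries.
#'
#' @param contacts A contact tibble from [find_polar_contacts()] (or the
#'   all-atom variant [find_close_contacts()]); every contact must involve
#'   exactly one protein and one DNA atom.
#' @return A list with `counts` (tibble: `class`, `n`) and `per_residue`
#'   (tibble: protein `chain`, `resno`, `resid`, `base`, `backbone`).
#' @export
classify_dna_contacts <- function(contacts) {
  if (nrow(contacts) == 0) {
    return(list(
      counts = tibble::tibble(class = c("base", "backbone"), n = c(0L, 0L)),
      per_residue = tibble::tibble(chain = character(), resno = integer(),
                                   resid = character(), base = integer(),
                                   backbone = integer())
    ))
  }
  don_prot <- is_protein_resid(contacts$donor_resid)
  acc_prot <- is_protein_resid(contacts$acceptor_resid)
  if (any(don_prot & acc_prot) || any(!don_prot & !acc_prot)) {
    stop("every contact must involve exactly one protein and one DNA atom",
         call. = FALSE)
  }
  prot <- tibble::tibble(
    chain = ifelse(don_prot, contacts$donor_chain, contacts$acceptor_chain),
    resno = ifelse(don_prot, contacts$donor_resno, contacts$acceptor_resno),
    resid = ifelse(don_prot, contacts$donor_resid, contacts$acceptor_resid),
    dna_atom = ifelse(don_prot, contacts$acceptor_atom, contacts$donor_atom)
  )
  prot$class <- ifelse(dna_atom_is_backbone(prot$dna_atom), "backbone", "base")
  counts <- tibble::tibble(
    class = c("base", "backbone"),
    n = c(sum(prot$class == "base"), sum(prot$class == "backbone"))
  )
  per_residue <- tidyr::pivot_wider(
    dplyr::count(prot, .data$chain, .data$resno, .data$resid, .data$class),
    names_from = "class", values_from = "n", values_fill = 0L
  )
  for (cl in c("base", "backbone")) {
    if (!cl %in% names(per_residue)) per_residue[[cl]] <- 0L
  }
  list(counts = counts, per_residue = per_residue)
}

#' All heavy-atom close contacts between two selections
#'
#' Unlike [find_polar_contacts()] this applies no donor/acceptor chemistry:
#' every heavy-atom pair within the cutoff counts. Useful for total-contact
#' inventories that mix hydrogen bonds with van der Waals packing; such
#' totals are reported separately and are never called hydrogen bonds.
#'
#' @inheritParams find_polar_contacts
#' @param cutoff Distance cutoff in angstrom (default 3.9).
#' @return A contact tibble in the same shape as [find_polar_contacts()]
#'   (the `donor_`/`acceptor_` columns record selection 1 and 2).
#' @export
find_close_contacts <- function(structure, sel1, sel2, cutoff = 3.9) {
  a1 <- resolve_selection(structure, sel1)
  a2 <- resolve_selection(structure, sel2)
  if (nrow(a1) == 0 || nrow(a2) == 0) stop("empty selection", call. = FALSE)
  d <- sqrt(outer(a1$x, a2$x, "-")^2 + outer(a1$y, a2$y, "-")^2 +
              outer(a1$z, a2$z, "-")^2)
  hits <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty_contacts())
  out <- tibble::tibble(
    donor_chain = a1$chain[hits[, 1]], donor_resno = a1$resno[hits[, 1]],
    donor_resid = a1$resid[hits[, 1]], donor_atom = a1$elety[hits[, 1]],
    acceptor_chain = a2$chain[hits[, 2]], acceptor_resno = a2$resno[hits[, 2]],
    acceptor_resid = a2$resid[hits[, 2]], acceptor_atom = a2$elety[hits[, 2]],
    distance = d[hits],
    category = mapply(contact_category, a1$resid[hits[, 1]], a1$elety[hits[, 1]],
                      a2$resid[hits[, 2]], a2$elety[hits[, 2]])
  )
  dplyr::arrange(out, .data$distance)
}

# Unordered pair identity used to match contacts across conformational states.
contact_pair_key <- function(contacts) {
  k1 <- paste(contacts$donor_chain, contacts$donor_resno, contacts$donor_atom, sep = ":")
  k2 <- paste(contacts$acceptor_chain, contacts$acceptor_resno, contacts$acceptor_atom, sep = ":")
  ifelse(k1 < k2, paste(k1, k2, sep = "|"), paste(k2, k1, sep = "|"))
}

#' Difference the polar-contact network between apo and bound states
#'
#' Polar contacts are detected independently in the two structures and keyed
#' by (chain, residue number, atom name) pairs after applying `chain_map`.
#' A pair within the cutoff in the apo state only is `disrupted`; in the
#' bound state only, `formed`; in both, `retained`. Distances in both states
#' are reported even when beyond the cutoff.
#'
#' @param apo,bound Structure tibbles of the two conformational states; mapped
#'   chains must share residue numbering for common residues.
#' @param chain_map Named character vector mapping apo chain ids to bound
#'   chain ids, e.g. `c(A = "A", B = "B")`.
#' @param sel1,sel2 Selections in apo naming (see [find_polar_contacts()]).
#' @param cutoff Heavy-atom cutoff in angstrom (default 3.5).
#' @return A tibble of class `interface_diff`: pair identity columns
#'   (`chain_1`, `resno_1`, `atom_1`, `chain_2`, `resno_2`, `atom_2`, in apo
#'   naming), `apo_dist`, `bound_dist`, `status`.
#' @export
diff_interface <- function(apo, bound, chain_map, sel1, sel2, cutoff = 3.5) {
  missing_apo <- setdiff(names(chain_map), unique(apo$chain))
  missing_bound <- setdiff(unname(chain_map), unique(bound$chain))
  if (length(missing_apo) || length(missing_bound)) {
    stop("unmappable chains - absent from apo: [",
         paste(missing_apo, collapse = ", "), "]; absent from bound: [",
         paste(missing_bound, collapse = ", "), "]", call. = FALSE)
  }
  map_sel <- function(sel) {
    if (is.character(sel)) return(unname(chain_map[sel]))
    if (is.list(sel) && !is.data.frame(sel)) {
      sel$chains <- unname(chain_map[sel$chains]); return(sel)
    }
    stop("selections must be chain vectors or chains/resno lists when diffing",
         call. = FALSE)
  }
  inv_map <- stats::setNames(names(chain_map), unname(chain_map))
  apo_ct <- find_polar_contacts(apo, sel1, sel2, cutoff)
  bound_ct <- find_polar_contacts(bound, map_sel(sel1), map_sel(sel2), cutoff)
  # re-express bound contacts in apo chain naming
  for (col in c("donor_chain", "acceptor_chain")) {
    bound_ct[[col]] <- unname(inv_map[bound_ct[[col]]])
  }
  apo_keys <- contact_pair_key(apo_ct)
  bound_keys <- contact_pair_key(bound_ct)
  all_keys <- union(apo_keys, bound_keys)
  parse_key <- function(key) {
    halves <- strsplit(key, "|", fixed = TRUE)[[1]]
    parts <- strsplit(halves, ":", fixed = TRUE)
    list(p1 = parts[[1]], p2 = parts[[2]])
  }
  dist_in <- function(structure, p, mapped) {
    ch1 <- if (mapped) unname(chain_map[p$p1[1]]) else p$p1[1]
    ch2 <- if (mapped) unname(chain_map[p$p2[1]]) else p$p2[1]
    d <- tryCatch({
      a <- get_atom(structure, ch1, as.integer(p$p1[2]), p$p1[3])
      b <- get_atom(structure, ch2, as.integer(p$p2[2]), p$p2[3])
      vnorm(a - b)
    }, error = function(e) NA_real_)
    d
  }
  rows <- lapply(all_keys, function(key) {
    p <- parse_key(key)
    in_apo <- key %in% apo_keys
    in_bound <- key %in% bound_keys
    tibble::tibble(
      chain_1 = p$p1[1], resno_1 = as.integer(p$p1[2]), atom_1 = p$p1[3],
      chain_2 = p$p2[1], resno_2 = as.integer(p$p2[2]), atom_2 = p$p2[3],
      apo_dist = dist_in(apo, p, mapped = FALSE),
      bound_dist = dist_in(bound, p, mapped = TRUE),
      status = if (in_apo && in_bound) "retained" else if (in_apo) "disrupted" else "formed"
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      chain_1 = character(), resno_1 = integer(), atom_1 = character(),
      chain_2 = character(), resno_2 = integer(), atom_2 = character(),
      apo_dist = numeric(), bound_dist = numeric(), status = character()
    )
  }
  out <- dplyr::arrange(out, .data$status, .data$chain_1, .data$resno_1)
  class(out) <- c("interface_diff", class(out))
  out
}

#' Count an interface diff by status
#'
#' @param diff An [diff_interface()] result.
#' @return A named integer vector with `disrupted`, `formed`, `retained`.
#' @export
diff_counts <- function(diff) {
  c(disrupted = sum(diff$status == "disrupted"),
    formed = sum(diff$status == "formed"),
    retained = sum(diff$status == "retained"))
}

#' Distance between two named atoms
#'
#' The recognition-helix center-to-center metric: the Euclidean distance
#' between two atoms given as `"chain:resno:atom"` references (e.g.
#' `"A:44:N"` for the backbone amide nitrogen of Gly44).
#'
#' @param structure A structure tibble.
#' @param ref1,ref2 Atom references, `"chain:resno:atom"`.
#' @return Distance in angstrom.
#' @export
center_to_center <- function(structure, ref1, ref2) {
  parse_ref <- function(ref) {
    parts <- strsplit(ref, ":", fixed = TRUE)[[1]]
    if (length(parts) != 3) stop("atom reference must be 'chain:resno:atom': ",
                                 ref, call. = FALSE)
    parts
  }
  p1 <- parse_ref(ref1); p2 <- parse_ref(ref2)
  a <- get_atom(structure, p1[1], as.integer(p1[2]), p1[3])
  b <- get_atom(structure, p2[1], as.integer(p2[2]), p2[3])
  vnorm(a - b)
}

#' Detect aromatic/base stacking by ring-centroid proximity
#'
#' Flags protein aromatic rings (Phe, Tyr, Trp, His) whose centroid lies
#' within the cutoff of a DNA base-ring centroid. Stacking contacts are
#' reported separately from hydrogen bonds and never mixed into polar-contact
#' counts.
#'
#' @param structure A structure tibble.
#' @param protein_chains,dna_chains Chain id vectors.
#' @param cutoff Centroid-centroid cutoff in angstrom (default 5.5).
#' @return Tibble: protein `chain`, `resno`, `resid`, DNA `dna_chain`,
#'   `dna_resno`, `dna_resid`, `centroid_dist`, `flag` (= "stacking").
#' @export
detect_stacking <- function(structure, protein_chains, dna_chains, cutoff = 5.5) {
  ring_atoms <- list(
    PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
    HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
  )
  centroid <- function(chain, resno, atoms) {
    sub <- structure[structure$chain == chain & structure$resno == resno &
                       structure$elety %in% atoms, ]
    if (nrow(sub) < 3) return(NULL)
    colMeans(as.matrix(sub[, c("x", "y", "z")]))
  }
  prot <- dplyr::distinct(
    structure[structure$chain %in% protein_chains &
                toupper(structure$resid) %in% names(ring_atoms), ],
    .data$chain, .data$resno, .data$resid
  )
  dna <- dplyr::distinct(
    structure[structure$chain %in% dna_chains & is_nucleotide_resid(structure$resid), ],
    .data$chain, .data$resno, .data$resid
  )
  rows <- list()
  for (i in seq_len(nrow(prot))) {
    pc <- centroid(prot$chain[i], prot$resno[i], ring_atoms[[toupper(prot$resid[i])]])
    if (is.null(pc)) next
    for (j in seq_len(nrow(dna))) {
      ring <- base_ring_atoms(normalize_base(dna$resid[j]))
      dc <- centroid(dna$chain[j], dna$resno[j], ring)
      if (is.null(dc)) next
      dd <- vnorm(pc - dc)
      if (dd <= cutoff) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          chain = prot$chain[i], resno = prot$resno[i], resid = prot$resid[i],
          dna_chain = dna$chain[j], dna_resno = dna$resno[j],
          dna_resid = dna$resid[j], centroid_dist = dd, flag = "stacking"
        )
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(chain = character(), resno = integer(),
                          resid = character(), dna_chain = character(),
                          dna_resno = integer(), dna_resid = character(),
                          centroid_dist = numeric(), flag = character()))
  }
  dplyr::bind_rows(rows)
}
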