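# Disulfide geometry and strain, quaternary arrangement, and surface area.

#' Torsional strain-energy constants for disulfide bonds
#'
#' Coefficients of the standard torsional disulfide strain expression
#' `E = k1[1+cos 3x1] + k1p[1+cos 3x1'] + k2[1+cos 3x2] + k2p[1+cos 3x2'] +
#' k3a[1+cos 2x3] + k3b[1+cos 3x3]` in kcal/mol. Exposed so the constant set
#' can be recalibrated against a reference structure.
#'
#' @param k1,k1p,k2,k2p,k3a,k3b Force constants in kcal/mol.
#' @return Named numeric vector of the six constants.
#' @export
disulfide_energy_constants <- function(k1 = 2.0, k1p = 2.0, k2 = 1.0, k2p = 1.0,
                                       k3a = 3.5, k3b = 0.6) {
  c(k1 = k1, k1p = k1p, k2 = k2, k2p = k2p, k3a = k3a, k3b = k3b)
}

disulfide_strain_energy <- function(chi1, chi2, chi3, chi2p, chi1p,
                                    constants = disulfide_energy_constants()) {
  k <- constants
  cosd <- function(x) cos(deg2rad(x))
  unname(
    k["k1"] * (1 + cosd(3 * chi1)) + k["k1p"] * (1 + cosd(3 * chi1p)) +
      k["k2"] * (1 + cosd(3 * chi2)) + k["k2p"] * (1 + cosd(3 * chi2p)) +
      k["k3a"] * (1 + cosd(2 * chi3)) + k["k3b"] * (1 + cosd(3 * chi3))
  )
}

# spiral / hook / staple taxonomy from the sign pattern of (chi2, chi2')
# relative to chi3; the handedness comes from the sign of chi3 alone.
classify_disulfide <- function(chi2, chi3, chi2p) {
  s3 <- sign(chi3)
  same <- c(sign(chi2) == s3, sign(chi2p) == s3)
  if (all(same)) "spiral" else if (!any(same)) "staple" else "hook"
}

#' Geometry, classification and torsional strain of a disulfide bond
#'
#' Computes the five side-chain dihedrals of a cystine bridge
#' (x1 = N-CA-CB-SG, x2 = CA-CB-SG-SG', x3 = CB-SG-SG'-CB', and the primed
#' angles mirrored on the partner residue), assigns handedness from the sign
#' of x3 (left-handed when negative), classifies the conformation as spiral,
#' hook or staple from the sign pattern of (x2, x2') against x3, and
#' evaluates the torsional strain energy.
#'
#' @param structure A structure tibble.
#' @param cys_a,cys_b Residue references `"chain:resno"` of the two cysteines.
#' @param constants Energy constants, see [disulfide_energy_constants()].
#' @return A list with `chi1`, `chi2`, `chi3`, `chi2_prime`, `chi1_prime`
#'   (degrees), `ss_distance` (angstrom), `handedness` (`"LH"`/`"RH"`),
#'   `conformation_class` and `strain_energy` (kcal/mol).
#' @export
disulfide_geometry <- function(structure, cys_a, cys_b,
                               constants = disulfide_energy_constants()) {
  parse_res <- function(ref) {
    parts <- strsplit(ref, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("residue reference must be 'chain:resno': ",
                                 ref, call. = FALSE)
    list(chain = parts[1], resno = as.integer(parts[2]))
  }
  ra <- parse_res(cys_a); rb <- parse_res(cys_b)
  need <- c("N", "CA", "CB", "SG")
  grab <- function(r) {
    res <- structure[structure$chain == r$chain & structure$resno == r$resno, ]
    if (nrow(res) == 0 || !toupper(res$resid[1]) %in% c("CYS", "CYX")) {
      stop("residue ", r$chain, ":", r$resno, " is not a cysteine", call. = FALSE)
    }
    miss <- setdiff(need, res$elety)
    if (length(miss)) stop("cysteine ", r$chain, ":", r$resno,
                           " missing atoms: ", paste(miss, collapse = ", "),
                           call. = FALSE)
    stats::setNames(lapply(need, function(a) get_atom(res, r$chain, r$resno, a)), need)
  }
  a <- grab(ra); b <- grab(rb)
  ss <- vnorm(a$SG - b$SG)
  if (ss > 2.5) {
    stop("not a disulfide: SG-SG distance ", round(ss, 2), " A exceeds 2.5 A",
         call. = FALSE)
  }
  chi1 <- dihedral_angle(a$N, a$CA, a$CB, a$SG)
  chi2 <- dihedral_angle(a$CA, a$CB, a$SG, b$SG)
  chi3 <- dihedral_angle(a$CB, a$SG, b$SG, b$CB)
  chi2p <- dihedral_angle(b$CA, b$CB, b$SG, a$SG)
  chi1p <- dihedral_angle(b$N, b$CA, b$CB, b$SG)
  list(
    chi1 = chi1, chi2 = chi2, chi3 = chi3, chi2_prime = chi2p, chi1_prime = chi1p,
    ss_distance = ss,
    handedness = if (chi3 < 0) "LH" else "RH",
    conformation_class = classify_disulfide(chi2, chi3, chi2p),
    strain_energy = disulfide_strain_energy(chi1, chi2, chi3, chi2p, chi1p, constants)
  )
}

# NeRF-style internal-to-Cartesian placement: position a new atom at bond
# length r from c, bond angle theta (deg) at c against b, and torsion phi
# (deg) about the b-c axis relative to a.
place_atom <- function(a, b, c, r, theta, phi) {
  bc <- unitize(c - b)
  n <- unitize(cross3(b - a, bc))
  m <- cross3(n, bc)
  th <- deg2rad(180 - theta); ph <- -deg2rad(phi)
  d <- r * (cos(th) * bc + sin(th) * (cos(ph) * m + sin(ph) * n))
  c + d
}

#' Build a two-cysteine model with prescribed disulfide dihedrals
#'
#' Constructs an eight-atom cystine fragment (N-CA-CB-SG-SG'-CB'-CA'-N') by
#' internal-coordinate chain extension so that the five side-chain dihedrals
#' take exactly the requested values. Intended for validating
#' [disulfide_geometry()] against closed-form expectations.
#'
#' @param chi1,chi2,chi3,chi2_prime,chi1_prime Target dihedrals in degrees.
#' @return A structure tibble with cysteines A:159 and B:159.
#' @export
build_disulfide_model <- function(chi1 = -60, chi2 = -60, chi3 = -87,
                                  chi2_prime = -60, chi1_prime = -60) {
  # idealized internal coordinates: N-CA 1.46, CA-CB 1.53, CB-SG 1.81,
  # SG-SG' 2.04 A; tetrahedral-ish angles
  n1 <- c(0, 0, 0)
  ca1 <- c(1.46, 0, 0)
  cb1 <- ca1 + 1.53 * c(cos(deg2rad(180 - 110.5)), sin(deg2rad(180 - 110.5)), 0)
  sg1 <- place_atom(n1, ca1, cb1, 1.81, 114.0, chi1)
  sg2 <- place_atom(ca1, cb1, sg1, 2.04, 104.0, chi2)
  cb2 <- place_atom(cb1, sg1, sg2, 1.81, 104.0, chi3)
  ca2 <- place_atom(sg1, sg2, cb2, 1.53, 114.0, chi2_prime)
  n2 <- place_atom(sg2, cb2, ca2, 1.46, 110.5, chi1_prime)
  xyz <- rbind(n1, ca1, cb1, sg1, sg2, cb2, ca2, n2)
  new_structure(tibble::tibble(
    chain = rep(c("A", "B"), each = 4),
    resno = 159L, resid = "CYS",
    elety = c("N", "CA", "CB", "SG", "SG", "CB", "CA", "N"),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    elesy = c("N", "C", "C", "S", "S", "C", "C", "N")
  ), id = "cystine_model")
}

#' Quaternary angle between two dimers about the DNA
#'
#' For a dimer-of-dimers complex, takes the centroid of all DNA heavy atoms
#' as the pivot and measures the angle at the pivot between the rays to the
#' C-alpha centroid of each dimer.
#'
#' @param structure A structure tibble.
#' @param dimer1_chains,dimer2_chains Disjoint protein chain-id vectors.
#' @param dna_chains DNA chain-id vector.
#' @return A list with `inter_dimer_angle` (degrees, in (0, 180]), `pivot`,
#'   `dimer_centroids` (2x3 matrix) and `dna_chains`.
#' @export
dimer_dna_angle <- function(structure, dimer1_chains, dimer2_chains, dna_chains) {
  if (length(intersect(dimer1_chains, dimer2_chains))) {
    stop("dimer selections overlap", call. = FALSE)
  }
  ca_centroid <- function(chains) {
    sub <- select_atoms(structure, chains = chains, elety = "CA")
    if (nrow(sub) == 0) {  # fall back to all heavy atoms for toy inputs
      sub <- select_atoms(structure, chains = chains)
    }
    if (nrow(sub) == 0) stop("no atoms in chains ", paste(chains, collapse = ","),
                             call. = FALSE)
    colMeans(atom_xyz(sub))
  }
  dna <- select_atoms(structure, chains = dna_chains)
  if (nrow(dna) == 0) stop("no DNA atoms in chains ",
                           paste(dna_chains, collapse = ","), call. = FALSE)
  pivot <- colMeans(atom_xyz(dna))
  c1 <- ca_centroid(dimer1_chains)
  c2 <- ca_centroid(dimer2_chains)
  v1 <- unitize(c1 - pivot); v2 <- unitize(c2 - pivot)
  ang <- rad2deg(acos(max(-1, min(1, sum(v1 * v2)))))
  list(
    inter_dimer_angle = ang,
    pivot = pivot,
    dimer_centroids = rbind(dimer1 = c1, dimer2 = c2),
    dna_chains = dna_chains
  )
}

# Deterministic near-uniform points on the unit sphere (Fibonacci spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (i - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom accessible area by deterministic spherical quadrature: each atom
#' is covered with a fixed Fibonacci-spiral point set on a sphere of radius
#' `r_vdw + probe`; the accessible area is the exposed-point fraction times
#' the sphere area. Hydrogens are ignored and waters dropped by default.
#'
#' @param structure A structure tibble.
#' @param probe Probe radius in angstrom (default 1.4).
#' @param n_points Quadrature points per atom (default 960).
#' @param radii Named element-radius vector, see [vdw_radii()].
#' @param include_waters Keep flagged waters (default FALSE).
#' @return A list with `total` (angstrom^2), `per_atom` (tibble: atom
#'   identity, `radius`, `area`), `probe`, `n_points`.
#' @export
sasa <- function(structure, probe = 1.4, n_points = 960, radii = vdw_radii(),
                 include_waters = FALSE) {
  at <- structure[!toupper(structure$elesy) %in% c("H", "D"), ]
  if (!include_waters) at <- at[!at$water, ]
  if (nrow(at) == 0) stop("no heavy atoms to measure", call. = FALSE)
  el <- toupper(trimws(at$elesy))
  unknown <- setdiff(unique(el), names(radii))
  if (length(unknown)) {
    stop("no van der Waals radius configured for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  r <- unname(radii[el]) + probe
  xyz <- atom_xyz(at)
  pts <- sphere_points(n_points)
  n <- nrow(at)
  area <- numeric(n)
  # neighbor lists from squared-distance threshold
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(di < r[i] + r & seq_len(n) != i)
    surf <- sweep(pts * r[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj2 <- colSums((t(surf[exposed, , drop = FALSE]) - xyz[j, ])^2)
      exposed[exposed] <- dj2 >= r[j]^2
    }
    area[i] <- sum(exposed) / n_points * 4 * pi * r[i]^2
  }
  per_atom <- tibble::tibble(
    chain = at$chain, resno = at$resno, resid = at$resid, elety = at$elety,
    element = el, radius = unname(radii[el]), area = area
  )
  list(total = sum(area), per_atom = per_atom, probe = probe, n_points = n_points)
}
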