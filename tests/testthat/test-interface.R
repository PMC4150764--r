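mini_pair <- function(d, donor_atom = "OG", donor_resid = "SER",
                      acceptor_atom = "OD1", acceptor_resid = "ASP") {
  new_structure(tibble::tibble(
    chain = c("A", "B"), resno = 1L,
    resid = c(donor_resid, acceptor_resid),
    elety = c(donor_atom, acceptor_atom),
    x = c(0, d), y = 0, z = 0
  ))
}

test_that("polar contacts respect distance and chemistry rules", {
  s <- mini_pair(2.7)
  ct <- find_polar_contacts(s, "A", "B")
  expect_equal(nrow(ct), 1)
  expect_equal(ct$distance, 2.7)
  expect_equal(nrow(find_polar_contacts(mini_pair(3.6), "A", "B")), 0)
  expect_equal(nrow(find_polar_contacts(mini_pair(3.5), "A", "B")), 1)  # boundary
  # carbon-carbon pairs are never polar contacts
  cc <- mini_pair(3.0, donor_atom = "CB", acceptor_atom = "CB")
  expect_equal(nrow(find_polar_contacts(cc, "A", "B")), 0)
  expect_error(find_polar_contacts(s, "A", "A"), "disjoint")
})

test_that("polar contacts are symmetric in the selections and monotone in cutoff", {
  toy <- make_toy_complex(4, 3, 2, seed = 21)
  c12 <- find_polar_contacts(toy$apo, "A", "B")
  c21 <- find_polar_contacts(toy$apo, "B", "A")
  key <- function(ct) sort(tetrdna:::contact_pair_key(ct))
  expect_identical(key(c12), key(c21))
  small <- find_polar_contacts(toy$apo, "A", "B", cutoff = 3.0)
  large <- find_polar_contacts(toy$apo, "A", "B", cutoff = 3.8)
  expect_true(all(key(small) %in% key(large)))
})

test_that("DNA contacts classify as base or backbone by atom identity", {
  s <- new_structure(tibble::tibble(
    chain = c("A", "E", "A", "E"), resno = c(43L, 5L, 47L, 6L),
    resid = c("LYS", "DG", "TYR", "DG"),
    elety = c("NZ", "OP1", "OH", "O6"),
    x = c(0, 2.8, 50, 52.9), y = 0, z = 0
  ))
  ct <- find_polar_contacts(s, "A", "E")
  expect_equal(nrow(ct), 2)
  cl <- classify_dna_contacts(ct)
  expect_equal(cl$counts$n[cl$counts$class == "backbone"], 1L)
  expect_equal(cl$counts$n[cl$counts$class == "base"], 1L)
  expect_setequal(ct$category, c("protein-DNA-backbone", "protein-DNA-base"))
  # sugar primes count as backbone
  expect_true(tetrdna:::dna_atom_is_backbone("O3'"))
  expect_false(tetrdna:::dna_atom_is_backbone("N7"))
  # protein-protein contacts cannot be classified against DNA
  pp <- find_polar_contacts(mini_pair(2.7), "A", "B")
  expect_error(classify_dna_contacts(pp), "one protein and one DNA")
})

test_that("toy complexes are recovered exactly by the interface diff", {
  toy <- make_toy_complex(5, 10, 9, seed = 1)
  d <- diff_interface(toy$apo, toy$bound, c(A = "A", B = "B"), "A", "B")
  expect_equal(unname(diff_counts(d)), c(10L, 9L, 5L))
  # distances in both states are reported, including beyond the cutoff
  disrupted <- d[d$status == "disrupted", ]
  expect_true(all(disrupted$apo_dist <= 3.5))
  expect_true(all(disrupted$bound_dist > 3.5))
  truth <- toy$truth[order(toy$truth$resno_1), ]
  got <- d[order(d$resno_1), ]
  expect_equal(got$apo_dist, truth$apo_dist, tolerance = 1e-9)
  expect_equal(got$bound_dist, truth$bound_dist, tolerance = 1e-9)
})

test_that("toy-complex edge cases validate their specification", {
  empty <- make_toy_complex(0, 0, 0)
  d <- diff_interface(empty$apo, empty$bound, c(A = "A", B = "B"), "A", "B")
  expect_equal(nrow(d), 0)
  expect_error(make_toy_complex(1, 1, 1, separation_distance = 3.4),
               "must exceed")
  expect_error(make_toy_complex(-1, 0, 0), "non-negative")
})

test_that("identical states diff to retained only, and bad maps fail loudly", {
  toy <- make_toy_complex(3, 0, 0, seed = 2)
  d <- diff_interface(toy$apo, toy$apo, c(A = "A", B = "B"), "A", "B")
  expect_equal(unname(diff_counts(d)), c(0L, 0L, 3L))
  expect_error(
    diff_interface(toy$apo, toy$bound, c(A = "A", Z = "B"), "A", "B"),
    "Z"
  )
})

test_that("the diff partition identity holds across 100 random toy complexes", {
  for (seed in 1:100) {
    set.seed(seed)
    counts <- sample(0:8, 3, replace = TRUE)
    toy <- make_toy_complex(counts[1], counts[2], counts[3], seed = seed)
    d <- diff_interface(toy$apo, toy$bound, c(A = "A", B = "B"), "A", "B")
    apo_ct <- find_polar_contacts(toy$apo, "A", "B")
    bound_ct <- find_polar_contacts(toy$bound, "A", "B")
    key <- function(ct) sort(tetrdna:::contact_pair_key(ct))
    dk <- d[d$status %in% c("disrupted", "retained"), ]
    fk <- d[d$status %in% c("formed", "retained"), ]
    diff_key <- function(dd) {
      k1 <- paste(dd$chain_1, dd$resno_1, dd$atom_1, sep = ":")
      k2 <- paste(dd$chain_2, dd$resno_2, dd$atom_2, sep = ":")
      sort(ifelse(k1 < k2, paste(k1, k2, sep = "|"), paste(k2, k1, sep = "|")))
    }
    expect_identical(diff_key(dk), key(apo_ct))
    expect_identical(diff_key(fk), key(bound_ct))
    # the three sets are disjoint by construction of status
    expect_equal(sum(unname(diff_counts(d))), length(unique(diff_key(d))))
  }
})

test_that("center-to-center distances are plain Euclidean metrics", {
  s <- new_structure(tibble::tibble(
    chain = c("A", "B"), resno = 44L, resid = "GLY", elety = "N",
    x = c(0, 3), y = c(0, 4), z = 0
  ))
  expect_equal(center_to_center(s, "A:44:N", "B:44:N"), 5)
  expect_equal(center_to_center(s, "A:44:N", "A:44:N"), 0)
  expect_error(center_to_center(s, "A:44:N", "C:44:N"), "C.*44.*N")
})

test_that("aromatic stacking is flagged by centroid distance and kept separate", {
  base <- tetrdna:::base_template("G")
  ring <- tetrdna:::base_ring_atoms("G")
  phe <- tibble::tibble(
    chain = "A", resno = 48L, resid = "PHE",
    elety = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    x = c(0, 1.2, -1.2, 1.2, -1.2, 0) * 1.2,
    y = c(1.4, 0.7, 0.7, -0.7, -0.7, -1.4),
    z = 3.4
  )
  dg <- tibble::tibble(
    chain = "E", resno = 5L, resid = "DG", elety = rownames(base),
    x = base[, 1] - mean(base[ring, 1]),
    y = base[, 2] - mean(base[ring, 2]),
    z = 0
  )
  s <- new_structure(dplyr::bind_rows(phe, dg))
  st <- detect_stacking(s, "A", "E")
  expect_equal(nrow(st), 1)
  expect_lt(st$centroid_dist, 5.5)
  expect_equal(st$flag, "stacking")
  # stacking never enters the polar-contact inventory
  expect_equal(nrow(find_polar_contacts(s, "A", "E")), 0)
})
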