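test_that("base frames are exact at identity and equivariant under rotation", {
  tmpl <- tetrdna:::nucleotide_template("G")
  res <- new_structure(tibble::tibble(
    chain = "A", resno = 1, resid = "DG", elety = rownames(tmpl),
    x = tmpl[, 1], y = tmpl[, 2], z = tmpl[, 3]
  ))
  fr <- base_frame(res, "A", 1)
  expect_equal(fr$axes, diag(3), tolerance = 1e-9)
  expect_equal(fr$origin, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(fr$rmsd, 0, tolerance = 1e-9)

  R <- random_rotation(3)
  moved <- transform_structure(res, R, c(1, 2, 3))
  fr2 <- base_frame(moved, "A", 1)
  expect_equal(fr2$axes, R, tolerance = 1e-6)
  expect_equal(fr2$origin, c(1, 2, 3), tolerance = 1e-6)
})

test_that("missing ring atoms are reported by name", {
  tmpl <- tetrdna:::nucleotide_template("A")
  keep <- rownames(tmpl) != "N9"
  res <- new_structure(tibble::tibble(
    chain = "A", resno = 1, resid = "DA", elety = rownames(tmpl)[keep],
    x = tmpl[keep, 1], y = tmpl[keep, 2], z = tmpl[keep, 3]
  ))
  expect_error(base_frame(res, "A", 1), "N9")
})

test_that("step parameters and averages behave arithmetically", {
  st <- tibble::tibble(
    step = 1:3, resno_i = 1:3, shift = 0, slide = 0, rise = 3.38,
    tilt = 0, roll = 0, twist = c(34, 36, 38)
  )
  av <- average_params(st)
  expect_equal(av$mean[av$parameter == "twist"], 36)
  expect_equal(av$sd[av$parameter == "twist"], 2)  # sample SD, n - 1
  one <- average_params(st[2, ])
  expect_equal(one$mean[one$parameter == "twist"], 36)
  expect_equal(one$sd[one$parameter == "twist"], 0)
  expect_error(average_params(st[0, ]), "average")
  ideal <- average_params(step_parameters(dup_ideal, "A", "B"))
  expect_equal(ideal$mean[ideal$parameter == "twist"], 36, tolerance = 1e-3)
})

test_that("global bend is zero when straight and matches a mid-helix kink", {
  expect_lt(global_bend(dup_ideal, "A", "B"), 0.2)
  rolls <- rep(0, 21); rolls[11] <- 10
  kinked <- build_ideal_bdna(CS, roll_profile = rolls)
  expect_equal(global_bend(kinked, "A", "B"), 10, tolerance = 0.5)
  expect_error(global_bend(build_ideal_bdna("ACG"), "A", "B"), "at least 4")
  # cumulative variant sums per-step bend magnitudes
  expect_equal(global_bend(kinked, "A", "B", method = "cumulative"), 10,
               tolerance = 1e-6)
})

test_that("groove widths match the ideal-B reference and a brute-force oracle", {
  gw <- groove_widths(dup_ideal, "A", "B")
  meas <- gw$major_width[!is.na(gw$major_width)]
  expect_gt(length(meas), 10)
  expect_true(all(abs(meas - 11.7) < 0.3))
  # uniformity along the sequence for a uniform duplex
  expect_lt(diff(range(meas)), 0.1)
  minor <- gw$minor_width[!is.na(gw$minor_width)]
  expect_lt(diff(range(minor)), 0.1)

  # independent exhaustive oracle for the minor groove: raw minimum over the
  # minor-groove window of cross-strand P-P distances, minus 5.8
  wc <- pairs_ideal[pairs_ideal$pair_type == "watson-crick", ]
  p_of <- function(chain, resno) {
    at <- dup_ideal[dup_ideal$chain == chain & dup_ideal$resno == resno &
                      dup_ideal$elety == "P", ]
    c(at$x, at$y, at$z)
  }
  n <- nrow(wc)
  for (l in seq_len(n)) {
    window <- (l - 6):(l - 3)
    if (any(window < 1) || any(window > n)) {
      expect_true(is.na(gw$minor_width[l]))
      next
    }
    d <- vapply(window, function(m) {
      sqrt(sum((p_of(wc$chain_i[l], wc$resno_i[l]) -
                  p_of(wc$chain_ii[m], wc$resno_ii[m]))^2))
    }, numeric(1))
    expect_equal(gw$minor_width[l], min(d) - 5.8, tolerance = 1e-9)
  }
  expect_error(groove_widths(build_ideal_bdna("ACGTAC"), "A", "B"), "at least 7")
})

test_that("geometry is rigid-body invariant", {
  d <- build_ideal_bdna(CS, roll_profile = 4, tilt_profile = -2)
  st <- step_parameters(d, "A", "B")
  gw <- groove_widths(d, "A", "B")
  bend <- global_bend(d, "A", "B")
  moved <- transform_structure(d, random_rotation(11), c(-40, 13, 7))
  st2 <- step_parameters(moved, "A", "B")
  expect_lt(max(abs(as.matrix(st[, 3:8]) - as.matrix(st2[, 3:8]))), 1e-6)
  gw2 <- groove_widths(moved, "A", "B")
  expect_equal(gw$major_width, gw2$major_width, tolerance = 1e-6)
  expect_equal(global_bend(moved, "A", "B"), bend, tolerance = 1e-6)
})

test_that("strand reversal negates tilt and preserves twist, rise and roll", {
  for (seed in 1:3) {
    set.seed(seed)
    d <- build_ideal_bdna(CS,
                          twist_per_step = 36 + rnorm(21, 0, 1),
                          rise_per_step = 3.38 + rnorm(21, 0, 0.05),
                          roll_profile = rnorm(21, 0, 4),
                          tilt_profile = rnorm(21, 0, 2))
    fwd <- step_parameters(d, "A", "B")
    rev <- step_parameters(d, "B", "A")
    rev_flipped <- rev[nrow(rev):1, ]
    expect_equal(rev_flipped$twist, fwd$twist, tolerance = 1e-6)
    expect_equal(rev_flipped$rise, fwd$rise, tolerance = 1e-6)
    expect_equal(rev_flipped$roll, fwd$roll, tolerance = 1e-6)
    expect_equal(rev_flipped$tilt, -fwd$tilt, tolerance = 1e-6)
  }
})
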