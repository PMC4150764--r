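test_that("window scores count IUPAC-compatible positions", {
  expect_equal(score_window(CS, CS), 22)
  expect_equal(score_window(strrep("N", 22), CS), 22)
  comp <- chartr("ACGT", "TGCA", CS)
  brute <- sum(strsplit(CS, "")[[1]] == strsplit(comp, "")[[1]])
  expect_equal(score_window(CS, comp), brute)
  expect_equal(score_window("RY", "AT"), 2)
  expect_equal(score_window("RY", "CA"), 0)
  expect_error(score_window("ACG", "AC"), "lengths differ")
  expect_error(score_window("ACX", "ACG"), "non-IUPAC")
})

test_that("planted motifs are found at the right place, strand and score", {
  g <- generate_genome(10000, plants = tibble::tibble(
    motif = CS, position = 4321, strand = "+", mismatches = 0), seed = 5)
  expect_equal(nchar(g), 10000)
  expect_equal(substr(g, 4321, 4342), CS)
  hits <- scan_motif(g, CS, min_score = 22)
  top <- hits[1, ]
  expect_equal(top$start, 4321)
  expect_equal(top$strand, "+")
  expect_equal(top$score, 22)
  expect_equal(top$subsequence, CS)

  gm <- generate_genome(10000, plants = tibble::tibble(
    motif = CS, position = 4321, strand = "-", mismatches = 0), seed = 5)
  hm <- scan_motif(gm, CS, min_score = 22)
  expect_equal(hm$start[1], 4321)
  expect_equal(hm$end[1], 4342)
  expect_equal(hm$strand[1], "-")
  expect_equal(hm$subsequence[1], CS)  # as read on its own strand
})

test_that("mismatched plants score exactly length minus mismatches", {
  g <- generate_genome(5000, plants = tibble::tibble(
    motif = CS, position = 1234, strand = "+", mismatches = 2), seed = 9)
  hits <- scan_motif(g, CS, min_score = 20, both_strands = FALSE)
  at_plant <- hits[hits$start == 1234, ]
  expect_equal(nrow(at_plant), 1)
  expect_equal(at_plant$score, 20)
  # exhaustive verification of the planted window
  expect_equal(score_window(CS, substr(g, 1234, 1255)), 20)
})

test_that("genome generation is deterministic and validates plants", {
  spec <- tibble::tibble(motif = CS, position = 100, strand = "+", mismatches = 1)
  expect_identical(generate_genome(2000, 0.6, spec, seed = 3),
                   generate_genome(2000, 0.6, spec, seed = 3))
  expect_false(identical(generate_genome(2000, 0.6, spec, seed = 3),
                         generate_genome(2000, 0.6, spec, seed = 4)))
  over <- tibble::tibble(motif = c(CS, CS), position = c(100, 110),
                         strand = "+", mismatches = 0)
  expect_error(generate_genome(2000, plants = over), "overlap")
  outside <- tibble::tibble(motif = CS, position = 1990, strand = "+",
                            mismatches = 0)
  expect_error(generate_genome(2000, plants = outside), "outside")
  # GC fraction is honored in the background
  g <- generate_genome(20000, gc_fraction = 0.72, seed = 8)
  gc <- mean(strsplit(g, "")[[1]] %in% c("G", "C"))
  expect_equal(gc, 0.72, tolerance = 0.02)
})

test_that("scanning is strand-symmetric across 50 random genomes", {
  for (seed in 1:50) {
    g <- generate_genome(300, gc_fraction = 0.5, seed = seed)
    L <- nchar(g)
    fwd <- scan_motif(g, CS, min_score = 12)
    rc <- scan_motif(revcomp(g), CS, min_score = 12)
    mirror <- tibble::tibble(
      start = L - rc$end + 1,
      strand = ifelse(rc$strand == "+", "-", "+"),
      score = rc$score
    )
    key <- function(d) sort(paste(d$start, d$strand, d$score))
    expect_identical(key(fwd), key(mirror))
  }
})

test_that("a zero threshold returns every window on both strands", {
  g <- generate_genome(500, seed = 2)
  hits <- scan_motif(g, CS, min_score = 0, both_strands = TRUE)
  expect_equal(nrow(hits), 2 * (500 - 22 + 1))
  plus_only <- scan_motif(g, CS, min_score = 0, both_strands = FALSE)
  expect_equal(nrow(plus_only), 500 - 22 + 1)
  # an unsatisfiable threshold is empty, not an error
  expect_equal(nrow(scan_motif(g, CS, min_score = 23)), 0)
})

test_that("conservation annotation follows the all/two/none column rule", {
  ann <- annotate_conservation(c("ACGT", "ACGT", "ACGT"))
  expect_equal(ann$annotation, "****")
  ann2 <- annotate_conservation(c("AAAG", "AACG", "AGTG"))
  # col1 all A -> *; col2 A,A,G -> :; col3 A,C,T -> ' '; col4 all G -> *
  expect_equal(ann2$annotation, "*: *")
  expect_error(annotate_conservation(c("ACG")), "at least 2")
  expect_error(annotate_conservation(c("ACG", "AC")), "ragged")
})

test_that("FASTA round trips preserve records and scanning accepts them", {
  path <- withr::local_tempfile(fileext = ".fa")
  seqs <- c(up_cprA = generate_genome(300, seed = 1),
            up_cprB = generate_genome(300, seed = 2))
  write_fasta(seqs, path)
  back <- read_fasta(path)
  expect_identical(back, seqs)
  hits <- scan_motif(back, CS, min_score = 10)
  expect_true(all(hits$record %in% names(seqs)))
})
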