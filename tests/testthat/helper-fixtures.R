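# Shared fixtures, built in code at load time.

CS <- consensus_cs()                  # 22-bp operator consensus
dup_ideal <- build_ideal_bdna(CS)     # default fiber duplex
pairs_ideal <- pair_duplex(dup_ideal, "A", "B")

random_rotation <- function(seed) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3, 3)
  s <- svd(m)
  r <- s$u %*% t(s$v)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

# direct torsional strain evaluation used as the closed-form oracle
strain_oracle <- function(chi1, chi2, chi3, chi2p, chi1p) {
  cosd <- function(x) cos(x * pi / 180)
  2.0 * (1 + cosd(3 * chi1)) + 2.0 * (1 + cosd(3 * chi1p)) +
    1.0 * (1 + cosd(3 * chi2)) + 1.0 * (1 + cosd(3 * chi2p)) +
    3.5 * (1 + cosd(2 * chi3)) + 0.6 * (1 + cosd(3 * chi3))
}
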