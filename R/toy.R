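#' Generate a paired apo/bound toy complex with a prescribed contact ledger
#'
#' Builds two small two-chain structures sharing chain and residue naming in
#' which exactly the requested numbers of donor-acceptor pairs lie within the
#' hydrogen-bond cutoff in the apo state only (`n_disrupted`), the bound
#' state only (`n_formed`), or both (`n_retained`). Chain A carries serine
#' hydroxyl donors, chain B aspartate carboxylate acceptors; pairs are spaced
#' far apart so no spurious cross-contacts arise. The ground-truth ledger is
#' returned alongside the structures and is recovered exactly by
#' [diff_interface()].
#'
#' @param n_retained,n_disrupted,n_formed Non-negative pair counts.
#' @param separation_distance Distance (angstrom) separating broken pairs in
#'   their non-bonded state; must exceed `cutoff`.
#' @param cutoff Hydrogen-bond cutoff the ledger is defined against
#'   (default 3.5 angstrom).
#' @param seed Integer seed controlling the jittered bond geometries.
#' @return A list with `apo`, `bound` (structure tibbles) and `truth`
#'   (tibble: pair identities, `apo_dist`, `bound_dist`, `status`).
#' @export
#' @examples
#' toy <- make_toy_complex(2, 3, 1, seed = 7)
#' table(toy$truth$status)
make_toy_complex <- function(n_retained, n_disrupted, n_formed,
                             separation_distance = 8, cutoff = 3.5, seed = 1) {
  counts <- c(n_retained, n_disrupted, n_formed)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("pair counts must be non-negative integers", call. = FALSE)
  }
  if (separation_distance <= cutoff) {
    stop("separation_distance (", separation_distance,
         ") must exceed the hydrogen-bond cutoff (", cutoff,
         "): broken pairs must be out of contact", call. = FALSE)
  }
  status <- rep(c("retained", "disrupted", "formed"), counts)
  n <- length(status)
  rng <- seeded_rng(seed)
  spacing <- 4 * separation_distance + 10
  bonded <- function() 2.6 + 0.6 * rng()          # inside cutoff
  apart <- function() separation_distance + 1.5 * rng()  # outside cutoff
  make_state <- function(dists) {
    rows <- vector("list", 2 * max(n, 1))
    for (k in seq_len(n)) {
      p <- c(k * spacing, 0, 0)
      theta <- 2 * pi * rng()
      dir <- c(0, cos(theta), sin(theta))  # keep displacement off the chain axis
      q <- p + dists[k] * dir
      rows[[2 * k - 1]] <- tibble::tibble(
        chain = "A", resno = k, resid = "SER",
        elety = c("CB", "OG"),
        x = c(p[1], p[1]), y = c(p[2], p[2]), z = c(p[3] - 1.5, p[3])
      )
      rows[[2 * k]] <- tibble::tibble(
        chain = "B", resno = k, resid = "ASP",
        elety = c("CB", "OD1"),
        x = c(q[1], q[1]), y = c(q[2], q[2]), z = c(q[3] + 1.5, q[3])
      )
    }
    if (n == 0) {
      rows[[1]] <- tibble::tibble(
        chain = c("A", "B"), resno = 1L, resid = c("SER", "ASP"),
        elety = "CB", x = c(0, spacing), y = 0, z = 0
      )
    }
    new_structure(dplyr::bind_rows(rows), id = "toy_complex")
  }
  apo_d <- numeric(n); bound_d <- numeric(n)
  for (k in seq_len(n)) {
    apo_d[k] <- switch(status[k], retained = bonded(), disrupted = bonded(),
                       formed = apart())
    bound_d[k] <- switch(status[k], retained = apo_d[k], disrupted = apart(),
                         formed = bonded())
  }
  apo <- make_state(apo_d)
  bound <- make_state(bound_d)
  truth <- tibble::tibble(
    chain_1 = rep("A", n), resno_1 = seq_len(n), atom_1 = rep("OG", n),
    chain_2 = rep("B", n), resno_2 = seq_len(n), atom_2 = rep("OD1", n),
    apo_dist = apo_d, bound_dist = bound_d, status = status
  )
  list(apo = apo, bound = bound, truth = truth)
}

# Small deterministic uniform(0,1) stream independent of the global RNG.
seeded_rng <- function(seed) {
  state <- as.double(seed %% 2147483647)
  if (state <= 0) state <- state + 2147483646
  function() {
    state <<- (state * 16807) %% 2147483647
    state / 2147483647
  }
}
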