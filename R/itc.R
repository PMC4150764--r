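# Isothermal titration calorimetry: Wiseman-isotherm models for one and two
# sets of sites, simulation, and multi-start least-squares fitting.
#
# Conventions: the macromolecule (here, a repressor dimer) sits in the cell
# and the DNA duplex is titrated from the syringe. Concentrations are
# accounted on the dimer basis throughout, so a fitted stoichiometry of
# about 0.5 reads "duplexes bound per dimer". Injection heats are kcal per
# mole of injectant, the per-injection normalization used by instrument
# software.

R_GAS <- 1.9872e-3  # kcal mol^-1 K^-1

#' Titration protocol description
#'
#' @param cell_volume_ul Cell volume V0 in microliters (default 200).
#' @param cell_conc_uM Macromolecule concentration in the cell, micromolar
#'   (dimer basis; default 10).
#' @param syringe_conc_uM Titrant (duplex) concentration, micromolar
#'   (default 120).
#' @param injection_volumes_ul Per-injection volumes in microliters
#'   (default 25 x 1.5).
#' @param temperature_K Temperature in kelvin (default 298.15).
#' @return A list of class `titration_protocol`.
#' @export
titration_protocol <- function(cell_volume_ul = 200, cell_conc_uM = 10,
                               syringe_conc_uM = 120,
                               injection_volumes_ul = rep(1.5, 25),
                               temperature_K = 298.15) {
  stopifnot(cell_volume_ul > 0, cell_conc_uM > 0, syringe_conc_uM > 0,
            all(injection_volumes_ul > 0),
            temperature_K >= 273, temperature_K <= 373)
  structure(
    list(cell_volume_ul = cell_volume_ul, cell_conc_uM = cell_conc_uM,
         syringe_conc_uM = syringe_conc_uM,
         injection_volumes_ul = injection_volumes_ul,
         temperature_K = temperature_K),
    class = "titration_protocol"
  )
}

#' Thermodynamic binding parameters
#'
#' One site class per element of the vectors: a one-set-of-sites model has
#' length-1 vectors, a two-sets-of-sites model length-2. Association
#' constants may be given directly (`ka`, M^-1) or as dissociation constants
#' (`kd_nM`).
#'
#' @param n Sites per macromolecule (dimer basis), one per site class.
#' @param dh Binding enthalpy per site class, kcal/mol.
#' @param kd_nM Dissociation constants in nanomolar (alternative to `ka`).
#' @param ka Association constants in M^-1.
#' @return A list of class `binding_params` with `n`, `ka`, `dh`, `model`.
#' @export
binding_params <- function(n, dh, kd_nM = NULL, ka = NULL) {
  if (is.null(ka)) {
    if (is.null(kd_nM)) stop("supply kd_nM or ka", call. = FALSE)
    ka <- 1 / (kd_nM * 1e-9)
  }
  stopifnot(length(n) == length(ka), length(dh) == length(ka),
            all(n > 0), all(ka > 0), length(n) %in% 1:2)
  structure(
    list(n = n, ka = ka, dh = dh,
         model = if (length(n) == 1) "one-site" else "two-site"),
    class = "binding_params"
  )
}

# Total cell concentrations (M) after each injection, with the standard
# per-injection displacement-dilution factor (1 - v/V0).
titration_totals <- function(protocol) {
  v0 <- protocol$cell_volume_ul
  f <- protocol$injection_volumes_ul / v0
  m <- numeric(length(f)); x <- numeric(length(f))
  m_prev <- protocol$cell_conc_uM * 1e-6
  x_prev <- 0
  xs <- protocol$syringe_conc_uM * 1e-6
  for (i in seq_along(f)) {
    m_prev <- m_prev * (1 - f[i])
    x_prev <- x_prev * (1 - f[i]) + xs * f[i]
    m[i] <- m_prev; x[i] <- x_prev
  }
  list(M = m, X = x)
}

# Free-titrant concentration from the mass balance
#   Xt = Xf + M * sum_j n_j Ka_j Xf / (1 + Ka_j Xf).
# Closed-form quadratic for one site class; bracketed root solve otherwise
# (the mass balance is strictly monotone in Xf).
free_ligand <- function(xt, m, params) {
  if (xt <= 0) return(0)
  if (length(params$ka) == 1) {
    ka <- params$ka[1]; nm <- params$n[1] * m
    b <- 1 + ka * (nm - xt)
    xf <- (-b + sqrt(b^2 + 4 * ka * xt)) / (2 * ka)
    return(max(xf, 0))
  }
  g <- function(xf) xf + m * sum(params$n * params$ka * xf / (1 + params$ka * xf)) - xt
  out <- stats::uniroot(g, lower = 0, upper = xt, tol = 1e-15 * max(xt, 1e-12),
                        maxiter = 2000)
  xf <- out$root
  stopifnot(abs(g(xf)) < 1e-10 * xt)
  xf
}

#' Model injection heats for a titration
#'
#' Evaluates the Wiseman isotherm: after each injection the total
#' concentrations are updated with the displacement-dilution correction, the
#' free-titrant concentration is solved from the binding mass balance, the
#' cumulative heat content `Q_i = V0 M_i sum_j n_j dH_j theta_ij` is formed,
#' and the injection heat is `Q_i - Q_{i-1} + (v_i/V0)(Q_i + Q_{i-1})/2`,
#' normalized per mole of injectant.
#'
#' @param params A [binding_params()] object.
#' @param protocol A [titration_protocol()].
#' @return A tibble with `injection`, `volume_ul`, `molar_ratio` (total
#'   titrant over total macromolecule) and `heat_kcal_per_mol`.
#' @export
model_heats <- function(params, protocol) {
  tot <- titration_totals(protocol)
  v0_l <- protocol$cell_volume_ul * 1e-6
  xs <- protocol$syringe_conc_uM * 1e-6
  vols_l <- protocol$injection_volumes_ul * 1e-6
  q_prev <- 0
  heats <- numeric(length(vols_l))
  for (i in seq_along(vols_l)) {
    xf <- free_ligand(tot$X[i], tot$M[i], params)
    theta <- params$ka * xf / (1 + params$ka * xf)
    q <- v0_l * tot$M[i] * sum(params$n * params$dh * theta)
    dq <- q - q_prev + (vols_l[i] / v0_l) * (q + q_prev) / 2
    heats[i] <- dq / (xs * vols_l[i])
    q_prev <- q
  }
  tibble::tibble(
    injection = seq_along(heats),
    volume_ul = protocol$injection_volumes_ul,
    molar_ratio = tot$X / tot$M,
    heat_kcal_per_mol = heats
  )
}

#' Simulate an ITC isotherm
#'
#' Model heats from [model_heats()] plus independent Gaussian noise;
#' `noise_sd = 0` returns the exact model values. Deterministic for a fixed
#' seed and independent of the global RNG state.
#'
#' @inheritParams model_heats
#' @param noise_sd Noise standard deviation, kcal per mole of injectant.
#' @param seed Integer seed.
#' @return An isotherm tibble (`injection`, `volume_ul`, `molar_ratio`,
#'   `heat_kcal_per_mol`) with the protocol attached as attribute
#'   `"protocol"`.
#' @export
simulate_itc <- function(params, protocol, noise_sd = 0, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  iso <- model_heats(params, protocol)
  if (noise_sd > 0) {
    iso$heat_kcal_per_mol <- iso$heat_kcal_per_mol +
      with_local_seed(seed, stats::rnorm(nrow(iso), 0, noise_sd))
  }
  attr(iso, "protocol") <- protocol
  iso
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Subtract a dilution blank from a sample isotherm
#'
#' @param sample,blank Isotherm tibbles with matching injection counts.
#' @return The sample isotherm with elementwise blank-corrected heats.
#' @export
subtract_dilution <- function(sample, blank) {
  if (nrow(sample) != nrow(blank)) {
    stop("sample and blank have different injection counts", call. = FALSE)
  }
  sample$heat_kcal_per_mol <- sample$heat_kcal_per_mol - blank$heat_kcal_per_mol
  sample
}

#' Derived thermodynamic quantities per site class
#'
#' `dG = -RT ln Ka` (R = 1.9872e-3 kcal/mol/K), `TdS = dH - dG`,
#' `Kd = 1/Ka`.
#'
#' @param params A [binding_params()] object.
#' @param temperature_K Temperature in kelvin.
#' @return A tibble per site class: `site`, `n`, `kd_nM`, `dh_kcal`,
#'   `dg_kcal`, `tds_kcal`, `ds_cal_per_mol_K`.
#' @export
derive_thermo <- function(params, temperature_K = 298.15) {
  dg <- -R_GAS * temperature_K * log(params$ka)
  tds <- params$dh - dg
  tibble::tibble(
    site = seq_along(params$ka),
    n = params$n,
    kd_nM = 1e9 / params$ka,
    dh_kcal = params$dh,
    dg_kcal = dg,
    tds_kcal = tds,
    ds_cal_per_mol_K = 1000 * tds / temperature_K
  )
}

# parameter vector <-> binding_params (log scale keeps n, Ka positive)
pack_params <- function(params) {
  c(rbind(log(params$n), log(params$ka), params$dh))
}
unpack_params <- function(theta, n_sites) {
  m <- matrix(theta, nrow = 3)
  binding_params(n = exp(m[1, ]), dh = m[3, ], ka = exp(m[2, ]))
}

#' Fit a binding model to an ITC isotherm
#'
#' Least-squares minimization of [model_heats()] residuals over
#' `(log n_j, log Ka_j, dH_j)` using Levenberg-Marquardt from multiple
#' seeded, dispersed starting points (Kd log-uniform in 1 nM - 10 uM, dH
#' uniform in +/-30 kcal/mol, n log-uniform in 0.1 - 2). For the two-site
#' model the site classes are ordered weakest first (Ka1 < Ka2).
#'
#' @param isotherm Isotherm tibble (needs attribute `"protocol"`, or pass
#'   `protocol`).
#' @param model `"one-site"` or `"two-site"`.
#' @param n_starts Number of multi-start initial points (default 20).
#' @param seed Integer seed for start dispersion.
#' @param protocol Optional [titration_protocol()] override.
#' @return An object of class `itc_fit`: list with `params`
#'   ([binding_params()]), `se` (per-parameter standard errors), `rss`,
#'   `sigma`, `aicc`, `converged`, `n_obs`, `model`, `protocol`,
#'   `isotherm`, `fitted`.
#' @export
fit_isotherm <- function(isotherm, model = c("one-site", "two-site"),
                         n_starts = 20, seed = 1, protocol = NULL) {
  model <- match.arg(model)
  protocol <- protocol %||% attr(isotherm, "protocol")
  if (is.null(protocol)) stop("no titration protocol supplied", call. = FALSE)
  y <- isotherm$heat_kcal_per_mol
  n_sites <- if (model == "one-site") 1 else 2
  n_par <- 3 * n_sites
  if (length(y) < n_par + 3) {
    stop("need at least ", n_par + 3, " injections to fit a ", model, " model",
         call. = FALSE)
  }
  resid_fn <- function(theta) {
    p <- tryCatch(unpack_params(theta, n_sites), error = function(e) NULL)
    if (is.null(p)) return(rep(1e6, length(y)))
    pred <- tryCatch(model_heats(p, protocol)$heat_kcal_per_mol,
                     error = function(e) rep(NA_real_, length(y)))
    r <- y - pred
    r[!is.finite(r)] <- 1e6
    r
  }
  starts <- with_local_seed(seed, {
    lapply(seq_len(n_starts), function(s) {
      kd <- 10^stats::runif(n_sites, log10(1e-9), log10(1e-5))
      n0 <- 10^stats::runif(n_sites, log10(0.1), log10(2))
      dh0 <- stats::runif(n_sites, -30, 30)
      c(rbind(log(n0), log(1 / kd), dh0))
    })
  })
  best <- NULL
  n_conv <- 0
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    n_conv <- n_conv + 1
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best_rss) {
      best <- fit; best_rss <- rss
    }
    if (best_rss < 1e-18) break  # machine-precision optimum; later starts moot
  }
  if (is.null(best)) stop("fit failed to converge from all ", n_starts,
                          " starting points", call. = FALSE)
  theta <- best$par
  params <- unpack_params(theta, n_sites)
  # order site classes weakest first
  ord <- order(params$ka)
  params <- binding_params(n = params$n[ord], dh = params$dh[ord],
                           ka = params$ka[ord])
  theta <- pack_params(params)
  n_obs <- length(y)
  rss <- best_rss
  dof <- max(n_obs - n_par, 1)
  sigma2 <- rss / dof
  # asymptotic standard errors on the natural scale via the delta method
  jac <- numeric_jacobian(resid_fn, theta)
  se_nat <- rep(NA_real_, n_par)
  covm <- tryCatch(sigma2 * solve(t(jac) %*% jac), error = function(e) NULL)
  if (!is.null(covm)) {
    se_log <- sqrt(pmax(diag(covm), 0))
    scale <- c(rbind(params$n, params$ka, rep(1, n_sites)))  # d(exp)/dtheta
    se_nat <- se_log * scale
  }
  aicc <- n_obs * log(rss / n_obs + 1e-300) + 2 * n_par +
    2 * n_par * (n_par + 1) / max(n_obs - n_par - 1, 1)
  fitted_iso <- model_heats(params, protocol)
  structure(
    list(params = params,
         se = matrix(se_nat, nrow = 3,
                     dimnames = list(c("n", "ka", "dh"),
                                     paste0("site", seq_len(n_sites)))),
         rss = rss, sigma = sqrt(sigma2), aicc = aicc,
         converged = n_conv > 0, n_starts_converged = n_conv,
         n_obs = n_obs, model = model, protocol = protocol,
         isotherm = isotherm, fitted = fitted_iso),
    class = "itc_fit"
  )
}

numeric_jacobian <- function(fn, theta, eps = 1e-6) {
  f0 <- fn(theta)
  J <- matrix(0, length(f0), length(theta))
  for (k in seq_along(theta)) {
    h <- eps * max(abs(theta[k]), 1)
    tp <- theta; tp[k] <- tp[k] + h
    J[, k] <- (fn(tp) - f0) / h
  }
  J
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("ITC", x$model, "fit:", x$n_obs, "injections, rss =",
      format(x$rss, digits = 4), "\n")
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy an ITC fit into one row per site class
#'
#' @param x An `itc_fit` object.
#' @param ... Unused.
#' @return Tibble: `site`, `n`, `n_se`, `kd_nM`, `ka`, `ka_se`, `dh_kcal`,
#'   `dh_se`, `dg_kcal`, `tds_kcal`, `ds_cal_per_mol_K`.
#' @method tidy itc_fit
#' @export
tidy.itc_fit <- function(x, ...) {
  th <- derive_thermo(x$params, x$protocol$temperature_K)
  th$n_se <- x$se["n", ]
  th$ka <- x$params$ka
  th$ka_se <- x$se["ka", ]
  th$dh_se <- x$se["dh", ]
  th[, c("site", "n", "n_se", "kd_nM", "ka", "ka_se", "dh_kcal", "dh_se",
         "dg_kcal", "tds_kcal", "ds_cal_per_mol_K")]
}

#' One-row model-level summary of an ITC fit
#'
#' @inheritParams tidy.itc_fit
#' @return Tibble: `model`, `n_obs`, `rss`, `sigma`, `aicc`, `converged`.
#' @method glance itc_fit
#' @export
glance.itc_fit <- function(x, ...) {
  tibble::tibble(model = x$model, n_obs = x$n_obs, rss = x$rss,
                 sigma = x$sigma, aicc = x$aicc, converged = x$converged)
}

#' Write / read the isotherm CSV dialect
#'
#' Header `injection,volume_ul,heat_kcal_per_mol`; one row per injection.
#'
#' @param isotherm Isotherm tibble.
#' @param path File path.
#' @return `read_isotherm_csv` returns an isotherm tibble (without protocol
#'   metadata, which must be supplied to [fit_isotherm()] separately).
#' @export
write_isotherm_csv <- function(isotherm, path) {
  utils::write.csv(
    isotherm[, c("injection", "volume_ul", "heat_kcal_per_mol")],
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_isotherm_csv
#' @export
read_isotherm_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("injection", "volume_ul", "heat_kcal_per_mol")
  if (!all(need %in% names(df))) {
    stop("isotherm CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(df)
}
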