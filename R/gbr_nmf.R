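#' Configuration for group/basis-restricted NMF
#'
#' Decomposes non-negative spectra as `V ~ W H` where the first
#' `n_constrained` rows of `H` are frozen to a pure-biochemical library and
#' `n_free_factors` additional rows (default 1) are fitted freely to absorb
#' unmodelled signal; all entries of `W` (the scores) and of the free `H`
#' rows are non-negative.
#'
#' @param library a `basis_library` (see [generate_basis_library()]).
#' @param n_free_factors number of unconstrained factors (default 1).
#' @param max_iter multiplicative-update cap (default 2000).
#' @param tol relative reconstruction-error change threshold (default 1e-6).
#' @param seed seed for the score initialization.
#' @param solver `"multiplicative"` (Lee-Seung-type updates, free rows
#'   allowed) or `"nnls"` (exact per-spectrum non-negative least squares,
#'   available when `n_free_factors = 0`).
#' @return an `nmf_config` list.
#' @export
nmf_config <- function(library, n_free_factors = 1L, max_iter = 2000L,
                       tol = 1e-6, seed = 1L,
                       solver = c("multiplicative", "nnls")) {
  solver <- match.arg(solver)
  if (!inherits(library, "basis_library")) {
    stop_config("library", "must be a basis_library")
  }
  if (n_free_factors < 0) stop_config("n_free_factors", "must be >= 0")
  if (tol <= 0) stop_config("tol", "must be > 0")
  if (solver == "nnls" && n_free_factors > 0) {
    stop_config("solver", "'nnls' requires n_free_factors = 0")
  }
  structure(list(library = library,
                 n_free_factors = as.integer(n_free_factors),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed), solver = solver),
            class = "nmf_config")
}

#' Total number of NMF factors
#'
#' @param cfg an [nmf_config()].
#' @return `n_constrained + n_free_factors`.
#' @export
factor_count <- function(cfg) {
  cfg$library$n_constrained + cfg$n_free_factors
}

NMF_FLOOR <- 1e-12

#' Fit the group/basis-restricted NMF
#'
#' Minimizes `||V - W H||_F^2` with `W >= 0`, constrained `H` rows frozen to
#' the library and free rows `>= 0`. The multiplicative solver alternates
#' Lee-Seung-type updates of `W` and of the free `H` rows (denominators
#' floored at 1e-12), which never increase the objective; the `nnls` solver
#' solves each spectrum exactly and independently.
#'
#' @param ds a [spectral_dataset()] (non-negative, on the library grid) or a
#'   non-negative intensity matrix.
#' @param cfg an [nmf_config()].
#' @return an `nmf_decomposition`: `scores` (`n x factor_count`), `bases`
#'   (factors x grid points; constrained rows bit-identical to the library),
#'   `reconstruction_error` (Frobenius residual per iteration), `converged`,
#'   `n_constrained`, `n_free_factors`.
#' @export
gbr_nmf_fit <- function(ds, cfg) {
  stopifnot(inherits(cfg, "nmf_config"))
  V <- nmf_input_matrix(ds, cfg)
  lib <- cfg$library
  nc <- lib$n_constrained
  nf <- cfg$n_free_factors
  r <- nc + nf
  n <- nrow(V)

  if (cfg$solver == "nnls") {
    H <- lib$basis_matrix
    W <- project_scores(V, H)
    err <- norm(V - W %*% H, "F")
    return(new_decomposition(W, H, err, TRUE, nc, nf, lib, cfg))
  }

  with_seed(cfg$seed, {
    H <- matrix(0, r, ncol(V))
    H[seq_len(nc), ] <- lib$basis_matrix
    if (nf > 0) {
      mbar <- colMeans(V)
      res <- pmax(mbar - drop(crossprod(
        lib$basis_matrix,
        nnls_solve(t(lib$basis_matrix), mbar)$x)), 0)
      if (sum(res) <= 0) res <- rep(mean(mbar), ncol(V))
      for (k in seq_len(nf)) H[nc + k, ] <- res * runif(1, 0.5, 1.5)
    }
    W <- matrix(runif(n * r), n, r) *
      (mean(V) / max(r * mean(H), NMF_FLOOR))

    errs <- numeric(0)
    converged <- FALSE
    prev <- norm(V - W %*% H, "F")
    for (it in seq_len(cfg$max_iter)) {
      W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + NMF_FLOOR)
      if (nf > 0) {
        free <- nc + seq_len(nf)
        num <- crossprod(W, V)
        den <- crossprod(W) %*% H + NMF_FLOOR
        H[free, ] <- H[free, , drop = FALSE] *
          num[free, , drop = FALSE] / den[free, , drop = FALSE]
      }
      e <- norm(V - W %*% H, "F")
      errs[it] <- e
      if (abs(prev - e) <= cfg$tol * max(prev, NMF_FLOOR)) {
        converged <- TRUE
        break
      }
      prev <- e
    }
    new_decomposition(W, H, errs, converged, nc, nf, lib, cfg)
  })
}

nmf_input_matrix <- function(ds, cfg) {
  if (inherits(ds, "spectral_dataset")) {
    if (!grid_equal(ds$grid, cfg$library$grid)) {
      stop("shape error: dataset and basis library grids differ",
           call. = FALSE)
    }
    V <- ds$intensities
  } else {
    V <- as.matrix(ds)
    if (ncol(V) != ncol(cfg$library$basis_matrix)) {
      stop("shape error: matrix columns do not match the library grid",
           call. = FALSE)
    }
  }
  if (any(V < 0)) {
    stop("domain error: NMF input contains negative intensities",
         call. = FALSE)
  }
  V
}

new_decomposition <- function(W, H, errs, converged, nc, nf, lib, cfg) {
  structure(list(scores = W, bases = H, reconstruction_error = errs,
                 converged = converged, n_constrained = nc,
                 n_free_factors = nf,
                 factor_names = c(lib$names,
                                  if (nf > 0) sprintf("free_%d",
                                                      seq_len(nf))),
                 library = lib, config = cfg),
            class = "nmf_decomposition")
}

#' @export
print.nmf_decomposition <- function(x, ...) {
  cat(sprintf(
    "<nmf_decomposition> %d spectra x (%d constrained + %d free) factors, final residual %.4g%s\n",
    nrow(x$scores), x$n_constrained, x$n_free_factors,
    utils::tail(x$reconstruction_error, 1),
    if (x$converged) " (converged)" else ""))
  invisible(x)
}

# NNLS projection of each spectrum onto fixed bases (rows of H).
project_scores <- function(V, H) {
  At <- t(H)
  W <- matrix(0, nrow(V), nrow(H))
  for (i in seq_len(nrow(V))) {
    W[i, ] <- nnls_solve(At, V[i, ])$x
  }
  W
}

#' Score new spectra against a fitted decomposition
#'
#' Holds every basis row fixed (constrained and previously fitted free rows)
#' and solves per-spectrum non-negative least squares for the scores, so
#' held-out spectra can be projected onto bases fitted on training spectra.
#'
#' @param dec an `nmf_decomposition` from [gbr_nmf_fit()].
#' @param ds a [spectral_dataset()] or non-negative matrix on the same grid.
#' @return non-negative score matrix, `n x factor_count`.
#' @export
gbr_nmf_transform <- function(dec, ds) {
  stopifnot(inherits(dec, "nmf_decomposition"))
  V <- nmf_input_matrix(ds, dec$config)
  project_scores(V, dec$bases)
}
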