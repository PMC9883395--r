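#' Configuration for the synthetic tissue-spectrum generator
#'
#' The generator emulates the structure of an irradiated-xenograft Raman
#' study: per dose arm, `n_mice_per_arm` mice each contribute
#' `sections_per_mouse` consecutive tumour sections, each section two Raman
#' maps, each map `spectra_per_map` spectra. Each spectrum is the sum of a
#' broad fluorescence baseline, dose-responsive Lorentzian bands and white
#' noise; band amplitudes carry multiplicative log-normal random effects at
#' the mouse, section and map levels so spectra from one animal are more
#' alike than spectra from different animals.
#'
#' @param grid a [wavenumber_grid()].
#' @param peaks a peak table as returned by [default_peak_table()].
#' @param n_mice_per_arm mice per dose arm (default 5).
#' @param sections_per_mouse tumour sections per mouse (default 3).
#' @param maps_per_section Raman maps per section (default 2).
#' @param spectra_per_map spectra per map (default 80).
#' @param doses dose arms in Gy, subset of `c(0, 5, 15)`.
#' @param day collection day post-irradiation (1 or 3).
#' @param mouse_sd,section_sd,map_sd log-scale SD of the multiplicative
#'   per-band random effects at each hierarchy level.
#' @param noise_sd additive Gaussian noise SD (intensity units; band heights
#'   are order 1).
#' @param baseline_amplitude scale of the smooth fluorescence background.
#' @param seed integer RNG seed.
#' @return a `generator_config` list.
#' @export
generator_config <- function(grid = wavenumber_grid(),
                             peaks = default_peak_table(),
                             n_mice_per_arm = 5L,
                             sections_per_mouse = 3L,
                             maps_per_section = 2L,
                             spectra_per_map = 80L,
                             doses = c(0, 15),
                             day = 3L,
                             mouse_sd = 0.10,
                             section_sd = 0.05,
                             map_sd = 0.05,
                             noise_sd = 0.02,
                             baseline_amplitude = 2,
                             seed = 1L) {
  cfg <- list(grid = grid, peaks = peaks,
              n_mice_per_arm = as.integer(n_mice_per_arm),
              sections_per_mouse = as.integer(sections_per_mouse),
              maps_per_section = as.integer(maps_per_section),
              spectra_per_map = as.integer(spectra_per_map),
              doses = doses, day = as.integer(day),
              mouse_sd = mouse_sd, section_sd = section_sd, map_sd = map_sd,
              noise_sd = noise_sd, baseline_amplitude = baseline_amplitude,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (!inherits(cfg$grid, "wavenumber_grid")) {
    stop_config("grid", "must be a wavenumber_grid")
  }
  for (f in c("n_mice_per_arm", "sections_per_mouse", "maps_per_section",
              "spectra_per_map")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) {
      stop_config(f, "must be a count >= 1")
    }
  }
  if (length(cfg$doses) < 1 || !all(cfg$doses %in% c(0, 5, 15))) {
    stop_config("doses", "must be a non-empty subset of {0, 5, 15}")
  }
  if (anyDuplicated(cfg$doses)) stop_config("doses", "must be distinct")
  if (!cfg$day %in% c(1L, 3L)) stop_config("day", "must be 1 or 3")
  for (f in c("mouse_sd", "section_sd", "map_sd", "noise_sd",
              "baseline_amplitude")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) {
      stop_config(f, "must be >= 0")
    }
  }
  validate_peak_table(cfg$peaks, cfg$grid)
  invisible(cfg)
}

# Smooth low-order polynomial fluorescence bump, non-negative by shifting.
random_baseline <- function(wavenumbers, amplitude) {
  if (amplitude == 0) return(numeric(length(wavenumbers)))
  x <- (wavenumbers - min(wavenumbers)) / diff(range(wavenumbers)) # 0..1
  coef <- rnorm(4, sd = c(0.5, 1, 1, 0.5))
  b <- coef[1] + coef[2] * x + coef[3] * x^2 + coef[4] * x^3
  b <- b - min(b)                     # non-negative
  if (max(b) > 0) b <- b / max(b)     # unit height
  amplitude * (0.25 + b)              # broad pedestal + bump
}

#' Generate a synthetic hierarchical Raman dataset
#'
#' @param config a [generator_config()].
#' @return a [spectral_dataset()] with
#'   `n_doses * n_mice_per_arm * sections_per_mouse * maps_per_section *
#'   spectra_per_map` spectra, clipped at zero and area-normalized.
#'   Deterministic for a fixed `config$seed`.
#' @export
generate_dataset <- function(config) {
  validate_generator_config(config)
  with_seed(config$seed, {
    wn <- config$grid$wavenumbers
    peaks <- config$peaks
    np <- nrow(peaks)
    n_per_arm <- config$n_mice_per_arm * config$sections_per_mouse *
      config$maps_per_section * config$spectra_per_map
    n_total <- length(config$doses) * n_per_arm
    X <- matrix(0, n_total, length(wn))
    meta <- vector("list", n_total)
    row <- 0L
    mouse_counter <- 0L
    for (dose in config$doses) {
      for (m in seq_len(config$n_mice_per_arm)) {
        mouse_counter <- mouse_counter + 1L
        mouse_id <- sprintf("m%02d", mouse_counter)
        g_mouse <- rlnorm(np, 0, config$mouse_sd)
        for (s in seq_len(config$sections_per_mouse)) {
          g_sec <- rlnorm(np, 0, config$section_sd)
          for (p in seq_len(config$maps_per_section)) {
            g_map <- rlnorm(np, 0, config$map_sd)
            amp <- peaks$base_amplitude *
              pmax(0, 1 + peaks$dose_coefficient * dose) *
              g_mouse * g_sec * g_map
            signal <- peak_signal(wn, peaks, amp)
            for (k in seq_len(config$spectra_per_map)) {
              row <- row + 1L
              # fluorescence varies point to point within a map
              baseline <- random_baseline(wn, config$baseline_amplitude)
              y <- signal + baseline
              if (config$noise_sd > 0) {
                y <- y + rnorm(length(wn), sd = config$noise_sd)
              }
              y <- pmax(y, 0)
              area <- trapz_area(wn, y)
              if (area <= 0) {
                stop("degenerate all-zero spectrum generated", call. = FALSE)
              }
              X[row, ] <- y / area
              meta[[row]] <- data.frame(
                dose_gy = dose, day = config$day, mouse_id = mouse_id,
                section_id = s, map_id = p, spectrum_index = k,
                label = if (dose == 0) "nonirradiated" else "irradiated",
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
    spectral_dataset(config$grid, X, do.call(rbind, meta))
  })
}

#' Generate a synthetic pure-biochemical basis library
#'
#' Stand-in for a library of measured pure-compound Raman spectra: each basis
#' is a sparse combination of Lorentzian bands at random positions,
#' area-normalized. Candidates too collinear with an accepted basis (cosine
#' similarity above `max_cosine`) are rejected so the library is
#' well-conditioned for constrained NMF.
#'
#' @param grid a [wavenumber_grid()].
#' @param n_constrained number of basis spectra (default 31).
#' @param seed integer RNG seed.
#' @param max_cosine pairwise cosine-similarity cap (default 0.90).
#' @param peaks_per_basis range of bands per compound.
#' @param max_tries rejection-sampling budget per basis.
#' @return a `basis_library`: list with `names`, `basis_matrix`
#'   (`n_constrained x grid$n_points`, rows area-normalized), `n_constrained`
#'   and `grid`.
#' @export
generate_basis_library <- function(grid = wavenumber_grid(),
                                   n_constrained = 31L,
                                   seed = 1L,
                                   max_cosine = 0.90,
                                   peaks_per_basis = c(2L, 5L),
                                   max_tries = 200L) {
  n_constrained <- as.integer(n_constrained)
  if (is.na(n_constrained) || n_constrained < 2L) {
    stop_config("n_constrained", "must be >= 2")
  }
  with_seed(seed, {
    wn <- grid$wavenumbers
    H <- matrix(0, n_constrained, grid$n_points)
    for (i in seq_len(n_constrained)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        k <- sample(seq(peaks_per_basis[1], peaks_per_basis[2]), 1)
        centers <- runif(k, grid$start + 20, grid$end - 20)
        widths <- runif(k, 5, 15)
        amps <- runif(k, 0.3, 1)
        y <- peak_signal(wn, data.frame(center = centers, width = widths),
                         amps)
        y <- y / trapz_area(wn, y)
        if (i == 1L) { ok <- TRUE } else {
          prev <- H[seq_len(i - 1L), , drop = FALSE]
          cosines <- (prev %*% y) /
            (sqrt(rowSums(prev^2)) * sqrt(sum(y^2)))
          ok <- max(cosines) <= max_cosine
        }
        if (ok) { H[i, ] <- y; break }
      }
      if (!ok) {
        stop("basis generation failed: could not place basis ", i,
             " under the cosine-similarity cap ", max_cosine, call. = FALSE)
      }
    }
    structure(list(names = sprintf("compound_%02d", seq_len(n_constrained)),
                   basis_matrix = H, n_constrained = n_constrained,
                   grid = grid),
              class = "basis_library")
  })
}

#' @export
print.basis_library <- function(x, ...) {
  cat(sprintf("<basis_library> %d constrained bases x %d points\n",
              x$n_constrained, ncol(x$basis_matrix)))
  invisible(x)
}

#' Write / read a basis library as delimited text
#'
#' First column is the compound name, remaining columns the intensities on
#' the grid (header row: `name` then the wavenumbers).
#'
#' @param lib a `basis_library`.
#' @param file path.
#' @return `read_basis_library` returns the reconstructed `basis_library`.
#' @export
write_basis_library <- function(lib, file) {
  df <- data.frame(name = lib$names,
                   formatC(lib$basis_matrix, digits = 17, format = "g"),
                   stringsAsFactors = FALSE)
  names(df) <- c("name", formatC(lib$grid$wavenumbers, digits = 17,
                                 format = "g"))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(lib)
}

#' @rdname write_basis_library
#' @export
read_basis_library <- function(file) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  wn <- as.numeric(names(df)[-1])
  grid <- wavenumber_grid(wn[1], wn[length(wn)], length(wn))
  H <- as.matrix(df[, -1, drop = FALSE])
  dimnames(H) <- NULL
  structure(list(names = df$name, basis_matrix = H,
                 n_constrained = nrow(H), grid = grid),
            class = "basis_library")
}
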