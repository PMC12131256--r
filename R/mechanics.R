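#' Slope-extraction configuration
#'
#' Controls how the initial slope dF/dx is taken from a force--displacement
#' curve. The curve's leading toe (seating/compliance, forces below
#' `toe_force_frac` of the peak force) is discarded, then least-squares
#' windows are searched over the first `search_fraction` of the remaining
#' displacement range. All candidate windows end at the search boundary and
#' differ in their start: sweeping the start forward sheds residual toe
#' curvature, and among starts whose r-squared falls within the near-optimal
#' band of the best achievable the earliest (hence longest) window is
#' chosen, subject to `r2_threshold` and at least `min_points` points.
#'
#' @param min_points Minimum window length (points), default 5.
#' @param search_fraction Fraction of the post-toe displacement range
#'   searched, default 0.5.
#' @param r2_threshold Minimum coefficient of determination, default 0.99.
#' @param toe_force_frac Force floor for toe exclusion as a fraction of peak
#'   force, default 0.02.
#' @return A list of class `"slope_config"`.
#' @export
slope_config <- function(min_points = 5L, search_fraction = 0.5,
                         r2_threshold = 0.99, toe_force_frac = 0.02) {
  stopifnot(min_points >= 3L, search_fraction > 0, search_fraction <= 1,
            r2_threshold >= 0, r2_threshold <= 1,
            toe_force_frac >= 0, toe_force_frac < 1)
  structure(list(min_points = as.integer(min_points),
                 search_fraction = search_fraction,
                 r2_threshold = r2_threshold,
                 toe_force_frac = toe_force_frac),
            class = "slope_config")
}

# O(1)-per-window least squares via prefix sums; vectorized over start
# indices i for a fixed end index j (or vice versa).
.window_fit <- function(cx, cy, cxy, cxx, cyy, i, j) {
  n  <- j - i + 1
  sx  <- cx[j + 1L] - cx[i]
  sy  <- cy[j + 1L] - cy[i]
  sxy <- cxy[j + 1L] - cxy[i]
  sxx <- cxx[j + 1L] - cxx[i]
  syy <- cyy[j + 1L] - cyy[i]
  vx <- sxx - sx^2 / n
  vy <- syy - sy^2 / n
  cv <- sxy - sx * sy / n
  slope <- cv / vx
  # r2 = 1 - SSE/SST; perfect fit and zero-variance y handled explicitly
  sse <- pmax(vy - cv^2 / vx, 0)
  r2 <- ifelse(vy > .Machine$double.eps * pmax(syy, 1), 1 - sse / vy, NA_real_)
  list(slope = slope, r2 = r2, n = n)
}

#' Extract the initial slope of a bending trace
#'
#' Least-squares estimate of dF/dx over the early linear region of the
#' curve, after toe exclusion (see [slope_config()]). Fails rather than
#' guessing on degenerate traces (all-zero or constant force) and on
#' negative fitted slopes, which signal a corrupted test.
#'
#' @param trace A [bending_trace()].
#' @param cfg A [slope_config()].
#' @return A list of class `"slope_estimate"`: `slope` (N/m), `fit_r2`,
#'   `window_start_idx`, `window_end_idx` (indices into the trace as
#'   cleaned/ordered by [bending_trace()]), `n_points`.
#' @export
extract_initial_slope <- function(trace, cfg = slope_config()) {
  stopifnot(inherits(trace, "bending_trace"), inherits(cfg, "slope_config"))
  x <- trace$displacement
  y <- trace$force
  fmax <- max(y)
  if (fmax <= 0 || max(y) == min(y))
    stop("degenerate trace: constant or non-positive force")
  m <- min(cfg$min_points, length(x))
  keep <- which(y >= cfg$toe_force_frac * fmax)
  first <- if (length(keep)) keep[1L] else 1L
  first <- min(first, length(x) - m + 1L)  # never strip below a fittable window
  x0 <- x[first:length(x)]
  y0 <- y[first:length(y)]
  n <- length(x0)
  xmax_search <- x0[1L] + cfg$search_fraction * (x0[n] - x0[1L])
  jmax <- max(max(which(x0 <= xmax_search)), m)
  cx  <- c(0, cumsum(x0)); cy <- c(0, cumsum(y0))
  cxy <- c(0, cumsum(x0 * y0)); cxx <- c(0, cumsum(x0^2)); cyy <- c(0, cumsum(y0^2))

  # Windows end at the search boundary; the start sweeps forward, shedding
  # any residual toe curvature. Among starts whose r2 lies within the
  # near-optimal band of the best achievable (1 - 2*(1 - r2max)), the
  # earliest (longest window) wins: noiseless toes give the exact linear
  # segment, while under noise the pinned end keeps windows long so no
  # lucky micro-window can hijack the fit.
  is <- seq_len(jmax - m + 1L)
  fit <- .window_fit(cx, cy, cxy, cxx, cyy, is, jmax)
  if (all(is.na(fit$r2)))
    stop("degenerate trace: no force variation in the search region")
  r2max <- max(fit$r2, na.rm = TRUE)
  if (r2max < cfg$r2_threshold)
    stop("no window meets the r-squared threshold (", cfg$r2_threshold,
         "); trace too noisy or nonlinear")
  band <- max(cfg$r2_threshold, 1 - 2 * (1 - r2max))
  i <- is[which(!is.na(fit$r2) & fit$r2 >= band)[1L]]
  slope <- fit$slope[i]
  if (slope < 0) stop("negative fitted slope: corrupted trace")
  structure(list(slope = slope, fit_r2 = fit$r2[i],
                 window_start_idx = first + i - 1L,
                 window_end_idx = first + jmax - 1L,
                 n_points = jmax - i + 1L),
            class = "slope_estimate")
}

#' Flexural rigidity from a four-point bending slope
#'
#' Euler--Bernoulli closed form for four-point bending:
#' `EI = slope * a * (3 L^2 - 4 a^2) / 48`, with `slope = dF/dx` the initial
#' slope of the force--displacement curve, `L` the support span and `a` the
#' probe offset. At `a = L/2` this reduces to the central-loading form
#' `slope * L^3 / 48`.
#'
#' @param slope Initial slope dF/dx in N/m (non-negative).
#' @param L Support span, metres.
#' @param a Probe offset, metres, `0 < a <= L/2`.
#' @return Flexural rigidity EI in N m^2.
#' @export
flexural_rigidity <- function(slope, L, a) {
  geom <- bend_geometry(L, a)  # validates
  if (any(!is.finite(slope)) || any(slope < 0))
    stop("slope must be finite and non-negative")
  slope * geom$a * (3 * geom$L^2 - 4 * geom$a^2) / 48
}

#' Second moment of area, circular section
#'
#' `I = pi R^4 / 4` for a solid circular cross-section of radius `R`.
#'
#' @param R Radius in metres (> 0). Vectorized.
#' @return I in m^4.
#' @export
second_moment_circular <- function(R) {
  if (any(!is.finite(R)) || any(R <= 0)) stop("non-positive radius")
  pi * R^4 / 4
}

#' Second moment of area, rectangular section
#'
#' `I = W D^3 / 12` with `W` the width across the rig and `D` the depth in
#' the bending direction; the form is orientation-sensitive.
#'
#' @param W,D Width and depth in metres (> 0). Vectorized.
#' @return I in m^4.
#' @export
second_moment_rectangular <- function(W, D) {
  if (any(!is.finite(c(W, D))) || any(W <= 0) || any(D <= 0))
    stop("non-positive dimension")
  W * D^3 / 12
}

#' Second moment of area of a cross-section object
#'
#' @param section A [cross_section()].
#' @return I in m^4.
#' @export
second_moment <- function(section) {
  stopifnot(inherits(section, "cross_section"))
  if (section$shape == "circular") second_moment_circular(section$radius)
  else second_moment_rectangular(section$width, section$depth)
}

#' Elastic modulus from rigidity and geometry
#'
#' `E = EI / I`: dividing flexural rigidity by the second moment of area
#' isolates the material stiffness from the cross-sectional geometry.
#'
#' @param EI Flexural rigidity, N m^2 (>= 0). Vectorized.
#' @param I Second moment of area, m^4 (> 0).
#' @return E in pascals.
#' @export
elastic_modulus <- function(EI, I) {
  if (any(!is.finite(I)) || any(I <= 0)) stop("zero or negative second moment of area")
  if (any(!is.finite(EI)) || any(EI < 0)) stop("negative flexural rigidity")
  EI / I
}

#' Quality-control filter on elastic modulus
#'
#' Samples whose derived `E` is erroneously high — strictly above the
#' threshold (default 35 GPa, the upper bound plausible for dense woody
#' tissue) — are flagged `qc_pass = FALSE` and partitioned out; a value of
#' exactly 35 GPa is retained.
#'
#' @param derived A derived-quantities `data.frame` with an `E_Pa` column.
#' @param threshold_pa QC threshold in pascals, default `35e9`.
#' @return A list with `retained` and `dropped` data.frames (disjoint,
#'   exhaustive); both carry an updated `qc_pass` column.
#' @export
qc_filter <- function(derived, threshold_pa = 35e9) {
  stopifnot(is.data.frame(derived), threshold_pa > 0)
  if (!"E_Pa" %in% names(derived) || anyNA(derived$E_Pa))
    stop("every record needs a computed E_Pa before QC")
  derived$qc_pass <- derived$E_Pa <= threshold_pa
  list(retained = derived[derived$qc_pass, , drop = FALSE],
       dropped  = derived[!derived$qc_pass, , drop = FALSE])
}

#' Derive per-sample mechanical quantities
#'
#' Runs the full mechanics chain for a set of samples: initial slope from
#' each trace, EI from the four-point bending formula, I recomputed from the
#' canonical SI cross-section (never read from input), E = EI / I, and the
#' QC flag. This table is the contract between the mechanics and statistics
#' stages.
#'
#' @param traces Named list of [bending_trace()] objects (names or
#'   `sample_id`s must cover the metadata), or a directory of trace files
#'   named `<sample_id>.csv`.
#' @param meta Canonical metadata `data.frame` from [read_metadata()].
#' @param cfg A [slope_config()].
#' @param geometry A [bend_geometry()]; required when `traces` is a
#'   directory, ignored otherwise (each trace carries its own).
#' @param qc_threshold_pa QC threshold in pascals.
#' @return `data.frame` with columns `sample_id`, `slope_N_per_m`, `fit_r2`,
#'   `I_m4`, `EI_Nm2`, `E_Pa`, `qc_pass`.
#' @export
derive_mechanics <- function(traces, meta, cfg = slope_config(),
                             geometry = NULL, qc_threshold_pa = 35e9) {
  if (is.character(traces) && length(traces) == 1L) {
    stopifnot(dir.exists(traces), inherits(geometry, "bend_geometry"))
    files <- list.files(traces, full.names = TRUE)
    names(files) <- sub("\\.[^.]*$", "", basename(files))
    traces <- lapply(files, read_trace, geometry = geometry)
  }
  ids <- vapply(traces, function(tr) tr$sample_id, "")
  names(traces) <- ids
  miss <- setdiff(meta$sample_id, ids)
  if (length(miss))
    stop("no trace for sample(s): ", paste(utils::head(miss, 5), collapse = ", "))
  n <- nrow(meta)
  slope <- r2 <- I <- numeric(n)
  for (k in seq_len(n)) {
    est <- extract_initial_slope(traces[[meta$sample_id[k]]], cfg)
    slope[k] <- est$slope
    r2[k] <- est$fit_r2
    I[k] <- second_moment(row_section(meta[k, ]))
  }
  EI <- vapply(seq_len(n), function(k) {
    tr <- traces[[meta$sample_id[k]]]
    flexural_rigidity(slope[k], tr$span_L, tr$offset_a)
  }, 0)
  E <- elastic_modulus(EI, I)
  out <- data.frame(sample_id = meta$sample_id, slope_N_per_m = slope,
                    fit_r2 = r2, I_m4 = I, EI_Nm2 = EI, E_Pa = E,
                    qc_pass = E <= qc_threshold_pa,
                    stringsAsFactors = FALSE)
  out
}
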