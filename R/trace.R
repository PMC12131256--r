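#' Bending-test apparatus geometry
#'
#' Geometry of a four-point bending rig: `L` is the distance between the two
#' lower supports and `a` the distance between an inner (loading) probe and
#' the adjacent outer support. Both are in metres; a valid rig has
#' `0 < a <= L/2`.
#'
#' @param L Support span in metres.
#' @param a Inner-to-outer probe offset in metres.
#' @return A list of class `"bend_geometry"` with elements `L` and `a`.
#' @examples
#' bend_geometry(L = 0.1, a = 0.025)
#' @export
bend_geometry <- function(L, a) {
  stopifnot(is.numeric(L), is.numeric(a), length(L) == 1L, length(a) == 1L)
  if (!is.finite(L) || !is.finite(a) || L <= 0 || a <= 0)
    stop("geometry violation: L and a must be finite and strictly positive")
  if (a > L / 2)
    stop("geometry violation: offset a exceeds L/2 (a = ", a, ", L = ", L, ")")
  structure(list(L = L, a = a), class = "bend_geometry")
}

#' Construct a force--displacement trace
#'
#' Canonical container for one sample's bending test: an ordered
#' displacement series (m), the matching force series (N) and the apparatus
#' geometry. Rows are sorted by displacement and exact duplicate
#' displacements are collapsed by averaging their forces (instrument jitter
#' produces occasional repeated encoder readings).
#'
#' @param displacement Numeric vector, metres.
#' @param force Numeric vector, newtons, same length as `displacement`.
#' @param geometry A [bend_geometry()].
#' @param sample_id Optional identifier string.
#' @return An object of class `"bending_trace"`.
#' @export
bending_trace <- function(displacement, force, geometry, sample_id = NA_character_) {
  stopifnot(inherits(geometry, "bend_geometry"))
  if (length(displacement) != length(force))
    stop("displacement and force series differ in length")
  if (anyNA(displacement) || anyNA(force) ||
      !all(is.finite(displacement)) || !all(is.finite(force)))
    stop("malformed numeric content: non-finite displacement or force")
  ord <- order(displacement)
  displacement <- displacement[ord]
  force <- force[ord]
  if (anyDuplicated(displacement)) {
    force <- as.numeric(tapply(force, factor(displacement, levels = unique(displacement)), mean))
    displacement <- unique(displacement)
  }
  if (length(displacement) < 2L)
    stop("insufficient points: a trace needs at least 2 distinct displacements")
  structure(
    list(sample_id = as.character(sample_id),
         displacement = displacement, force = force,
         span_L = geometry$L, offset_a = geometry$a),
    class = "bending_trace")
}

#' @export
print.bending_trace <- function(x, ...) {
  cat(sprintf("<bending_trace %s: %d points, x in [%.3g, %.3g] m, L = %g m, a = %g m>\n",
              x$sample_id, length(x$displacement),
              min(x$displacement), max(x$displacement), x$span_L, x$offset_a))
  invisible(x)
}

# unit multipliers to SI
.disp_units  <- c(m = 1, cm = 1e-2, mm = 1e-3, um = 1e-6)
.force_units <- c(N = 1, kN = 1e3, mN = 1e-3)

.sniff_delim <- function(lines) {
  cand <- c(",", "\t", ";")
  counts <- vapply(cand, function(d) sum(lengths(strsplit(lines, d, fixed = TRUE)) - 1L), 0L)
  if (all(counts == 0L)) "" else cand[which.max(counts)]  # "" = whitespace
}

#' Read a raw force--displacement trace file
#'
#' Reads one two-column delimited text file (displacement then force) as
#' produced by a portable universal testing machine, converts to SI and
#' returns a validated [bending_trace()]. The delimiter (comma, tab,
#' semicolon or whitespace) is sniffed and a single non-numeric header line
#' is skipped if present. Input units default to SI and are declared per
#' file, not guessed.
#'
#' @param path Path to the trace file.
#' @param geometry A [bend_geometry()].
#' @param units Named character vector declaring input units,
#'   `c(displacement = "m"|"cm"|"mm"|"um", force = "N"|"mN"|"kN")`.
#' @param sample_id Identifier; defaults to the file name without extension.
#' @return A [bending_trace()].
#' @export
read_trace <- function(path, geometry,
                       units = c(displacement = "m", force = "N"),
                       sample_id = NULL) {
  stopifnot(inherits(geometry, "bend_geometry"))
  if (!file.exists(path)) stop("trace file not found: ", path)
  du <- .disp_units[[match.arg(units[["displacement"]], names(.disp_units))]]
  fu <- .force_units[[match.arg(units[["force"]], names(.force_units))]]
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("insufficient points: empty trace file ", path)
  delim <- .sniff_delim(lines)
  split1 <- if (nzchar(delim)) strsplit(lines[1L], delim, fixed = TRUE)[[1L]]
            else strsplit(lines[1L], "[[:space:]]+")[[1L]]
  skip <- if (suppressWarnings(all(is.na(as.numeric(split1[1:2]))))) 1L else 0L
  body <- lines[(skip + 1L):length(lines)]
  if (length(body) < 2L) stop("insufficient points: trace has fewer than 2 rows")
  mat <- if (nzchar(delim)) strsplit(body, delim, fixed = TRUE)
         else strsplit(body, "[[:space:]]+")
  if (any(lengths(mat) < 2L)) stop("malformed numeric content: expected two columns")
  x <- suppressWarnings(as.numeric(vapply(mat, `[[`, "", 1L)))
  f <- suppressWarnings(as.numeric(vapply(mat, `[[`, "", 2L)))
  if (anyNA(x) || anyNA(f)) stop("malformed numeric content in ", path)
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  bending_trace(x * du, f * fu, geometry, sample_id = sample_id)
}

#' Write a trace to a two-column CSV file (SI units)
#'
#' @param trace A [bending_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "bending_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("displacement_m,force_N", con)
  writeLines(paste(sprintf("%.17g", trace$displacement),
                   sprintf("%.17g", trace$force), sep = ","), con)
  invisible(path)
}
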