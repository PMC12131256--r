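#' Cross-section descriptor
#'
#' A sample's idealized cross-section: circular (radius) or rectangular
#' (width across the rig, depth in the bending direction), dimensions in
#' metres. Exactly the fields for the declared shape may be set.
#'
#' @param shape `"circular"` or `"rectangular"`.
#' @param radius Radius in metres (circular only).
#' @param width,depth Width and depth in metres (rectangular only).
#' @return A list of class `"cross_section"`.
#' @export
cross_section <- function(shape = c("circular", "rectangular"),
                          radius = NULL, width = NULL, depth = NULL) {
  shape <- match.arg(shape)
  if (shape == "circular") {
    if (is.null(radius) || !is.null(width) || !is.null(depth))
      stop("circular section takes exactly a radius")
    if (!is.finite(radius) || radius <= 0) stop("non-positive radius")
    out <- list(shape = shape, radius = radius)
  } else {
    if (is.null(width) || is.null(depth) || !is.null(radius))
      stop("rectangular section takes exactly width and depth")
    if (!all(is.finite(c(width, depth))) || width <= 0 || depth <= 0)
      stop("non-positive dimension")
    out <- list(shape = shape, width = width, depth = depth)
  }
  structure(out, class = "cross_section")
}

.material_levels   <- c("twig", "vine", "bark", "grass")
.preference_levels <- c("most_preferred", "less_preferred", "never_used")

.meta_required <- c("sample_id", "plant_id", "species", "mound_id", "plant_part",
                    "material_type", "length_cm", "tool_source_species",
                    "preference", "plant_used")

.as_flag <- function(x, what) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "yes", "y", "1", "used")] <- TRUE
  out[v %in% c("false", "f", "no", "n", "0", "not_used")] <- FALSE
  if (anyNA(out)) stop("unparseable logical values in column ", what)
  out
}

#' Read a sample-metadata table
#'
#' Reads the delimited field-dialect metadata table (dimensions in cm/mm)
#' and returns one row per tested sample in canonical SI form. Cross-section
#' shape is inferred from which dimension columns are populated: a
#' `diameter_mm` value implies circular, `breadth_mm` + `depth_mm` imply
#' rectangular; a row with both set is an error. Tables already in SI
#' canonical form (columns `shape`, `radius_m`, `width_m`, `depth_m`,
#' `length_m`, as written by [write_metadata()]) are read back directly.
#'
#' @param path Path to a delimited table (delimiter sniffed; header required).
#' @return A `data.frame` with columns `sample_id`, `plant_id`, `species`,
#'   `mound_id`, `plant_part`, `material_type`, `shape`, `radius_m`,
#'   `width_m`, `depth_m`, `length_m`, `tool_source_species`, `preference`,
#'   `plant_used`. Unset dimensions are `NA`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  l1 <- readLines(path, n = 1L)
  sep <- if (grepl("\t", l1)) "\t" else if (grepl(";", l1)) ";" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = TRUE)
  si_form <- all(c("shape", "length_m") %in% names(df))
  need <- if (si_form)
    c("sample_id", "plant_id", "species", "mound_id", "plant_part",
      "material_type", "shape", "radius_m", "width_m", "depth_m", "length_m",
      "tool_source_species", "preference", "plant_used")
  else .meta_required
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))

  df$material_type <- tolower(trimws(df$material_type))
  bad <- setdiff(unique(df$material_type), .material_levels)
  if (length(bad)) stop("unknown material type: ", paste(bad, collapse = ", "))
  df$preference <- tolower(trimws(df$preference))
  badp <- setdiff(unique(df$preference), .preference_levels)
  if (length(badp)) stop("unknown preference level: ", paste(badp, collapse = ", "))
  df$tool_source_species <- .as_flag(df$tool_source_species, "tool_source_species")
  df$plant_used <- .as_flag(df$plant_used, "plant_used")
  if (any(df$preference == "never_used" & df$tool_source_species))
    stop("inconsistent metadata: never_used species flagged as tool source")

  if (si_form) {
    for (col in c("radius_m", "width_m", "depth_m", "length_m"))
      df[[col]] <- as.numeric(df[[col]])
  } else {
    has_d <- "diameter_mm" %in% names(df) & !is.na(df[["diameter_mm"]])
    has_b <- if (all(c("breadth_mm", "depth_mm") %in% names(df)))
      !is.na(df$breadth_mm) & !is.na(df$depth_mm) else rep(FALSE, nrow(df))
    if (any(has_d & has_b))
      stop("record with both diameter and breadth/depth set: ",
           paste(df$sample_id[has_d & has_b], collapse = ", "))
    if (any(!has_d & !has_b))
      stop("record with no cross-section dimensions: ",
           paste(df$sample_id[!has_d & !has_b], collapse = ", "))
    df$shape <- ifelse(has_d, "circular", "rectangular")
    df$radius_m <- ifelse(has_d, df$diameter_mm / 2 * 1e-3, NA_real_)
    df$width_m  <- ifelse(has_b, df$breadth_mm * 1e-3, NA_real_)
    df$depth_m  <- ifelse(has_b, df$depth_mm * 1e-3, NA_real_)
    df$length_m <- df$length_cm * 1e-2
  }
  dims <- c(df$radius_m[df$shape == "circular"],
            df$width_m[df$shape == "rectangular"], df$depth_m[df$shape == "rectangular"])
  if (any(!is.finite(dims)) || any(dims <= 0)) stop("non-positive cross-section dimension")
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in metadata")

  df[, c("sample_id", "plant_id", "species", "mound_id", "plant_part",
         "material_type", "shape", "radius_m", "width_m", "depth_m",
         "length_m", "tool_source_species", "preference", "plant_used")]
}

#' Write sample metadata in SI canonical form
#'
#' Writes the canonical SI table produced by [read_metadata()] (or the
#' synthetic generator) so that re-reading reproduces every field exactly.
#'
#' @param meta Canonical metadata `data.frame`.
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  out <- meta
  for (col in c("radius_m", "width_m", "depth_m", "length_m")) {
    v <- sprintf("%.17g", out[[col]])
    v[v == "NA"] <- NA
    out[[col]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Cross-section of one metadata row
#'
#' @param row One row of a canonical metadata `data.frame`.
#' @return A [cross_section()].
#' @export
row_section <- function(row) {
  if (row$shape == "circular") cross_section("circular", radius = row$radius_m)
  else cross_section("rectangular", width = row$width_m, depth = row$depth_m)
}
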