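#' Classify species tool preference from assemblage share
#'
#' Species are ranked by how often they appear in recovered tool
#' assemblages: a share of 11.7% or more of recovered tools makes a species
#' `most_preferred`, 10% or less makes it `less_preferred`, and species
#' never recorded as tool sources are `never_used`. Shares falling in the
#' open gap (0.10, 0.117) are unaddressed by the ranking rule; they are
#' classified `less_preferred` (the conservative choice for the
#' most-preferred set) with a warning.
#'
#' @param share Numeric vector of assemblage shares in `[0, 1]`.
#' @param tool_source Logical vector; `FALSE` forces `never_used`.
#' @return Character vector of preference levels.
#' @export
classify_preference <- function(share, tool_source = rep(TRUE, length(share))) {
  stopifnot(length(share) == length(tool_source))
  if (any(!is.finite(share)) || any(share < 0) || any(share > 1))
    stop("share outside [0, 1]")
  out <- ifelse(!tool_source, "never_used",
         ifelse(share >= 0.117, "most_preferred", "less_preferred"))
  gap <- tool_source & share > 0.10 & share < 0.117
  if (any(gap))
    warning(sum(gap), " share(s) in the unaddressed gap (0.10, 0.117); ",
            "classified as less_preferred")
  out
}

.scheme_defs <- list(
  tool_source = list(
    levels = c("yes", "no"),
    subset_rule = "all QC-passed samples",
    subset = function(m) rep(TRUE, nrow(m)),
    level  = function(m) ifelse(m$tool_source_species, "yes", "no")),
  preference = list(
    levels = c("most_preferred", "less_preferred", "never_used"),
    subset_rule = "all QC-passed samples",
    subset = function(m) rep(TRUE, nrow(m)),
    level  = function(m) m$preference),
  plant_used = list(
    levels = c("used", "not_used"),
    subset_rule = "tool-source species only (non-source species removed)",
    subset = function(m) m$tool_source_species,
    level  = function(m) ifelse(m$plant_used, "used", "not_used")),
  material_type = list(
    levels = c("twig", "vine", "bark", "grass"),
    subset_rule = "tool-source species only",
    subset = function(m) m$tool_source_species,
    level  = function(m) m$material_type)
)

#' Names of the available grouping schemes
#' @return Character vector.
#' @export
scheme_names <- function() names(.scheme_defs)

#' Assign samples to a comparison scheme
#'
#' Builds one of the four grouping schemes used to compare tool materials:
#' `tool_source` (species used as a tool source: yes/no, all samples),
#' `preference` (most/less preferred, never used; all samples),
#' `plant_used` (individual plant shows removal scars: used/not used;
#' tool-source species only) and `material_type` (twig/vine/bark/grass;
#' tool-source species only). Level membership partitions the scheme's
#' subset.
#'
#' @param meta Canonical metadata `data.frame` (QC-filtered upstream).
#' @param scheme_name One of [scheme_names()].
#' @return A list of class `"group_scheme"`: `name`, `levels`, `assignment`
#'   (named character vector `sample_id -> level`), `subset_rule`.
#' @export
assign_scheme <- function(meta, scheme_name = scheme_names()) {
  scheme_name <- match.arg(scheme_name)
  def <- .scheme_defs[[scheme_name]]
  needed <- switch(scheme_name,
                   tool_source = "tool_source_species",
                   preference = "preference",
                   plant_used = c("tool_source_species", "plant_used"),
                   material_type = c("tool_source_species", "material_type"))
  miss <- setdiff(needed, names(meta))
  if (length(miss))
    stop("scheme '", scheme_name, "' needs metadata field(s): ",
         paste(miss, collapse = ", "))
  sub <- meta[def$subset(meta), , drop = FALSE]
  lv <- if (nrow(sub)) def$level(sub) else character(0)
  bad <- setdiff(unique(lv), def$levels)
  if (length(bad)) stop("values outside scheme levels: ", paste(bad, collapse = ", "))
  structure(list(name = scheme_name, levels = def$levels,
                 assignment = stats::setNames(lv, sub$sample_id),
                 subset_rule = def$subset_rule),
            class = "group_scheme")
}

#' Per-level sample counts of a scheme
#' @param scheme A `"group_scheme"`.
#' @return Named integer vector over the scheme's declared levels.
#' @export
scheme_counts <- function(scheme) {
  stopifnot(inherits(scheme, "group_scheme"))
  tab <- table(factor(scheme$assignment, levels = scheme$levels))
  stats::setNames(as.integer(tab), scheme$levels)
}

#' Tidy long export of a scheme assignment
#' @param scheme A `"group_scheme"`.
#' @return `data.frame` with columns `sample_id`, `scheme`, `level`.
#' @export
scheme_table <- function(scheme) {
  stopifnot(inherits(scheme, "group_scheme"))
  data.frame(sample_id = names(scheme$assignment),
             scheme = rep(scheme$name, length(scheme$assignment)),
             level = unname(scheme$assignment),
             stringsAsFactors = FALSE)
}

#' @export
print.group_scheme <- function(x, ...) {
  cnt <- scheme_counts(x)
  cat(sprintf("<group_scheme %s (%s): %s>\n", x$name, x$subset_rule,
              paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", ")))
  invisible(x)
}
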