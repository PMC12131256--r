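#' Pipeline run configuration
#'
#' @param traces Directory of per-sample trace files, or a named list of
#'   [bending_trace()] objects.
#' @param metadata Path to the metadata table, or a canonical metadata
#'   `data.frame`.
#' @param geometry A [bend_geometry()] (required when traces come from
#'   files).
#' @param slope_cfg A [slope_config()].
#' @param qc_gpa QC threshold in GPa (default 35).
#' @param schemes Character vector of schemes to analyze (default all
#'   four).
#' @param out Output directory for the result tables, or `NULL` to skip
#'   writing.
#' @param seed Integer seed recorded in the run log (the analysis itself is
#'   deterministic; the seed matters for synthetic runs).
#' @param verbose Emit stage-tagged progress messages.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(traces, metadata, geometry = NULL,
                       slope_cfg = slope_config(), qc_gpa = 35,
                       schemes = scheme_names(), out = NULL,
                       seed = 1L, verbose = TRUE) {
  stopifnot(qc_gpa > 0, length(schemes) >= 1L)
  schemes <- match.arg(schemes, scheme_names(), several.ok = TRUE)
  structure(list(traces = traces, metadata = metadata, geometry = geometry,
                 slope_cfg = slope_cfg, qc_gpa = qc_gpa, schemes = schemes,
                 out = out, seed = as.integer(seed), verbose = verbose),
            class = "run_config")
}

.log_stage <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, paste0(...)))
}

.write_tab <- function(df, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full measurement-to-inference pipeline
#'
#' Ingest -> mechanics -> QC -> scheme assignment -> per-scheme mixed
#' models (both responses where the data allow), with every stage logged
#' and every dropped sample accounted for. Each requested scheme yields a
#' type-II ANOVA table, Tukey-adjusted EMM contrasts and median-based
#' percent rigidity differences against the scheme's first level.
#'
#' @param cfg A [run_config()].
#' @return A list of class `"pipeline_result"`: `derived`, `qc`
#'   (`retained`/`dropped`), `schemes` (tidy assignment table), `anova`,
#'   `contrasts`, `percent_diff`, `fits` (named list of `"flex_lmm"`),
#'   `log` (character vector of stage messages).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  logline <- character(0)
  note <- function(stage, ...) {
    msg <- sprintf("[%s] %s", stage, paste0(...))
    logline <<- c(logline, msg)
    if (cfg$verbose) message(msg)
  }
  note("config", "seed=", cfg$seed, " qc=", cfg$qc_gpa, " GPa; schemes: ",
       paste(cfg$schemes, collapse = ", "))

  meta <- if (is.data.frame(cfg$metadata)) cfg$metadata else read_metadata(cfg$metadata)
  note("ingest", nrow(meta), " metadata records")

  derived <- tryCatch(
    derive_mechanics(cfg$traces, meta, cfg$slope_cfg, geometry = cfg$geometry,
                     qc_threshold_pa = cfg$qc_gpa * 1e9),
    error = function(e) stop("[mechanics] ", conditionMessage(e), call. = FALSE))
  qc <- qc_filter(derived, threshold_pa = cfg$qc_gpa * 1e9)
  note("qc", nrow(qc$retained), " retained, ", nrow(qc$dropped),
       " dropped (E > ", cfg$qc_gpa, " GPa)")
  stopifnot(nrow(qc$retained) + nrow(qc$dropped) == nrow(derived))
  if (nrow(qc$retained) == 0) stop("[qc] empty analysis set", call. = FALSE)
  meta_kept <- meta[meta$sample_id %in% qc$retained$sample_id, , drop = FALSE]

  scheme_tabs <- list(); anova_tabs <- list(); contrast_tabs <- list()
  pct_tabs <- list(); fits <- list()
  for (sc in cfg$schemes) {
    scheme <- assign_scheme(meta_kept, sc)
    scheme_tabs[[sc]] <- scheme_table(scheme)
    cnt <- scheme_counts(scheme)
    note("groups", sc, ": ", paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "))
    for (resp in c("log_EI", "log_E")) {
      tab <- analysis_table(qc$retained, meta_kept, scheme)
      fit <- tryCatch(fit_group_model(tab, resp), error = function(e) {
        note("stats", sc, "/", resp, " skipped: ", conditionMessage(e))
        NULL
      })
      if (is.null(fit)) next
      key <- paste(sc, resp, sep = ".")
      fits[[key]] <- fit
      if (fit$singular) note("stats", "WARN singular fit for ", key)
      av <- anova_type2(fit)
      av <- cbind(scheme = sc, response = resp, av)
      anova_tabs[[key]] <- av
      ct <- emm_contrasts(fit)
      contrast_tabs[[key]] <- cbind(scheme = sc, response = resp, ct)
      lv <- levels(tab$group)
      raw <- data.frame(group = tab$group,
                        value = if (resp == "log_EI") tab$EI_Nm2 else tab$E_Pa)
      pct <- lapply(lv[-1], function(b) data.frame(
        scheme = sc, response = resp, reference = lv[1], level = b,
        pct_median = percent_rigidity_difference(raw, lv[1], b, "median"),
        pct_emm = percent_rigidity_difference(fit, lv[1], b, "emm")))
      pct_tabs[[key]] <- do.call(rbind, pct)
      note("stats", key, ": F(", av$df1[1], ", ", round(av$df2[1], 2), ") = ",
           round(av$F[1], 2), ", p = ", signif(av$p[1], 3))
    }
  }

  res <- structure(list(
    derived = derived, qc = qc,
    schemes = do.call(rbind, c(scheme_tabs, list(make.row.names = FALSE))),
    anova = do.call(rbind, c(anova_tabs, list(make.row.names = FALSE))),
    contrasts = do.call(rbind, c(contrast_tabs, list(make.row.names = FALSE))),
    percent_diff = do.call(rbind, c(pct_tabs, list(make.row.names = FALSE))),
    fits = fits, log = logline), class = "pipeline_result")

  if (!is.null(cfg$out)) {
    dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
    .write_tab(.format_num(res$derived), cfg$out, "derived.tsv")
    .write_tab(res$schemes, cfg$out, "schemes.tsv")
    .write_tab(.format_num(res$anova), cfg$out, "anova.tsv")
    .write_tab(.format_num(res$contrasts), cfg$out, "contrasts.tsv")
    .write_tab(.format_num(res$percent_diff), cfg$out, "percent_diff.tsv")
    writeLines(c(paste0("flexrig ", as.character(utils::packageVersion("flexrig")),
                        " | R ", getRversion()), res$log),
               file.path(cfg$out, "run_log.txt"))
    note("output", "tables written to ", cfg$out)
  }
  res
}

# fixed-precision text rendering so identical runs give byte-identical files
.format_num <- function(df) {
  for (col in names(df)) if (is.numeric(df[[col]]) && !is.integer(df[[col]]))
    df[[col]] <- sprintf("%.12g", df[[col]])
  df
}

#' Convenience wrapper: simulate a cohort and analyze it in one call
#'
#' @param cfg A [synthetic_config()].
#' @param ... Passed to [run_config()] (e.g. `out`, `schemes`, `qc_gpa`).
#' @return A `"pipeline_result"`.
#' @export
run_synthetic <- function(cfg = synthetic_config(), ...) {
  cohort <- generate_cohort(cfg)
  traces <- simulate_cohort_traces(cohort)
  run_pipeline(run_config(traces = traces, metadata = cohort$meta,
                          seed = cfg$seed, ...))
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort to disk), `analyze`
#' (run the pipeline on a trace directory + metadata table) and `all`
#' (simulate, write, then analyze the written copy). Installed at
#' `system.file("cli", "flexrig.R", package = "flexrig")`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status, invisibly.
#' @export
flexrig_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: flexrig.R <simulate|analyze|all> [options]"
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]
  opts <- list(
    optparse::make_option("--traces", type = "character", default = NULL),
    optparse::make_option("--metadata", type = "character", default = NULL),
    optparse::make_option("--geometry", type = "character", default = "0.1,0.025",
                          help = "L,a in metres [default %default]"),
    optparse::make_option("--qc-gpa", type = "double", default = 35, dest = "qc_gpa"),
    optparse::make_option("--scheme", type = "character", default = "all",
                          help = "comma-separated schemes or 'all'"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character", default = "flexrig_out"),
    optparse::make_option("--quiet", action = "store_true", default = FALSE))
  parsed <- optparse::parse_args(
    optparse::OptionParser(usage = usage, option_list = opts),
    args = args[-1L])
  geom <- as.numeric(strsplit(parsed$geometry, ",")[[1L]])
  geometry <- bend_geometry(geom[1L], geom[2L])
  schemes <- if (parsed$scheme == "all") scheme_names()
             else strsplit(parsed$scheme, ",")[[1L]]
  if (cmd == "simulate" || cmd == "all") {
    cohort <- generate_cohort(synthetic_config(seed = parsed$seed, geometry = geometry))
    write_cohort(cohort, parsed$out)
    if (!parsed$quiet) message("[simulate] cohort written to ", parsed$out)
    if (cmd == "simulate") return(invisible(0L))
    parsed$traces <- file.path(parsed$out, "traces")
    parsed$metadata <- file.path(parsed$out, "metadata.tsv")
  }
  if (!(cmd %in% c("analyze", "all"))) { message(usage); return(invisible(1L)) }
  if (is.null(parsed$traces) || is.null(parsed$metadata))
    stop("analyze needs --traces and --metadata")
  cfg <- run_config(traces = parsed$traces, metadata = parsed$metadata,
                    geometry = geometry, qc_gpa = parsed$qc_gpa,
                    schemes = schemes, out = file.path(parsed$out, "results"),
                    seed = parsed$seed, verbose = !parsed$quiet)
  run_pipeline(cfg)
  invisible(0L)
}
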