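# Umbrella pipeline: dosimetry table + mutation calls + spectrum summary
# + frequency table, written as TSVs and a JSON report.

#' Call mutation events for a table of amplicon pairs
#'
#' Runs [find_event()] row by row; per-row failures (N at the event site,
#' malformed sequences) are caught and reported in an `error` column
#' rather than aborting the batch.
#'
#' @param pairs data.frame with `allele_id`, `wt_seq`, `mut_seq`.
#' @return data.frame with one row per input: `allele_id`, `type` (`BS`/
#'   `Del`/`Ins`/`CR`/`NM`), `size`, `wt_allele`, `mut_allele`,
#'   `canonical_start`, `mh_length`, `ambiguity_span`, `error`.
#' @export
call_pairs <- function(pairs) {
  if (!is.data.frame(pairs) ||
      !all(c("allele_id", "wt_seq", "mut_seq") %in% names(pairs))) {
    ionmut_error("pairs needs allele_id/wt_seq/mut_seq columns",
                 "ionmut_domain_error")
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    out <- data.frame(allele_id = pairs$allele_id[i], type = NA_character_,
                      size = NA_integer_, wt_allele = NA_character_,
                      mut_allele = NA_character_,
                      canonical_start = NA_integer_,
                      mh_length = NA_integer_,
                      ambiguity_span = NA_integer_,
                      error = NA_character_, stringsAsFactors = FALSE)
    cl <- tryCatch(
      find_event(pairs$wt_seq[i], pairs$mut_seq[i], pairs$allele_id[i]),
      ionmut_error = function(e) e)
    if (inherits(cl, "condition")) {
      out$error <- conditionMessage(cl)
      return(out)
    }
    out$type <- switch(cl$event_type, substitution = "BS",
                       deletion = "Del", insertion = "Ins",
                       complex = "CR", none = "NM")
    out$size <- cl$size
    out$wt_allele <- cl$wt_allele
    out$mut_allele <- cl$mut_allele
    out$canonical_start <- cl$canonical_start
    out$mh_length <- cl$mh_length
    out$ambiguity_span <- cl$ambiguity_span
    out
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' @param config a list with any of: `pairs`, `partials`, `catalog`,
#'   `cohorts` (each a path or a data.frame), `threshold` (bp, default
#'   100), `out_dir` (optional; TSV + JSON outputs written there),
#'   `density`, `nucleus_area`, `seed`.
#' @return (invisibly) a list: `conditions` (dosimetry table), `calls`,
#'   `partial_mh`, `spectrum`, `frequencies`, `n_errors`, and `files`
#'   when written.
#' @export
run_pipeline <- function(config = list()) {
  thr <- config$threshold %||% 100
  density <- config$density %||% 1
  area <- config$nucleus_area %||% 100
  load_df <- function(x, reader) {
    if (is.null(x)) NULL else if (is.data.frame(x)) x else reader(x)
  }
  pairs <- load_df(config$pairs, read_pairs)
  partials <- load_df(config$partials, read_partials)
  catalog <- load_df(config$catalog, read_catalog)
  cohorts <- load_df(config$cohorts, read_cohorts)

  out <- list(n_errors = 0L)

  if (!is.null(cohorts)) {
    out$conditions <- condition_table(
      data.frame(let = cohorts$let, dose = cohorts$dose),
      density = density, nucleus_area = area)
    freq <- lapply(seq_len(nrow(cohorts)), function(i) {
      f <- mutation_frequency(cohorts$n_mutants[i], cohorts$n_m2[i])
      data.frame(let = cohorts$let[i], dose = cohorts$dose[i],
                 n_m1 = cohorts$n_m1[i], n_m2 = cohorts$n_m2[i],
                 n_mutants = cohorts$n_mutants[i],
                 frequency_permil = f$frequency_permil,
                 ci_lower_permil = f$ci_lower_permil,
                 ci_upper_permil = f$ci_upper_permil)
    })
    out$frequencies <- do.call(rbind, freq)
  }

  if (!is.null(pairs)) {
    out$calls <- call_pairs(pairs)
    out$n_errors <- out$n_errors + sum(!is.na(out$calls$error))
  }

  if (!is.null(partials)) {
    out$partial_mh <- do.call(rbind, lapply(seq_len(nrow(partials)),
      function(i) {
        p <- partials[i, ]
        r <- tryCatch(
          mh_from_partial(p$left_flank, p$del_prefix, p$del_suffix,
                          p$right_flank, p$declared_size, p$allele_id),
          ionmut_error = function(e) NULL)
        data.frame(allele_id = p$allele_id,
                   mh_length = if (is.null(r)) NA_integer_ else r$mh,
                   determined = if (is.null(r)) FALSE else r$determined,
                   declared_size = p$declared_size,
                   stringsAsFactors = FALSE)
      }))
    out$n_errors <- out$n_errors + sum(!out$partial_mh$determined &
                                         is.na(out$partial_mh$mh_length))
  }

  if (!is.null(catalog)) {
    has_grp <- "let" %in% names(catalog)
    out$spectrum <- summarize_spectrum(catalog,
                                       group_by = if (has_grp) "let"
                                                  else NULL,
                                       threshold = thr)
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c()
    wr <- function(df, name) {
      if (is.null(df)) return()
      p <- file.path(config$out_dir, name)
      write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      files[[name]] <<- p
    }
    wr(out$conditions, "conditions.tsv")
    wr(out$frequencies, "frequencies.tsv")
    wr(out$calls, "calls.tsv")
    wr(out$partial_mh, "partial_mh.tsv")
    wr(out$spectrum, "spectrum.tsv")
    report <- list(
      tool = "ionmut", version = as.character(utils::packageVersion("ionmut")),
      seed = config$seed %||% NA,
      threshold_bp = thr, density = density, nucleus_area_um2 = area,
      n_errors = out$n_errors,
      spectrum = out$spectrum, frequencies = out$frequencies)
    rp <- file.path(config$out_dir, "report.json")
    jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files[["report.json"]] <- rp
    out$files <- unlist(files)
  }
  invisible(out)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
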