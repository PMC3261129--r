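# Readers and writers for the formats the pipeline touches.

#' Read a FASTA file
#'
#' Wraps `Biostrings::readDNAStringSet()`.  Sequences are uppercased on
#' read; the original strings are retained in the `"original"` attribute.
#' Duplicate record ids and empty records are errors.
#'
#' @param path FASTA file path.
#' @return named character vector of uppercased sequences, with attribute
#'   `original` (as read).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    ionmut_error(sprintf("no such file: %s", path), "ionmut_io_error")
  }
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    ionmut_error(sprintf("duplicate FASTA id(s): %s",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")),
                 "ionmut_io_error")
  }
  orig <- as.character(ss)
  if (any(nchar(orig) == 0L)) {
    ionmut_error(sprintf("empty FASTA record(s): %s",
                         paste(ids[nchar(orig) == 0L], collapse = ", ")),
                 "ionmut_io_error")
  }
  out <- setNames(toupper(orig), ids)
  attr(out, "original") <- setNames(orig, ids)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector (names become record ids).
#' @param path output path.
#' @param width line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (length(seqs) && (is.null(names(seqs)) || any(names(seqs) == ""))) {
    ionmut_error("all sequences must be named", "ionmut_io_error")
  }
  if (anyDuplicated(names(seqs))) {
    ionmut_error("duplicate sequence names", "ionmut_io_error")
  }
  ss <- Biostrings::BStringSet(setNames(as.character(seqs), names(seqs)))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Parse a catalogue position string
#'
#' Accepts `"Chr.5: 10,363,437"` (single position) and
#' `"Chr.4: 5,724,273-74"` (range with truncated end).  Thousands
#' separators are stripped; a truncated range end is expanded by
#' digit-prefix substitution (the end token replaces the last `k` digits
#' of the start, where `k` is the number of digits printed), so
#' `5,724,273-74` means 5,724,273-5,724,274 and `5,697,598-730,031`
#' means 5,697,598-5,730,031.
#'
#' @param text position string (single).
#' @return list with `chromosome` (character), `start`, `end` (numeric,
#'   1-based inclusive; `start == end` for single positions).
#' @examples
#' parse_position("Chr.4: 5,724,273-74")
#' @export
parse_position <- function(text) {
  if (is.na(text) || !nzchar(trimws(text))) {
    ionmut_error("empty position string", "ionmut_parse_error")
  }
  m <- regmatches(text, regexec(
    "^\\s*Chr\\.?\\s*([0-9IVXYM]+)\\s*:\\s*([0-9,]+)(?:\\s*[-–]\\s*([0-9,]+))?\\s*$",
    text))[[1L]]
  if (length(m) == 0L) {
    ionmut_error(sprintf("unparsable position: '%s'", text),
                 "ionmut_parse_error")
  }
  chrom <- m[2L]
  start_digits <- gsub(",", "", m[3L], fixed = TRUE)
  start <- as.numeric(start_digits)
  if (is.na(m[4L]) || !nzchar(m[4L])) {
    end <- start
  } else {
    end_digits <- gsub(",", "", m[4L], fixed = TRUE)
    if (nchar(end_digits) < nchar(start_digits)) {
      prefix <- substr(start_digits, 1L,
                       nchar(start_digits) - nchar(end_digits))
      end_digits <- paste0(prefix, end_digits)
    }
    end <- as.numeric(end_digits)
  }
  if (end < start) {
    ionmut_error(sprintf("position range inverted after expansion: '%s'",
                         text), "ionmut_parse_error")
  }
  list(chromosome = chrom, start = start, end = end)
}

#' Read an allele catalogue TSV
#'
#' Expected columns: `let`, `dose`, `allele_id`, `gene`, `type` (codes
#' `BS`, `Del`, `Ins`, `RTL`, `CR`, `NM`), `size` (bp; blank where not
#' applicable), `wt_base`, `mut_base` (for `BS` rows) and `position`
#' (catalogue style, parsed with [parse_position()]).  Rows whose
#' position fails to parse are kept with `NA` coordinates and a warning.
#' Where both a `Del` size and a coordinate span are present, a mismatch
#' between `end - start + 1` and the stated size triggers a warning (not
#' an error) naming the allele.
#'
#' @param path TSV path.
#' @return data.frame with derived `chromosome`, `pos_start`, `pos_end`
#'   columns appended.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) {
    ionmut_error(sprintf("no such file: %s", path), "ionmut_io_error")
  }
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("allele_id", "type")
  if (!all(need %in% names(df))) {
    ionmut_error(sprintf("catalogue must have columns %s",
                         paste(need, collapse = ", ")), "ionmut_io_error")
  }
  if (!is.null(df$size)) {
    df$size <- suppressWarnings(as.numeric(gsub(",", "", df$size)))
  }
  df$chromosome <- NA_character_
  df$pos_start <- NA_real_
  df$pos_end <- NA_real_
  for (i in seq_len(nrow(df))) {
    ptxt <- if (is.null(df$position)) NA else df$position[i]
    if (is.na(ptxt) || !nzchar(trimws(ptxt))) next
    p <- tryCatch(parse_position(ptxt), ionmut_error = function(e) {
      warning(sprintf("row %d (%s): %s; coordinates set to NA", i,
                      df$allele_id[i], conditionMessage(e)))
      NULL
    })
    if (is.null(p)) next
    df$chromosome[i] <- p$chromosome
    df$pos_start[i] <- p$start
    df$pos_end[i] <- p$end
    if (identical(df$type[i], "Del") && !is.na(df$size[i])) {
      span <- p$end - p$start + 1
      if (span != df$size[i]) {
        warning(sprintf(
          "allele %s: coordinate span %g disagrees with stated size %g",
          df$allele_id[i], span, df$size[i]))
      }
    }
  }
  df
}

#' @noRd
read_tsv_checked <- function(path, need, what) {
  if (!file.exists(path)) {
    ionmut_error(sprintf("no such file: %s", path), "ionmut_io_error")
  }
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(need %in% names(df))) {
    ionmut_error(sprintf("%s needs columns: %s", what,
                         paste(need, collapse = ", ")), "ionmut_io_error")
  }
  df
}

#' Read a wild-type/mutant amplicon pair table
#'
#' @param path TSV with columns `allele_id`, `wt_seq`, `mut_seq` (extra
#'   columns are carried through).
#' @return data.frame.
#' @export
read_pairs <- function(path) {
  read_tsv_checked(path, c("allele_id", "wt_seq", "mut_seq"),
                   "pair table")
}

#' Read a partial (ellipsis) junction table
#'
#' @param path TSV with columns `allele_id`, `left_flank`, `del_prefix`,
#'   `del_suffix`, `right_flank`, `declared_size`.
#' @return data.frame.
#' @export
read_partials <- function(path) {
  read_tsv_checked(path, c("allele_id", "left_flank", "del_prefix",
                           "del_suffix", "right_flank", "declared_size"),
                   "partial-junction table")
}

#' Read a screening cohort table
#'
#' @param path TSV with columns `let`, `dose`, `n_m1`, `n_m2`,
#'   `n_mutants`.
#' @return data.frame.
#' @export
read_cohorts <- function(path) {
  df <- read_tsv_checked(path, c("let", "dose", "n_m1", "n_m2",
                                 "n_mutants"), "cohort table")
  for (col in c("n_m1", "n_m2", "n_mutants")) {
    df[[col]] <- as.numeric(gsub(",", "", df[[col]]))
  }
  df
}

#' Path to or content of a packaged example dataset
#'
#' The package ships the published carbon-ion mutagenesis screen of
#' *Arabidopsis thaliana* as plain-text fixtures: the allele catalogue
#' (22 identified mutations plus one unresolved row), the printed
#' wild-type/mutant junction sequence pairs (10 full deletion pairs and
#' 1 insertion pair), the four partially printed (ellipsis) deletion
#' junctions, and the three screening cohorts.
#'
#' @param name one of `"alleles"`, `"pairs"`, `"partials"`, `"cohorts"`.
#' @param as_path return the file path instead of the parsed data.frame.
#' @return data.frame (or path).
#' @examples
#' head(ci_fixture("alleles"))
#' @export
ci_fixture <- function(name = c("alleles", "pairs", "partials", "cohorts"),
                       as_path = FALSE) {
  name <- match.arg(name)
  fn <- c(alleles = "carbon_ion_alleles.tsv",
          pairs = "carbon_ion_junction_pairs.tsv",
          partials = "carbon_ion_partial_junctions.tsv",
          cohorts = "carbon_ion_cohorts.tsv")[[name]]
  path <- system.file("extdata", fn, package = "ionmut", mustWork = TRUE)
  if (as_path) return(path)
  switch(name,
         alleles = read_catalog(path),
         pairs = read_pairs(path),
         partials = read_partials(path),
         cohorts = read_cohorts(path))
}
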