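# Mutation-spectrum classification and screening-frequency statistics.

#' Classify mutations as small alterations or rearrangements
#'
#' Base substitutions and indels shorter than the size threshold are
#' "small alterations"; indels at or above the threshold, reciprocal
#' translocations and complex rearrangements are "rearrangements".  Rows
#' typed `NM` (no mutation identified) are excluded (`NA`).
#'
#' @param type character vector of type codes: `BS` (base substitution),
#'   `Del`, `Ins`, `RTL` (reciprocal translocation), `CR` (complex
#'   rearrangement), `NM`; or a single `mutation_call` object.
#' @param size event size in bp (required for `Del`/`Ins`).
#' @param threshold size (bp) at and above which an indel counts as a
#'   rearrangement (default 100; "small" means strictly less).
#' @return character vector: `"small"`, `"rearrangement"`, or `NA` for
#'   `NM` rows.
#' @examples
#' classify_mutation(c("BS", "Del", "Del", "RTL"), c(NA, 51, 32335, NA))
#' @export
classify_mutation <- function(type, size = NA, threshold = 100) {
  if (inherits(type, "mutation_call")) {
    size <- type$size
    type <- switch(type$event_type,
                   substitution = "BS", deletion = "Del",
                   insertion = "Ins", complex = "CR", none = "NM")
  }
  check_scalar_number(threshold, "threshold", positive = TRUE)
  type <- as.character(type)
  size <- suppressWarnings(as.numeric(size))
  known <- c("BS", "Del", "Ins", "RTL", "CR", "NM")
  if (!all(type %in% known)) {
    ionmut_error(sprintf("unknown type code(s): %s",
                         paste(setdiff(type, known), collapse = ", ")),
                 "ionmut_domain_error")
  }
  indel <- type %in% c("Del", "Ins")
  if (any(indel & is.na(size))) {
    ionmut_error("Del/Ins rows require a size", "ionmut_domain_error")
  }
  out <- rep(NA_character_, length(type))
  out[type == "BS"] <- "small"
  out[indel] <- ifelse(size[indel] < threshold, "small", "rearrangement")
  out[type %in% c("RTL", "CR")] <- "rearrangement"
  out
}

#' Summarise a mutation spectrum by group
#'
#' @param calls a data.frame with columns `type` (codes as in
#'   [classify_mutation()]), `size`, optionally `wt_base`/`mut_base` for
#'   `BS` rows, and the grouping column.
#' @param group_by name of the grouping column (default `"let"`); use
#'   `NULL` for a single overall group.
#' @param threshold small/rearrangement size threshold in bp.
#' @return a data.frame with one row per group: `group`, `n_small`,
#'   `n_rearrangement`, `pct_small`, `pct_rearrangement` (1 decimal,
#'   half-away-from-zero), `n_transition`, `n_transversion`,
#'   `size_threshold`.  Groups with no classified call are omitted with a
#'   warning.
#' @examples
#' df <- data.frame(type = c("BS", "Del", "RTL"), size = c(NA, 5, NA),
#'                  let = 30)
#' summarize_spectrum(df)
#' @export
summarize_spectrum <- function(calls, group_by = "let", threshold = 100) {
  if (!is.data.frame(calls) || !all(c("type") %in% names(calls))) {
    ionmut_error("calls must be a data.frame with a 'type' column",
                 "ionmut_domain_error")
  }
  if (is.null(calls$size)) calls$size <- NA
  grp <- if (is.null(group_by)) rep("all", nrow(calls))
         else as.character(calls[[group_by]])
  cls <- classify_mutation(calls$type, calls$size, threshold)

  res <- lapply(unique(grp), function(g) {
    sel <- grp == g & !is.na(cls)
    n_small <- sum(cls[sel] == "small")
    n_re <- sum(cls[sel] == "rearrangement")
    tot <- n_small + n_re
    if (tot == 0L) {
      warning(sprintf("group '%s' has no classified call; omitted", g))
      return(NULL)
    }
    bs <- sel & calls$type == "BS"
    titv <- if (any(bs) && !is.null(calls$wt_base)) {
      table(factor(classify_substitution(calls$wt_base[bs],
                                         calls$mut_base[bs]),
                   levels = c("transition", "transversion")))
    } else c(transition = 0L, transversion = 0L)
    data.frame(group = g, n_small = n_small, n_rearrangement = n_re,
               pct_small = round_half_away(100 * n_small / tot, 1),
               pct_rearrangement = round_half_away(100 * n_re / tot, 1),
               n_transition = as.integer(titv[["transition"]]),
               n_transversion = as.integer(titv[["transversion"]]),
               size_threshold = threshold, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Screening mutation frequency with exact binomial interval
#'
#' The point estimate is `1000 * n_mutants / n_m2` (per-mil of M2 plants
#' screened), rounded half-away-from-zero to 2 decimals.  The attached
#' 95% Clopper-Pearson interval is an addition to the published
#' arithmetic (which reports the point estimate only) and is returned
#' unrounded.
#'
#' @param n_mutants mutants found (k).
#' @param n_m2 M2 plants screened (n > 0).
#' @param conf_level confidence level (default 0.95).
#' @return a list of class `mutation_frequency`: `n_mutants`, `n_m2`,
#'   `frequency_permil` (rounded to 2 decimals), `frequency_raw`,
#'   `ci_lower_permil`, `ci_upper_permil`, `conf_level`,
#'   `ci_method = "Clopper-Pearson (not from published arithmetic)"`.
#' @examples
#' mutation_frequency(23, 29595)$frequency_permil  # 0.78
#' @export
mutation_frequency <- function(n_mutants, n_m2, conf_level = 0.95) {
  check_scalar_number(n_m2, "n_m2", positive = TRUE)
  check_scalar_number(n_mutants, "n_mutants", nonnegative = TRUE)
  if (n_mutants > n_m2) {
    ionmut_error("n_mutants exceeds n_m2", "ionmut_domain_error")
  }
  ci <- binom.test(n_mutants, n_m2, conf.level = conf_level)$conf.int
  raw <- 1000 * n_mutants / n_m2
  out <- list(n_mutants = n_mutants, n_m2 = n_m2,
              frequency_permil = round_half_away(raw, 2),
              frequency_raw = raw,
              ci_lower_permil = 1000 * ci[1], ci_upper_permil = 1000 * ci[2],
              conf_level = conf_level,
              ci_method = "Clopper-Pearson (not from published arithmetic)")
  class(out) <- "mutation_frequency"
  out
}

#' @export
print.mutation_frequency <- function(x, ...) {
  cat(sprintf(
    "<mutation_frequency> %d / %s M2 plants = %.2f permil [%.3f, %.3f] (%s)\n",
    x$n_mutants, format(x$n_m2, big.mark = ","), x$frequency_permil,
    x$ci_lower_permil, x$ci_upper_permil, x$ci_method))
  invisible(x)
}

#' Ratio of two screening mutation frequencies
#'
#' Fold change of per-mil frequencies between two cohorts, with a
#' conditional exact confidence interval (binomial for `k_a` out of
#' `k_a + k_b` given the cohort-size ratio, interval transformed to the
#' ratio scale) and a two-sided Fisher exact p-value on the 2x2
#' mutant/non-mutant table.  Both inferential additions are labelled as
#' not part of the published arithmetic.
#'
#' @param k_a,n_a mutants and M2 plants in the numerator cohort.
#' @param k_b,n_b mutants and M2 plants in the denominator cohort.
#' @param conf_level confidence level.
#' @return list of class `frequency_ratio`: `ratio`, `ci_lower`,
#'   `ci_upper`, `fisher_p`, plus the inputs.  If `k_b == 0` the ratio is
#'   `Inf`-undefined: `ratio = NA` with a one-sided lower bound in
#'   `ci_lower`.
#' @examples
#' frequency_ratio(23, 29595, 5, 11662)$ratio  # ~ 1.8
#' @export
frequency_ratio <- function(k_a, n_a, k_b, n_b, conf_level = 0.95) {
  for (v in list(c(k_a, n_a), c(k_b, n_b))) {
    if (v[1] > v[2]) ionmut_error("k exceeds n", "ionmut_domain_error")
  }
  check_scalar_number(n_a, "n_a", positive = TRUE)
  check_scalar_number(n_b, "n_b", positive = TRUE)
  fisher_p <- fisher.test(matrix(c(k_a, n_a - k_a, k_b, n_b - k_b),
                                 nrow = 2, byrow = TRUE))$p.value
  N <- k_a + k_b
  theta_to_ratio <- function(theta) (theta / (1 - theta)) * (n_b / n_a)
  if (N > 0) {
    ci_theta <- binom.test(k_a, N, conf.level = conf_level)$conf.int
  } else {
    ci_theta <- c(0, 1)
  }
  out <- list(k_a = k_a, n_a = n_a, k_b = k_b, n_b = n_b,
              conf_level = conf_level, fisher_p = fisher_p,
              ci_method = "conditional exact (not from published arithmetic)")
  if (k_b == 0) {
    out$ratio <- NA_real_
    out$ci_lower <- theta_to_ratio(ci_theta[1])
    out$ci_upper <- Inf
  } else {
    out$ratio <- (1000 * k_a / n_a) / (1000 * k_b / n_b)
    out$ci_lower <- theta_to_ratio(ci_theta[1])
    out$ci_upper <- theta_to_ratio(ci_theta[2])
  }
  class(out) <- "frequency_ratio"
  out
}

#' @export
print.frequency_ratio <- function(x, ...) {
  cat(sprintf(
    "<frequency_ratio> %.3f [%.3f, %.3f], Fisher p = %.3g (%s)\n",
    x$ratio, x$ci_lower, x$ci_upper, x$fisher_p, x$ci_method))
  invisible(x)
}

#' Tidy dose-response table with derived fluence
#'
#' @param points data.frame with columns `let`, `dose` and one or more
#'   response columns (e.g. `survival_pct`, `albino_pct`; values in
#'   [0, 100]).
#' @inheritParams fluence_from_dose
#' @return the input with a derived `fluence` column, sorted by `let`
#'   then `fluence`.
#' @seealso [interpolate_fluence()]
#' @export
dose_response_table <- function(points, density = 1, nucleus_area = 100) {
  if (!is.data.frame(points) || !all(c("let", "dose") %in% names(points))) {
    ionmut_error("points needs columns 'let' and 'dose'",
                 "ionmut_domain_error")
  }
  pct <- intersect(c("survival_pct", "albino_pct"), names(points))
  for (col in pct) {
    if (any(points[[col]] < 0 | points[[col]] > 100, na.rm = TRUE)) {
      ionmut_error(sprintf("%s outside [0, 100]", col),
                   "ionmut_domain_error")
    }
  }
  points$fluence <- fluence_from_dose(points$dose, points$let, density,
                                      nucleus_area)
  points[order(points$let, points$fluence), , drop = FALSE]
}

#' Interpolate the fluence at which a response level is reached
#'
#' Piecewise-linear interpolation between adjacent fluences of one LET
#' series.  Extrapolation outside the observed response range is refused.
#'
#' @param fluence numeric vector of fluences (any order; sorted
#'   internally).
#' @param response responses at those fluences (same length, >= 2).
#' @param level response level to solve for.
#' @return the smallest fluence at which the interpolated response equals
#'   `level`.
#' @examples
#' interpolate_fluence(c(10000, 14000), c(40, 0), 0)   # 14000
#' @export
interpolate_fluence <- function(fluence, response, level) {
  if (length(fluence) < 2L || length(fluence) != length(response)) {
    ionmut_error(">= 2 (fluence, response) points required",
                 "ionmut_domain_error")
  }
  o <- order(fluence)
  x <- fluence[o]; y <- response[o]
  if (level < min(y) || level > max(y)) {
    ionmut_error(sprintf(
      "level %g outside observed response range [%g, %g]; refusing to extrapolate",
      level, min(y), max(y)), "ionmut_extrapolation")
  }
  for (i in seq_len(length(x) - 1L)) {
    y0 <- y[i]; y1 <- y[i + 1L]
    if ((level - y0) * (level - y1) <= 0) {
      if (y0 == y1) return(x[i])
      return(x[i] + (level - y0) / (y1 - y0) * (x[i + 1L] - x[i]))
    }
  }
  # level within global range but not bracketed by any segment: cannot
  # happen for continuous piecewise-linear data; defensive only
  ionmut_error("level not bracketed by any segment", "ionmut_domain_error")
}
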