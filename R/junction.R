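# Junction caller: infer the single mutation event separating a wild-type
# and a mutant amplicon sequence, with left-aligned placement, placement
# ambiguity, and junction microhomology; classify rearrangement junctions.
#
# The caller computes P = longest common prefix and S = longest common
# suffix of the two sequences.  For an indel of size d = |len(wt)-len(mut)|
# the valid 0-based placements form the contiguous interval
# [max(0, n_short - S), min(P, n_short)] where n_short is the shorter
# length, so the number of alternative placements minus one — the
# junction microhomology / placement ambiguity — is P + S - n_short.

#' Call the mutation event separating a wild-type/mutant pair
#'
#' Identifies the single contiguous event (substitution, deletion or
#' insertion) that converts `wt_seq` into `mut_seq`, reports its size, the
#' left-most (canonical) placement, the placement-ambiguity span (equal to
#' the junction microhomology for indels), and the affected alleles.
#' Sequences are uppercased on ingest.
#'
#' @param wt_seq wild-type (reference) amplicon sequence, A/C/G/T/N.
#' @param mut_seq mutant amplicon sequence.
#' @param allele_id optional identifier carried into the call.
#' @param genomic_anchor optional list `list(chrom =, pos =)` giving the
#'   1-based genomic coordinate of the first base of `wt_seq`; when
#'   supplied the call carries 1-based genomic coordinates of the
#'   left-aligned event.
#' @param n_guard window (bp) around the event inside which an `N` base
#'   invalidates the call (at least this many; the realised window is
#'   `max(mh_length, n_guard)`).
#' @return an object of class `mutation_call`: a list with elements
#'   `allele_id`, `event_type` (`none`, `substitution`, `deletion`,
#'   `insertion` or `complex`), `size`, `wt_allele`, `mut_allele`,
#'   `canonical_start` (0-based, half-open, within `wt_seq`),
#'   `ambiguity_span`, `mh_length`, `wt_seq`, `mut_seq`, and (optionally)
#'   `genomic_chrom`, `genomic_start`, `genomic_end` (1-based inclusive).
#'   For `complex` calls a `diagnostic` message is attached and size/
#'   placement fields are `NA`.
#' @details For deletions the deleted segment reported is the one at the
#'   canonical (left-most) placement; `mh_length` counts how many
#'   alternative placements exist beyond it.  Re-applying the event to
#'   `wt_seq` with [apply_event()] reconstructs `mut_seq` exactly.
#' @examples
#' find_event("TGCAGGCTATTCAAAGAGACA", "TGCAGGCTATCAAAGAGACA")
#' @seealso [enumerate_placements()], [apply_event()]
#' @export
find_event <- function(wt_seq, mut_seq, allele_id = NA_character_,
                       genomic_anchor = NULL, n_guard = 5L) {
  wt <- normalize_seq(wt_seq, "wt_seq")
  mut <- normalize_seq(mut_seq, "mut_seq")
  nw <- nchar(wt); nm <- nchar(mut)

  call0 <- list(
    allele_id = allele_id, event_type = "none", size = 0L,
    wt_allele = "", mut_allele = "",
    canonical_start = NA_integer_, ambiguity_span = NA_integer_,
    mh_length = NA_integer_, wt_seq = wt, mut_seq = mut
  )
  class(call0) <- "mutation_call"
  if (identical(wt, mut)) return(call0)

  P <- lcp_len(wt, mut)
  S <- lcs_len(wt, mut)

  if (nw == nm) {
    if (P + S == nw - 1L) {
      call0$event_type <- "substitution"
      call0$size <- 1L
      call0$canonical_start <- P
      call0$ambiguity_span <- 0L
      call0$mh_length <- 0L
      call0$wt_allele <- substr(wt, P + 1L, P + 1L)
      call0$mut_allele <- substr(mut, P + 1L, P + 1L)
    } else {
      return(complex_call(call0, sprintf(
        "equal-length pair with %d mismatching positions (not a single substitution)",
        nw - P - S)))
    }
  } else {
    short <- min(nw, nm)
    if (P + S < short) {
      return(complex_call(call0, "more than one disjoint mismatch block"))
    }
    d <- abs(nw - nm)
    mh <- P + S - short
    start <- max(0L, short - S)      # left-most valid placement
    if (nw > nm) {
      call0$event_type <- "deletion"
      call0$wt_allele <- substr(wt, start + 1L, start + d)
      call0$mut_allele <- ""
    } else {
      call0$event_type <- "insertion"
      call0$wt_allele <- ""
      call0$mut_allele <- substr(mut, start + 1L, start + d)
    }
    call0$size <- d
    call0$canonical_start <- start
    call0$ambiguity_span <- mh
    call0$mh_length <- mh
  }

  guard_n_bases(call0, n_guard)

  if (!is.null(genomic_anchor)) {
    call0 <- add_genomic_coords(call0, genomic_anchor)
  }
  call0
}

#' @noRd
complex_call <- function(call0, diagnostic) {
  call0$event_type <- "complex"
  call0$size <- NA_integer_
  call0$diagnostic <- diagnostic
  call0
}

# An N within max(mh, n_guard) bp of the event invalidates the call.
#' @noRd
guard_n_bases <- function(call, n_guard) {
  w <- max(call$mh_length, n_guard, na.rm = TRUE)
  lo <- max(1L, call$canonical_start + 1L - w)
  check <- function(s, hi_extra) {
    hi <- min(nchar(s), call$canonical_start + hi_extra + w)
    grepl("N", substr(s, lo, hi), fixed = TRUE)
  }
  hit <- switch(call$event_type,
    substitution = check(call$wt_seq, 1L) || check(call$mut_seq, 1L),
    deletion = check(call$wt_seq, call$size) || check(call$mut_seq, 0L),
    insertion = check(call$wt_seq, 0L) || check(call$mut_seq, call$size),
    FALSE)
  if (isTRUE(hit)) {
    ionmut_error(sprintf(
      "allele %s: N base within %d bp of the event site; flagged for manual review",
      call$allele_id, w), "ionmut_n_at_event")
  }
  invisible(NULL)
}

#' @noRd
add_genomic_coords <- function(call, anchor) {
  if (!is.list(anchor) || is.null(anchor$pos)) {
    ionmut_error("genomic_anchor must be list(chrom =, pos =)",
                 "ionmut_domain_error")
  }
  pos0 <- as.numeric(anchor$pos)   # 1-based genomic position of wt_seq[1]
  call$genomic_chrom <- anchor$chrom
  if (call$event_type %in% c("substitution", "deletion")) {
    call$genomic_start <- pos0 + call$canonical_start
    call$genomic_end <- pos0 + call$canonical_start + call$size - 1L
  } else if (call$event_type == "insertion") {
    # coordinate of the wt base immediately 5' of the insertion point
    call$genomic_start <- pos0 + call$canonical_start - 1L
    call$genomic_end <- call$genomic_start
  }
  call
}

#' @export
print.mutation_call <- function(x, ...) {
  cat(sprintf("<mutation_call> %s: %s", x$allele_id, x$event_type))
  if (x$event_type %in% c("substitution", "deletion", "insertion")) {
    cat(sprintf(" size=%d start=%d mh=%d", x$size, x$canonical_start,
                x$mh_length))
    if (x$event_type == "substitution") {
      cat(sprintf(" (%s->%s)", x$wt_allele, x$mut_allele))
    }
    if (!is.null(x$genomic_start)) {
      cat(sprintf(" %s:%s-%s", x$genomic_chrom,
                  format(x$genomic_start, big.mark = ","),
                  format(x$genomic_end, big.mark = ",")))
    }
  }
  if (!is.null(x$diagnostic)) cat(" [", x$diagnostic, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Re-apply a called event to a wild-type sequence
#'
#' @param call a `mutation_call`.
#' @param wt_seq wild-type sequence (defaults to the one in the call).
#' @param start 0-based placement to apply at (defaults to the canonical
#'   start).
#' @return the reconstructed mutant sequence.
#' @export
apply_event <- function(call, wt_seq = call$wt_seq,
                        start = call$canonical_start) {
  wt <- normalize_seq(wt_seq, "wt_seq")
  n <- nchar(wt)
  switch(call$event_type,
    none = wt,
    substitution = paste0(substr(wt, 1L, start), call$mut_allele,
                          substr(wt, start + 2L, n)),
    deletion = paste0(substr(wt, 1L, start),
                      substr(wt, start + call$size + 1L, n)),
    insertion = paste0(substr(wt, 1L, start), call$mut_allele,
                       substr(wt, start + 1L, n)),
    ionmut_error("cannot apply a complex/none call", "ionmut_domain_error"))
}

#' Enumerate all valid placements of an indel call
#'
#' Brute-force oracle: tries every 0-based start position and keeps those
#' at which applying the event to the wild-type sequence reproduces the
#' mutant sequence exactly.  For a consistent call the result is a
#' contiguous ascending run whose first element is the canonical start and
#' whose length is `mh_length + 1`.
#'
#' @param call a `mutation_call` of type deletion or insertion (the
#'   sequences travel inside the call).
#' @return integer vector of 0-based start positions, sorted ascending.
#' @examples
#' cl <- find_event("TGCAGGCTATTCAAAGAGACA", "TGCAGGCTATCAAAGAGACA")
#' enumerate_placements(cl)  # two placements -> mh 1
#' @export
enumerate_placements <- function(call) {
  if (!inherits(call, "mutation_call") ||
      !call$event_type %in% c("deletion", "insertion")) {
    ionmut_error("enumerate_placements needs a deletion or insertion call",
                 "ionmut_domain_error")
  }
  wt <- call$wt_seq; mut <- call$mut_seq
  d <- call$size
  if (call$event_type == "deletion") {
    limit <- nchar(mut)
    hits <- which(vapply(0:limit, function(i) {
      identical(paste0(substr(wt, 1L, i),
                       substr(wt, i + d + 1L, nchar(wt))), mut)
    }, logical(1))) - 1L
  } else {
    limit <- nchar(wt)
    hits <- which(vapply(0:limit, function(i) {
      identical(paste0(substr(wt, 1L, i),
                       substr(mut, i + 1L, i + d),
                       substr(wt, i + 1L, nchar(wt))), mut)
    }, logical(1))) - 1L
  }
  if (length(hits) == 0L) {
    ionmut_error("inconsistent call: no valid placement reproduces mut_seq",
                 "ionmut_domain_error")
  }
  sort(hits)
}

#' Microhomology from a partially printed deletion junction
#'
#' Deletion catalogues often print only the first and last few bases of a
#' long deleted segment (an ellipsis row).  The junction microhomology is
#' still computable as L + R, where L is the number of trailing bases of
#' the deleted segment that match the trailing bases of the retained 5'
#' flank (left shifts of the junction) and R is the number of leading
#' bases of the deleted segment matching the leading bases of the retained
#' 3' flank (right shifts).  Each count is capped at the printed fragment
#' length; if a count reaches its cap without encountering a mismatch the
#' true value is only bounded below and the result is flagged
#' undetermined.
#'
#' @param left_flank retained sequence 5' of the junction.
#' @param del_prefix first printed bases of the deleted segment.
#' @param del_suffix last printed bases of the deleted segment.
#' @param right_flank retained sequence 3' of the junction.
#' @param declared_size full deletion size in bp from the catalogue
#'   (must be >= both printed fragment lengths).
#' @param allele_id optional identifier.
#' @return an object of class `partial_mh`: list with `mh` (integer, or
#'   `NA` if undetermined), `determined` (logical), `at_least` (lower
#'   bound, equals `mh` when determined), `left_shifts`, `right_shifts`.
#' @examples
#' mh_from_partial("AGTGGTCTT", "cttcgc", "ctcctt", "AGAGTT", 51)$mh  # 3
#' @export
mh_from_partial <- function(left_flank, del_prefix, del_suffix, right_flank,
                            declared_size, allele_id = NA_character_) {
  lf <- normalize_seq(left_flank, "left_flank")
  dp <- normalize_seq(del_prefix, "del_prefix")
  ds <- normalize_seq(del_suffix, "del_suffix")
  rf <- normalize_seq(right_flank, "right_flank")
  check_scalar_number(declared_size, "declared_size", positive = TRUE)
  if (declared_size < nchar(dp) || declared_size < nchar(ds)) {
    ionmut_error("declared_size smaller than a printed fragment",
                 "ionmut_domain_error")
  }

  # shifts left: trailing bases of del_suffix vs trailing bases of left_flank
  capL <- min(nchar(ds), nchar(lf))
  L <- 0L
  while (L < capL &&
         substr(ds, nchar(ds) - L, nchar(ds) - L) ==
         substr(lf, nchar(lf) - L, nchar(lf) - L)) {
    L <- L + 1L
  }
  # shifts right: leading bases of del_prefix vs leading bases of right_flank
  capR <- min(nchar(dp), nchar(rf))
  R <- 0L
  while (R < capR &&
         substr(dp, R + 1L, R + 1L) == substr(rf, R + 1L, R + 1L)) {
    R <- R + 1L
  }

  determined <- !(L == capL || R == capR)
  out <- list(allele_id = allele_id,
              mh = if (determined) L + R else NA_integer_,
              determined = determined, at_least = L + R,
              left_shifts = L, right_shifts = R,
              declared_size = declared_size)
  class(out) <- "partial_mh"
  out
}

#' @export
print.partial_mh <- function(x, ...) {
  cat(sprintf("<partial_mh> %s: %s (L=%d, R=%d, size=%s)\n", x$allele_id,
              if (x$determined) x$mh else sprintf("undetermined (>= %d)",
                                                  x$at_least),
              x$left_shifts, x$right_shifts,
              format(x$declared_size, big.mark = ",")))
  invisible(x)
}

#' Classify a base substitution as transition or transversion
#'
#' Transitions exchange bases within a chemical class (purine A/G or
#' pyrimidine C/T); transversions exchange across classes.
#'
#' @param wt_base,mut_base single bases in A/C/G/T (case-insensitive),
#'   vectorised.
#' @return character vector, `"transition"` or `"transversion"`.
#' @examples
#' classify_substitution("G", "A")  # transition
#' classify_substitution("A", "T")  # transversion
#' @export
classify_substitution <- function(wt_base, mut_base) {
  w <- toupper(wt_base); m <- toupper(mut_base)
  ok <- w %in% c("A", "C", "G", "T") & m %in% c("A", "C", "G", "T")
  if (!all(ok)) {
    ionmut_error("bases must be one of A/C/G/T", "ionmut_domain_error")
  }
  if (any(w == m)) {
    ionmut_error("wt_base and mut_base must differ", "ionmut_domain_error")
  }
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  unname(ifelse(purine[w] == purine[m], "transition", "transversion"))
}

#' Classify a rearrangement junction against its two donor sequences
#'
#' Locates the maximal prefix of the joined (junction-spanning) read that
#' occurs in the 5' donor and the maximal suffix occurring in the 3'
#' donor.  If the two matches overlap within the read the joint is a
#' microhomology joint (shared bases present once in the product but
#' matching both donors); if they abut exactly it is blunt; if a gap of
#' unmatched bases remains those bases are filler DNA.
#'
#' @param joined_seq sequence read across the junction.
#' @param donor_left reference segment contributing the 5' side.
#' @param donor_right reference segment contributing the 3' side.
#' @param nominal_breakpoints optional `list(left =, right =)`: 1-based
#'   position in `donor_left` of the last base nominally retained, and in
#'   `donor_right` of the first base nominally retained; used to compute
#'   breakpoint deletion sizes (bases lost from each donor, assuming
#'   maximal retention under the anchor rule).
#' @param min_anchor minimum exact-match anchor length per side
#'   (default 10 bp); shorter maximal matches raise an unresolved-junction
#'   error.
#' @param junction_id optional identifier.
#' @return object of class `rearrangement_junction`: list with
#'   `joint_class` (`"microhomology"`, `"blunt"` or `"filler"`),
#'   `mh_length`, `filler_seq`, `match_left`/`match_right` (matched
#'   lengths), `donor_left_end`/`donor_right_start` (1-based coordinates
#'   of the retained donor segments, left-most occurrence), and
#'   `breakpoint_deletion_left`/`_right` when nominal breakpoints are
#'   given.
#' @examples
#' analyze_rearrangement(
#'   paste0(strrep("ACGTG", 3), "TTT", strrep("CATGA", 3)),
#'   strrep("ACGTG", 4), strrep("CATGA", 4))
#' @export
analyze_rearrangement <- function(joined_seq, donor_left, donor_right,
                                  nominal_breakpoints = NULL,
                                  min_anchor = 10L,
                                  junction_id = NA_character_) {
  jn <- normalize_seq(joined_seq, "joined_seq")
  dl <- normalize_seq(donor_left, "donor_left")
  dr <- normalize_seq(donor_right, "donor_right")
  n <- nchar(jn)

  # maximal k such that the length-k prefix (suffix) of jn is a substring
  # of the donor; occurrence of a prefix is monotone in k -> binary search
  max_prefix <- function(seq, donor) {
    lo <- 0L; hi <- min(nchar(seq), nchar(donor))
    while (lo < hi) {
      mid <- as.integer(ceiling((lo + hi) / 2))
      if (grepl(substr(seq, 1L, mid), donor, fixed = TRUE)) lo <- mid
      else hi <- mid - 1L
    }
    lo
  }
  rev_str <- function(x) paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]),
                               collapse = "")
  A <- max_prefix(jn, dl)
  B <- max_prefix(rev_str(jn), rev_str(dr))

  if (A < min_anchor || B < min_anchor) {
    ionmut_error(sprintf(
      "junction %s: unresolved (anchor %d/%d bp on left/right, need >= %d)",
      junction_id, A, B, min_anchor), "ionmut_unresolved_junction")
  }

  ov <- A + B - n
  if (ov > 0L) {
    joint_class <- "microhomology"; mh <- ov; filler <- ""
  } else if (ov == 0L) {
    joint_class <- "blunt"; mh <- 0L; filler <- ""
  } else {
    joint_class <- "filler"; mh <- 0L
    filler <- substr(jn, A + 1L, n - B)
  }

  # left-most occurrence tie-break for donor coordinates
  posL <- as.integer(regexpr(substr(jn, 1L, A), dl, fixed = TRUE))
  posR <- as.integer(regexpr(substr(jn, n - B + 1L, n), dr, fixed = TRUE))
  out <- list(junction_id = junction_id, joined_seq = jn,
              donor_left = dl, donor_right = dr,
              joint_class = joint_class, mh_length = mh,
              filler_seq = filler, match_left = A, match_right = B,
              donor_left_end = posL + A - 1L, donor_right_start = posR,
              breakpoint_deletion_left = NA_integer_,
              breakpoint_deletion_right = NA_integer_)
  if (!is.null(nominal_breakpoints)) {
    out$breakpoint_deletion_left <-
      as.integer(nominal_breakpoints$left) - out$donor_left_end
    out$breakpoint_deletion_right <-
      out$donor_right_start - as.integer(nominal_breakpoints$right)
  }
  class(out) <- "rearrangement_junction"
  out
}

#' @export
print.rearrangement_junction <- function(x, ...) {
  cat(sprintf("<rearrangement_junction> %s: %s", x$junction_id,
              x$joint_class))
  if (x$joint_class == "microhomology") cat(sprintf(" (mh=%d)", x$mh_length))
  if (x$joint_class == "filler") {
    cat(sprintf(" (filler=%s, %d bp)", x$filler_seq, nchar(x$filler_seq)))
  }
  if (!is.na(x$breakpoint_deletion_left)) {
    cat(sprintf(" bp-del L=%d R=%d", x$breakpoint_deletion_left,
                x$breakpoint_deletion_right))
  }
  cat("\n")
  invisible(x)
}
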