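# Ground-truthed synthetic data: amplicon pairs carrying exactly one
# engineered mutation event, rearrangement junctions, and screening
# cohorts.  Every planted event is re-measured with the package's own
# caller before it is returned, so the recorded truth is the realised
# value, not the requested one.

#' Mixture specification for synthetic mutation spectra
#'
#' Defaults reproduce the empirical spectrum of a carbon-ion screen of 22
#' identified alleles: 4 base substitutions (1 transition : 3
#' transversions), 13 small deletions (1-51 bp), 1 small insertion, 1
#' large deletion and 3 translocation/complex events; simple-deletion
#' junction microhomology 0-3 bp, rearrangement-junction microhomology
#' 2-5 bp, filler insertions 3-16 bp and breakpoint deletions 9-28 bp.
#'
#' @param p_substitution,p_small_del,p_small_ins,p_large_del,p_translocation
#'   class probabilities; must sum to 1.
#' @param titv_ratio expected transitions per transversion.
#' @param small_size_range,large_size_range indel size ranges in bp.
#' @param mh_range junction microhomology range for simple deletions.
#' @param junction_mh_range microhomology range at rearrangement joints.
#' @param filler_range filler-DNA length range in bp.
#' @param breakpoint_del_range breakpoint deletion range in bp.
#' @param p_breakpoint_del probability that a donor side carries a
#'   breakpoint deletion (4 of 5 observed breakpoints did).
#' @param amplicon_range amplicon length range in bp (typical Sanger
#'   amplicons).
#' @param gc genomic GC fraction (default 0.36, *A. thaliana*).
#' @return a list of class `spectrum_spec`.
#' @export
spectrum_spec <- function(p_substitution = 4 / 22, p_small_del = 13 / 22,
                          p_small_ins = 1 / 22, p_large_del = 1 / 22,
                          p_translocation = 3 / 22, titv_ratio = 1 / 3,
                          small_size_range = c(1, 51),
                          large_size_range = c(100, 35000),
                          mh_range = c(0, 3),
                          junction_mh_range = c(2, 5),
                          filler_range = c(3, 16),
                          breakpoint_del_range = c(9, 28),
                          p_breakpoint_del = 0.8,
                          amplicon_range = c(400, 900), gc = 0.36) {
  p <- c(p_substitution, p_small_del, p_small_ins, p_large_del,
         p_translocation)
  if (abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
    ionmut_error("class probabilities must be non-negative and sum to 1",
                 "ionmut_domain_error")
  }
  for (r in list(small_size_range, large_size_range, mh_range,
                 junction_mh_range, filler_range, breakpoint_del_range,
                 amplicon_range)) {
    if (length(r) != 2L || r[1] > r[2]) {
      ionmut_error("ranges must be ordered length-2 vectors",
                   "ionmut_domain_error")
    }
  }
  check_scalar_number(titv_ratio, "titv_ratio", positive = TRUE)
  out <- list(p_substitution = p_substitution, p_small_del = p_small_del,
              p_small_ins = p_small_ins, p_large_del = p_large_del,
              p_translocation = p_translocation, titv_ratio = titv_ratio,
              small_size_range = small_size_range,
              large_size_range = large_size_range, mh_range = mh_range,
              junction_mh_range = junction_mh_range,
              filler_range = filler_range,
              breakpoint_del_range = breakpoint_del_range,
              p_breakpoint_del = p_breakpoint_del,
              amplicon_range = amplicon_range, gc = gc)
  class(out) <- "spectrum_spec"
  out
}

#' Random amplicon sequence
#'
#' @param length sequence length in bp (>= 40).
#' @param gc GC fraction, strictly between 0 and 1.
#' @param seed optional integer; when given, the RNG is seeded so the
#'   sequence is reproducible.
#' @return a single A/C/G/T string.
#' @examples
#' random_amplicon(60, 0.36, seed = 7)
#' @export
random_amplicon <- function(length, gc = 0.36, seed = NULL) {
  check_scalar_number(length, "length", positive = TRUE)
  if (length < 40) {
    ionmut_error("amplicon length must be >= 40 bp", "ionmut_domain_error")
  }
  if (!is.numeric(gc) || gc <= 0 || gc >= 1) {
    ionmut_error("gc must be strictly between 0 and 1",
                 "ionmut_domain_error")
  }
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' @noRd
truth_record <- function(allele_id, event_type, size, planted_start,
                         planted_mh = NA_integer_, planted_filler = "",
                         donors = NULL) {
  list(allele_id = allele_id, event_type = event_type, size = size,
       planted_start = planted_start, planted_mh = planted_mh,
       planted_filler = planted_filler, donors = donors)
}

# verify a planted indel by calling it back; returns realised call or NULL
#' @noRd
verify_pair <- function(wt, mut, type, size, mh = NULL) {
  cl <- tryCatch(find_event(wt, mut), ionmut_error = function(e) NULL)
  if (is.null(cl) || cl$event_type != type || cl$size != size) return(NULL)
  if (!is.null(mh) && cl$mh_length != mh) return(NULL)
  pl <- enumerate_placements(cl)
  if (length(pl) != cl$mh_length + 1L || pl[1L] != cl$canonical_start) {
    return(NULL)
  }
  cl
}

#' Plant a deletion with a requested junction microhomology
#'
#' Engineers a repeat into the supplied sequence so that deleting `size`
#' bases leaves a junction whose placement ambiguity (microhomology) is
#' exactly `mh`, then verifies the construct with the package's own
#' caller and placement enumerator, retrying with fresh random bases on
#' accidental extra homology.
#'
#' @param seq base sequence (A/C/G/T; length >= `size + 2 * (mh + 10)`).
#' @param size deletion size in bp (>= 1).
#' @param mh requested junction microhomology, `0 <= mh <= size` (the
#'   engineered repeat lives inside the deleted segment).
#' @param seed optional RNG seed.
#' @param allele_id identifier for the truth record.
#' @param max_retries attempts before giving up (default 100).
#' @return list with `pair` (list `allele_id`, `wt_seq`, `mut_seq`),
#'   `truth` (realised values, re-measured) and `call` (the verifying
#'   `mutation_call`).
#' @examples
#' x <- plant_deletion(random_amplicon(200, seed = 1), 5, 2, seed = 2)
#' x$truth$planted_mh  # 2
#' @export
plant_deletion <- function(seq, size, mh, seed = NULL,
                           allele_id = "synthetic_del",
                           max_retries = 100L) {
  seq <- normalize_seq(seq)
  check_scalar_number(size, "size", positive = TRUE)
  check_scalar_number(mh, "mh", nonnegative = TRUE)
  if (mh > size) {
    ionmut_error("infeasible request: mh must be <= size for a planted deletion",
                 "ionmut_domain_error")
  }
  L <- nchar(seq)
  need <- size + 2 * (mh + 10)
  if (L < need) {
    ionmut_error(sprintf("sequence too short: need >= %d bp", need),
                 "ionmut_domain_error")
  }
  if (!is.null(seed)) set.seed(seed)

  for (attempt in seq_len(max_retries)) {
    ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
    # random start, event (incl. engineered repeat) >= 10 bp from each end
    lo <- 11L
    hi <- L - size - mh - 10L
    i <- if (hi > lo) sample(lo:hi, 1L) else lo    # 1-based first deleted
    # engineered repeat: the mh bases following the deleted segment copy
    # the first mh bases of the deleted segment
    if (mh > 0) ch[(i + size):(i + size + mh - 1L)] <- ch[i:(i + mh - 1L)]
    # stop bases: block left shift and extra right shift
    not_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    ch[i - 1L] <- not_base(ch[i + size - 1L])
    ch[i + size + mh] <- not_base(ch[i + mh])
    wt <- paste(ch, collapse = "")
    mut <- paste0(substr(wt, 1L, i - 1L), substr(wt, i + size, L))
    cl <- verify_pair(wt, mut, "deletion", size, mh)
    if (!is.null(cl)) {
      pair <- list(allele_id = allele_id, wt_seq = wt, mut_seq = mut)
      return(list(pair = pair,
                  truth = truth_record(allele_id, "deletion", size,
                                       cl$canonical_start, cl$mh_length),
                  call = cl))
    }
    # accidental homology beyond the engineered repeat: re-randomise
    seq <- random_amplicon(L, gc = 0.36)
  }
  ionmut_error(sprintf(
    "could not realise deletion size=%d mh=%d after %d retries",
    size, mh, max_retries), "ionmut_generation_failed")
}

#' Plant a single-base substitution
#'
#' @param seq base sequence.
#' @param titv_choice `"transition"` or `"transversion"`.
#' @param seed optional RNG seed.
#' @param allele_id identifier.
#' @return list with `pair`, `truth` (with `titv` field) and `call`.
#' @export
plant_substitution <- function(seq,
                               titv_choice = c("transition", "transversion"),
                               seed = NULL,
                               allele_id = "synthetic_bs") {
  seq <- normalize_seq(seq)
  titv_choice <- match.arg(titv_choice)
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(seq)
  pos <- sample(11:(L - 10L), 1L)
  wt_base <- substr(seq, pos, pos)
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  mut_base <- if (titv_choice == "transition") {
    transition_of[[wt_base]]
  } else {
    tv <- if (wt_base %in% c("A", "G")) c("C", "T") else c("A", "G")
    sample(tv, 1L)
  }
  mut <- paste0(substr(seq, 1L, pos - 1L), mut_base,
                substr(seq, pos + 1L, L))
  cl <- find_event(seq, mut, allele_id)
  stopifnot(cl$event_type == "substitution",
            classify_substitution(cl$wt_allele, cl$mut_allele) ==
              titv_choice)
  tr <- truth_record(allele_id, "substitution", 1L, cl$canonical_start, 0L)
  tr$titv <- titv_choice
  list(pair = list(allele_id = allele_id, wt_seq = seq, mut_seq = mut),
       truth = tr, call = cl)
}

#' Plant an insertion
#'
#' The inserted bases are random; the realised placement ambiguity is
#' re-measured with the caller's enumerator (insertions next to repeats
#' legitimately have ambiguity, possibly exceeding the event size).
#'
#' @param seq base sequence.
#' @param size insertion size in bp (>= 1).
#' @param seed optional RNG seed.
#' @param allele_id identifier.
#' @return list with `pair`, `truth` and `call`.
#' @export
plant_insertion <- function(seq, size, seed = NULL,
                            allele_id = "synthetic_ins") {
  seq <- normalize_seq(seq)
  check_scalar_number(size, "size", positive = TRUE)
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(seq)
  pos <- sample(10:(L - 10L), 1L)     # bases retained 5' of the insertion
  ins <- paste(sample(c("A", "C", "G", "T"), size, replace = TRUE),
               collapse = "")
  mut <- paste0(substr(seq, 1L, pos), ins, substr(seq, pos + 1L, L))
  cl <- verify_pair(seq, mut, "insertion", size)
  if (is.null(cl)) {
    ionmut_error("insertion verification failed", "ionmut_generation_failed")
  }
  list(pair = list(allele_id = allele_id, wt_seq = seq, mut_seq = mut),
       truth = truth_record(allele_id, "insertion", size,
                            cl$canonical_start, cl$mh_length,
                            planted_filler = ins),
       call = cl)
}

#' Plant a rearrangement (translocation-style) junction
#'
#' Joins the retained 5' prefix of `donor_left` to the retained 3' suffix
#' of `donor_right` with the requested joint class: `"microhomology"`
#' (overlap of `param` bases engineered into the right donor), `"blunt"`,
#' or `"filler"` (`param` random inserted bases matching neither donor).
#' Optional breakpoint deletions trim each donor before joining.  The
#' construct is verified with [analyze_rearrangement()]; on accidental
#' homology the random content is re-drawn (donors are only re-drawn when
#' generated internally).
#'
#' @param donor_left,donor_right donor sequences, or `NULL` to generate
#'   150 bp random donors.
#' @param joint_class `"microhomology"`, `"blunt"` or `"filler"`.
#' @param param microhomology length (joint_class `"microhomology"`,
#'   typically 2-5) or filler length (`"filler"`, typically 3-16);
#'   ignored for `"blunt"`.
#' @param breakpoint_deletions length-2 vector: bp trimmed from the left
#'   donor's retained prefix and the right donor's retained suffix
#'   relative to the nominal breakpoints (observed range 9-28).
#' @param seed optional RNG seed.
#' @param junction_id identifier.
#' @param min_anchor anchor length passed to the verifier.
#' @param max_retries attempts before giving up.
#' @return list with `joined_seq`, `donor_left`, `donor_right`,
#'   `nominal_breakpoints`, `truth` and the verifying `junction`
#'   (`rearrangement_junction`).
#' @export
plant_translocation_junction <- function(donor_left = NULL,
                                         donor_right = NULL,
                                         joint_class = c("microhomology",
                                                         "blunt", "filler"),
                                         param = NULL,
                                         breakpoint_deletions = c(0L, 0L),
                                         seed = NULL,
                                         junction_id = "synthetic_junction",
                                         min_anchor = 10L,
                                         max_retries = 100L) {
  joint_class <- match.arg(joint_class)
  if (!is.null(seed)) set.seed(seed)
  if (joint_class == "microhomology") {
    check_scalar_number(param, "param (mh length)", positive = TRUE)
  }
  if (joint_class == "filler") {
    check_scalar_number(param, "param (filler length)", positive = TRUE)
  }
  bdl <- as.integer(breakpoint_deletions[1L])
  bdr <- as.integer(breakpoint_deletions[2L])
  fixed_donors <- !is.null(donor_left) || !is.null(donor_right)

  for (attempt in seq_len(max_retries)) {
    dl <- if (is.null(donor_left)) random_amplicon(150) else
      normalize_seq(donor_left, "donor_left")
    dr <- if (is.null(donor_right)) random_amplicon(150) else
      normalize_seq(donor_right, "donor_right")
    nominal_left <- nchar(dl) %/% 2L          # last retained base, nominal
    nominal_right <- nchar(dr) %/% 2L + 1L    # first retained base, nominal
    keepL <- nominal_left - bdl
    startR <- nominal_right + bdr
    if (keepL < min_anchor + 5L || nchar(dr) - startR + 1L < min_anchor + 5L) {
      ionmut_error("donors too short for requested breakpoint deletions",
                   "ionmut_domain_error")
    }
    lret <- substr(dl, 1L, keepL)
    filler <- ""
    if (joint_class == "microhomology") {
      m <- as.integer(param)
      # engineer the overlap into the right donor's retained start
      substr(dr, startR, startR + m - 1L) <-
        substr(lret, keepL - m + 1L, keepL)
      joined <- paste0(lret, substr(dr, startR + m, nchar(dr)))
    } else if (joint_class == "filler") {
      filler <- paste(sample(c("A", "C", "G", "T"), as.integer(param),
                             replace = TRUE), collapse = "")
      joined <- paste0(lret, filler, substr(dr, startR, nchar(dr)))
    } else {
      joined <- paste0(lret, substr(dr, startR, nchar(dr)))
    }
    jx <- tryCatch(
      analyze_rearrangement(joined, dl, dr,
                            nominal_breakpoints = list(left = nominal_left,
                                                       right = nominal_right),
                            min_anchor = min_anchor,
                            junction_id = junction_id),
      ionmut_error = function(e) NULL)
    ok <- !is.null(jx) && jx$joint_class == joint_class &&
      jx$breakpoint_deletion_left == bdl &&
      jx$breakpoint_deletion_right == bdr &&
      (joint_class != "microhomology" || jx$mh_length == param) &&
      (joint_class != "filler" || identical(jx$filler_seq, filler))
    if (ok) {
      tr <- truth_record(junction_id, paste0("junction_", joint_class),
                         NA_integer_, NA_integer_,
                         planted_mh = jx$mh_length,
                         planted_filler = filler,
                         donors = list(left = dl, right = dr))
      tr$breakpoint_deletions <- c(left = bdl, right = bdr)
      return(list(joined_seq = joined, donor_left = dl, donor_right = dr,
                  nominal_breakpoints = list(left = nominal_left,
                                             right = nominal_right),
                  truth = tr, junction = jx))
    }
    if (fixed_donors) {
      if (joint_class != "filler" || attempt == max_retries) {
        ionmut_error(
          "supplied donors produce accidental homology at the junction",
          "ionmut_generation_failed")
      }
      # filler content is re-drawn on the next attempt
    }
  }
  ionmut_error(sprintf("could not realise %s junction after %d retries",
                       joint_class, max_retries),
               "ionmut_generation_failed")
}

#' Simulate a screening cohort
#'
#' Mutant counts are binomial: each M2 plant independently shows the
#' scored phenotype with probability `true_freq_permil / 1000`.
#'
#' @param n_m2 number of M2 plants screened (> 0).
#' @param true_freq_permil true mutation frequency in per-mil (0-1000).
#' @param seed optional RNG seed.
#' @param let,dose,n_m1 metadata carried into the cohort row.
#' @return one-row data.frame: `let`, `dose`, `n_m1`, `n_m2`,
#'   `n_mutants`, `frequency_permil` (2-decimal rounded estimate).
#' @examples
#' simulate_cohort(29595, 0.78, seed = 1)
#' @export
simulate_cohort <- function(n_m2, true_freq_permil, seed = NULL,
                            let = NA_real_, dose = NA_real_,
                            n_m1 = NA_integer_) {
  check_scalar_number(n_m2, "n_m2", positive = TRUE)
  if (!is.numeric(true_freq_permil) || true_freq_permil < 0 ||
      true_freq_permil > 1000) {
    ionmut_error("true_freq_permil must be in [0, 1000]",
                 "ionmut_domain_error")
  }
  if (!is.null(seed)) set.seed(seed)
  k <- rbinom(1L, as.integer(n_m2), true_freq_permil / 1000)
  data.frame(let = let, dose = dose, n_m1 = n_m1, n_m2 = as.integer(n_m2),
             n_mutants = k,
             frequency_permil = round_half_away(1000 * k / n_m2, 2))
}

#' Generate a full synthetic dataset with ground truth
#'
#' Draws `n_alleles` mutation events from the mixture in `spec`, builds
#' the corresponding wild-type/mutant amplicon pairs (and, for
#' translocations, junction reads with their donors), and optionally
#' writes FASTA (`<id>|wt` / `<id>|mut` records), a catalog TSV, a
#' junctions TSV and a truth TSV (seed recorded in a `#` header line).
#'
#' @param spec a [spectrum_spec()].
#' @param n_alleles number of events to draw (>= 0).
#' @param seed integer seed for the single RNG stream of the dataset.
#' @param out_dir optional directory; created if needed.  When `NULL`
#'   nothing is written.
#' @return (invisibly) a list with `pairs` (data.frame `allele_id`,
#'   `wt_seq`, `mut_seq`), `junctions` (data.frame, possibly 0 rows),
#'   `truth` (data.frame) and `files` (named paths when written).
#' @export
generate_dataset <- function(spec = spectrum_spec(), n_alleles, seed = 1L,
                             out_dir = NULL) {
  if (!inherits(spec, "spectrum_spec")) {
    ionmut_error("spec must be a spectrum_spec", "ionmut_domain_error")
  }
  check_scalar_number(n_alleles, "n_alleles", nonnegative = TRUE)
  set.seed(seed)
  classes <- c("substitution", "small_del", "small_ins", "large_del",
               "translocation")
  probs <- c(spec$p_substitution, spec$p_small_del, spec$p_small_ins,
             spec$p_large_del, spec$p_translocation)
  drawn <- if (n_alleles > 0) {
    sample(classes, n_alleles, replace = TRUE, prob = probs)
  } else character(0)

  pairs <- list(); junctions <- list(); truth <- list()
  p_ts <- spec$titv_ratio / (1 + spec$titv_ratio)
  rint <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)

  for (i in seq_along(drawn)) {
    id <- sprintf("SYN-%04d", i)
    cls <- drawn[i]
    amp_len <- rint(spec$amplicon_range)
    if (cls == "substitution") {
      x <- plant_substitution(random_amplicon(amp_len, spec$gc),
                              titv_choice = if (runif(1) < p_ts)
                                "transition" else "transversion",
                              allele_id = id)
    } else if (cls == "small_del") {
      size <- rint(spec$small_size_range)
      mh <- rint(c(spec$mh_range[1], min(spec$mh_range[2], size)))
      x <- plant_deletion(random_amplicon(max(amp_len, size + 2 * (mh + 10)),
                                          spec$gc),
                          size, mh, allele_id = id)
    } else if (cls == "small_ins") {
      size <- rint(spec$small_size_range)
      x <- plant_insertion(random_amplicon(amp_len, spec$gc), size,
                           allele_id = id)
    } else if (cls == "large_del") {
      size <- rint(spec$large_size_range)
      mh <- rint(c(spec$mh_range[1], min(spec$mh_range[2], size)))
      x <- plant_deletion(random_amplicon(size + 2 * (mh + 10) + 400,
                                          spec$gc),
                          size, mh, allele_id = id)
    } else {
      jc <- sample(c("microhomology", "filler"), 1L)
      param <- rint(if (jc == "microhomology") spec$junction_mh_range
                    else spec$filler_range)
      bd <- vapply(1:2, function(j) {
        if (runif(1) < spec$p_breakpoint_del)
          rint(spec$breakpoint_del_range) else 0L
      }, integer(1))
      x <- plant_translocation_junction(joint_class = jc, param = param,
                                        breakpoint_deletions = bd,
                                        junction_id = id)
      junctions[[length(junctions) + 1L]] <- data.frame(
        junction_id = id, joined_seq = x$joined_seq,
        donor_left = x$donor_left, donor_right = x$donor_right,
        joint_class = jc, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        allele_id = id, event_type = x$truth$event_type,
        size = NA_integer_, planted_start = NA_integer_,
        planted_mh = x$truth$planted_mh,
        planted_filler = x$truth$planted_filler,
        bp_del_left = x$truth$breakpoint_deletions[["left"]],
        bp_del_right = x$truth$breakpoint_deletions[["right"]],
        stringsAsFactors = FALSE)
      next
    }
    pairs[[length(pairs) + 1L]] <- data.frame(
      allele_id = id, wt_seq = x$pair$wt_seq, mut_seq = x$pair$mut_seq,
      stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      allele_id = id, event_type = x$truth$event_type,
      size = x$truth$size, planted_start = x$truth$planted_start,
      planted_mh = x$truth$planted_mh,
      planted_filler = x$truth$planted_filler,
      bp_del_left = NA_integer_, bp_del_right = NA_integer_,
      stringsAsFactors = FALSE)
  }

  empty_pairs <- data.frame(allele_id = character(0), wt_seq = character(0),
                            mut_seq = character(0))
  empty_junc <- data.frame(junction_id = character(0),
                           joined_seq = character(0),
                           donor_left = character(0),
                           donor_right = character(0),
                           joint_class = character(0))
  empty_truth <- data.frame(allele_id = character(0),
                            event_type = character(0), size = integer(0),
                            planted_start = integer(0),
                            planted_mh = integer(0),
                            planted_filler = character(0),
                            bp_del_left = integer(0),
                            bp_del_right = integer(0))
  out <- list(
    pairs = if (length(pairs)) do.call(rbind, pairs) else empty_pairs,
    junctions = if (length(junctions)) do.call(rbind, junctions)
                else empty_junc,
    truth = if (length(truth)) do.call(rbind, truth) else empty_truth,
    files = NULL, seed = seed
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(out_dir, "pairs.fasta")
    seqs <- character(0)
    if (nrow(out$pairs)) {
      seqs <- setNames(
        as.vector(rbind(out$pairs$wt_seq, out$pairs$mut_seq)),
        as.vector(rbind(paste0(out$pairs$allele_id, "|wt"),
                        paste0(out$pairs$allele_id, "|mut"))))
    }
    write_fasta(seqs, fa)
    cat_tsv <- file.path(out_dir, "catalog.tsv")
    write.table(out$pairs, cat_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    jx_tsv <- file.path(out_dir, "junctions.tsv")
    write.table(out$junctions, jx_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    truth_tsv <- file.path(out_dir, "truth.tsv")
    con <- file(truth_tsv, "w")
    writeLines(sprintf("# ionmut synthetic truth; seed=%d", seed), con)
    write.table(out$truth, con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    close(con)
    out$files <- c(fasta = fa, catalog = cat_tsv, junctions = jx_tsv,
                   truth = truth_tsv)
  }
  invisible(out)
}
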