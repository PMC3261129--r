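# mutation-event calling, placement ambiguity and junction microhomology

test_that("find_event calls the packaged fixture pairs correctly", {
  pairs <- ci_fixture("pairs")
  for (i in seq_len(nrow(pairs))) {
    exp <- fixture_expected[fixture_expected$allele_id ==
                              pairs$allele_id[i], ]
    cl <- find_event(pairs$wt_seq[i], pairs$mut_seq[i], pairs$allele_id[i])
    expect_identical(cl$event_type,
                     c(Del = "deletion", Ins = "insertion")[[exp$type]],
                     info = exp$allele_id)
    expect_identical(cl$size, exp$size, info = exp$allele_id)
    expect_identical(cl$mh_length, exp$mh, info = exp$allele_id)
    # reconstruction invariant, at every enumerated placement
    for (s in enumerate_placements(cl)) {
      expect_identical(apply_event(cl, start = s), cl$mut_seq)
    }
    # oracle equivalence on the fixture
    oracle <- if (cl$event_type == "deletion") {
      oracle_del_placements(cl$wt_seq, cl$mut_seq)
    } else {
      oracle_ins_placements(cl$wt_seq, cl$mut_seq)
    }
    expect_identical(enumerate_placements(cl), oracle)
    expect_identical(cl$mh_length, length(oracle) - 1L)
    expect_identical(cl$canonical_start, oracle[1L])
  }
})

test_that("trivial and degenerate inputs are handled", {
  expect_identical(find_event("ACGTACGT", "ACGTACGT")$event_type, "none")
  expect_identical(find_event("acgt", "ACGT")$event_type, "none")

  cx <- find_event("AACCGGTT", "AGCCGGTA")  # two separated mismatches
  expect_identical(cx$event_type, "complex")
  expect_true(is.na(cx$size))

  cx2 <- find_event("AAACCCGGG", "AAAGGGCCC")  # shuffled blocks
  expect_identical(cx2$event_type, "complex")

  expect_error(find_event("", "ACGT"), class = "ionmut_bad_sequence")
  expect_error(find_event("ACGT", "AXGT"), class = "ionmut_bad_sequence")
})

test_that("substitutions are localised and classified", {
  cl <- find_event("ACGTACGTACGT", "ACGTACTTACGT")
  expect_identical(cl$event_type, "substitution")
  expect_identical(cl$size, 1L)
  expect_identical(cl$canonical_start, 6L)
  expect_identical(cl$wt_allele, "G")
  expect_identical(cl$mut_allele, "T")
  expect_identical(apply_event(cl), cl$mut_seq)

  expect_identical(classify_substitution("G", "A"), "transition")
  expect_identical(classify_substitution("A", "T"), "transversion")
  # all 12 ordered pairs: 4 transitions, 8 transversions
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(w = bases, m = bases, stringsAsFactors = FALSE)
  grid <- grid[grid$w != grid$m, ]
  cls <- classify_substitution(grid$w, grid$m)
  expect_identical(sum(cls == "transition"), 4L)
  expect_identical(sum(cls == "transversion"), 8L)
  expect_error(classify_substitution("A", "A"),
               class = "ionmut_domain_error")
  expect_error(classify_substitution("N", "A"),
               class = "ionmut_domain_error")
})

test_that("N near the event site invalidates the call", {
  # N within 5 bp of the deletion junction
  expect_error(find_event("ACGTACGTNACCGTACGTACGT", "ACGTACGTNACGTACGTACGT"),
               class = "ionmut_n_at_event")
  # N far from the event is tolerated
  cl <- find_event("NACGTACGTACGTACGTACGTAAA", "NACGTACGTACGTACGTACGTAA")
  expect_identical(cl$event_type, "deletion")
})

test_that("placement formula agrees with the brute-force oracle", {
  set.seed(101)
  for (i in 1:200) {
    p <- random_deletion_pair()
    cl <- find_event(p$wt, p$mut)
    expect_identical(cl$event_type, "deletion")
    expect_identical(cl$size, p$size)
    oracle <- oracle_del_placements(p$wt, p$mut)
    expect_identical(cl$mh_length, length(oracle) - 1L)
    expect_identical(cl$canonical_start, oracle[1L])
    expect_identical(enumerate_placements(cl), oracle)
  }
})

test_that("homopolymer deletions have maximal ambiguity", {
  # deleting one unit from a k-unit homopolymer: k placements
  for (k in c(3, 5, 8)) {
    wt <- paste0("CGT", strrep("A", k), "CGT")
    mut <- paste0("CGT", strrep("A", k - 1), "CGT")
    cl <- find_event(wt, mut)
    expect_identical(length(enumerate_placements(cl)), as.integer(k))
    expect_identical(cl$mh_length, as.integer(k - 1))
  }
})

test_that("calls are reverse-complement consistent and idempotent", {
  pairs <- ci_fixture("pairs")
  for (i in seq_len(nrow(pairs))) {
    cl <- find_event(pairs$wt_seq[i], pairs$mut_seq[i])
    rc <- find_event(revcomp(pairs$wt_seq[i]), revcomp(pairs$mut_seq[i]))
    expect_identical(rc$event_type, cl$event_type)
    expect_identical(rc$size, cl$size)
    expect_identical(rc$mh_length, cl$mh_length)
    again <- find_event(cl$wt_seq, cl$mut_seq)
    expect_identical(again$canonical_start, cl$canonical_start)
  }
})

test_that("genomic anchors project to 1-based coordinates", {
  cl <- find_event("TGCAGGCTATTCAAAGAGACA", "TGCAGGCTATCAAAGAGACA",
                   genomic_anchor = list(chrom = "1", pos = 30038612))
  # left-aligned deletion interval; catalogue membership, not identity
  expect_true(cl$genomic_start <= 30038621 &&
                30038621 <= cl$genomic_end + cl$mh_length)
  expect_equal(cl$genomic_end - cl$genomic_start + 1, cl$size)
})

test_that("mh_from_partial applies the shift rule with caps", {
  expect_identical(mh_from_partial("AGTGGTCTT", "cttcgc", "ctcctt",
                                   "AGAGTT", 51)$mh, 3L)
  expect_identical(mh_from_partial("GGTTTGT", "tcctt", "gtctggt",
                                   "GGTGG", 23)$mh, 2L)
  expect_identical(mh_from_partial("AAAACTCA", "caa", "cagttca",
                                   "AGAG", 36)$mh, 3L)
  expect_identical(mh_from_partial("AACTAA", "accgta", "ggtatg",
                                   "GTTCA", 32335)$mh, 0L)
  expect_identical(mh_from_partial("AAAA", "CGGT", "TGCG", "TTTT", 10)$mh,
                   0L)
  # printed fragment exhausted without mismatch -> undetermined (>= k)
  und <- mh_from_partial("ACGTT", "cac", "gtt", "CACGG", 20)
  expect_false(und$determined)
  expect_true(is.na(und$mh))
  expect_gte(und$at_least, 3L)
  expect_error(mh_from_partial("ACG", "ACGT", "ACGT", "ACG", 2),
               class = "ionmut_domain_error")
})

test_that("analyze_rearrangement classifies joints", {
  set.seed(77)
  dl <- random_amplicon(80)
  dr <- random_amplicon(80)
  # stop bases so that anchor matches cannot accidentally extend across
  # the seam: donor continuation bases differ from the joined read's
  other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  substr(dl, 41, 41) <- other(substr(dr, 31, 31))
  substr(dr, 30, 30) <- other(substr(dl, 40, 40))
  lret <- substr(dl, 1, 40)
  rret <- substr(dr, 31, 80)

  blunt <- analyze_rearrangement(paste0(lret, rret), dl, dr,
                                 nominal_breakpoints = list(left = 40,
                                                            right = 31))
  expect_identical(blunt$joint_class, "blunt")
  expect_identical(blunt$mh_length, 0L)
  expect_identical(blunt$filler_seq, "")
  expect_identical(blunt$breakpoint_deletion_left, 0L)
  expect_identical(blunt$breakpoint_deletion_right, 0L)

  # filler whose edge bases cannot extend either donor anchor
  fil <- paste0(other(substr(dl, 41, 41)), "CGTACG",
                other(substr(dr, 30, 30)))
  filler <- analyze_rearrangement(paste0(lret, fil, rret), dl, dr)
  expect_identical(filler$joint_class, "filler")
  expect_identical(filler$filler_seq, fil)

  # engineered 4-bp overlap, with stop bases around it
  dr2 <- dr
  substr(dr2, 31, 34) <- substr(lret, 37, 40)
  substr(dr2, 30, 30) <- other(substr(lret, 36, 36))
  substr(dr2, 35, 35) <- other(substr(dl, 41, 41))
  mh <- analyze_rearrangement(paste0(lret, substr(dr2, 35, 80)), dl, dr2)
  expect_identical(mh$joint_class, "microhomology")
  expect_identical(mh$mh_length, 4L)

  expect_error(analyze_rearrangement("ACGTACGTAAACCCGGGTTT",
                                     random_amplicon(60),
                                     random_amplicon(60)),
               class = "ionmut_unresolved_junction")
})

test_that("anchor split agrees with brute force over all split points", {
  # for every split of the joined read, check whether prefix/suffix occur
  # in the donors; the maximal-anchor rule must match that enumeration
  set.seed(78)
  for (rep in 1:20) {
    dl <- random_amplicon(70)
    dr <- random_amplicon(70)
    lret <- substr(dl, 1, 35)
    rret <- substr(dr, 25, 70)
    jn <- paste0(lret, rret)
    jx <- analyze_rearrangement(jn, dl, dr)
    max_pref <- max(c(0L, Filter(function(k)
      grepl(substr(jn, 1, k), dl, fixed = TRUE), seq_len(nchar(jn)))))
    max_suff <- max(c(0L, Filter(function(k)
      grepl(substr(jn, nchar(jn) - k + 1, nchar(jn)), dr, fixed = TRUE),
      seq_len(nchar(jn)))))
    expect_identical(jx$match_left, as.integer(max_pref))
    expect_identical(jx$match_right, as.integer(max_suff))
    ov <- max_pref + max_suff - nchar(jn)
    expect_identical(jx$joint_class,
                     if (ov > 0) "microhomology" else if (ov == 0) "blunt"
                     else "filler")
  }
})
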