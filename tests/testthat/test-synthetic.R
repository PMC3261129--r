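# ground-truthed generators and their closed loop with the caller

test_that("random_amplicon is reproducible and respects GC", {
  expect_identical(random_amplicon(500, 0.36, seed = 7),
                   random_amplicon(500, 0.36, seed = 7))
  s <- random_amplicon(10000, 0.5, seed = 8)
  gc <- nchar(gsub("[AT]", "", s)) / 10000
  expect_true(gc >= 0.485 && gc <= 0.515)   # binomial 3 sigma
  expect_identical(nchar(random_amplicon(40, seed = 9)), 40L)
  expect_error(random_amplicon(39), class = "ionmut_domain_error")
  expect_error(random_amplicon(100, gc = 0), class = "ionmut_domain_error")
})

test_that("plant_deletion realises the requested microhomology exactly", {
  set.seed(31)
  for (rep in 1:25) {
    size <- sample(1:20, 1)
    mh <- sample(0:min(3, size), 1)
    x <- plant_deletion(random_amplicon(200), size, mh)
    expect_identical(x$truth$size, size)
    expect_identical(x$truth$planted_mh, mh)
    cl <- find_event(x$pair$wt_seq, x$pair$mut_seq)
    expect_identical(cl$event_type, "deletion")
    expect_identical(cl$mh_length, mh)
    expect_identical(enumerate_placements(cl),
                     oracle_del_placements(x$pair$wt_seq, x$pair$mut_seq))
  }
  expect_error(plant_deletion(random_amplicon(200), 1, 2),
               class = "ionmut_domain_error")   # mh > size infeasible
  expect_error(plant_deletion(random_amplicon(40), 30, 3),
               class = "ionmut_domain_error")   # sequence too short
})

test_that("plant_substitution matches the requested class", {
  set.seed(32)
  for (choice in c("transition", "transversion")) {
    for (rep in 1:10) {
      x <- plant_substitution(random_amplicon(150), choice)
      cl <- x$call
      expect_identical(cl$event_type, "substitution")
      expect_identical(classify_substitution(cl$wt_allele, cl$mut_allele),
                       choice)
    }
  }
})

test_that("plant_insertion measures realised ambiguity with the oracle", {
  set.seed(33)
  for (rep in 1:15) {
    size <- sample(1:10, 1)
    x <- plant_insertion(random_amplicon(150), size)
    expect_identical(x$truth$size, size)
    expect_identical(x$truth$planted_mh + 1L,
                     length(oracle_ins_placements(x$pair$wt_seq,
                                                  x$pair$mut_seq)))
  }
  # insertion duplicating an adjacent base is legitimately ambiguous
  wt <- "ACGGGACTAGCATACGGATCGA"
  mut <- paste0(substr(wt, 1, 4), "G", substr(wt, 5, nchar(wt)))
  expect_gte(find_event(wt, mut)$mh_length, 1L)
  expect_error(plant_insertion(random_amplicon(150), 0),
               class = "ionmut_domain_error")
})

test_that("plant_translocation_junction round-trips through the analyser", {
  set.seed(34)
  for (m in c(2, 5)) {
    x <- plant_translocation_junction(joint_class = "microhomology",
                                      param = m,
                                      breakpoint_deletions = c(9, 28))
    expect_identical(x$junction$joint_class, "microhomology")
    expect_identical(x$junction$mh_length, as.integer(m))
    expect_identical(x$junction$breakpoint_deletion_left, 9L)
    expect_identical(x$junction$breakpoint_deletion_right, 28L)
  }
  for (f in c(3, 16)) {
    x <- plant_translocation_junction(joint_class = "filler", param = f)
    expect_identical(x$junction$joint_class, "filler")
    expect_identical(nchar(x$junction$filler_seq), as.integer(f))
    expect_identical(x$junction$filler_seq, x$truth$planted_filler)
  }
  x <- plant_translocation_junction(joint_class = "blunt")
  expect_identical(x$junction$joint_class, "blunt")
  expect_identical(x$junction$mh_length, 0L)
  expect_identical(x$junction$filler_seq, "")
  expect_error(
    plant_translocation_junction(donor_left = random_amplicon(40),
                                 donor_right = random_amplicon(40),
                                 joint_class = "blunt",
                                 breakpoint_deletions = c(15, 15)),
    class = "ionmut_domain_error")
})

test_that("simulate_cohort is binomial with the stated moments", {
  set.seed(35)
  ks <- vapply(1:1000, function(i) {
    simulate_cohort(29595, 0.78)$n_mutants
  }, numeric(1))
  mu <- 29595 * 0.78e-3                      # 23.08
  sigma <- sqrt(29595 * 0.78e-3 * (1 - 0.78e-3))
  expect_lt(abs(mean(ks) - mu), 3 * sigma / sqrt(1000))
  expect_identical(simulate_cohort(500, 0, seed = 2)$n_mutants, 0L)
  expect_error(simulate_cohort(0, 1), class = "ionmut_domain_error")
  expect_error(simulate_cohort(10, 1500), class = "ionmut_domain_error")
})

test_that("generate_dataset: determinism, empty case, mixture recovery", {
  d1 <- generate_dataset(n_alleles = 12, seed = 99, out_dir = tempfile())
  d2 <- generate_dataset(n_alleles = 12, seed = 99, out_dir = tempfile())
  for (f in names(d1$files)) {
    expect_identical(readLines(d1$files[[f]]), readLines(d2$files[[f]]),
                     info = f)
  }
  # files round-trip through the package readers
  fa <- read_fasta(d1$files[["fasta"]])
  expect_identical(length(fa), 2L * nrow(d1$pairs))
  cat_back <- read_pairs(d1$files[["catalog"]])
  expect_identical(cat_back$wt_seq, d1$pairs$wt_seq)

  d0 <- generate_dataset(n_alleles = 0, seed = 1, out_dir = tempfile())
  expect_identical(nrow(d0$pairs), 0L)
  expect_true(all(file.exists(d0$files)))
  expect_identical(nrow(read_pairs(d0$files[["catalog"]])), 0L)

  # class mixture at n = 220 within binomial 3 sigma of the defaults
  set.seed(41)
  spec <- spectrum_spec(large_size_range = c(100, 2000))  # keep test fast
  d <- generate_dataset(spec, n_alleles = 220, seed = 123)
  n <- 220
  counts <- c(
    substitution = sum(d$truth$event_type == "substitution"),
    insertion = sum(d$truth$event_type == "insertion"),
    junction = sum(startsWith(d$truth$event_type, "junction")),
    deletion = sum(d$truth$event_type == "deletion"))
  probs <- c(substitution = 4 / 22, insertion = 1 / 22, junction = 3 / 22,
             deletion = 14 / 22)
  for (cls in names(counts)) {
    mu <- n * probs[[cls]]
    expect_lt(abs(counts[[cls]] - mu),
              3 * sqrt(n * probs[[cls]] * (1 - probs[[cls]])) + 1e-9,
              label = cls)
  }
  # closed loop on the generated pairs
  calls <- call_pairs(d$pairs)
  truth_pairs <- d$truth[!startsWith(d$truth$event_type, "junction"), ]
  expect_identical(calls$size, truth_pairs$size)
  expect_identical(calls$mh_length, truth_pairs$planted_mh)
})
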