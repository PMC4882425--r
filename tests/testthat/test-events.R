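lib <- ctd_repeat_library()

test_that("classify_events applies the length rules for both reporters", {
  # 4stop reporter: reference = 26-unit amplicon; a 4-unit contraction
  ref4 <- 120 + 21 * 26
  wt <- 120 + 21 * 26
  del4 <- classify_events(tibble::tibble(amplicon_bp = ref4 - 84),
                          reference_bp = ref4, wildtype_bp = wt,
                          reporter = "4stop")
  expect_identical(del4$assigned_class, "contraction")
  expect_identical(del4$delta_units, -4L)

  # band at the reference length is "other", whatever the reporter
  same <- classify_events(tibble::tibble(amplicon_bp = ref4),
                          reference_bp = ref4, wildtype_bp = wt,
                          reporter = "4stop")
  expect_identical(same$assigned_class, "other")
  expect_identical(same$delta_units, 0L)

  # CTD8 reporter: a band at the genomic wild-type length is recombination;
  # any other longer band is an expansion
  ref8 <- 120 + 21 * 8
  ctd8 <- classify_events(
    tibble::tibble(amplicon_bp = c(ref8, ref8 + 21 * 18, ref8 + 21 * 5,
                                   ref8 - 21 * 2)),
    reference_bp = ref8, wildtype_bp = wt, reporter = "CTD8")
  expect_identical(ctd8$assigned_class,
                   c("other", "recombination", "expansion", "contraction"))
  expect_identical(ctd8$delta_units, c(0L, 18L, 5L, -2L))

  # the same wild-type-length band from the 4stop reporter is NOT callable as
  # recombination (indistinguishable from the reference by PCR) -- but a
  # 4stop band longer than the 26-unit reference is an expansion
  fs <- classify_events(tibble::tibble(amplicon_bp = ref4 + 21 * 3),
                        reference_bp = ref4, wildtype_bp = wt,
                        reporter = "4stop")
  expect_identical(fs$assigned_class, "expansion")

  # bands within the +/-10 bp tolerance quantize to the same call
  tol <- classify_events(tibble::tibble(amplicon_bp = c(ref8 + 9, ref8 - 10,
                                                        ref8 + 11)),
                         reference_bp = ref8, wildtype_bp = wt,
                         reporter = "CTD8")
  expect_identical(tol$assigned_class, c("other", "other", "expansion"))

  expect_error(classify_events(tibble::tibble(amplicon_bp = 0),
                               reference_bp = ref8, wildtype_bp = wt),
               "input error")
})

test_that("classification recovers the generator's planted classes exactly", {
  # for CTD8, an expansion of exactly +18 units lands at the genomic
  # wild-type length and is genuinely indistinguishable from recombination
  # by amplicon length, so the exact-recovery check excludes that one size
  for (rep_cfg in list(list(reporter = "CTD8",
                            mix = c(expansion = 0.4, contraction = 0.1,
                                    recombination = 0.2, other = 0.3),
                            exp_range = setdiff(1:22, 18L),
                            seed = 101),
                       list(reporter = "4stop",
                            mix = c(expansion = 0.05, contraction = 0.55,
                                    recombination = 0, other = 0.4),
                            exp_range = 1:22,
                            seed = 102))) {
    spec <- simulate_suppressor_spectrum(
      reporter = rep_cfg$reporter, class_mix = rep_cfg$mix,
      n_events = 400, expansion_range = rep_cfg$exp_range,
      seed = rep_cfg$seed)
    got <- classify_events(spec$events, reference_bp = spec$reference_bp,
                           wildtype_bp = spec$wildtype_bp)
    # at 21-bp quantized lengths and tolerance 10, recovery is exact
    expect_identical(got$assigned_class, spec$truth$true_class)
    expect_identical(got$delta_units, spec$truth$true_delta_units)
  }
})

test_that("tally_events reproduces the published suppressor percentages", {
  # expansion/recombination/other counts per strain for both reporters
  counts <- tibble::tribble(
    ~strain,     ~reporter, ~expansion, ~recombination, ~other, ~claimed_total,
    "WT",        "CTD8",    65L,        15L,            89L,    169L,
    "pif1-m2",   "CTD8",    44L,        1L,             33L,    78L,
    "rad52delta","CTD8",    6L,         0L,             115L,   115L,
    "WT",        "4stop",   59L,        1L,             55L,    115L,
    "pif1-m2",   "4stop",   47L,        0L,             35L,    82L,
    "rad52delta","4stop",   51L,        0L,             1L,     52L
  )
  long <- tidyr::pivot_longer(counts, c("expansion", "recombination", "other"),
                              names_to = "assigned_class", values_to = "n")
  events <- tidyr::uncount(long, weights = n)
  events$total <- events$claimed_total

  # one published total (rad52delta/CTD8: 115) disagrees with its own class
  # counts (6 + 0 + 115 = 121); the tally recomputes and warns
  expect_warning(tl <- tally_events(events), "rad52delta/CTD8")

  pct <- function(s, r, cl) {
    tl$percent[tl$strain == s & tl$reporter == r & tl$class == cl]
  }
  expect_identical(pct("WT", "CTD8", "expansion"), 38L)
  expect_identical(pct("pif1-m2", "CTD8", "expansion"), 56L)
  expect_identical(pct("rad52delta", "CTD8", "expansion"), 5L)
  expect_identical(pct("WT", "4stop", "expansion"), 51L)
  expect_identical(pct("pif1-m2", "4stop", "expansion"), 57L)
  expect_identical(pct("rad52delta", "4stop", "expansion"), 98L)

  # counts sum to the recomputed totals
  sums <- dplyr::summarise(dplyr::group_by(tl, .data$strain, .data$reporter),
                           s = sum(count), t = total[1], .groups = "drop")
  expect_true(all(sums$s == sums$t))
})

test_that("tally_events handles trivial and randomized inputs", {
  one <- tally_events(tibble::tibble(assigned_class = "contraction"))
  expect_identical(one$percent, 100L)
  expect_identical(one$count, 1L)

  set.seed(17)
  rnd <- tibble::tibble(
    strain = sample(c("a", "b"), 300, replace = TRUE),
    assigned_class = sample(c("expansion", "contraction", "other"),
                            300, replace = TRUE))
  tl <- tally_events(rnd)
  per_grp <- dplyr::summarise(dplyr::group_by(tl, .data$strain),
                              p = sum(percent), .groups = "drop")
  # integer percents sum to 100 up to rounding (one count per class at most)
  expect_true(all(abs(per_grp$p - 100) <= 2))

  expect_error(tally_events(tibble::tibble(assigned_class = character())))
})

test_that("find_deletion_junction calls the worked microhomology case", {
  # deleting CCCGGG from AAATTT|CCCGGG|TTTAAA: the junction placement is
  # unique (the bases adjacent to the deletion differ on both sides), so
  # microhomology_len = |P| + |S| - len(suppressor) = 0 -- but the retained
  # flanks share the 3-bp TTT homology visible on both sides of the junction,
  # which is reported separately as flank_homology
  j <- find_deletion_junction("AAATTTCCCGGGTTTAAA", "AAATTTTTTAAA")
  expect_identical(j$deleted_bp, 6L)
  expect_identical(j$microhomology_len, 0L)
  expect_identical(j$flank_homology, 3L)
  expect_identical(j$deletion_start, j$placement_min)
  expect_identical(j$placement_max - j$placement_min, j$microhomology_len)
  # leftmost placement, and it reproduces the suppressor
  p <- "AAATTTCCCGGGTTTAAA"
  expect_identical(paste0(substr(p, 1, j$deletion_start),
                          substring(p, j$deletion_end + 1)),
                   "AAATTTTTTAAA")

  # a deletion inside a homopolymer run: here the placement really is
  # ambiguous and the formula counts the equivalent shifts
  j3 <- find_deletion_junction("AATTTTAA", "AATTAA")
  expect_identical(j3$deleted_bp, 2L)
  expect_identical(j3$microhomology_len, 2L)
  expect_identical(j3$placement_max - j3$placement_min, 2L)

  # unambiguous deletion: no microhomology
  j2 <- find_deletion_junction("AACCGGTT", "AAGGTT")
  expect_identical(j2$deleted_bp, 2L)
  expect_identical(j2$microhomology_len, 0L)
  expect_identical(j2$deletion_start, 2L)

  # parent == suppressor and non-deletion pairs are flagged, not called
  expect_identical(find_deletion_junction("ACGT", "ACGT")$flag, "no-deletion")
  expect_identical(find_deletion_junction("ACGT", "ACGTAC")$flag, "no-deletion")
  expect_identical(find_deletion_junction("AAACCCGGGTTT", "AAAGGGCCC")$flag,
                   "multi-segment")
})

test_that("a planted 84-bp deletion with 5-bp microhomology is recovered", {
  # two identical 5-bp blocks ("GATCA") flank an 84-bp segment carrying four
  # stop-codon-bearing units; deleting segment+one copy leaves one copy
  set.seed(41)
  mh <- "GATCA"
  stops <- paste(sub("^TA[TC]", "TAA", lib$known_units[8:11]), collapse = "")
  expect_identical(nchar(stops), 84L)
  left <- random_dna(60, c(A = 0.3, C = 0.2, G = 0.2, T = 0.3))
  right <- random_dna(60, c(A = 0.3, C = 0.2, G = 0.2, T = 0.3))
  parent <- paste0(left, mh, stops, mh, right)
  suppressor <- paste0(left, mh, right)
  j <- find_deletion_junction(parent, suppressor)
  expect_identical(j$deleted_bp, 84L + 5L)
  expect_gte(j$microhomology_len, 5L)
  # the placement range spans both planted-equivalent junctions: deleting
  # mh+stops (start 60) or stops+mh (start 65); at start 65 the deleted
  # segment is exactly the four stop-bearing units plus one homology copy
  expect_lte(j$placement_min, 60L)
  expect_gte(j$placement_max, 65L)
  expect_identical(substr(parent, 66, 66 + 89 - 1), paste0(stops, mh))
})

test_that("junction calls agree with the exhaustive deletion-pair oracle", {
  set.seed(53)
  n_checked <- 0L
  for (rep in 1:60) {
    L <- sample(40:500, 1)
    parent <- random_dna(L, c(A = 0.35, C = 0.15, G = 0.15, T = 0.35))
    D <- sample(1:(L - 10), 1)
    a <- sample(0:(L - D), 1)
    sup <- paste0(substr(parent, 1, a), substring(parent, a + D + 1))
    j <- find_deletion_junction(parent, sup)
    hits <- oracle_deletions(parent, sup)
    expect_gte(length(hits), 1L)
    starts <- vapply(hits, `[`, numeric(1), 1)
    # the full placement range, and nothing else, is reported
    expect_identical(as.integer(j$placement_min), as.integer(min(starts)))
    expect_identical(as.integer(j$placement_max), as.integer(max(starts)))
    expect_identical(as.integer(j$microhomology_len),
                     as.integer(length(hits) - 1L))
    expect_identical(j$deletion_start, j$placement_min)
    n_checked <- n_checked + 1L
  }
  expect_identical(n_checked, 60L)
})

test_that("microhomology is invariant to the equivalent placement chosen", {
  set.seed(67)
  for (rep in 1:20) {
    parent <- random_dna(120, c(A = 0.4, C = 0.1, G = 0.1, T = 0.4))
    D <- sample(3:40, 1)
    a <- sample(0:(120 - D), 1)
    sup <- paste0(substr(parent, 1, a), substring(parent, a + D + 1))
    j <- find_deletion_junction(parent, sup)
    # every placement in the reported range reproduces the suppressor, so
    # recomputing from any placement gives the same microhomology
    for (a2 in j$placement_min:j$placement_max) {
      cand <- paste0(substr(parent, 1, a2), substring(parent, a2 + D + 1))
      expect_identical(cand, sup)
    }
  }
})

test_that("suppressor proteins and viability classes are called correctly", {
  # 4stop parent: stops in units 8-11, 7 functional repeats, not all-consensus
  fourstop <- build_ctd_construct(26, lib, stops_at_units = 8:11)$sequence
  parent <- check_suppressor_protein(fourstop, lib)
  expect_identical(parent$functional_repeats, 7L)
  expect_false(parent$all_consensus)

  # a contraction that removes exactly units 8-11 restores a consensus CTD
  d <- decompose_repeats(fourstop, lib)
  contracted <- paste0(d$left_flank,
                       paste(d$units$sequence[-(8:11)], collapse = ""),
                       d$right_flank)
  sup <- check_suppressor_protein(contracted, lib)
  expect_identical(sup$functional_repeats, 22L)
  expect_true(sup$all_consensus)

  # consensus 26-mer
  full <- check_suppressor_protein(build_ctd_construct(26, lib)$sequence, lib)
  expect_identical(full$functional_repeats, 26L)
  expect_true(full$all_consensus)

  expect_identical(viability_class(c(0L, 7L, 8L, 9L, 10L, 26L)),
                   c("inviable", "inviable", "impaired", "impaired",
                     "normal", "normal"))
  expect_error(viability_class(-1))
})
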