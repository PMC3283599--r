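cons_of <- function(seq, sample_id = "S1", fragment_id = "C1",
                    session = "p1", start = 1, n_clones = 8) {
  a <- amplicon(sample_id, fragment_id, session, rep(seq, n_clones),
                c(start, start + nchar(seq) - 1))
  call_amplicon_consensus(a)
}

test_that("class partition separates divergent groups, not damage noise", {
  set.seed(301)
  base <- rand_seq(150)
  near <- mutate_at(base, sample(150, 1))          # < 1% apart
  far <- mutate_at(base, sample(150, 18))          # 12% apart
  one <- partition_classes(list(cons_of(base), cons_of(near, session = "p2")))
  expect_length(one, 1)
  two <- partition_classes(list(cons_of(base), cons_of(near, session = "p2"),
                                cons_of(far, sample_id = "S2")))
  expect_length(two, 2)
  # ordered by clone count, majority first
  expect_gte(two[[1]]$clone_count, two[[2]]$clone_count)
})

test_that("partition recovers the simulated truth partition", {
  cfg <- sim_config(numt_divergence = 0.12, numt_weight = 0.25, seed = 302)
  lib <- simulate_clone_library(cfg)
  amps <- amplicons_from_library(lib)
  amps <- amps[vapply(amps, function(a) !startsWith(a$fragment_id, "I"), NA)]
  cl <- lib$clones
  for (f in unique(vapply(amps, function(a) a$fragment_id, ""))) {
    sel <- amps[vapply(amps, function(a) a$fragment_id == f, NA)]
    classes <- partition_classes(lapply(sel, call_amplicon_consensus))
    # truth: group member amplicons by their template class
    truth_of <- function(ids) {
      key <- paste(cl$sample_id, cl$fragment_id, cl$pcr_session, sep = "|")
      unique(cl$template_truth[key %in% ids])
    }
    for (cls in classes) {
      tr <- truth_of(cls$member_ids)
      expect_length(tr, 1)       # no class mixes mt and numt templates
    }
    truths <- vapply(classes, function(cls) truth_of(cls$member_ids), "")
    expect_equal(length(classes), length(unique(truths)))
  }
})

test_that("frequency evidence flags minority classes", {
  set.seed(303)
  base <- rand_seq(100)
  far <- mutate_at(base, sample(100, 12))
  classes <- partition_classes(list(
    cons_of(base, n_clones = 30), cons_of(far, session = "p2", n_clones = 6)))
  fe <- frequency_evidence(classes)
  expect_equal(fe$freq_ratio, c(30, 6) / 36, tolerance = 1e-12)
  expect_equal(fe$minority, c(FALSE, TRUE))
  one <- frequency_evidence(partition_classes(list(cons_of(base))))
  expect_equal(one$freq_ratio, 1)
  expect_false(one$minority)
})

test_that("ORF check applies the right genetic code", {
  expect_true(orf_check("ATGAAACCC", 1, "vertebrate_mito")$orf_intact)
  bad <- orf_check("ATGAGACCC", 1, "vertebrate_mito")
  expect_false(bad$orf_intact)          # AGA is a mito stop
  expect_equal(bad$stop_positions, 4)
  expect_true(orf_check("ATGAGACCC", 1, "standard")$orf_intact)
  expect_false(orf_check("ATGTGACCC", 1, "standard")$orf_intact)
  # frames shift the codon grid
  expect_true(orf_check("TTAGCCC", 2, "vertebrate_mito")$orf_intact == FALSE)
  expect_error(orf_check("AT", 1), "codon")
  # ambiguity only counts as stop if every resolution is a stop
  expect_true(orf_check("ATGTRAACC", 1, "standard")$orf_intact == FALSE) # TAA/TGA
  expect_true(orf_check("ATGYAAACC", 1, "standard")$orf_intact)          # CAA ok
})

test_that("third-position composition distance is a bounded metric", {
  # composition at the published reference: distance ~0 (the printed
  # reference sums to 0.99, so exactly 0 is unattainable)
  ref_codons <- c(rep("AAA", 39), rep("AAC", 36), rep("AAG", 3), rep("AAT", 21))
  tc <- thirdpos_composition(paste(ref_codons, collapse = ""))
  expect_lte(tc$distance, 0.01)
  expect_true(tc$typical)
  # distance is exactly 0 iff the composition equals the reference
  exact <- c(rep("AAA", 4), rep("AAC", 3), rep("AAG", 1), rep("AAT", 2))
  tc2 <- thirdpos_composition(paste(exact, collapse = ""),
                              reference = c(A = 0.4, C = 0.3, G = 0.1,
                                            T = 0.2))
  expect_equal(tc2$distance, 0)
  # uniform composition: 0.5*(0.14+0.11+0.22+0.04) = 0.255
  seq_unif <- paste(rep(c("AAA", "AAC", "AAG", "AAT"), 25), collapse = "")
  expect_equal(thirdpos_composition(seq_unif)$distance, 0.255)
  # symmetry and boundedness against arbitrary references
  set.seed(304)
  for (rep in 1:10) {
    f1 <- runif(4); f1 <- f1 / sum(f1); names(f1) <- BASES
    s <- paste(vapply(sample(BASES, 60, TRUE, prob = f1),
                      function(b) paste0("AA", b), ""), collapse = "")
    obs <- thirdpos_composition(s)$composition
    d12 <- thirdpos_composition(s, reference = f1)$distance
    expect_lte(d12, 1)
    expect_gte(d12, 0)
    d_self <- 0.5 * sum(abs(obs - obs))
    expect_equal(d_self, 0)
  }
  expect_true(thirdpos_composition("AAAAAC")$low_power)
})

test_that("codon-rate profile recognises coding-like divergence", {
  set.seed(305)
  s1 <- rand_seq(300)
  expect_equal(codon_rate_profile(c(s1, s1))$rates, c(0, 0, 0))
  expect_equal(codon_rate_profile(c(s1, s1))$ordering, "other")
  # per-position mutation rates 0.02 / 0.005 / 0.1 -> ordering 3>1>2
  x <- strsplit(s1, "")[[1]]
  rates <- rep(c(0.02, 0.005, 0.1), 100)
  hit <- runif(300) < rates
  x[hit] <- vapply(x[hit], function(b) sample(setdiff(BASES, b), 1), "")
  prof <- codon_rate_profile(c(s1, paste(x, collapse = "")))
  expect_equal(prof$ordering, "3>1>2")
  expect_gt(prof$rates[3], prof$rates[1])
  # flat divergence is not miscalled as coding
  y <- mutate_at(s1, sample(300, 30))
  expect_equal(codon_rate_profile(c(s1, y, y))$ordering %in% c("other", "3>1>2"),
               TRUE)
  expect_error(codon_rate_profile("ACG"), "two sequences")
})

test_that("preservation threshold needs consistent, well-supported failures", {
  # the published case: 0 successes in 22 attempts for 123-152 bp fragments
  ch475 <- data.frame(sample_id = "CH475",
                      length_bp = c(123, 151, 152, 167),
                      attempts = c(8, 6, 4, 4),
                      successes = c(0, 0, 0, 0))
  got <- preservation_threshold(ch475)
  expect_equal(got$L_star, 123)
  expect_true(got$consistent)

  # all lengths succeed -> no threshold
  ok <- transform(ch475, successes = c(2, 1, 1, 1))
  expect_true(is.na(preservation_threshold(ok)$L_star))

  # success at a longer length than a failure -> inconsistent, NA
  mixed <- transform(ch475, successes = c(0, 2, 0, 0))
  res <- preservation_threshold(mixed)
  expect_true(is.na(res$L_star))
  expect_false(res$consistent)

  # too few attempts are no evidence of non-preservation
  thin <- transform(ch475, attempts = c(2, 2, 2, 2))
  expect_true(is.na(preservation_threshold(thin)$L_star))
  expect_equal(preservation_threshold(thin, min_attempts = 4)$L_star, 123)

  expect_equal(nrow(preservation_threshold(ch475[0, ])), 0)
})

test_that("anchors classify by identity over the shared span", {
  set.seed(306)
  gene <- rand_seq(300)
  anchor <- cons_of(substr(gene, 1, 150), fragment_id = "CA", start = 1)
  same <- cons_of(substr(gene, 30, 126), fragment_id = "CB", start = 30)
  numt <- cons_of(mutate_at(substr(gene, 30, 126), sample(97, 12)),
                  fragment_id = "CB", session = "p2", start = 30)
  classes <- c(partition_classes(list(anchor)),
               partition_classes(list(same, numt)))
  res <- anchor_assignment(classes, L_star = 123)
  expect_equal(res$length_verdict[1], "anchor_genuine")
  expect_equal(res$anchor_verdict[1], "GENUINE")
  i_same <- which(res$length_bp == 97 & res$anchor_identity > 0.99)
  i_numt <- which(res$length_bp == 97 & res$anchor_identity < 0.9)
  expect_equal(res$anchor_verdict[i_same], "GENUINE")
  expect_equal(res$anchor_verdict[i_numt], "NUMT")

  # L* defined but nothing long enough to anchor: everything ambiguous
  expect_warning(res2 <- anchor_assignment(classes[-1], L_star = 200),
                 "no class qualifies")
  expect_true(all(res2$anchor_verdict == "AMBIGUOUS"))
})

test_that("the decision list is anchored first, frequency+divergence second", {
  base <- list(freq_ratio = 0.2, minority = TRUE, divergence_to_major = 0.12,
               orf_intact = TRUE, thirdpos_distance = 0.05,
               codon_rate_ordering = "3>1>2", length_bp = 150,
               length_verdict = NA, anchor_verdict = NA,
               anchor_identity = NA, n_classes_in_fragment = 2)
  # corroborating evidence looks genuine, but divergence+frequency decide
  expect_equal(classify_class(base)$verdict, "NUMT")
  # anchor verdict dominates the same evidence
  anch <- modifyList(base, list(length_verdict = "anchor_genuine"))
  expect_equal(classify_class(anch)$verdict, "GENUINE")
  over <- modifyList(base, list(anchor_verdict = "GENUINE",
                                anchor_identity = 0.99))
  expect_equal(classify_class(over)$verdict, "GENUINE")
  # a minority class separated at the partition scale is a numt candidate
  weak <- modifyList(base, list(divergence_to_major = 0.04))
  expect_equal(classify_class(weak)$verdict, "NUMT")
  # ... but a majority class at weak divergence stays ambiguous
  maj <- modifyList(weak, list(minority = FALSE, freq_ratio = 0.6))
  expect_equal(classify_class(maj)$verdict, "AMBIGUOUS")
  # single clean class: genuine with the unreplicated caveat
  single <- modifyList(base, list(divergence_to_major = 0.001,
                                  minority = FALSE, freq_ratio = 1,
                                  n_classes_in_fragment = 1,
                                  length_verdict = "n/a"))
  out <- classify_class(single)
  expect_equal(out$verdict, "GENUINE")
  expect_match(out$rationale, "unreplicated-class")
})

test_that("screen verdicts are invariant to amplicon input order", {
  cfg <- sim_config(numt_divergence = 0.12, numt_weight = 0.25, seed = 307)
  lib <- simulate_clone_library(cfg)
  amps <- amplicons_from_library(lib)
  s1 <- numt_screen(amps, nuclear_outcomes = nuclear_outcomes(lib))
  set.seed(1); s2 <- numt_screen(sample(amps),
                                 nuclear_outcomes = nuclear_outcomes(lib))
  o1 <- as.data.frame(s1)[order(s1$class_id), c("class_id", "verdict")]
  o2 <- as.data.frame(s2)[order(s2$class_id), c("class_id", "verdict")]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("screening a library with known numts matches the truth labels", {
  cfg <- sim_config(numt_divergence = 0.12, numt_weight = 0.25, seed = 308)
  lib <- simulate_clone_library(cfg)
  sc <- numt_screen(lib)
  perf <- screen_performance(sc, lib)
  expect_gt(perf$tp, 0)
  expect_equal(perf$fp, 0)
  expect_equal(perf$fn, 0)
})
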