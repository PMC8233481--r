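make_read <- function(scheme, genotype, cleaved, pad = phasing_pads()[["12"]]) {
  paste0(pad, if (!cleaved) scheme$leader else "",
         genotype_to_sequence(scheme, genotype), scheme$primer_site)
}

test_that("classify_read resolves state and genotype from the anchors", {
  sc <- default_scheme()
  anc <- ancestral_genotype(sc)
  r <- classify_read(make_read(sc, anc, cleaved = FALSE), sc)
  expect_identical(r$state, "uncleaved")
  expect_identical(r$genotype, anc)
  r <- classify_read(make_read(sc, anc, cleaved = TRUE), sc)
  expect_identical(r$state, "cleaved")
  expect_identical(r$genotype, anc)
  # read without the primer site cannot be anchored
  r <- classify_read(substr(make_read(sc, anc, TRUE), 1, 70), sc)
  expect_identical(r$state, "unassigned")
  expect_true(is.na(r$genotype))
  expect_identical(r$reason, "no_primer")
})

test_that("classification is insensitive to the phasing pad", {
  sc <- default_scheme()
  set.seed(14)
  g <- sample(enumerate_genotypes(sc), 5)
  for (x in g) for (cl in c(TRUE, FALSE)) {
    res <- lapply(phasing_pads(), function(p)
      classify_read(make_read(sc, x, cl, pad = p), sc))
    states <- vapply(res, `[[`, "", "state")
    genos <- vapply(res, `[[`, "", "genotype")
    expect_length(unique(states), 1L)
    expect_length(unique(genos), 1L)
    expect_identical(unname(genos[1]), x)
  }
})

test_that("anchor mismatch tolerance is enforced and variable-site errors reject", {
  sc <- default_scheme()
  anc <- ancestral_genotype(sc)
  rd <- make_read(sc, anc, cleaved = TRUE)
  # one substitution inside the primer site is tolerated
  p_off <- nchar(rd) - 5L
  rd1 <- rd; substr(rd1, p_off, p_off) <- setdiff(c("A","C","G","U"),
                                                  substr(rd, p_off, p_off))[1]
  expect_identical(classify_read(rd1, sc)$genotype, anc)
  # two substitutions exceed the default tolerance
  rd2 <- rd1
  p_off2 <- nchar(rd) - 8L
  substr(rd2, p_off2, p_off2) <- setdiff(c("A","C","G","U"),
                                         substr(rd, p_off2, p_off2))[1]
  expect_identical(classify_read(rd2, sc)$state, "unassigned")
  expect_identical(classify_read(rd2, sc, max_mismatch = 2)$genotype, anc)
  # an error at a variable position is rejected, not corrected
  rd3 <- make_read(sc, anc, cleaved = TRUE, pad = phasing_pads()[["9"]])
  v1 <- 9L + 1L  # pad + G1 offset
  substr(rd3, v1, v1) <- "C"  # C not allowed at G1
  r <- classify_read(rd3, sc)
  expect_true(is.na(r$genotype))
  expect_identical(r$reason, "offscheme_allele")
})

test_that("count_reads conserves reads and matches a naive scan oracle", {
  sc <- default_scheme()
  expect_equal(nrow(count_reads(data.frame(sequence = character(0),
                                           replicate = integer(0)), sc)), 0L)
  tl <- generate_truth_landscape(sc)
  set.seed(5)
  gset <- sample(tl$genotype, 10)
  rs <- simulate_reads(tl, sc, reads_per_genotype = 50, n_replicates = 2,
                       error_rate = 0, seed = 6, genotypes = gset)
  ct <- count_reads(rs, sc)
  expect_true(all(ct$n_rejected == 0L))
  expect_true(all(attr(ct, "unassigned") == 0L))
  tot <- tapply(ct$n_cleaved + ct$n_uncleaved + ct$n_rejected,
                ct$genotype, sum)
  expect_true(all(tot == 100L))
  expect_equal(sum(ct$n_cleaved + ct$n_uncleaved + ct$n_rejected) +
                 sum(attr(ct, "unassigned")), nrow(rs))
  # independent exact-substring oracle on 1,000 reads
  rs2 <- simulate_reads(tl, sc, reads_per_genotype = 25, n_replicates = 2,
                        error_rate = 0.002, seed = 8, genotypes = gset)
  rs2 <- rs2[seq_len(min(1000L, nrow(rs2))), ]
  ct2 <- count_reads(rs2, sc, max_mismatch = 0)
  orc <- oracle_read_counts(rs2, sc)
  for (i in seq_len(nrow(ct2))) {
    for (st in c("cleaved", "uncleaved")) {
      k <- paste(ct2$genotype[i], ct2$replicate[i], st, sep = "|")
      expected <- if (is.null(orc$tab[[k]])) 0L else orc$tab[[k]]
      got <- if (st == "cleaved") ct2$n_cleaved[i] else ct2$n_uncleaved[i]
      expect_identical(got, expected)
    }
  }
  expect_identical(sum(attr(ct2, "unassigned")) + sum(ct2$n_rejected),
                   orc$unassigned)
})

test_that("fraction_cleaved is the exact count ratio with an NA no-data marker", {
  expect_identical(fraction_cleaved(92, 8), 0.92)
  expect_identical(fraction_cleaved(0, 10), 0)
  expect_true(is.na(fraction_cleaved(0, 0)))
  expect_error(fraction_cleaved(-1, 5), "non-negative")
  set.seed(30)
  for (i in 1:50) {
    n <- sample(1:500, 1); k <- sample(0:n, 1)
    expect_equal(fraction_cleaved(k, n - k), k / n, tolerance = 1e-15)
  }
})

test_that("replicate aggregation averages qualifying replicates and reports correlations", {
  counts <- data.frame(
    genotype = rep(c("AA", "AC", "CC"), each = 2),
    replicate = rep(1:2, 3),
    n_cleaved = c(90, 90, 50, 50, 5, 5),
    n_uncleaved = c(10, 10, 50, 50, 95, 95),
    n_rejected = 0L)
  at <- aggregate_replicates(counts, min_reads = 20)
  expect_equal(at$mean_fraction, c(0.9, 0.5, 0.05))
  rc <- attr(at, "replicate_cor")
  expect_equal(rc[1, 2], 1.0)
  # single replicate: mean equals that replicate's fraction
  at1 <- aggregate_replicates(counts[counts$replicate == 1, ], min_reads = 20)
  expect_equal(at1$mean_fraction, at1$frac_rep1)
  # below-threshold cells are excluded from the mean and flagged
  counts$n_cleaved[counts$genotype == "CC" & counts$replicate == 2] <- 1
  counts$n_uncleaved[counts$genotype == "CC" & counts$replicate == 2] <- 2
  at2 <- aggregate_replicates(counts, min_reads = 20)
  expect_equal(at2$mean_fraction[at2$genotype == "CC"], 0.05)
  counts2 <- counts[counts$genotype == "CC" & counts$replicate == 2, ]
  expect_warning(at3 <- aggregate_replicates(counts2, min_reads = 20),
                 "min_reads")
  expect_false(any(at3$qc_pass))
  expect_true(is.na(at3$mean_fraction))
  # pooled alternative
  atp <- aggregate_replicates(counts[counts$genotype == "AA", ], pooled = TRUE)
  expect_equal(atp$mean_fraction, 180 / 200)
})

test_that("three replicates at realistic depth correlate tightly", {
  sc <- toy_scheme(c(2, 3, 2), seed = 10)
  # spread activities over [0.05, 0.9] via varied penalties
  rules <- default_landscape_rules(p0 = 0.9, p_g1 = 0.05,
                                   penalty_strong = 0.6, penalty_l4 = 0.98,
                                   penalty_mild = 0.8, penalty_wobble = 0.4,
                                   mild_names = sc$positions$name[2],
                                   wobble_name = sc$positions$name[3])
  tl <- generate_truth_landscape(sc, rules)
  rs <- simulate_reads(tl, sc, reads_per_genotype = 1000, n_replicates = 3,
                       error_rate = 0, seed = 17)
  at <- aggregate_replicates(count_reads(rs, sc))
  rc <- attr(at, "replicate_cor")
  expect_true(all(rc[upper.tri(rc)] > 0.95))
})

test_that("the estimator recovers the truth within a simultaneous binomial bound", {
  sc <- toy_scheme(c(2, 3), seed = 12)
  rules <- default_landscape_rules(p0 = 0.85, p_g1 = 0.1, penalty_strong = 0.5,
                                   mild_names = character(0),
                                   wobble_name = character(0))
  tl <- generate_truth_landscape(sc, rules)
  n <- 10000L
  rs <- simulate_reads(tl, sc, reads_per_genotype = n, n_replicates = 1,
                       error_rate = 0, seed = 19)
  at <- aggregate_replicates(count_reads(rs, sc))
  truth <- setNames(tl$p, tl$genotype)[at$genotype]
  bound <- 4 * sqrt(pmax(truth * (1 - truth), 1e-6) / n)
  expect_true(all(abs(at$mean_fraction - truth) <= bound))
})

test_that("the activity table is invariant to read order", {
  sc <- toy_scheme(c(2, 2, 2), seed = 13)
  tl <- toy_landscape(sc)
  rs <- simulate_reads(tl, sc, 30, 2, 0.005, seed = 23)
  at1 <- aggregate_replicates(count_reads(rs, sc), min_reads = 5)
  set.seed(1)
  at2 <- aggregate_replicates(count_reads(rs[sample(nrow(rs)), ], sc),
                              min_reads = 5)
  expect_identical(at1, at2)
})

test_that("counts and activity tables round-trip through TSV", {
  sc <- toy_scheme(c(2, 2), seed = 15)
  tl <- toy_landscape(sc)
  rs <- simulate_reads(tl, sc, 40, 2, 0, seed = 3)
  ct <- count_reads(rs, sc)
  at <- aggregate_replicates(ct, min_reads = 5)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(ct, f1)
  write_activity_tsv(at, f2)
  ct2 <- read_counts_tsv(f1)
  at2 <- read_activity_tsv(f2)
  expect_equal(as.data.frame(ct)[names(ct2)], as.data.frame(ct2),
               ignore_attr = TRUE)
  expect_equal(at$mean_fraction, at2$mean_fraction)
})
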