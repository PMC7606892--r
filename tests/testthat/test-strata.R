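test_that("expression quartiles are rank-based and exclude zeros", {
  set.seed(2)
  vals <- 2 ^ runif(100, 0, 14)
  expr <- tibble::tibble(gene_id = sprintf("g%03d", 1:100), expression = vals)
  cls <- classify_expression(expr)
  expect_equal(sum(cls$expression_class == "HEG"), 25)
  expect_equal(sum(cls$expression_class == "WEG"), 25)

  # invariance under a strictly monotone transform
  cls2 <- classify_expression(dplyr::mutate(expr, expression = expression^3))
  expect_equal(cls2$expression_class, cls$expression_class)

  expr$expression[1] <- 0
  cls3 <- classify_expression(expr)
  expect_equal(cls3$expression_class[1], "unexpressed")

  expect_error(classify_expression(tibble::tibble(gene_id = letters[1:10],
                                                  expression = rep(4, 10))),
               "identical")
  expect_error(classify_expression(tibble::tibble(gene_id = letters[1:5],
                                                  expression = 1:5)),
               "at least 8")
})

test_that("size classes use inclusive printed bounds with gaps unbinned", {
  expect_equal(assign_size_class(28L), "26-30")
  expect_equal(assign_size_class(35L), "unbinned")
  expect_equal(assign_size_class(100L), "94-100")
  expect_equal(assign_size_class(c(26L, 30L, 44L, 45L, 101L)),
               c("26-30", "26-30", "44-45", "44-45", "unbinned"))
})

test_that("two-proportion test reproduces printed contingency P-values", {
  # in-paper incomplete-excision counts: HEG vs WEG, IRS > 0.1 over IRS >= 0
  expect_equal(two_proportion_test(12, 8108, 87, 9504), 2.3e-11, tolerance = 0.05)
  expect_equal(two_proportion_test(4, 5142, 46, 4725), 9.5e-10, tolerance = 0.05)
  expect_equal(two_proportion_test(7, 2765, 38, 4544), 0.0033, tolerance = 0.05)

  # symmetric under group swap; identical groups give p = 1 with correction
  expect_equal(two_proportion_test(12, 8108, 87, 9504),
               two_proportion_test(87, 9504, 12, 8108))
  expect_equal(two_proportion_test(5, 100, 5, 100), 1)
  expect_error(two_proportion_test(0, 0, 1, 10), ">= 1")
})

test_that("one-tailed Fisher matches hypergeometric enumeration", {
  expect_equal(round(fisher_one_tail(7, 2, 25, 35), 3), 0.047)
  expect_equal(round(fisher_one_tail(5, 2, 11, 21), 3), 0.085)
  expect_equal(fisher_one_tail(0, 5, 5, 5), 1)
  expect_error(fisher_one_tail(0, 0, 0, 0), "all-zero")

  # enumeration oracle over a dense grid of small tables
  for (a in 0:4) for (b in 0:4) for (cc in 0:4) for (d in 0:4) {
    if (a + b + cc + d == 0) next
    expect_equal(fisher_one_tail(a, b, cc, d),
                 oracle_fisher_greater(a, b, cc, d), tolerance = 1e-10)
  }
})

test_that("Kendall tau-b matches pair enumeration and flags constants", {
  expect_equal(kendall_tau(1:10, 1:10)$tau, 1)
  expect_equal(kendall_tau(1:10, 10:1)$tau, -1)
  set.seed(14)
  x <- sample(1:8, 50, replace = TRUE)  # ties on purpose
  y <- x + sample(-2:2, 50, replace = TRUE)
  expect_equal(kendall_tau(x, y)$tau, oracle_tau_b(x, y), tolerance = 1e-10)
  expect_error(kendall_tau(rep(1, 5), 1:5), "constant")
})

test_that("rank-sum test is sane and close to the permutation null", {
  set.seed(6)
  a <- rnorm(12); b <- rnorm(12)
  expect_gt(wilcoxon_rank_sum(a, a), 0.99)

  # sampled permutation oracle at moderate separation
  a <- rnorm(10); b <- rnorm(10, 1.1)
  p_pkg <- wilcoxon_rank_sum(a, b, alternative = "less")
  pooled <- c(a, b)
  w_obs <- sum(rank(pooled)[1:10])
  perm <- replicate(40000, {
    idx <- sample(20, 10)
    sum(rank(pooled)[idx])
  })
  p_perm <- mean(perm <= w_obs)
  expect_equal(p_pkg, p_perm, tolerance = 0.10)

  # sidedness contract for a symmetric configuration
  p2 <- wilcoxon_rank_sum(a, b, "two.sided")
  p1 <- wilcoxon_rank_sum(a, b, "less")
  expect_equal(p2, 2 * p1, tolerance = 1e-9)
  expect_error(wilcoxon_rank_sum(numeric(0), b), ">= 3")
})

test_that("size-class count ratios apply the >= 3 per-condition rule", {
  tr <- small_truth(seed = 61)
  loci <- tr$ies_loci
  mk_rec <- function(irs_by_id) {
    tibble::tibble(ies_id = names(irs_by_id), irs = unname(irs_by_id),
                   n_total = 100L)
  }
  ex <- loci$ies_id[loci$location_class == "exon"]
  base <- stats::setNames(rep(0, nrow(loci)), loci$ies_id)
  base[ex[1:12]] <- 0.5

  same <- count_ratio_by_size_class(mk_rec(base), mk_rec(base), loci)
  kept <- same$by_class[same$by_class$kept, ]
  expect_true(all(kept$ratio == 1))
  expect_true(all(same$pooled$ratio == 1))

  # a class with only 2 retained loci in F1 is dropped
  cls <- assign_size_class(loci$length[match(ex, loci$ies_id)])
  pick <- ex[cls == "26-30"]
  f0 <- base; f0[pick] <- 0.5
  f1 <- base; f1[pick] <- 0; f1[pick[1:2]] <- 0.5
  out <- count_ratio_by_size_class(mk_rec(f0), mk_rec(f1), loci)
  expect_false(out$by_class$kept[out$by_class$size_class == "26-30"])
})

test_that("median IRS by size class tracks a planted size gradient", {
  tr <- small_truth(seed = 71)
  loci <- tr$ies_loci
  ex <- loci[loci$location_class == "exon", ]
  # plant IRS increasing with length among exonic loci
  irs <- stats::setNames(rep(0, nrow(loci)), loci$ies_id)
  irs[ex$ies_id] <- pmin(0.95, 0.1 + 0.008 * ex$length)
  rec <- tibble::tibble(ies_id = names(irs), irs = unname(irs), n_total = 100L)
  med <- median_irs_by_size_class(rec, loci, min_per_class = 1L)
  kept <- med[med$kept, ]
  expect_gt(nrow(kept), 2)
  kt <- kendall_tau(kept$midpoint, kept$median_irs)
  expect_gt(kt$tau, 0)

  # single retained record per class -> median is that score
  one <- rec[rec$ies_id == ex$ies_id[1], ]
  m1 <- median_irs_by_size_class(one, loci, min_per_class = 1L)
  expect_equal(m1$median_irs[m1$kept], one$irs)
  expect_equal(median(c(0.2, 0.4)), 0.3)
})

test_that("epi-class enrichment matches the hypergeometric oracle", {
  bg <- tibble::tibble(ies_id = sprintf("i%03d", 1:20),
                       epi_class = rep(c("DCL5", "none"), each = 10))
  ret <- bg$ies_id[c(1:8, 11, 12)]  # 8 of 10 epi loci retained
  res <- epi_enrichment(ret, bg, "DCL5")
  expect_equal(res$observed_fraction, 0.8)
  expect_equal(res$expected_fraction, 0.5)
  expect_equal(res$fisher_p, oracle_fisher_greater(8, 2, 2, 8), tolerance = 1e-12)

  all_res <- epi_enrichment(bg$ies_id, bg, "DCL5")
  expect_equal(all_res$observed_fraction, all_res$expected_fraction)
  expect_error(epi_enrichment(character(), bg, "DCL5"), "empty")
  expect_error(epi_enrichment("nope", bg, "DCL5"), "subset")
})

test_that("PTC folds reproduce the printed ratios exactly", {
  expect_equal(ptc_fold(348, 147)$fold_rounded, 2.4)
  expect_equal(ptc_fold(14, 1)$fold_rounded, 14)
  expect_equal(ptc_fold(80, 41)$fold_rounded, 2.0)
  expect_warning(inf <- ptc_fold(5, 0), "infinite")
  expect_true(inf$infinite)
})

test_that("exclusive overlap is exact set algebra with a breakdown", {
  sets <- list(A = c("a", "b", "c"), B = c("b", "c", "d"), C = c("c", "b"),
               X = c("b"))
  res <- exclusive_overlap(sets, include = c("A", "B", "C"), exclude = "X")
  expect_equal(sort(res$ies_ids), "c")   # b is in the excluded set

  # brute-force set-operations oracle on random sets
  set.seed(15)
  ids <- sprintf("i%02d", 1:40)
  rsets <- list(s1 = sample(ids, 20), s2 = sample(ids, 20), s3 = sample(ids, 20),
                ex = sample(ids, 10))
  got <- exclusive_overlap(rsets, include = c("s1", "s2", "s3"), exclude = "ex")
  want <- ids[ids %in% rsets$s1 & ids %in% rsets$s2 & ids %in% rsets$s3 &
                !(ids %in% rsets$ex)]
  expect_setequal(got$ies_ids, want)

  expect_equal(exclusive_overlap(list(A = "a", B = "b"),
                                 include = c("A", "B"))$ies_ids, character(0))
  expect_error(exclusive_overlap(sets, include = c("A", "A")), "overlap")
  expect_error(exclusive_overlap(sets, include = c("A", "ZZ")), "unknown")
})

test_that("terminal PWM scoring is max-normalised frequency agreement", {
  train <- c("TATATCGATTAGCTAGCTTACGATCGTA",
             "TATATCGAGGCCGGCCGGTACGATCGTA",
             "TATATCGATTTTAAAACCTACGATCGTA",
             "TAGATCGATTAGCTAGCTTACGATCGTA",
             "TATATCGATTAGCTAGCTTACGATCTTA")
  pwm <- build_terminal_pwm(train, w = 8)
  # consensus sequence scores exactly 1
  consensus <- function(mat) paste(rownames(mat)[apply(mat, 2, which.max)],
                                   collapse = "")
  best <- paste0(consensus(pwm$left), strrep("G", 5), consensus(pwm$right))
  expect_equal(cis_signal_score(best, pwm), 1)

  # hand-computed score for the first training sequence:
  # per-position frequency of its own bases over the 5 sequences, / max
  sc <- cis_signal_score(train[1], pwm)
  hand_end <- function(strs, probe) {
    m <- do.call(rbind, strsplit(strs, ""))
    p <- strsplit(probe, "")[[1]]
    mean(vapply(seq_along(p), function(i) {
      f <- table(factor(m[, i], levels = c("A", "C", "G", "T"))) / nrow(m)
      as.numeric(f[p[i]] / max(f))
    }, numeric(1)))
  }
  hand <- (hand_end(substr(train, 1, 8), substr(train[1], 1, 8)) +
             hand_end(substr(train, nchar(train) - 7, nchar(train)),
                      substr(train[1], nchar(train[1]) - 7, nchar(train[1])))) / 2
  expect_equal(sc, hand, tolerance = 1e-12)

  # degenerate uniform profile scores 1 for any sequence
  pwm_u <- pwm
  pwm_u$left[] <- 0.25; pwm_u$right[] <- 0.25
  expect_equal(cis_signal_score("TAGGCCGGCCGGCCGGTA", pwm_u), 1)

  expect_error(cis_signal_score("TACGTA", pwm), "2w")
  expect_error(build_terminal_pwm("TACGTA", w = 8), "2w")
})

test_that("stratum labels join host expression and size information", {
  tr <- small_truth(seed = 81)
  lab <- label_strata(tr$ies_loci, tr$expression)
  expect_equal(nrow(lab), nrow(tr$ies_loci))
  expect_true(all(is.na(lab$expression_class[lab$location_class != "exon"])))
  expect_true(all(lab$small_or_large %in% c("small", "large")))
  idx <- lab$size_class != "unbinned"
  lo <- as.integer(sub("-.*", "", lab$size_class[idx]))
  hi <- as.integer(sub(".*-", "", lab$size_class[idx]))
  len <- tr$ies_loci$length[idx]
  expect_true(all(len >= lo & len <= hi))
})

test_that("a planted small-IES count effect is recovered at the truth-derived ratio", {
  # plant a 4x retention increase on small exonic IESs and compare the
  # measured pooled count ratio against the ratio implied by the generative
  # truth itself (threshold crossings of the true retention probabilities)
  eff <- list(list(condition = "F1_32C", size = "small", location = "exon",
                   multiplier = 4))
  cfg <- sim_config(n_genes = 150L, n_ies = 1000L,
                    conditions = c("F0_25C", "F1_32C"),
                    baseline_zero_fraction = 0.3, effects = eff)
  tr <- suppressWarnings(simulate_truth(cfg, seed = 55))
  loci <- tr$ies_loci
  p_of <- function(cond) {
    tr$true_retention$p[tr$true_retention$condition == cond][
      match(loci$ies_id, tr$true_retention$ies_id[
        tr$true_retention$condition == cond])]
  }
  perfect <- function(cond) {
    tibble::tibble(ies_id = loci$ies_id, irs = p_of(cond), n_total = 10000L)
  }
  oracle <- count_ratio_by_size_class(perfect("F0_25C"), perfect("F1_32C"), loci)
  oracle_small <- oracle$pooled$ratio[oracle$pooled$small_or_large == "small"]

  measured <- count_ratio_by_size_class(
    compute_irs(simulate_counts(tr, "F0_25C", 2000, seed = 55)),
    compute_irs(simulate_counts(tr, "F1_32C", 2000, seed = 55)), loci)
  meas_small <- measured$pooled$ratio[measured$pooled$small_or_large == "small"]
  expect_gt(meas_small, 1)
  expect_equal(meas_small, oracle_small, tolerance = 0.35)
})
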