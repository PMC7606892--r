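# Stratification (expression quartiles, size classes, location, epi-class)
# and the contingency/correlation statistics computed over those strata.

#' Classify genes by expression quartile
#'
#' HEG (highly expressed genes) are the top quartile and WEG (weakly
#' expressed genes) the bottom quartile of the log2-transformed expression
#' distribution over genes with positive expression. Quartile boundaries use
#' linear-interpolation quantiles; values tied exactly with a boundary are
#' resolved to `mid`. Zero-expression genes are labelled `unexpressed` and
#' never enter the quartile computation.
#'
#' @param expr_table Tibble with `gene_id` and `expression` (from
#'   [read_expression()] or [simulate_truth()]).
#' @return A tibble `gene_id`, `expression_class` in
#'   \{HEG, WEG, mid, unexpressed\}.
#' @export
classify_expression <- function(expr_table) {
  pos <- expr_table$expression > 0
  if (sum(pos) < 8) abort("need at least 8 genes with positive expression")
  lv <- log2(expr_table$expression[pos])
  if (diff(range(lv)) == 0) abort("quartiles undefined: all expression values identical")
  q <- quantile(lv, c(0.25, 0.75), type = 7, names = FALSE)
  cls <- rep("mid", length(lv))
  cls[lv < q[1]] <- "WEG"
  cls[lv > q[2]] <- "HEG"
  out <- rep("unexpressed", nrow(expr_table))
  out[pos] <- cls
  tibble(gene_id = expr_table$gene_id, expression_class = out)
}

#' Assign an IES length to its printed size class
#'
#' The most frequent IES size classes (bp) are 26-30, 44-45, 46-50, 54-60,
#' 64-70, 74-80, 84-90 and 94-100, with inclusive bounds. Lengths between
#' classes map to `"unbinned"`.
#'
#' @param length Integer vector of IES lengths (>= 26).
#' @param classes Two-column matrix of class bounds (default the printed
#'   classes).
#' @return Character vector of class labels.
#' @export
assign_size_class <- function(length, classes = IES_SIZE_CLASSES) {
  out <- rep("unbinned", length(length))
  for (i in seq_len(nrow(classes))) {
    hit <- length >= classes[i, "lo"] & length <= classes[i, "hi"]
    out[hit] <- rownames(classes)[i]
  }
  out
}

#' Label IESs with all stratification variables
#'
#' Joins expression class (via the host gene), size class, a small/large
#' split at `small_max_length`, location and epigenetic class into one
#' stratum table.
#'
#' @param loci IES tibble.
#' @param expr_table Expression tibble (optional; without it expression_class
#'   is `unknown`).
#' @param small_max_length Largest length still called "small" (default 32,
#'   the end of the first printed size class).
#' @return A tibble of stratum labels, one row per IES.
#' @export
label_strata <- function(loci, expr_table = NULL, small_max_length = 32L) {
  ec <- if (!is.null(expr_table)) classify_expression(expr_table) else NULL
  expr_class <- if (is.null(ec)) rep(NA_character_, nrow(loci)) else
    ec$expression_class[match(loci$host_gene_id, ec$gene_id)]
  expr_class[loci$location_class != "exon"] <- NA_character_
  tibble(
    ies_id = loci$ies_id,
    expression_class = expr_class,
    size_class = assign_size_class(loci$length),
    small_or_large = ifelse(loci$length <= small_max_length, "small", "large"),
    location_class = loci$location_class,
    epi_class = loci$epi_class
  )
}

#' Two-proportion test (chi-squared with continuity correction)
#'
#' Equality-of-proportions chi-squared test with Yates continuity
#' correction, the variant that reproduces the printed two-proportion
#' Z-test P-values on the in-paper contingency counts. A one-sided
#' alternative is selectable.
#'
#' @param k1,n1 Successes and total in group 1.
#' @param k2,n2 Successes and total in group 2.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (proportion 1 vs proportion 2).
#' @return The P-value.
#' @export
two_proportion_test <- function(k1, n1, k2, n2, alternative = "two.sided") {
  if (n1 < 1 || n2 < 1) abort("group totals must be >= 1")
  stopifnot(k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  suppressWarnings(
    prop.test(c(k1, k2), c(n1, n2), alternative = alternative, correct = TRUE)$p.value
  )
}

#' One-tailed Fisher exact test for enrichment of the first cell
#'
#' Hypergeometric tail probability that the top-left cell of the 2x2 table
#' `rbind(c(a, b), c(c, d))` is at least as large as observed (alternative
#' "greater": enrichment of `a` relative to its margins).
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise.
#' @return The one-tailed P-value.
#' @export
fisher_one_tail <- function(a, b, c, d) {
  if (a + b + c + d == 0) abort("all-zero contingency table")
  stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE),
                     alternative = "greater")$p.value
}

join_class_counts <- function(records, loci, location, irs_threshold,
                              small_max_length) {
  strata <- label_strata(loci, small_max_length = small_max_length)
  records |>
    filter(!is.na(.data$irs), .data$irs > irs_threshold) |>
    left_join(strata, by = "ies_id") |>
    filter(.data$location_class == location, .data$size_class != "unbinned")
}

#' F1/F0 count ratios of incompletely excised IESs by size class
#'
#' Counts loci with IRS above the threshold per printed size class in each
#' generation, drops classes with fewer than `min_per_class` such loci in
#' either condition, and reports per-class and pooled small/large F1/F0
#' ratios (pooled over the surviving classes, split at `small_max_length`).
#'
#' @param f0_records,f1_records IRS tibbles for the two generations.
#' @param loci IES tibble (provides lengths and location).
#' @param location Location class analysed (default `"exon"`).
#' @param irs_threshold Somatic-IES threshold (default 0.1; IRS > threshold
#'   counts as incompletely excised).
#' @param min_per_class Minimum incompletely excised loci per class per
#'   condition (default 3).
#' @param small_max_length Small/large split (default 32).
#' @return A list with `by_class` (tibble: size_class, n_f0, n_f1, ratio,
#'   kept) and `pooled` (tibble: small_or_large, n_f0, n_f1, ratio).
#' @export
count_ratio_by_size_class <- function(f0_records, f1_records, loci,
                                      location = "exon", irs_threshold = 0.1,
                                      min_per_class = 3L,
                                      small_max_length = 32L) {
  cnt <- function(records) {
    join_class_counts(records, loci, location, irs_threshold, small_max_length) |>
      count(.data$size_class, .data$small_or_large, name = "n")
  }
  all_classes <- tibble(size_class = rownames(IES_SIZE_CLASSES))
  f0c <- cnt(f0_records); f1c <- cnt(f1_records)
  by_class <- all_classes |>
    left_join(f0c |> select("size_class", n_f0 = "n"), by = "size_class") |>
    left_join(f1c |> select("size_class", n_f1 = "n"), by = "size_class") |>
    mutate(across(c("n_f0", "n_f1"), ~ tidyr::replace_na(.x, 0L)),
           kept = .data$n_f0 >= min_per_class & .data$n_f1 >= min_per_class,
           ratio = ifelse(.data$kept & .data$n_f0 > 0, .data$n_f1 / .data$n_f0, NA_real_))
  lo <- as.integer(sub("-.*", "", by_class$size_class))
  by_class$small_or_large <- ifelse(lo <= small_max_length &
                                      as.integer(sub(".*-", "", by_class$size_class)) <= small_max_length,
                                    "small", "large")
  pooled <- by_class |>
    filter(.data$kept) |>
    group_by(.data$small_or_large) |>
    summarise(n_f0 = sum(.data$n_f0), n_f1 = sum(.data$n_f1), .groups = "drop") |>
    mutate(ratio = ifelse(.data$n_f0 > 0, .data$n_f1 / .data$n_f0, NA_real_))
  if (any(pooled$n_f0 == 0)) warn("pooled F0 count 0: ratio undefined")
  list(by_class = by_class, pooled = pooled)
}

#' Median IRS of incompletely excised IESs by size class
#'
#' Same stratification and class-dropping rule as
#' [count_ratio_by_size_class()], with per-class medians of the retained
#' scores instead of counts.
#'
#' @inheritParams count_ratio_by_size_class
#' @param records IRS tibble for one condition.
#' @return A tibble `size_class`, `midpoint`, `n`, `median_irs`, `kept`.
#' @export
median_irs_by_size_class <- function(records, loci, location = "exon",
                                     irs_threshold = 0.1, min_per_class = 3L,
                                     small_max_length = 32L) {
  joined <- join_class_counts(records, loci, location, irs_threshold,
                              small_max_length)
  cls <- IES_SIZE_CLASSES
  tibble(size_class = rownames(cls),
         midpoint = (cls[, "lo"] + cls[, "hi"]) / 2) |>
    left_join(joined |>
                group_by(.data$size_class) |>
                summarise(n = n(), median_irs = median(.data$irs), .groups = "drop"),
              by = "size_class") |>
    mutate(n = tidyr::replace_na(.data$n, 0L),
           kept = .data$n >= min_per_class,
           median_irs = ifelse(.data$kept, .data$median_irs, NA_real_))
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall tau with a normal-approximation P-value.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param alternative Test sidedness (default two-sided).
#' @return A one-row tibble `tau`, `p_value`, `n`.
#' @export
kendall_tau <- function(x, y, alternative = "two.sided") {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    abort("kendall_tau undefined for a constant vector")
  }
  ct <- suppressWarnings(cor.test(x, y, method = "kendall",
                                  alternative = alternative, exact = FALSE))
  tibble(tau = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Wilcoxon rank-sum test
#'
#' Rank-sum (Mann-Whitney) test with tie handling, normal approximation and
#' continuity correction.
#'
#' @param a,b Numeric samples (each >= 3 values).
#' @param alternative `"two.sided"` (default), `"less"`, `"greater"`.
#' @return The P-value.
#' @export
wilcoxon_rank_sum <- function(a, b, alternative = "two.sided") {
  if (length(a) < 3 || length(b) < 3) abort("each sample needs >= 3 values")
  suppressWarnings(
    wilcox.test(a, b, alternative = alternative, exact = FALSE, correct = TRUE)$p.value
  )
}

#' Enrichment of an epigenetic-control class among retained IESs
#'
#' Compares the fraction of `epi_class` loci among a retained set with the
#' fraction in its underlying background sub-population, with a one-tailed
#' Fisher test for enrichment among the retained set.
#'
#' @param retained_ids IES ids of the retained (e.g. IRS > 0.1) set; must be
#'   a subset of the background.
#' @param background Tibble with `ies_id` and `epi_class` for the underlying
#'   sub-population (IRS >= 0).
#' @param epi_class Class tested (e.g. `"DCL2/3"` or `"DCL5"`).
#' @return A one-row tibble `observed_fraction`, `expected_fraction`,
#'   `fisher_p`, `n_retained`, `n_background`.
#' @export
epi_enrichment <- function(retained_ids, background, epi_class) {
  if (length(retained_ids) == 0) abort("empty retained set")
  if (!all(retained_ids %in% background$ies_id)) {
    abort("retained set must be a subset of the background")
  }
  is_epi <- background$epi_class == epi_class
  in_ret <- background$ies_id %in% retained_ids
  a <- sum(is_epi & in_ret); b <- sum(!is_epi & in_ret)
  c_ <- sum(is_epi & !in_ret); d <- sum(!is_epi & !in_ret)
  tibble(
    observed_fraction = a / (a + b),
    expected_fraction = mean(is_epi),
    fisher_p = fisher_one_tail(a, b, c_, d),
    n_retained = a + b,
    n_background = nrow(background)
  )
}

#' PTC-inducing versus PTC-free fold ratio
#'
#' @param ptc_inducing_count,ptc_free_count Non-negative counts;
#'   `ptc_free_count` must be >= 1 for a finite fold.
#' @return A one-row tibble `fold` (raw ratio), `fold_rounded` (one
#'   decimal, as reported), `infinite` flag.
#' @export
ptc_fold <- function(ptc_inducing_count, ptc_free_count) {
  if (ptc_free_count == 0) {
    warn("ptc_free_count = 0: fold reported as infinite")
    return(tibble(fold = Inf, fold_rounded = Inf, infinite = TRUE))
  }
  f <- ptc_inducing_count / ptc_free_count
  tibble(fold = f, fold_rounded = round(f, 1), infinite = FALSE)
}

#' IESs shared exclusively among named call sets
#'
#' Returns the loci present in every `include` set and absent from every
#' `exclude` set, with small/large and intragenic/intergenic tallies when a
#' locus table is supplied.
#'
#' @param call_sets Named list of character vectors of IES ids.
#' @param include Names of the sets that must all contain a locus.
#' @param exclude Names of the sets that must not contain it.
#' @param loci Optional IES tibble for the breakdown.
#' @param small_max_length Small/large split (default 32).
#' @return A list with `ies_ids` and (when `loci` given) `breakdown`.
#' @export
exclusive_overlap <- function(call_sets, include, exclude = character(),
                              loci = NULL, small_max_length = 32L) {
  if (anyDuplicated(c(include, exclude))) {
    abort("include and exclude set names must not overlap")
  }
  missing_sets <- setdiff(c(include, exclude), names(call_sets))
  if (length(missing_sets)) {
    abort(sprintf("unknown set name(s): %s", paste(missing_sets, collapse = ", ")))
  }
  shared <- Reduce(intersect, call_sets[include])
  for (e in exclude) shared <- setdiff(shared, call_sets[[e]])
  out <- list(ies_ids = shared)
  if (!is.null(loci) && length(shared)) {
    sub <- loci |> filter(.data$ies_id %in% shared)
    out$breakdown <- tibble(
      n = length(shared),
      n_small = sum(sub$length <= small_max_length),
      n_large = sum(sub$length > small_max_length),
      n_intragenic = sum(sub$location_class == "exon"),
      n_intergenic = sum(sub$location_class == "intergenic")
    )
  }
  out
}

#' Terminal position-weight profile of IES ends
#'
#' Builds base-frequency matrices over the first and last `w` nucleotides of
#' a training set of IES sequences; the cis-acting splicing-signal score of a
#' sequence is the mean, over both termini and all positions, of the
#' observed-base frequency normalised by the per-position maximum frequency
#' (1 = consensus at every position).
#'
#' @param training_seqs Character vector of TA-bounded IES sequences.
#' @param w Terminal window width (default 8).
#' @return An object of class `ies_pwm` (list of two `4 x w` frequency
#'   matrices, `left` and `right`).
#' @export
build_terminal_pwm <- function(training_seqs, w = 8L) {
  if (any(nchar(training_seqs) < 2 * w)) {
    abort(sprintf("all training IESs must be at least %d nt (2w)", 2 * w))
  }
  freq_mat <- function(strs) {
    m <- do.call(rbind, strsplit(strs, ""))
    apply(m, 2, function(col) {
      tab <- table(factor(col, levels = c("A", "C", "G", "T")))
      as.numeric(tab) / length(col)
    })
  }
  left <- freq_mat(substr(training_seqs, 1L, w))
  right <- freq_mat(substr(training_seqs, nchar(training_seqs) - w + 1L,
                           nchar(training_seqs)))
  rownames(left) <- rownames(right) <- c("A", "C", "G", "T")
  structure(list(left = left, right = right, w = as.integer(w)),
            class = "ies_pwm")
}

#' Score the cis-acting splicing signal of an IES
#'
#' @param ies_sequence Character vector of IES sequences (each >= 2w nt).
#' @param pwm Profile from [build_terminal_pwm()].
#' @return Numeric vector of scores in \[0, 1\].
#' @export
cis_signal_score <- function(ies_sequence, pwm) {
  w <- pwm$w
  if (any(nchar(ies_sequence) < 2 * w)) {
    abort(sprintf("IES shorter than 2w = %d nt", 2 * w))
  }
  score_end <- function(strs, mat) {
    m <- do.call(rbind, strsplit(strs, ""))
    mx <- apply(mat, 2, max)
    vapply(seq_len(nrow(m)), function(r) {
      f <- vapply(seq_len(w), function(i) mat[m[r, i], i], numeric(1))
      mean(f / mx)
    }, numeric(1))
  }
  l <- score_end(substr(ies_sequence, 1L, w), pwm$left)
  r <- score_end(substr(ies_sequence, nchar(ies_sequence) - w + 1L,
                        nchar(ies_sequence)), pwm$right)
  (l + r) / 2
}
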