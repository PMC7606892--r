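# F0-referenced binomial transition calling. The null for an upward call is
# the upper bound of a (default 75%) confidence interval on the F0 retention
# score; for a downward call, the lower bound. One-sided exact binomial tail
# probabilities are computed for the F1 counts against those bounds.

#' Reference bounds on the F0 retention score
#'
#' Two-sided Clopper-Pearson (exact) confidence bounds on the F0 IES
#' retention proportion, used as reference retention scores for the binomial
#' transition tests. A Wilson score interval is available as an alternative.
#'
#' @param k0 Integer vector of F0 IES-supporting read counts.
#' @param n0 Integer vector of F0 total read counts (>= 1).
#' @param level Confidence level in (0, 1); default 0.75.
#' @param method `"clopper-pearson"` (default) or `"wilson"`.
#' @return A tibble `k0`, `n0`, `level`, `p_lower`, `p_upper`.
#' @export
reference_bounds <- function(k0, n0, level = 0.75, method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  if (any(n0 < 1)) abort("n0 = 0: locus must already be coverage-filtered")
  stopifnot(all(k0 >= 0), all(k0 <= n0), level > 0, level < 1)
  a <- 1 - level
  if (method == "clopper-pearson") {
    p_lower <- ifelse(k0 == 0, 0, qbeta(a / 2, k0, n0 - k0 + 1))
    p_upper <- ifelse(k0 == n0, 1, qbeta(1 - a / 2, k0 + 1, n0 - k0))
  } else {
    z <- stats::qnorm(1 - a / 2)
    ph <- k0 / n0
    den <- 1 + z^2 / n0
    ctr <- (ph + z^2 / (2 * n0)) / den
    hw <- z * sqrt(ph * (1 - ph) / n0 + z^2 / (4 * n0^2)) / den
    p_lower <- ifelse(k0 == 0, 0, pmax(0, ctr - hw))
    p_upper <- ifelse(k0 == n0, 1, pmin(1, ctr + hw))
  }
  tibble(k0 = as.integer(k0), n0 = as.integer(n0), level = level,
         p_lower = p_lower, p_upper = p_upper)
}

#' One-sided binomial transition tests for F1 counts
#'
#' `p_value_up` is the exact upper-tail probability P(X >= k1) under
#' Binomial(n1, p_upper); `p_value_down` is P(X <= k1) under
#' Binomial(n1, p_lower). Direction and significance are decided in
#' [call_transitions()] after multiple-testing adjustment.
#'
#' @param k1 Integer vector of F1 IES-supporting counts.
#' @param n1 Integer vector of F1 totals (>= 1).
#' @param bounds Tibble from [reference_bounds()] (row-aligned with `k1`).
#' @return A tibble `k1`, `n1`, `f1_irs`, `p_value_up`, `p_value_down`.
#' @export
test_transition <- function(k1, n1, bounds) {
  if (any(n1 < 1)) abort("n1 must be >= 1")
  stopifnot(all(k1 >= 0), all(k1 <= n1))
  p_up <- pbinom(k1 - 1, n1, bounds$p_upper, lower.tail = FALSE)
  p_down <- pbinom(k1, n1, bounds$p_lower)
  tibble(k1 = as.integer(k1), n1 = as.integer(n1), f1_irs = k1 / n1,
         p_value_up = p_up, p_value_down = p_down)
}

irs_to_counts <- function(tbl) {
  if (!"k_ies" %in% names(tbl)) {
    tbl$k_ies <- as.integer(round(tbl$irs * tbl$n_total))
  }
  if (!"irs" %in% names(tbl)) tbl$irs <- tbl$k_ies / tbl$n_total
  tbl
}

#' Call significant retention transitions between two generations
#'
#' Joins the F0 and F1 tables by locus, builds reference bounds on the F0
#' score, computes one-sided exact binomial P-values for the F1 counts
#' against those bounds, adjusts per direction over all tested loci, and
#' calls `up` / `down` / `none`. A locus whose F1 score falls exactly on a
#' bound is never called (strict inequalities). Loci failing filters in
#' either generation are excluded from testing but kept in the audit table.
#'
#' @param f0_table,f1_table IRS tibbles ([compute_irs()], optionally through
#'   [apply_filters()]); need `ies_id`, `n_total`, and `irs` or `k_ies`.
#' @param level Confidence level of the reference interval (default 0.75).
#' @param alpha Significance threshold on the adjusted P (default 0.05).
#' @param adjust `"BH"` (Benjamini-Hochberg, default) or `"none"`.
#' @param ci_method Passed to [reference_bounds()].
#' @return An `ies_transitions` object; [tidy()] returns the per-locus calls,
#'   [glance()] a one-row summary.
#' @export
call_transitions <- function(f0_table, f1_table, level = 0.75, alpha = 0.05,
                             adjust = c("BH", "none"),
                             ci_method = "clopper-pearson") {
  adjust <- match.arg(adjust)
  f0 <- irs_to_counts(f0_table)
  f1 <- irs_to_counts(f1_table)
  audit <- list()
  drop_unfiltered <- function(tbl, gen) {
    if ("passed_filters" %in% names(tbl)) {
      bad <- tbl |> filter(!.data$passed_filters)
      if (nrow(bad)) {
        audit[[gen]] <<- tibble(ies_id = bad$ies_id, generation = gen,
                                reason = bad$filter_reasons %||% "failed_filters")
      }
      tbl <- tbl |> filter(.data$passed_filters)
    }
    tbl
  }
  f0 <- drop_unfiltered(f0, "F0")
  f1 <- drop_unfiltered(f1, "F1")
  shared <- inner_join(
    f0 |> select("ies_id", k0 = "k_ies", n0 = "n_total", f0_irs = "irs"),
    f1 |> select("ies_id", k1 = "k_ies", n1 = "n_total", f1_irs = "irs"),
    by = "ies_id"
  )
  if (nrow(shared) == 0L) abort("zero shared loci between F0 and F1 tables")
  b <- reference_bounds(shared$k0, shared$n0, level = level, method = ci_method)
  tt <- test_transition(shared$k1, shared$n1, b)
  p_adj_up <- p.adjust(tt$p_value_up, method = if (adjust == "BH") "BH" else "none")
  p_adj_down <- p.adjust(tt$p_value_down, method = if (adjust == "BH") "BH" else "none")
  up <- p_adj_up <= alpha & shared$f1_irs > b$p_upper
  down <- p_adj_down <= alpha & shared$f1_irs < b$p_lower
  calls <- tibble(
    ies_id = shared$ies_id,
    k0 = shared$k0, n0 = shared$n0, f0_irs = shared$f0_irs,
    k1 = shared$k1, n1 = shared$n1, f1_irs = shared$f1_irs,
    p_lower = b$p_lower, p_upper = b$p_upper,
    p_value_up = tt$p_value_up, p_value_down = tt$p_value_down,
    p_adjusted = dplyr::case_when(up ~ p_adj_up, down ~ p_adj_down,
                                  .default = pmin(p_adj_up, p_adj_down)),
    direction = dplyr::case_when(up ~ "up", down ~ "down", .default = "none"),
    significant = up | down
  )
  structure(list(
    calls = calls,
    audit = bind_rows(audit),
    params = list(level = level, alpha = alpha, adjust = adjust,
                  ci_method = ci_method)
  ), class = "ies_transitions")
}

#' @export
print.ies_transitions <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<ies_transitions> %d loci tested: %d up, %d down (level %.2f, alpha %.3g, %s)\n",
    g$n_tested, g$n_up, g$n_down, g$level, g$alpha, g$adjust))
  invisible(x)
}

#' @describeIn call_transitions Per-locus transition calls as a tibble.
#' @param x An `ies_transitions` object.
#' @param ... Unused.
#' @method tidy ies_transitions
#' @export
tidy.ies_transitions <- function(x, ...) x$calls

#' @describeIn call_transitions One-row summary (loci tested, up/down counts,
#'   parameters).
#' @method glance ies_transitions
#' @export
glance.ies_transitions <- function(x, ...) {
  tibble(
    n_tested = nrow(x$calls),
    n_up = sum(x$calls$direction == "up"),
    n_down = sum(x$calls$direction == "down"),
    n_audit = nrow(x$audit),
    level = x$params$level, alpha = x$params$alpha, adjust = x$params$adjust
  )
}

#' @describeIn call_transitions F0 vs F1 retention scatter coloured by call.
#' @param object An `ies_transitions` object.
#' @method autoplot ies_transitions
#' @export
autoplot.ies_transitions <- function(object, ...) {
  ggplot2::ggplot(object$calls,
                  ggplot2::aes(x = .data$f0_irs, y = .data$f1_irs,
                               colour = .data$direction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(up = "#c23b22", down = "#2b6cb0",
                                            none = "grey70")) +
    ggplot2::labs(x = "F0 IRS", y = "F1 IRS", colour = "transition") +
    ggplot2::theme_minimal()
}
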