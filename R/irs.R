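# Junction-read classification, IES+/IES- counting, IES Retention Scores,
# and the study-wide locus filters.

#' Junction strings for one locus
#'
#' Builds the three exact-match junction strings used by [classify_read()]:
#' the MAC junction (excised form) and the left and right boundaries of the
#' IES-retaining form. Each string carries `min_flank` bases on both sides of
#' its breakpoint. The breakpoint convention follows the one-TA-retained
#' biology: MAC = left flank + TA + right flank, retained form = left flank +
#' full TA-bounded IES + right flank, so the left seam falls after the shared
#' leading TA and the right seam after the IES's trailing TA.
#'
#' @param locus One-row IES tibble (needs `scaffold`, `mac_insertion_point`,
#'   `ies_sequence`).
#' @param mac_genome Named character vector of scaffold sequences.
#' @param min_flank Exact-match flank on each side of the breakpoint (>= 1).
#' @return A named list of strings: `mac`, `ies_left`, `ies_right`.
#' @export
locus_junctions <- function(locus, mac_genome, min_flank = 10L) {
  if (min_flank < 1L) abort("config error: min_flank must be >= 1")
  scaf <- mac_genome[[locus$scaffold]]
  i <- locus$mac_insertion_point
  f <- as.integer(min_flank)
  ies <- locus$ies_sequence
  L2 <- nchar(ies)
  left_f <- substr(scaf, i + 3L - f, i + 2L)          # f bases ending at the TA
  right_f <- substr(scaf, i + 3L, i + 2L + f)         # f bases after the TA
  if (nchar(left_f) < f || nchar(right_f) < f) {
    abort(sprintf("locus %s too close to scaffold edge for min_flank %d",
                  locus$ies_id, f))
  }
  list(
    mac = paste0(left_f, right_f),
    ies_left = paste0(left_f, substr(ies, 3L, 2L + f)),
    ies_right = paste0(substr(ies, L2 - f + 1L, L2), right_f)
  )
}

#' Classify one read against one locus
#'
#' Exact-match junction classification: `IES_PLUS` if the read (or its
#' reverse complement) contains an IES+ boundary string, `MAC` if it contains
#' the MAC junction string, `AMBIGUOUS` if both match (possible for tiny
#' flanks), `NO_MATCH` otherwise.
#'
#' @param read_sequence Character vector of read sequences.
#' @param junctions Junction strings from [locus_junctions()].
#' @param min_flank Flank used to build `junctions` (validated only).
#' @return Character vector of classifications.
#' @export
classify_read <- function(read_sequence, junctions, min_flank = 10L) {
  if (min_flank < 1L) abort("config error: min_flank must be >= 1")
  rc <- revcomp(read_sequence)
  hit <- function(j) {
    stringr::str_detect(read_sequence, stringr::fixed(j)) |
      stringr::str_detect(rc, stringr::fixed(j))
  }
  mac <- hit(junctions$mac)
  ies <- hit(junctions$ies_left) | hit(junctions$ies_right)
  dplyr::case_when(
    mac & ies ~ "AMBIGUOUS",
    ies ~ "IES_PLUS",
    mac ~ "MAC",
    .default = "NO_MATCH"
  )
}

#' Count IES+ / IES- junction reads per locus
#'
#' Classifies every read against every locus. A read contributes to at most
#' one category per locus; a read matching junctions of two different loci is
#' counted as ambiguous at both (evidence is never double-counted).
#'
#' @param reads A tibble with `read_id` and `sequence`, or a FASTQ path.
#' @param loci IES tibble.
#' @param mac_genome Named character vector of scaffold sequences.
#' @param min_flank Exact-match flank (default 10).
#' @return A junction-counts tibble: `ies_id`, `k_ies`, `k_mac`, `n_total`,
#'   `n_ambiguous`.
#' @export
count_reads <- function(reads, loci, mac_genome, min_flank = 10L) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  if (anyDuplicated(reads$read_id)) {
    warn("duplicate read identifiers; all occurrences processed")
  }
  n_loci <- nrow(loci)
  if (nrow(reads) == 0L) {
    return(tibble(ies_id = loci$ies_id, k_ies = 0L, k_mac = 0L,
                  n_total = 0L, n_ambiguous = 0L))
  }
  rc <- revcomp(reads$sequence)
  hit <- function(j) {
    stringr::str_detect(reads$sequence, stringr::fixed(j)) |
      stringr::str_detect(rc, stringr::fixed(j))
  }
  mac_hits <- matrix(FALSE, nrow(reads), n_loci)
  ies_hits <- matrix(FALSE, nrow(reads), n_loci)
  for (j in seq_len(n_loci)) {
    jn <- locus_junctions(loci[j, ], mac_genome, min_flank)
    mac_hits[, j] <- hit(jn$mac)
    ies_hits[, j] <- hit(jn$ies_left) | hit(jn$ies_right)
  }
  any_hit <- mac_hits | ies_hits
  n_loci_hit <- rowSums(any_hit)
  multi <- n_loci_hit > 1L               # cross-locus matches -> ambiguous
  k_ies <- k_mac <- n_amb <- integer(n_loci)
  for (j in seq_len(n_loci)) {
    rel <- any_hit[, j]
    amb <- rel & (multi | (mac_hits[, j] & ies_hits[, j]))
    k_ies[j] <- sum(rel & !amb & ies_hits[, j])
    k_mac[j] <- sum(rel & !amb & mac_hits[, j])
    n_amb[j] <- sum(amb)
  }
  tibble(ies_id = loci$ies_id, k_ies = k_ies, k_mac = k_mac,
         n_total = k_ies + k_mac, n_ambiguous = n_amb)
}

#' Compute IES Retention Scores
#'
#' IRS = IES-containing reads / all classified junction reads,
#' `k_ies / (k_ies + k_mac)`. 0 means complete excision, 1 full retention.
#' Loci with no classified reads get an undefined (NA) score and are flagged,
#' never NaN.
#'
#' @param counts Junction-counts tibble (`ies_id`, `k_ies`, `k_mac`).
#' @return An IRS tibble: `ies_id`, `irs`, `n_total`, `undefined`.
#' @export
compute_irs <- function(counts) {
  stopifnot(all(counts$k_ies >= 0), all(counts$k_mac >= 0))
  n <- counts$k_ies + counts$k_mac
  tibble(
    ies_id = counts$ies_id,
    irs = ifelse(n > 0, counts$k_ies / n, NA_real_),
    n_total = as.integer(n),
    undefined = n == 0L
  )
}

#' Apply the study-wide locus filters
#'
#' Excludes loci supported by fewer than `min_reads` junction reads and IESs
#' shorter than `min_length` (eliminated-segment length). Excluded records
#' are retained with their reasons for audit.
#'
#' @param records IRS tibble from [compute_irs()].
#' @param loci IES tibble (provides lengths), joinable by `ies_id`.
#' @param min_reads Minimum read support (default 20: loci with < 20 reads
#'   are excluded).
#' @param min_length Minimum IES length (default 26, i.e. longer than 25 nt).
#' @return `records` with `passed_filters` and `filter_reasons` columns.
#' @export
apply_filters <- function(records, loci, min_reads = 20L, min_length = 26L) {
  orphans <- setdiff(records$ies_id, loci$ies_id)
  if (length(orphans)) {
    abort(sprintf("ies_id in records but not in loci: %s",
                  paste(head(orphans, 5), collapse = ", ")))
  }
  len <- loci$length[match(records$ies_id, loci$ies_id)]
  low_cov <- records$n_total < min_reads | records$undefined
  short <- len < min_length
  reasons <- purrr::map2_chr(low_cov, short, function(a, b) {
    paste(c(if (a) "low_coverage", if (b) "short_ies"), collapse = ";")
  })
  records |>
    mutate(length = len,
           passed_filters = !low_cov & !short,
           filter_reasons = reasons)
}
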