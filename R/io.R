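# On-disk formats. One coordinate convention is enforced at this boundary:
# GFF3 is 1-based inclusive on disk, everything internal is 0-based half-open.

GFF3_IES_TYPE <- "internal_eliminated_sequence"

# Cheap structural scan so malformed rows fail with a line number before the
# file reaches the GFF3 parser.
check_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "" || startsWith(ln, "#")) {
      if (startsWith(ln, "##FASTA")) break
      next
    }
    if (length(strsplit(ln, "\t", fixed = TRUE)[[1]]) != 9) {
      abort(sprintf("malformed GFF3 line %d in %s: expected 9 tab-separated fields",
                    i, path))
    }
  }
  invisible(path)
}

validate_ies_loci <- function(loci) {
  bad <- !grepl("^TA[ACGT]*TA$", loci$ies_sequence)
  if (any(bad)) {
    abort(sprintf("IES sequence not TA-bounded (or non-ACGT) for: %s",
                  paste(loci$ies_id[bad], collapse = ", ")))
  }
  stopifnot(all(loci$length == nchar(loci$ies_sequence) - 2L))
  exon_no_host <- loci$location_class == "exon" & is.na(loci$host_gene_id)
  if (any(exon_no_host)) {
    abort(sprintf("exon-mapping IES without host gene: %s",
                  paste(loci$ies_id[exon_no_host], collapse = ", ")))
  }
  invisible(loci)
}

#' Read IES annotations from GFF3 (plus optional sequence FASTA)
#'
#' Parses `internal_eliminated_sequence` features. The IES sequence is taken
#' from the `sequence` attribute when present, otherwise looked up by ID in
#' the companion FASTA. GFF3 coordinates (1-based inclusive) are converted to
#' the internal convention: `mac_insertion_point` is the 0-based position on
#' the somatic (MAC) reference where the retained TA dinucleotide begins.
#' The reported `length` is the eliminated-segment length, i.e. the sequence
#' length minus the single TA that stays behind in the MAC
#' (`nchar(ies_sequence) - 2`).
#'
#' @param path_gff3 GFF3 file of IES features.
#' @param path_fasta Optional FASTA of IES sequences keyed by IES id.
#' @return A tibble with one row per IES: `ies_id`, `scaffold`,
#'   `mac_insertion_point`, `ies_sequence`, `length`, `location_class`,
#'   `host_gene_id`, `strand_of_host`, `epi_class`.
#' @export
read_ies_annotation <- function(path_gff3, path_fasta = NULL) {
  check_gff3_lines(path_gff3)
  gr <- rtracklayer::import(path_gff3, format = "gff3")
  gr <- gr[as.character(gr$type) == GFF3_IES_TYPE]
  mc <- as.data.frame(GenomicRanges::mcols(gr))
  get_attr <- function(nm, default = NA_character_) {
    if (nm %in% names(mc)) as.character(mc[[nm]]) else rep(default, length(gr))
  }
  seqs <- get_attr("sequence")
  if (anyNA(seqs)) {
    if (is.null(path_fasta)) {
      abort("IES sequences missing from GFF3 attributes and no FASTA given")
    }
    fa <- Biostrings::readDNAStringSet(path_fasta)
    names(fa) <- sub("\\s.*$", "", names(fa))
    ids <- get_attr("ID")
    miss <- is.na(seqs)
    orphan <- setdiff(ids[miss], names(fa))
    if (length(orphan)) {
      abort(sprintf("IES ids absent from FASTA: %s", paste(orphan, collapse = ", ")))
    }
    seqs[miss] <- as.character(fa[ids[miss]])
  }
  loci <- tibble(
    ies_id = get_attr("ID"),
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    mac_insertion_point = GenomicRanges::start(gr) - 1L,
    ies_sequence = toupper(seqs),
    length = nchar(seqs) - 2L,
    location_class = get_attr("location_class", "other"),
    host_gene_id = get_attr("host_gene"),
    strand_of_host = get_attr("host_strand"),
    epi_class = get_attr("epi_class", "unknown")
  )
  loci$location_class[is.na(loci$location_class)] <- "other"
  loci$epi_class[is.na(loci$epi_class)] <- "unknown"
  validate_ies_loci(loci)
  loci
}

#' Write IES annotations to GFF3
#'
#' Inverse of [read_ies_annotation()]: the feature spans the retained TA
#' dinucleotide on the MAC reference (two bases, 1-based inclusive), and the
#' full TA-bounded sequence travels in the `sequence` attribute.
#'
#' @param loci IES tibble as returned by [read_ies_annotation()] or
#'   [simulate_truth()].
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_ies_annotation <- function(loci, path) {
  validate_ies_loci(loci)
  gr <- GenomicRanges::GRanges(
    seqnames = loci$scaffold,
    ranges = IRanges::IRanges(start = loci$mac_insertion_point + 1L,
                              end = loci$mac_insertion_point + 2L),
    strand = "*"
  )
  gr$type <- GFF3_IES_TYPE
  gr$source <- "iesretention"
  gr$ID <- loci$ies_id
  gr$sequence <- loci$ies_sequence
  gr$location_class <- loci$location_class
  gr$host_gene <- loci$host_gene_id
  gr$host_strand <- loci$strand_of_host
  gr$epi_class <- loci$epi_class
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models (CDS chains) from GFF3
#'
#' Expects `gene` features with `CDS` children (`Parent` attribute). CDS
#' segments are converted to 0-based half-open intervals on the MAC
#' reference and sorted in genomic order.
#'
#' @param path_gff3 GFF3 file of gene models.
#' @return A tibble with `gene_id`, `scaffold`, `strand`, and a
#'   `cds_segments` list-column of two-column matrices (`start`, `end`).
#' @export
read_gene_models <- function(path_gff3) {
  check_gff3_lines(path_gff3)
  gr <- rtracklayer::import(path_gff3, format = "gff3")
  cds <- gr[as.character(gr$type) == "CDS"]
  parent <- as.character(S4Vectors::unstrsplit(cds$Parent, ","))
  df <- tibble(
    gene_id = parent,
    scaffold = as.character(GenomicRanges::seqnames(cds)),
    strand = as.character(GenomicRanges::strand(cds)),
    start = GenomicRanges::start(cds) - 1L,
    end = GenomicRanges::end(cds)
  )
  df |>
    group_by(.data$gene_id) |>
    summarise(
      scaffold = .data$scaffold[1],
      strand = .data$strand[1],
      cds_segments = list(cbind(start = sort(.data$start),
                                end = .data$end[order(.data$start)])),
      .groups = "drop"
    )
}

#' Write gene models to GFF3
#'
#' @param genes Gene tibble as returned by [read_gene_models()].
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  rows <- purrr::pmap(genes, function(gene_id, scaffold, strand, cds_segments, ...) {
    seg <- cds_segments
    gene_r <- GenomicRanges::GRanges(scaffold,
      IRanges::IRanges(min(seg[, "start"]) + 1L, max(seg[, "end"])), strand)
    gene_r$type <- "gene"; gene_r$ID <- gene_id; gene_r$Parent <- NA_character_
    gene_r$phase <- NA_integer_
    cds_r <- GenomicRanges::GRanges(scaffold,
      IRanges::IRanges(seg[, "start"] + 1L, seg[, "end"]), strand)
    cds_r$type <- "CDS"
    lens <- seg[, "end"] - seg[, "start"]
    ord <- if (strand == "-") rev(seq_along(lens)) else seq_along(lens)
    cum <- cumsum(c(0L, lens[ord]))[seq_along(lens)]
    cds_r$phase <- integer(length(lens))
    cds_r$phase[ord] <- (3L - cum %% 3L) %% 3L
    cds_r$ID <- paste0(gene_id, ".cds", seq_len(nrow(seg)))
    cds_r$Parent <- gene_id
    c(gene_r, cds_r)
  })
  # genes legitimately live on different scaffolds; combining their ranges
  # triggers a seqlevel notice that is noise here
  gr <- suppressWarnings(do.call(c, rows))
  gr$source <- "iesretention"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a gene expression table
#'
#' Two-column tab-separated file (`gene_id`, `expression_value`), header
#' optional, `#` comments allowed. Values must be non-negative; zero-expression
#' genes are kept but carry no `log2_value` and are excluded downstream from
#' quartile computation.
#'
#' @param path_tsv Path to the TSV.
#' @return A tibble `gene_id`, `expression`, `log2_value`.
#' @export
read_expression <- function(path_tsv) {
  raw <- readr::read_tsv(path_tsv, col_names = FALSE, comment = "#",
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) != 2) abort("expression table must have exactly two columns")
  if (nrow(raw) > 0 && is.na(suppressWarnings(as.numeric(raw[[2]][1])))) {
    raw <- raw[-1, , drop = FALSE]  # header row
  }
  vals <- suppressWarnings(as.numeric(raw[[2]]))
  if (anyNA(vals)) abort("non-numeric expression value in table")
  if (any(vals < 0)) {
    abort(sprintf("negative expression value for gene %s", raw[[1]][which(vals < 0)[1]]))
  }
  dup <- raw[[1]][duplicated(raw[[1]])]
  if (length(dup)) {
    abort(sprintf("duplicate gene_id in expression table: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  tibble(
    gene_id = raw[[1]],
    expression = vals,
    log2_value = ifelse(vals > 0, log2(vals), NA_real_)
  )
}

#' Write an expression table
#' @param expr Tibble with `gene_id` and `expression`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(expr[, c("gene_id", "expression")], path, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Read precomputed junction counts
#'
#' @param path_tsv TSV with columns `ies_id`, `k_ies`, `k_mac` (and optionally
#'   `n_ambiguous`).
#' @return A junction-counts tibble (`ies_id`, `k_ies`, `k_mac`, `n_total`,
#'   `n_ambiguous`).
#' @export
read_counts <- function(path_tsv) {
  df <- readr::read_tsv(path_tsv, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (!all(c("ies_id", "k_ies", "k_mac") %in% names(df))) {
    abort("counts TSV must have columns ies_id, k_ies, k_mac")
  }
  if (!"n_ambiguous" %in% names(df)) df$n_ambiguous <- 0L
  tibble(
    ies_id = as.character(df$ies_id),
    k_ies = as.integer(df$k_ies),
    k_mac = as.integer(df$k_mac),
    n_total = as.integer(df$k_ies + df$k_mac),
    n_ambiguous = as.integer(df$n_ambiguous)
  )
}

#' Write junction counts
#' @param counts Junction-counts tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

# Recursively replace NaN by NA (serialised as null) and refuse
# unserialisable fields, naming them.
sanitize_report <- function(x, path = "results") {
  if (is.function(x) || is.environment(x)) {
    abort(sprintf("unserializable field in report: %s", path))
  }
  if (is.list(x)) {
    nms <- names(x) %||% as.character(seq_along(x))
    for (i in seq_along(x)) {
      x[i] <- list(sanitize_report(x[[i]], paste(path, nms[i], sep = ".")))
    }
    return(x)
  }
  if (is.numeric(x) && any(is.nan(x))) {
    warn(sprintf("NaN in report field %s serialized as null", path))
    x[is.nan(x)] <- NA_real_
  }
  x
}

#' Write a JSON analysis report
#'
#' Wraps `results` with run metadata (package version, seed, configuration
#' hash) and writes deterministic, round-trippable JSON. `NaN` values are
#' serialised as `null` with a warning.
#'
#' @param results A (possibly nested) list of results from any pipeline stage.
#' @param path Output JSON path.
#' @param seed Seed used for the run (recorded in metadata).
#' @param config Optional configuration list; its hash is recorded.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, seed = NULL, config = NULL) {
  results <- sanitize_report(results)
  report <- list(
    metadata = list(
      package = "iesretention",
      version = as.character(packageVersion("iesretention")),
      seed = seed,
      config_hash = if (!is.null(config)) rlang::hash(config) else NULL
    ),
    results = results
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a JSON report written by [write_report()]
#' @param path Path to the JSON report.
#' @return The report as a nested list.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                     simplifyMatrix = FALSE)
}
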