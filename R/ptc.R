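# Consequence of retaining an exon-mapping IES in its host coding sequence.
# Under the ciliate nuclear genetic code (NCBI table 6) TAA and TAG encode
# glutamine and only TGA terminates translation, so premature termination
# must be called with that table, not the standard one.

genetic_code_table <- function(genetic_code = c("ciliate", "standard")) {
  genetic_code <- match.arg(genetic_code)
  Biostrings::getGeneticCode(if (genetic_code == "ciliate") "6" else "1")
}

find_cds_segment <- function(gene, insertion_point) {
  seg <- gene$cds_segments[[1]]
  inside <- insertion_point > seg[, "start"] & insertion_point + 2L < seg[, "end"]
  if (!any(inside)) {
    abort(sprintf("insertion point %d of locus in gene %s is on a CDS boundary or outside the CDS",
                  insertion_point, gene$gene_id))
  }
  which(inside)[1]
}

#' Extract the MAC coding sequence of a gene
#'
#' Concatenates CDS segments in genomic order and reverse-complements for
#' minus-strand genes, yielding the coding-orientation sequence.
#'
#' @param gene One-row gene tibble (`gene_id`, `scaffold`, `strand`,
#'   `cds_segments`).
#' @param mac_genome Named character vector of scaffold sequences.
#' @return The coding sequence as a character string.
#' @export
extract_cds <- function(gene, mac_genome) {
  scaf <- mac_genome[[gene$scaffold]]
  seg <- gene$cds_segments[[1]]
  genomic <- paste(vapply(seq_len(nrow(seg)), function(r) {
    substr(scaf, seg[r, "start"] + 1L, seg[r, "end"])
  }, character(1)), collapse = "")
  if (gene$strand == "-") revcomp(genomic) else genomic
}

#' Build the IES-retaining coding sequence
#'
#' Splices the full TA-bounded IES sequence into the host CDS at its MAC
#' insertion point (replacing the single retained TA), then returns the
#' result in coding orientation. Excising the eliminated segment again
#' restores the MAC CDS exactly.
#'
#' @param gene One-row gene tibble.
#' @param ies One-row IES tibble (`scaffold`, `mac_insertion_point`,
#'   `ies_sequence`).
#' @param mac_genome Named character vector of scaffold sequences.
#' @return The retained coding sequence as a character string.
#' @export
build_retained_cds <- function(gene, ies, mac_genome) {
  if (gene$scaffold != ies$scaffold) {
    abort(sprintf("scaffold mismatch: gene %s on %s, IES %s on %s",
                  gene$gene_id, gene$scaffold, ies$ies_id, ies$scaffold))
  }
  i <- ies$mac_insertion_point
  si <- find_cds_segment(gene, i)
  scaf <- mac_genome[[gene$scaffold]]
  seg <- gene$cds_segments[[1]]
  pieces <- vapply(seq_len(nrow(seg)), function(r) {
    s <- substr(scaf, seg[r, "start"] + 1L, seg[r, "end"])
    if (r == si) {
      off <- i - seg[r, "start"]      # 0-based offset of the TA in the segment
      paste0(substr(s, 1L, off), ies$ies_sequence,
             substr(s, off + 3L, nchar(s)))
    } else s
  }, character(1))
  out <- paste(pieces, collapse = "")
  if (gene$strand == "-") revcomp(out) else out
}

#' Translate a coding sequence, returning all stop positions
#'
#' Codon-by-codon translation under the ciliate nuclear (default) or
#' standard genetic code. Any incomplete trailing codon (possible for
#' frame-shifted retained transcripts) is ignored. Stops are reported as `*`
#' in the protein string and as 1-based codon indices.
#'
#' @param cds Coding sequence (A/C/G/T only, length >= 3).
#' @param genetic_code `"ciliate"` (TGA sole stop, TAA/TAG = Gln) or
#'   `"standard"`.
#' @return A list with `protein` (character string) and `stop_positions`
#'   (integer vector of codon indices).
#' @export
translate_cds <- function(cds, genetic_code = "ciliate") {
  assert_dna(cds, "CDS")
  if (nchar(cds) < 3L) abort("CDS shorter than one codon")
  code <- genetic_code_table(genetic_code)
  n_cod <- nchar(cds) %/% 3L
  starts <- (seq_len(n_cod) - 1L) * 3L + 1L
  codons <- substring(cds, starts, starts + 2L)
  aa <- unname(code[codons])
  list(protein = paste(aa, collapse = ""), stop_positions = which(aa == "*"))
}

#' Classify the coding consequence of retaining one IES
#'
#' Builds the retained transcript, translates it, and compares the first
#' stop codon with the codon corresponding to the gene's native stop
#' (located by coordinate arithmetic, not sequence search):
#' \itemize{
#'   \item `PTC_INDUCING` - translation terminates strictly before the
#'     native stop codon;
#'   \item `ORF_INTACT` - the eliminated-segment length is a multiple of 3
#'     and no stop lies inside the retained frame;
#'   \item `FRAMESHIFT_NO_STOP` - the frame is shifted but no premature stop
#'     is created upstream of the native stop position.
#' }
#'
#' @param gene One-row gene tibble.
#' @param ies One-row IES tibble.
#' @param mac_genome Named character vector of scaffold sequences.
#' @param genetic_code `"ciliate"` (default) or `"standard"`.
#' @return A one-row tibble: `ies_id`, `host_gene_id`, `consequence`,
#'   `frame_shift`, `first_stop_codon_index`, `native_stop_codon_index`.
#' @export
classify_ptc <- function(gene, ies, mac_genome, genetic_code = "ciliate") {
  retained <- build_retained_cds(gene, ies, mac_genome)
  L <- ies$length
  frame_shift <- L %% 3L
  mac_len <- sum(gene$cds_segments[[1]][, "end"] - gene$cds_segments[[1]][, "start"])
  # first base of the native stop in retained coordinates, then its codon
  native_codon <- (mac_len - 3L + L) %/% 3L + 1L
  tr <- translate_cds(retained, genetic_code)
  internal <- tr$stop_positions[tr$stop_positions < native_codon]
  consequence <- if (length(internal)) {
    "PTC_INDUCING"
  } else if (frame_shift == 0L) {
    "ORF_INTACT"
  } else {
    "FRAMESHIFT_NO_STOP"
  }
  tibble(
    ies_id = ies$ies_id,
    host_gene_id = gene$gene_id,
    consequence = consequence,
    frame_shift = as.integer(frame_shift),
    first_stop_codon_index = if (length(internal)) min(internal) else NA_integer_,
    native_stop_codon_index = native_codon
  )
}

#' Annotate all exon-mapping IESs for PTC consequences
#'
#' Vectorised driver for [classify_ptc()] over an IES table; non-exonic loci
#' are skipped.
#'
#' @param loci IES tibble.
#' @param genes Gene tibble.
#' @param mac_genome Named character vector of scaffold sequences.
#' @param genetic_code `"ciliate"` (default) or `"standard"`.
#' @return A tibble with one row per exon-mapping IES (columns as
#'   [classify_ptc()], plus `ptc_inducing` logical).
#' @export
annotate_ptc <- function(loci, genes, mac_genome, genetic_code = "ciliate") {
  ex <- loci |> filter(.data$location_class == "exon")
  if (nrow(ex) == 0L) {
    return(tibble(ies_id = character(), host_gene_id = character(),
                  consequence = character(), frame_shift = integer(),
                  first_stop_codon_index = integer(),
                  native_stop_codon_index = integer(),
                  ptc_inducing = logical()))
  }
  rows <- purrr::map(seq_len(nrow(ex)), function(j) {
    ies <- ex[j, ]
    gene <- genes[genes$gene_id == ies$host_gene_id, ]
    if (nrow(gene) != 1L) {
      abort(sprintf("host gene %s of IES %s not found", ies$host_gene_id, ies$ies_id))
    }
    classify_ptc(gene, ies, mac_genome, genetic_code)
  })
  bind_rows(rows) |> mutate(ptc_inducing = .data$consequence == "PTC_INDUCING")
}

#' Permutation test for PTC enrichment in an observed IES set
#'
#' Compares the PTC-inducing fraction of an observed set of loci with its
#' expectation under random draws of the same size from a background
#' stratum. The empirical one-sided P-value uses the add-one correction
#' (1 + #{permutation fraction >= observed}) / (n_perm + 1).
#'
#' @param observed_ids Character vector of observed IES ids (subset of the
#'   background).
#' @param background Tibble with `ies_id` and `ptc_inducing` for the stratum.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return A one-row tibble: `observed_fraction`, `expected_fraction`,
#'   `p_empirical`, `n_observed`, `n_background`, `n_perm`.
#' @export
ptc_enrichment <- function(observed_ids, background, n_perm = 10000L, seed) {
  if (!all(observed_ids %in% background$ies_id)) {
    abort("observed set must be a subset of the background stratum")
  }
  n_obs <- length(observed_ids)
  if (nrow(background) < n_obs) abort("background smaller than observed set")
  if (n_obs == 0L) abort("observed set is empty")
  flag <- background$ptc_inducing
  obs_frac <- mean(flag[match(observed_ids, background$ies_id)])
  with_seed(derive_seed(seed, "ptc_perm"), {
    perm <- vapply(seq_len(n_perm), function(i) {
      mean(flag[sample.int(nrow(background), n_obs)])
    }, numeric(1))
    tibble(
      observed_fraction = obs_frac,
      expected_fraction = mean(perm),
      p_empirical = (1 + sum(perm >= obs_frac)) / (n_perm + 1),
      n_observed = n_obs,
      n_background = nrow(background),
      n_perm = as.integer(n_perm)
    )
  })
}
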