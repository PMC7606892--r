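# Shared fixtures and independent brute-force oracles. Fixtures are built in
# code; nothing is read from disk except files the tests themselves write.

# A minimal hand-built locus: scaffold = left + TA + right, one IES.
make_mini_locus <- function(left = "CCGGATCCGGAAGCTTGGCC",
                            right = "GGCCAAGCTTCCGGATCCGG",
                            interior = "GGGCCCGGGCCCGGGCCCGGGCCC") {
  ies_seq <- paste0("TA", interior, "TA")
  scaf <- paste0(left, "TA", right)
  list(
    mac_genome = c(chr1 = scaf),
    loci = tibble::tibble(
      ies_id = "ies_x",
      scaffold = "chr1",
      mac_insertion_point = nchar(left),
      ies_sequence = ies_seq,
      length = nchar(ies_seq) - 2L,
      location_class = "other",
      host_gene_id = NA_character_,
      strand_of_host = NA_character_,
      epi_class = "none"
    ),
    retained = paste0(left, ies_seq, right),
    mac_local = scaf
  )
}

# A single-CDS gene with a TA planted at a chosen codon-relative offset, plus
# an IES to splice into it. strand "+" or "-" (genomic sequence rev-comped).
make_gene_fixture <- function(n_codons = 40L, ta_codon = 15L, strand = "+",
                              interior = "GGGCCCGGGCCCGGGCCCGGGCCCG",
                              scaffold_id = "chrG", pad = 30L) {
  codon_pool <- c("GCT", "GGT", "CCA", "TCA", "CTT", "AAC", "GAA", "TAC")
  body <- sample(codon_pool, n_codons - 2L, replace = TRUE)
  body[ta_codon] <- "TAC"          # codon starting with TA -> insertion site
  cds <- paste0("ATG", paste(body, collapse = ""), "TGA")
  genomic <- if (strand == "+") cds else revcomp_chr(cds)
  scaf <- paste0(strrep("C", pad), genomic, strrep("G", pad))
  cds_off <- if (strand == "+") 3L * ta_codon else
    nchar(cds) - 3L * ta_codon - 2L   # genomic offset of the TA
  ins <- pad + cds_off
  ies_seq <- paste0("TA", interior, "TA")
  list(
    gene = tibble::tibble(
      gene_id = "geneF", scaffold = scaffold_id, strand = strand,
      cds_segments = list(cbind(start = pad, end = pad + nchar(cds)))
    ),
    ies = tibble::tibble(
      ies_id = "iesF", scaffold = scaffold_id, mac_insertion_point = ins,
      ies_sequence = ies_seq, length = nchar(ies_seq) - 2L,
      location_class = "exon", host_gene_id = "geneF",
      strand_of_host = strand, epi_class = "none"
    ),
    mac_genome = stats::setNames(scaf, scaffold_id),
    cds = cds
  )
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Naive PTC oracle: splice by plain string surgery, translate with a literal
# codon scan, locate the native stop by counting codons.
oracle_ptc <- function(gene, ies, mac_genome) {
  scaf <- mac_genome[[gene$scaffold]]
  seg <- gene$cds_segments[[1]]
  s <- substr(scaf, seg[1, "start"] + 1, seg[1, "end"])
  off <- ies$mac_insertion_point - seg[1, "start"]
  ret <- paste0(substr(s, 1, off), ies$ies_sequence, substr(s, off + 3, nchar(s)))
  if (gene$strand == "-") ret <- revcomp_chr(ret)
  nc <- nchar(ret) %/% 3
  codons <- substring(ret, 3 * (1:nc) - 2, 3 * (1:nc))
  stops <- which(codons == "TGA")
  maclen <- sum(seg[, "end"] - seg[, "start"])
  native <- (maclen - 3 + ies$length) %/% 3 + 1
  internal <- stops[stops < native]
  if (length(internal)) "PTC_INDUCING"
  else if (ies$length %% 3 == 0) "ORF_INTACT"
  else "FRAMESHIFT_NO_STOP"
}

# Hypergeometric enumeration oracle for the one-tailed Fisher test on
# rbind(c(a, b), c(c, d)), alternative: a enriched.
oracle_fisher_greater <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(xs, function(x) {
    exp(lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1))
  }, numeric(1))
  sum(probs[xs >= a])
}

# O(n^2) pair-enumeration tau-b oracle with tie correction.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
}

# Tiny deterministic truth used by several files.
small_truth <- function(seed = 42, ...) {
  simulate_truth(sim_config(n_genes = 30L, n_ies = 100L, ...), seed = seed)
}
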