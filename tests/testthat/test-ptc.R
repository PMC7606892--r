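test_that("translation uses the ciliate code by default, standard on request", {
  tr <- translate_cds("ATGTAAGGGTGA", "ciliate")
  expect_equal(tr$protein, "MQG*")           # TAA = Gln under the ciliate code
  expect_equal(tr$stop_positions, 4L)

  ts <- translate_cds("ATGTAAGGGTGA", "standard")
  expect_equal(ts$stop_positions, c(2L, 4L)) # TAA terminates immediately

  # random TGA-free sequence has no ciliate stop (scan oracle by construction)
  set.seed(5)
  pool <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                    c("A","C","G","T")), 1, paste, collapse = ""),
                  "TGA")
  cds <- paste(sample(pool, 333, replace = TRUE), collapse = "")
  expect_length(translate_cds(cds, "ciliate")$stop_positions, 0)

  expect_error(translate_cds("AT"), "codon")
  expect_error(translate_cds("ATGNNN"), "non-ACGT")
})

test_that("retained CDS construction is exact and reversible on both strands", {
  set.seed(8)
  fx <- make_gene_fixture(strand = "+", interior = strrep("GCC", 9)) # 29-nt seq
  ret <- build_retained_cds(fx$gene, fx$ies, fx$mac_genome)
  expect_equal(nchar(ret), nchar(fx$cds) + fx$ies$length)  # longer by L = 27

  # excising the eliminated segment (all but the trailing TA) restores the CDS
  off <- fx$ies$mac_insertion_point - fx$gene$cds_segments[[1]][1, "start"]
  restored <- paste0(substr(ret, 1, off),
                     substr(ret, off + fx$ies$length + 1, nchar(ret)))
  expect_identical(restored, fx$cds)

  # minus-strand construction equals the reverse complement of the genomic splice
  fxm <- make_gene_fixture(strand = "-", interior = strrep("GCC", 9))
  retm <- build_retained_cds(fxm$gene, fxm$ies, fxm$mac_genome)
  seg <- fxm$gene$cds_segments[[1]]
  scaf <- fxm$mac_genome[[1]]
  genomic <- substr(scaf, seg[1, "start"] + 1, seg[1, "end"])
  o <- fxm$ies$mac_insertion_point - seg[1, "start"]
  spliced <- paste0(substr(genomic, 1, o), fxm$ies$ies_sequence,
                    substr(genomic, o + 3, nchar(genomic)))
  expect_identical(retm, revcomp_chr(spliced))

  # boundary and mismatch errors
  bad <- fx$ies; bad$mac_insertion_point <- seg[1, "start"]
  expect_error(build_retained_cds(fx$gene, bad, fx$mac_genome), "boundary")
  bad2 <- fx$ies; bad2$scaffold <- "elsewhere"
  expect_error(build_retained_cds(fx$gene, bad2, fx$mac_genome), "mismatch")
})

test_that("PTC classification follows frame and stop content", {
  set.seed(12)
  # 27-nt eliminated segment carrying an in-frame TGA (insertion is at a codon
  # start in the fixture, so IES offset 3 is in frame)
  int_tga <- paste0("GTGAGCC", strrep("GCC", 6))      # seq TA|GTGAGCC...|TA
  fx <- make_gene_fixture(strand = "+", interior = int_tga)
  expect_equal(fx$ies$length, 27L)
  ann <- classify_ptc(fx$gene, fx$ies, fx$mac_genome)
  expect_equal(ann$consequence, "PTC_INDUCING")
  expect_equal(ann$frame_shift, 0L)

  # same length, no TGA in any frame -> ORF intact
  fx2 <- make_gene_fixture(strand = "+", interior = paste0("G", strrep("GCC", 8)))
  expect_equal(fx2$ies$length, 27L)
  ann2 <- classify_ptc(fx2$gene, fx2$ies, fx2$mac_genome)
  expect_equal(ann2$consequence, "ORF_INTACT")
  expect_true(is.na(ann2$first_stop_codon_index))

  # 26-nt segment shifts frame; TGA-free interior but the shifted downstream
  # read-through can terminate early - compare against the brute-force oracle
  fx3 <- make_gene_fixture(strand = "+", interior = strrep("GC", 12))
  expect_equal(fx3$ies$length %% 3, 2)
  ann3 <- classify_ptc(fx3$gene, fx3$ies, fx3$mac_genome)
  expect_equal(ann3$consequence, oracle_ptc(fx3$gene, fx3$ies, fx3$mac_genome))
  expect_true(ann3$consequence != "ORF_INTACT")  # frame shift forbids intact ORF
  if (ann3$consequence == "PTC_INDUCING") {
    ins_codon <- (fx3$ies$mac_insertion_point -
                    fx3$gene$cds_segments[[1]][1, "start"]) %/% 3 + 1
    expect_gte(ann3$first_stop_codon_index, ins_codon)
  }
})

test_that("classification agrees with the brute-force oracle on random fixtures", {
  set.seed(33)
  for (rep in 1:60) {
    interior_len <- sample(24:60, 1)
    interior <- paste(sample(c("A", "C", "G", "T"), interior_len,
                             replace = TRUE, prob = c(.35, .15, .15, .35)),
                      collapse = "")
    fx <- make_gene_fixture(n_codons = sample(20:60, 1),
                            ta_codon = sample(5:15, 1),
                            strand = sample(c("+", "-"), 1),
                            interior = interior)
    got <- classify_ptc(fx$gene, fx$ies, fx$mac_genome)
    expect_equal(got$consequence, oracle_ptc(fx$gene, fx$ies, fx$mac_genome),
                 label = sprintf("rep %d (%s strand)", rep, fx$gene$strand))
    if (got$frame_shift != 0L) expect_true(got$consequence != "ORF_INTACT")
  }
})

test_that("annotate_ptc covers all exonic loci of a simulated truth", {
  tr <- small_truth(seed = 51)
  ann <- annotate_ptc(tr$ies_loci, tr$genes, tr$mac_genome)
  expect_equal(nrow(ann), sum(tr$ies_loci$location_class == "exon"))
  expect_true(all(ann$consequence %in%
                    c("PTC_INDUCING", "ORF_INTACT", "FRAMESHIFT_NO_STOP")))
  shift <- ann$frame_shift != 0
  expect_true(all(ann$consequence[shift] != "ORF_INTACT"))
})

test_that("permutation enrichment behaves at the degenerate corners", {
  bg <- tibble::tibble(ies_id = sprintf("i%03d", 1:60),
                       ptc_inducing = rep(c(TRUE, FALSE), each = 30))
  # observed = entire background
  res <- ptc_enrichment(bg$ies_id, bg, n_perm = 500, seed = 2)
  expect_equal(res$observed_fraction, res$expected_fraction, tolerance = 1e-12)
  expect_gt(res$p_empirical, 0.99)

  # background without any PTC-inducing locus
  bg0 <- tibble::tibble(ies_id = bg$ies_id, ptc_inducing = FALSE)
  res0 <- ptc_enrichment(bg$ies_id[1:10], bg0, n_perm = 200, seed = 2)
  expect_equal(res0$expected_fraction, 0)

  expect_error(ptc_enrichment(c("zzz"), bg, 100, seed = 1), "subset")
  expect_error(ptc_enrichment(character(), bg, 100, seed = 1), "empty")
})

test_that("a planted PTC excess in the observed set is detected", {
  set.seed(9)
  bg <- tibble::tibble(ies_id = sprintf("i%04d", 1:400),
                       ptc_inducing = runif(400) < 0.15)
  # observed: 40 loci drawn preferentially from the PTC-inducing pool (~3x)
  w <- ifelse(bg$ptc_inducing, 3, 1)
  obs <- sample(bg$ies_id, 40, prob = w)
  res <- ptc_enrichment(obs, bg, n_perm = 2000, seed = 4)
  expect_gt(res$observed_fraction, res$expected_fraction)
  expect_lt(res$p_empirical, 0.05)
})
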