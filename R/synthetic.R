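# Ground-truth simulator: an AT-rich MAC genome with TA-bounded IES insertion
# points, single-CDS gene models, log-normal expression, and per-condition
# retention probabilities with planted multiplicative effects.

# Printed size classes of the most frequent IES lengths (bp).
IES_SIZE_CLASSES <- cbind(
  lo = c(26L, 44L, 46L, 54L, 64L, 74L, 84L, 94L),
  hi = c(30L, 45L, 50L, 60L, 70L, 80L, 90L, 100L)
)
rownames(IES_SIZE_CLASSES) <- paste0(IES_SIZE_CLASSES[, "lo"], "-",
                                     IES_SIZE_CLASSES[, "hi"])

default_effects <- function() {
  list(
    # Count of incompletely excised small exonic IESs rises in shifted
    # conditions, more than for large exonic IESs; mild changes in the
    # stable-environment line.
    list(condition = "F1_18C",    size = "small", location = "exon", multiplier = 4),
    list(condition = "F1_18C",    size = "large", location = "exon", multiplier = 2),
    list(condition = "F1_32C",    size = "small", location = "exon", multiplier = 5),
    list(condition = "F1_32C",    size = "large", location = "exon", multiplier = 2.5),
    list(condition = "F1_25C_HS", size = "small", location = "exon", multiplier = 2.4),
    list(condition = "F1_25C_HS", size = "large", location = "exon", multiplier = 1.2),
    list(condition = "F1_25C",    size = "small", location = "exon", multiplier = 1.3),
    list(condition = "F1_25C",    size = "large", location = "exon", multiplier = 0.8),
    # DCL5-sensitive large exonic IESs are excised better (retention down)
    # in the shifted conditions.
    list(condition = "F1_18C", size = "large", location = "exon",
         epi = "DCL5", multiplier = 0.5),
    list(condition = "F1_32C", size = "large", location = "exon",
         epi = "DCL5", multiplier = 0.4),
    list(condition = "F1_25C_HS", size = "large", location = "exon",
         epi = "DCL5", multiplier = 0.5)
  )
}

#' Simulation configuration
#'
#' Returns the default configuration for [simulate_truth()], with any field
#' overridable by name. Defaults emulate the study design: an F0 line grown
#' at 25C and four F1 lines (25C stable, 18C, 32C, and 25C with a daily
#' parental heat shock), an AT-rich MAC genome, a peaked IES size
#' distribution over the most frequent size classes, a baseline retention
#' mixture with most loci fully excised, and multiplicative planted effects
#' raising small-exonic-IES retention (and lowering DCL5-sensitive
#' large-exonic-IES retention) in the shifted conditions.
#'
#' @param ... Named overrides of default fields.
#' @return A named list of class `ies_sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_genes = 150L,
    n_ies = 600L,
    conditions = c("F0_25C", "F1_25C", "F1_18C", "F1_32C", "F1_25C_HS"),
    f0_condition = "F0_25C",
    size_classes = IES_SIZE_CLASSES,
    size_class_weights = c(0.36, 0.06, 0.12, 0.12, 0.10, 0.08, 0.06, 0.05),
    size_background_weight = 0.05,   # uniform over 26..100 outside the classes
    exon_fraction = 0.50,
    intergenic_fraction = 0.45,
    expr_meanlog2 = 5,
    expr_sdlog2 = 2,
    zero_expr_fraction = 0.05,
    baseline_zero_fraction = 0.90,
    baseline_beta = c(0.5, 20),
    overdispersion = 0,              # beta-binomial rho; 0 = pure binomial
    epi_fractions = c("DCL2/3" = 0.10, "DCL5" = 0.05),
    ptc_tga_rate = 0.4,              # fraction of IESs seeded with in-frame TGA
    at_content = 0.70,
    cds_codons_range = c(100L, 260L),
    intergenic_len = 250L,
    genes_per_scaffold = 25L,
    min_ies_separation = 60L,
    small_max_length = 32L,
    effects = default_effects()
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    abort(sprintf("unknown sim_config fields: %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  structure(cfg, class = c("ies_sim_config", "list"))
}

base_probs <- function(at) c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)

rand_dna <- function(n, at) {
  p <- base_probs(at)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Random CDS: starts ATG, ends with the sole ciliate stop TGA, no internal
# in-frame TGA.
rand_cds <- function(n_codons, at) {
  p <- base_probs(at)
  codons <- apply(expand.grid(names(p), names(p), names(p)), 1, paste, collapse = "")
  codons <- setdiff(codons, "TGA")
  w <- vapply(strsplit(codons, ""), function(b) prod(p[b]), numeric(1))
  body <- sample(codons, n_codons - 2L, replace = TRUE, prob = w)
  paste0("ATG", paste(body, collapse = ""), "TGA")
}

sample_ies_length <- function(n, cfg) {
  cls <- cfg$size_classes
  w <- cfg$size_class_weights / sum(cfg$size_class_weights)
  in_class <- unlist(lapply(seq_len(nrow(cls)), function(i) cls[i, "lo"]:cls[i, "hi"]))
  all_len <- 26:100
  outside <- setdiff(all_len, in_class)
  p_bg <- cfg$size_background_weight
  pick_bg <- runif(n) < p_bg & length(outside) > 0
  out <- integer(n)
  if (any(!pick_bg)) {
    ci <- sample(nrow(cls), sum(!pick_bg), replace = TRUE, prob = w)
    out[!pick_bg] <- vapply(ci, function(i) {
      sample(cls[i, "lo"]:cls[i, "hi"], 1L)
    }, integer(1))
  }
  if (any(pick_bg)) out[pick_bg] <- sample(outside, sum(pick_bg), replace = TRUE)
  out
}

# TA dinucleotide start positions (0-based) within mac[lo, hi) margin-checked.
ta_positions <- function(seqstr, lo, hi) {
  window <- substr(seqstr, lo + 1L, hi)
  m <- gregexpr("TA", window, fixed = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  as.integer(m) - 1L + lo
}

match_stratum <- function(loci, expr_class, effect, small_max_length) {
  keep <- rep(TRUE, nrow(loci))
  if (!is.null(effect$size)) {
    small <- loci$length <= small_max_length
    keep <- keep & if (effect$size == "small") small else !small
  }
  if (!is.null(effect$location)) keep <- keep & loci$location_class == effect$location
  if (!is.null(effect$epi)) keep <- keep & loci$epi_class == effect$epi
  if (!is.null(effect$expression)) {
    cls <- expr_class$expression_class[match(loci$host_gene_id, expr_class$gene_id)]
    keep <- keep & !is.na(cls) & cls == effect$expression
  }
  keep
}

#' Simulate a ground-truth dataset
#'
#' Builds a scaled-down MAC reference with TA-bounded IES insertion points,
#' single-CDS gene models, a log-normal expression table, per-IES epigenetic
#' class labels, and per-condition true retention probabilities with planted
#' multiplicative effects. Deterministic given `seed`. When `dir` is given
#' the full plain-text fixture set is also written there (FASTA, two GFF3s,
#' expression/epi/retention TSVs).
#'
#' @param config Configuration from [sim_config()].
#' @param seed Integer seed; mandatory.
#' @param dir Optional directory to write the fixture set to.
#' @return An object of class `ies_truth`: a list with `mac_genome` (named
#'   character vector of scaffold sequences), `ies_loci`, `genes`,
#'   `expression`, `conditions`, `true_retention` (tibble `ies_id`,
#'   `condition`, `p`), `planted_effects`, `n_clamped`, `config`, `seed`.
#' @export
simulate_truth <- function(config = sim_config(), seed, dir = NULL) {
  if (missing(seed)) abort("seed is mandatory for simulate_truth()")
  cfg <- config
  if (cfg$n_ies < length(cfg$effects)) {
    abort("config error: n_ies smaller than the number of planted-effect strata")
  }
  with_seed(derive_seed(seed, "truth"), {
    at <- cfg$at_content

    # --- genes and scaffolds -------------------------------------------------
    n_scaf <- max(1L, ceiling(cfg$n_genes / cfg$genes_per_scaffold))
    gene_tbl <- vector("list", cfg$n_genes)
    scaffolds <- character(n_scaf)
    spacer_regions <- list()
    gi <- 0L
    for (s in seq_len(n_scaf)) {
      scaf_id <- sprintf("scaffold_%03d", s)
      parts <- character(0)
      pos <- 0L
      spacers <- list()
      genes_here <- min(cfg$genes_per_scaffold, cfg$n_genes - gi)
      for (g in seq_len(genes_here)) {
        sp <- rand_dna(cfg$intergenic_len, at)
        spacers[[length(spacers) + 1L]] <- c(pos, pos + cfg$intergenic_len)
        parts <- c(parts, sp); pos <- pos + cfg$intergenic_len
        n_cod <- sample(cfg$cds_codons_range[1]:cfg$cds_codons_range[2], 1L)
        cds <- rand_cds(n_cod, at)
        strand <- sample(c("+", "-"), 1L)
        genomic <- if (strand == "+") cds else revcomp(cds)
        gi <- gi + 1L
        gene_tbl[[gi]] <- tibble(
          gene_id = sprintf("gene_%04d", gi),
          scaffold = scaf_id, strand = strand,
          cds_segments = list(cbind(start = pos, end = pos + nchar(genomic)))
        )
        parts <- c(parts, genomic); pos <- pos + nchar(genomic)
      }
      sp <- rand_dna(cfg$intergenic_len, at)
      spacers[[length(spacers) + 1L]] <- c(pos, pos + cfg$intergenic_len)
      parts <- c(parts, sp)
      scaffolds[s] <- paste(parts, collapse = "")
      names(scaffolds)[s] <- scaf_id
      spacer_regions[[scaf_id]] <- do.call(rbind, spacers)
    }
    genes <- bind_rows(gene_tbl)

    # --- expression ----------------------------------------------------------
    vals <- 2 ^ rnorm(cfg$n_genes, cfg$expr_meanlog2, cfg$expr_sdlog2)
    vals[runif(cfg$n_genes) < cfg$zero_expr_fraction] <- 0
    expression <- tibble(gene_id = genes$gene_id, expression = vals,
                         log2_value = ifelse(vals > 0, log2(vals), NA_real_))

    # --- IES placement -------------------------------------------------------
    n_ies <- cfg$n_ies
    u <- runif(n_ies)
    loc_class <- ifelse(u < cfg$exon_fraction, "exon",
                 ifelse(u < cfg$exon_fraction + cfg$intergenic_fraction,
                        "intergenic", "other"))
    lens <- sample_ies_length(n_ies, cfg)
    used <- lapply(names(scaffolds), function(x) integer(0))
    names(used) <- names(scaffolds)
    loci_rows <- vector("list", n_ies)
    n_placed <- 0L
    for (j in seq_len(n_ies)) {
      L <- lens[j]
      placed <- FALSE
      for (try in 1:30) {
        if (loc_class[j] == "exon") {
          g <- genes[sample(nrow(genes), 1L), ]
          seg <- g$cds_segments[[1]]
          cand <- ta_positions(scaffolds[[g$scaffold]],
                               seg[1, "start"] + 6L, seg[1, "end"] - 8L)
          scaf <- g$scaffold; host <- g$gene_id; hstrand <- g$strand
        } else {
          scaf <- sample(names(scaffolds), 1L)
          regs <- spacer_regions[[scaf]]
          r <- regs[sample(nrow(regs), 1L), ]
          cand <- ta_positions(scaffolds[[scaf]], r[1] + 6L, r[2] - 8L)
          host <- NA_character_; hstrand <- NA_character_
        }
        cand <- cand[!vapply(cand, function(p) {
          any(abs(used[[scaf]] - p) < cfg$min_ies_separation)
        }, logical(1))]
        if (!length(cand)) next
        ins <- cand[sample.int(length(cand), 1L)]
        used[[scaf]] <- c(used[[scaf]], ins)
        interior <- rand_dna(L - 2L, at)
        seq <- paste0("TA", interior, "TA")
        # seed an in-frame TGA so PTC status varies
        if (runif(1) < cfg$ptc_tga_rate) {
          if (loc_class[j] == "exon") {
            g2 <- genes[genes$gene_id == host, ]
            seg <- g2$cds_segments[[1]]
            q <- if (hstrand == "+") ins - seg[1, "start"]
                 else seg[1, "end"] - ins - 2L
            # in the retained CDS, the (rev-comped for -) IES starts at offset q;
            # choose j0 in [2, L-3] with (q + j0) %% 3 == 0
            j0 <- ((3L - (q %% 3L)) %% 3L) + 3L  # >= 3 keeps TA bounds intact
            while (j0 < 2L) j0 <- j0 + 3L
            if (j0 <= L - 3L) {
              if (hstrand == "+") {
                substr(seq, j0 + 1L, j0 + 3L) <- "TGA"
              } else {
                # forward-strand image of an in-frame TGA on the minus strand
                k0 <- (L + 2L) - j0 - 3L
                substr(seq, k0 + 1L, k0 + 3L) <- "TCA"
              }
            }
          } else if (L >= 8L) {
            j0 <- sample(2:(L - 3L), 1L)
            substr(seq, j0 + 1L, j0 + 3L) <- "TGA"
          }
        }
        n_placed <- n_placed + 1L
        loci_rows[[n_placed]] <- tibble(
          ies_id = sprintf("ies_%05d", n_placed),
          scaffold = scaf, mac_insertion_point = ins,
          ies_sequence = seq, length = L,
          location_class = loc_class[j], host_gene_id = host,
          strand_of_host = hstrand, epi_class = "none"
        )
        placed <- TRUE
        break
      }
      if (!placed) next
    }
    loci <- bind_rows(loci_rows[seq_len(n_placed)])
    if (n_placed < n_ies) {
      warn(sprintf("placed %d of %d requested IESs (TA sites exhausted)",
                   n_placed, n_ies))
    }

    # epigenetic-control labels
    ep <- cfg$epi_fractions
    u <- runif(nrow(loci))
    cum <- cumsum(ep)
    lab <- rep("none", nrow(loci))
    for (k in rev(seq_along(ep))) lab[u < cum[k]] <- names(ep)[k]
    loci$epi_class <- lab

    # --- true retention ------------------------------------------------------
    base_p <- ifelse(runif(nrow(loci)) < cfg$baseline_zero_fraction, 0,
                     stats::rbeta(nrow(loci), cfg$baseline_beta[1], cfg$baseline_beta[2]))
    expr_class <- classify_expression(expression)
    n_clamped <- 0L
    tr_rows <- list()
    eff_rows <- list()
    for (cond in cfg$conditions) {
      p <- base_p
      for (e in cfg$effects) {
        if (e$condition != cond) next
        hit <- match_stratum(loci, expr_class, e, cfg$small_max_length)
        p[hit] <- p[hit] * e$multiplier
        eff_rows[[length(eff_rows) + 1L]] <- tibble(
          condition = cond,
          size = e$size %||% NA_character_,
          location = e$location %||% NA_character_,
          epi = e$epi %||% NA_character_,
          expression = e$expression %||% NA_character_,
          multiplier = e$multiplier, n_affected = sum(hit)
        )
      }
      over <- p > 1
      if (any(over)) { n_clamped <- n_clamped + sum(over); p[over] <- 1 }
      tr_rows[[cond]] <- tibble(ies_id = loci$ies_id, condition = cond, p = p)
    }
    if (n_clamped > 0) {
      warn(sprintf("%d retention probabilities clamped to [0,1]", n_clamped))
    }
    truth <- structure(list(
      mac_genome = scaffolds,
      ies_loci = loci,
      genes = genes,
      expression = expression,
      conditions = cfg$conditions,
      true_retention = bind_rows(tr_rows),
      planted_effects = bind_rows(eff_rows),
      n_clamped = n_clamped,
      config = cfg,
      seed = seed
    ), class = "ies_truth")
    if (!is.null(dir)) write_truth_fixtures(truth, dir)
    truth
  })
}

#' @export
print.ies_truth <- function(x, ...) {
  cat(sprintf("<ies_truth> %d scaffolds, %d genes, %d IESs, %d conditions (seed %s)\n",
              length(x$mac_genome), nrow(x$genes), nrow(x$ies_loci),
              length(x$conditions), format(x$seed)))
  invisible(x)
}

#' Write the full fixture set for a simulated truth
#'
#' Writes `mac_genome.fasta`, `ies.gff3`, `genes.gff3`, `expression.tsv`,
#' `epi_class.tsv` and `true_retention.tsv` under `dir`.
#'
#' @param truth An `ies_truth` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_truth_fixtures <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- Biostrings::DNAStringSet(truth$mac_genome)
  Biostrings::writeXStringSet(fa, file.path(dir, "mac_genome.fasta"))
  write_ies_annotation(truth$ies_loci, file.path(dir, "ies.gff3"))
  write_gene_models(truth$genes, file.path(dir, "genes.gff3"))
  write_expression(truth$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(truth$ies_loci[, c("ies_id", "epi_class")],
                   file.path(dir, "epi_class.tsv"), progress = FALSE)
  readr::write_tsv(truth$true_retention, file.path(dir, "true_retention.tsv"),
                   progress = FALSE)
  invisible(dir)
}

#' Simulate per-locus junction read counts
#'
#' For every IES locus the total junction-spanning read count is
#' Poisson(`mean_coverage`) and the IES-supporting count is Binomial in the
#' locus's true retention probability for `condition` (beta-binomial when the
#' configuration sets `overdispersion > 0`).
#'
#' @param truth An `ies_truth` object.
#' @param condition Condition label (must be one of `truth$conditions`).
#' @param mean_coverage Mean junction coverage per locus (> 0).
#' @param seed Integer seed.
#' @return A junction-counts tibble: `ies_id`, `k_ies`, `k_mac`, `n_total`,
#'   `n_ambiguous`, `condition`.
#' @export
simulate_counts <- function(truth, condition, mean_coverage, seed) {
  if (!condition %in% truth$conditions) {
    abort(sprintf("unknown condition label: %s", condition))
  }
  stopifnot(mean_coverage > 0)
  tr <- truth$true_retention |> filter(.data$condition == !!condition)
  tr <- tr[match(truth$ies_loci$ies_id, tr$ies_id), ]
  with_seed(derive_seed(seed, paste0("counts:", condition)), {
    n <- rpois(nrow(tr), mean_coverage)
    p <- tr$p
    rho <- truth$config$overdispersion
    if (rho > 0) {
      s <- 1 / rho - 1
      p <- stats::rbeta(length(p), pmax(p * s, 1e-9), pmax((1 - p) * s, 1e-9))
      p[tr$p == 0] <- 0
      p[tr$p == 1] <- 1
    }
    k <- rbinom(length(n), n, p)
    tibble(ies_id = tr$ies_id, k_ies = k, k_mac = n - k,
           n_total = n, n_ambiguous = 0L, condition = condition)
  })
}

#' Simulate junction-spanning reads
#'
#' Each locus receives Poisson(`mean_coverage`) reads; each read is drawn
#' from the IES-retaining form with the locus's true retention probability,
#' otherwise from the excised MAC form. Reads are placed so that the junction
#' (the MAC seam, or one IES boundary chosen at random) is covered with at
#' least `min_flank` bases on each side. Read names encode the locus and
#' origin (`<ies_id>|<IES_PLUS|MAC>|<serial>`) as a ground-truth oracle.
#'
#' @param truth An `ies_truth` object.
#' @param condition Condition label.
#' @param read_length Read length in nt; must be at least `2 * min_flank`.
#' @param mean_coverage Mean reads per locus.
#' @param seed Integer seed.
#' @param min_flank Guaranteed junction flank in each read.
#' @return A tibble `read_id`, `sequence`, `ies_id`, `origin`.
#' @export
simulate_reads <- function(truth, condition, read_length = 100L, mean_coverage,
                           seed, min_flank = 10L) {
  if (!condition %in% truth$conditions) {
    abort(sprintf("unknown condition label: %s", condition))
  }
  if (read_length < 2L * min_flank) {
    abort("config error: read_length must be at least 2 * min_flank")
  }
  tr <- truth$true_retention |> filter(.data$condition == !!condition)
  loci <- truth$ies_loci |> left_join(tr[, c("ies_id", "p")], by = "ies_id")
  with_seed(derive_seed(seed, paste0("reads:", condition)), {
    out <- vector("list", nrow(loci))
    for (j in seq_len(nrow(loci))) {
      lc <- loci[j, ]
      n <- rpois(1L, mean_coverage)
      if (n == 0L) next
      scaf <- truth$mac_genome[[lc$scaffold]]
      i <- lc$mac_insertion_point
      ctx_lo <- max(0L, i - read_length - 2L)
      left_ctx <- substr(scaf, ctx_lo + 1L, i)               # up to insertion
      right_ctx <- substr(scaf, i + 3L, min(nchar(scaf), i + 2L + read_length + 2L))
      mac_local <- paste0(left_ctx, "TA", right_ctx)
      seam_mac <- nchar(left_ctx) + 2L                        # 0-based seam offset
      ret_local <- paste0(left_ctx, lc$ies_sequence, right_ctx)
      seam_l <- nchar(left_ctx) + 2L                          # after leading TA
      seam_r <- nchar(left_ctx) + nchar(lc$ies_sequence)      # after trailing TA
      is_plus <- runif(n) < lc$p
      seqs <- character(n)
      for (r in seq_len(n)) {
        if (is_plus[r]) {
          seam <- if (runif(1) < 0.5) seam_l else seam_r
          src <- ret_local
        } else {
          seam <- seam_mac
          src <- mac_local
        }
        a_min <- max(0L, seam - read_length + min_flank)
        a_max <- min(nchar(src) - read_length, seam - min_flank)
        a <- if (a_max <= a_min) a_min else sample(a_min:a_max, 1L)
        seqs[r] <- substr(src, a + 1L, a + read_length)
      }
      out[[j]] <- tibble(
        read_id = sprintf("%s|%s|%d", lc$ies_id,
                          ifelse(is_plus, "IES_PLUS", "MAC"), seq_len(n)),
        sequence = seqs, ies_id = lc$ies_id,
        origin = ifelse(is_plus, "IES_PLUS", "MAC")
      )
    }
    bind_rows(out)
  })
}

#' Write reads to FASTQ
#' @param reads Tibble from [simulate_reads()].
#' @param path Output FASTQ path (uncompressed).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n",
                      strrep("I", nchar(reads$sequence))), con, sep = "\n")
  }
  invisible(path)
}

#' Read a FASTQ file into a tibble
#' @param path FASTQ path.
#' @return A tibble `read_id`, `sequence`.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = sub("\\s.*$", "", names(ss)),
         sequence = unname(as.character(ss)))
}
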