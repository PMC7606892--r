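# End-to-end orchestration: simulate -> count -> IRS -> transitions -> PTC ->
# stratified statistics -> JSON report, from a single validated configuration
# with one mandatory seed. Every stochastic stage draws from an independent
# substream derived from that seed, so adding a stage never perturbs the
# random streams of earlier stages.

#' Pipeline run configuration
#'
#' Returns the default run configuration with any field overridable. Every
#' default threshold is either a study-wide filter (minimum 20 supporting
#' reads, minimum IES length 26 nt, somatic-IES threshold IRS > 0.1, 75%
#' reference interval) or a documented package choice (BH adjustment at
#' alpha 0.05, small/large split at 32 nt, ciliate genetic code, 10000
#' permutations).
#'
#' @param ... Named overrides. `sim` is a list of [sim_config()] overrides.
#' @return A named list of class `ies_run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = NULL,                 # mandatory
    out_dir = NULL,              # mandatory
    sim = list(),
    simulate_only = FALSE,
    mean_coverage = 100,
    irs_threshold = 0.1,
    ci_level = 0.75,
    alpha = 0.05,
    adjust = "BH",
    min_reads = 20L,
    min_length = 26L,
    small_max_length = 32L,
    genetic_code = "ciliate",
    n_perm = 10000L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    abort(sprintf("unknown run_config fields: %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  structure(cfg, class = c("ies_run_config", "list"))
}

#' Read a run configuration from a YAML file
#' @param path YAML file whose keys are [run_config()] fields.
#' @return An `ies_run_config` list.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$seed)) abort("validation error: seed is mandatory")
  if (is.null(cfg$out_dir)) abort("validation error: out_dir is mandatory")
  if (!is_scalar_number(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    abort("validation error: alpha must be in (0, 1)")
  }
  if (!is_scalar_number(cfg$ci_level) || cfg$ci_level <= 0 || cfg$ci_level >= 1) {
    abort("validation error: ci_level must be in (0, 1)")
  }
  if (!is_scalar_number(cfg$irs_threshold) || cfg$irs_threshold < 0 ||
      cfg$irs_threshold >= 1) {
    abort("validation error: irs_threshold must be in [0, 1)")
  }
  if (cfg$mean_coverage <= 0) abort("validation error: mean_coverage must be > 0")
  if (!cfg$adjust %in% c("BH", "none")) {
    abort("validation error: adjust must be 'BH' or 'none'")
  }
  if (!cfg$genetic_code %in% c("ciliate", "standard")) {
    abort("validation error: genetic_code must be 'ciliate' or 'standard'")
  }
  invisible(cfg)
}

log_line <- function(con, ...) writeLines(sprintf(...), con)

#' Run the full analysis pipeline
#'
#' Simulates a ground-truth dataset, draws per-condition junction counts,
#' computes filtered IES Retention Scores, calls F0-referenced retention
#' transitions for every F1 line, annotates PTC consequences of exonic IESs,
#' computes the stratified statistics (size-class count ratios and median
#' IRS profiles for exonic and intergenic loci, epigenetic-class enrichment,
#' PTC folds, exclusive overlaps across shifted lines), and writes all stage
#' outputs plus a JSON report under `config$out_dir`. Deterministic given
#' the configuration seed.
#'
#' @param config An `ies_run_config` from [run_config()].
#' @return Invisibly, a list with `truth`, `irs` (per condition),
#'   `transitions` (per F1 line), `ptc`, `stats`, and `report_path`.
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  con <- file(log_path, "w")
  on.exit(close(con))
  log_line(con, "seed=%s", format(cfg$seed))
  for (f in c("mean_coverage", "irs_threshold", "ci_level", "alpha", "adjust",
              "min_reads", "min_length", "small_max_length", "genetic_code",
              "n_perm")) {
    log_line(con, "%s=%s", f, format(cfg[[f]]))
  }
  # hash the analysis-relevant configuration, not the output location
  cfg_hash <- unclass(cfg)[setdiff(names(cfg), "out_dir")]
  log_line(con, "config_hash=%s", rlang::hash(cfg_hash))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log_line(con, "stage_failed=%s: %s", name, conditionMessage(e))
      abort(sprintf("stage %s failed: %s", name, conditionMessage(e)))
    })
  }

  # --- simulate ------------------------------------------------------------
  truth <- stage("simulate", {
    sc <- do.call(sim_config, cfg$sim)
    simulate_truth(sc, seed = cfg$seed, dir = file.path(cfg$out_dir, "fixtures"))
  })
  log_line(con, "stage=simulate n_ies=%d n_genes=%d",
           nrow(truth$ies_loci), nrow(truth$genes))
  if (isTRUE(cfg$simulate_only)) {
    write_report(list(simulate_only = TRUE,
                      n_ies = nrow(truth$ies_loci),
                      n_genes = nrow(truth$genes)),
                 file.path(cfg$out_dir, "report.json"),
                 seed = cfg$seed, config = cfg_hash)
    return(invisible(list(truth = truth,
                          report_path = file.path(cfg$out_dir, "report.json"))))
  }

  loci <- truth$ies_loci
  f0_cond <- truth$config$f0_condition
  f1_conds <- setdiff(truth$conditions, f0_cond)

  # --- counts and IRS ------------------------------------------------------
  irs_tabs <- stage("irs", {
    purrr::map(setNames(truth$conditions, truth$conditions), function(cond) {
      cts <- simulate_counts(truth, cond, cfg$mean_coverage, seed = cfg$seed)
      write_counts(cts, file.path(cfg$out_dir, sprintf("counts_%s.tsv", cond)))
      compute_irs(cts) |>
        apply_filters(loci, min_reads = cfg$min_reads, min_length = cfg$min_length)
    })
  })
  for (cond in names(irs_tabs)) {
    readr::write_tsv(irs_tabs[[cond]],
                     file.path(cfg$out_dir, sprintf("irs_%s.tsv", cond)),
                     progress = FALSE)
  }
  log_line(con, "stage=irs conditions=%s", paste(names(irs_tabs), collapse = ","))

  # --- transitions ---------------------------------------------------------
  transitions <- stage("transitions", {
    purrr::map(setNames(f1_conds, f1_conds), function(cond) {
      call_transitions(irs_tabs[[f0_cond]], irs_tabs[[cond]],
                       level = cfg$ci_level, alpha = cfg$alpha,
                       adjust = cfg$adjust)
    })
  })
  for (cond in names(transitions)) {
    readr::write_tsv(tidy(transitions[[cond]]),
                     file.path(cfg$out_dir, sprintf("transitions_%s.tsv", cond)),
                     progress = FALSE)
  }
  log_line(con, "stage=transitions")

  # --- PTC annotation ------------------------------------------------------
  ptc <- stage("ptc", {
    annotate_ptc(loci, truth$genes, truth$mac_genome,
                 genetic_code = cfg$genetic_code)
  })
  readr::write_tsv(ptc, file.path(cfg$out_dir, "ptc_annotation.tsv"),
                   progress = FALSE)
  log_line(con, "stage=ptc n_exonic=%d n_ptc=%d", nrow(ptc), sum(ptc$ptc_inducing))

  # --- stratified statistics ----------------------------------------------
  stats_out <- stage("stats", {
    strata <- label_strata(loci, truth$expression,
                           small_max_length = cfg$small_max_length)
    retained_ids <- function(cond) {
      tab <- irs_tabs[[cond]]
      tab$ies_id[tab$passed_filters & !is.na(tab$irs) & tab$irs > cfg$irs_threshold]
    }
    per_line <- purrr::map(setNames(f1_conds, f1_conds), function(cond) {
      cr_ex <- count_ratio_by_size_class(
        irs_tabs[[f0_cond]], irs_tabs[[cond]], loci, location = "exon",
        irs_threshold = cfg$irs_threshold, small_max_length = cfg$small_max_length)
      cr_ig <- count_ratio_by_size_class(
        irs_tabs[[f0_cond]], irs_tabs[[cond]], loci, location = "intergenic",
        irs_threshold = cfg$irs_threshold, small_max_length = cfg$small_max_length)
      med <- median_irs_by_size_class(
        irs_tabs[[cond]], loci, location = "exon",
        irs_threshold = cfg$irs_threshold, small_max_length = cfg$small_max_length)
      # epigenetic enrichment of retained exonic IESs over the exonic background
      ret <- retained_ids(cond)
      bg <- loci |>
        filter(.data$location_class == "exon",
               .data$ies_id %in% irs_tabs[[cond]]$ies_id[irs_tabs[[cond]]$passed_filters])
      ret_ex <- intersect(ret, bg$ies_id)
      epi <- if (length(ret_ex) > 0) {
        epi_enrichment(ret_ex, bg[, c("ies_id", "epi_class")], "DCL2/3")
      } else NULL
      # PTC folds among retained exonic IESs, epi vs non-epi
      ptc_ret <- ptc |> filter(.data$ies_id %in% ret_ex) |>
        left_join(loci[, c("ies_id", "epi_class")], by = "ies_id")
      fold_of <- function(sub) {
        if (nrow(sub) == 0 || sum(!sub$ptc_inducing) == 0) return(NULL)
        ptc_fold(sum(sub$ptc_inducing), sum(!sub$ptc_inducing))
      }
      list(
        count_ratio_exon = cr_ex, count_ratio_intergenic = cr_ig,
        median_irs_exon = med,
        epi_enrichment = epi,
        ptc_fold_epi = fold_of(ptc_ret |> filter(.data$epi_class != "none")),
        ptc_fold_nonepi = fold_of(ptc_ret |> filter(.data$epi_class == "none")),
        n_retained = length(ret)
      )
    })
    shifted <- intersect(c("F1_18C", "F1_32C", "F1_25C_HS"), f1_conds)
    stable <- intersect("F1_25C", f1_conds)
    excl <- if (length(shifted) >= 2) {
      exclusive_overlap(purrr::map(setNames(truth$conditions, truth$conditions),
                                   retained_ids),
                        include = shifted, exclude = stable, loci = loci,
                        small_max_length = cfg$small_max_length)
    } else NULL
    list(per_line = per_line, exclusive_overlap = excl, strata = strata)
  })
  log_line(con, "stage=stats")

  # --- report --------------------------------------------------------------
  report <- list(
    n_ies = nrow(loci),
    n_genes = nrow(truth$genes),
    conditions = truth$conditions,
    transitions = purrr::map(transitions, function(tr) as.list(glance(tr)[1, ])),
    per_line = purrr::map(stats_out$per_line, function(st) {
      list(
        n_retained = st$n_retained,
        pooled_count_ratio_exon = purrr::transpose(as.list(st$count_ratio_exon$pooled)),
        pooled_count_ratio_intergenic = purrr::transpose(as.list(st$count_ratio_intergenic$pooled)),
        epi_enrichment = if (!is.null(st$epi_enrichment)) as.list(st$epi_enrichment[1, ]),
        ptc_fold_epi = if (!is.null(st$ptc_fold_epi)) as.list(st$ptc_fold_epi[1, ]),
        ptc_fold_nonepi = if (!is.null(st$ptc_fold_nonepi)) as.list(st$ptc_fold_nonepi[1, ])
      )
    }),
    exclusive_overlap = if (!is.null(stats_out$exclusive_overlap)) {
      list(ies_ids = stats_out$exclusive_overlap$ies_ids,
           breakdown = if (!is.null(stats_out$exclusive_overlap$breakdown)) {
             as.list(stats_out$exclusive_overlap$breakdown[1, ])
           })
    }
  )
  report_path <- file.path(cfg$out_dir, "report.json")
  write_report(report, report_path, seed = cfg$seed, config = cfg_hash)
  log_line(con, "stage=report path=%s", report_path)

  invisible(list(truth = truth, irs = irs_tabs, transitions = transitions,
                 ptc = ptc, stats = stats_out, report_path = report_path))
}
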