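#' Run the full domestication-scan pipeline
#'
#' Orchestrates the whole analysis chain on either a simulated study or
#' user-supplied files: ingest -> site filters -> windowed theta-pi ratio
#' scan -> sweep calling -> gene intersection -> in-silico PCR genotyping ->
#' allele-frequency / Fst survey -> MYB subgroup classification ->
#' genotype-phenotype association. Intermediate tables are written to
#' `out_dir` as they are produced, together with a `state.json` marker, so a
#' partial failure leaves completed intermediates behind; any stage error
#' aborts with the stage name. Given the same inputs and seed the report is
#' identical from run to run.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed driving the simulation and bootstrap.
#' @param sim A [simulation_config()] used when no `vcf` is given.
#' @param vcf,panel,gff Optional input file paths; when `vcf` is set the
#'   pipeline ingests files instead of simulating (stages needing allele
#'   templates or phenotypes are then skipped unless the files exist
#'   alongside).
#' @param max_missing,min_maf Site-filter thresholds (see
#'   [apply_variant_filters()]).
#' @param window_size,step,top_fraction,min_overlap Scan and sweep-calling
#'   parameters (see [pi_ratio_scan()], [call_sweeps()], [genes_in_sweeps()]).
#' @param alpha Significance level for the association stage.
#' @param bootstrap_replicates Bootstrap replicates for the classification
#'   stage, default 100.
#' @return A `pipeline_report` list; also written to `report.json`.
#' @export
run_pipeline <- function(out_dir, seed = 7, sim = simulation_config(),
                         vcf = NULL, panel = NULL, gff = NULL,
                         max_missing = 0.20, min_maf = 0.05,
                         window_size = 50000, step = 5000,
                         top_fraction = 0.05, min_overlap = 0.10,
                         alpha = 0.05, bootstrap_replicates = 100) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list(completed = character(0), seed = seed)
  log_msg <- function(...) message(sprintf("[pome-sweep %s] %s",
                                           format(Sys.time(), "%H:%M:%S"),
                                           sprintf(...)))
  save_state <- function(stage) {
    state$completed <<- c(state$completed, stage)
    jsonlite::write_json(state, file.path(out_dir, "state.json"),
                         auto_unbox = TRUE)
  }
  stage <- function(name, expr) {
    log_msg("stage: %s", name)
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      cl <- conditionCall(e)
      abort(sprintf("pipeline stage '%s' failed: %s%s", name,
                    conditionMessage(e),
                    if (is.null(cl)) "" else
                      paste0(" (in ", paste(deparse(cl), collapse = " "), ")")))
    })
    log_msg("stage %s done (%.1fs)", name,
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
    save_state(name)
    out
  }
  tsv <- function(x, fname) {
    write.table(as.data.frame(x), file.path(out_dir, fname), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  inputs <- stage("ingest", {
    if (is.null(vcf)) {
      st <- simulate_domestication(sim, seed = seed)
      write_study(st, file.path(out_dir, "fixtures"))
      list(gm = st$genotypes, panel = st$panel, genes = st$genes, study = st)
    } else {
      if (!file.exists(vcf)) abort(paste0("input VCF not found: ", vcf))
      pn <- read_panel(panel)
      list(gm = read_vcf(vcf, pn), panel = pn,
           genes = if (!is.null(gff)) read_gff(gff) else NULL, study = NULL)
    }
  })
  study <- inputs$study

  filtered <- stage("filter", {
    fl <- apply_variant_filters(inputs$gm, max_missing, min_maf)
    tsv(fl$report, "filter_report.tsv")
    fl
  })

  sweeps <- stage("scan", {
    scan <- pi_ratio_scan(filtered$genotypes, inputs$panel,
                          window_size = window_size, step = step)
    calls <- call_sweeps(scan, top_fraction)
    tsv(scan_to_bed(calls$windows), "windows.tsv")
    tsv(calls$intervals, "sweep_intervals.tsv")
    calls
  })

  gene_hits <- stage("gene_hits", {
    if (is.null(inputs$genes)) NULL else {
      hits <- genes_in_sweeps(sweeps$intervals, inputs$genes, min_overlap)
      if (nrow(hits) > 0) {
        hits$is_myb <- grepl("family=MYB", inputs$genes$attributes[
          match(hits$gene_id, inputs$genes$gene_id)])
      }
      tsv(hits, "sweep_gene_hits.tsv")
      hits
    }
  })

  survey <- stage("survey", {
    if (is.null(study)) NULL else {
      cls <- focal_genotype_classes(study$genotypes, study$truth$focal_pos)
      calls <- dplyr::left_join(cls, study$panel, by = "sample_id") |>
        dplyr::mutate(call = c(TT = "hom_no_insertion", Tt = "heterozygous",
                               tt = "hom_insertion")[.data$genotype_class])
      freq <- allele_frequency_table(calls, group = "pool")
      rec <- split(freq, freq$group)
      fst <- pairwise_fst(rec[["wild"]], rec[["cultivated"]])
      tsv(freq, "allele_frequencies.tsv")
      tsv(fst, "fst.tsv")
      list(frequencies = freq, fst = fst, calls = calls)
    }
  })

  classification <- stage("classify", {
    myb <- simulate_myb_alignment(seed = seed)
    tree <- bootstrap_support(myb$alignment, replicates = bootstrap_replicates,
                              seed = seed)
    asg <- assign_subgroup(tree, myb$reference_labels)
    ape::write.tree(tree, file.path(out_dir, "myb_tree.nwk"))
    tsv(asg, "subgroup_assignments.tsv")
    list(assignments = asg, truth = myb$truth)
  })

  association <- stage("associate", {
    if (is.null(study)) NULL else {
      fit <- anova_lsd(study$phenotypes, alpha = alpha)
      tsv(tidy(fit), "association_groups.tsv")
      fit
    }
  })

  report <- list(
    provenance = list(
      seed = seed,
      package_version = as.character(utils::packageVersion("pomesweep")),
      config_hash = rlang::hash(list(sim = if (is.null(vcf)) sim else NULL,
                                     vcf = vcf, max_missing = max_missing,
                                     min_maf = min_maf,
                                     window_size = window_size, step = step,
                                     top_fraction = top_fraction,
                                     min_overlap = min_overlap, alpha = alpha))
    ),
    filter = list(n_input_sites = nrow(inputs$gm$sites),
                  n_removed = nrow(filtered$report),
                  n_retained = nrow(filtered$genotypes$sites)),
    sweep = list(threshold = sweeps$threshold,
                 n_windows = nrow(sweeps$windows),
                 n_called = sum(sweeps$windows$called),
                 n_intervals = nrow(sweeps$intervals)),
    gene_hits = if (!is.null(gene_hits)) as.data.frame(gene_hits),
    allele_frequencies = if (!is.null(survey)) as.data.frame(survey$frequencies),
    fst = if (!is.null(survey)) as.data.frame(survey$fst),
    subgroup_assignments = as.data.frame(classification$assignments),
    association = if (!is.null(association))
      list(groups = as.data.frame(tidy(association)),
           summary = as.data.frame(glance(association)))
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  save_state("report")
  structure(report, class = c("pipeline_report", "list"))
}

# windows tibble in BED-like output convention (0-based half-open), used
# only on output; all internal coordinates stay 1-based inclusive
scan_to_bed <- function(windows) {
  dplyr::transmute(windows,
                   chrom = .data$chrom, start0 = .data$start - 1L,
                   end = .data$end, pi_wild = .data$pi_wild,
                   pi_cult = .data$pi_cult, ratio = .data$ratio,
                   status = .data$status,
                   called = if ("called" %in% names(windows)) .data$called else NA)
}

#' One-command synthetic-study demonstration
#'
#' Simulates the default study, runs the full pipeline on it and returns the
#' report. A compact end-to-end smoke run of every stage.
#'
#' @param out_dir Output directory, default a fresh temporary directory.
#' @param seed Seed, default 7.
#' @return The `pipeline_report`.
#' @export
run_demo <- function(out_dir = file.path(tempdir(), "pomesweep-demo"),
                     seed = 7) {
  run_pipeline(out_dir, seed = seed)
}
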