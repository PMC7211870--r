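#' Run configuration for the analysis pipeline
#'
#' A declarative configuration object carrying input paths, prior bounds,
#' simulation sizes and the seed.  Defaults reproduce the study settings:
#' the prior bounds of [default_priors()], a 1% rejection tolerance, a
#' six-year generation time, 14 loci and the 91/414/40 sampling design.
#'
#' @param ... named overrides of the defaults (unknown names are an
#'   error).  Commonly: `genepop`, `fasta`, `metadata`, `loglik`,
#'   `qmatrix` (input paths); `out_dir`; `population_labels`;
#'   `n_per_scenario`; `tolerance`; `generation_time`; `seed`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    genepop = NULL, fasta = NULL, metadata = NULL,
    loglik = NULL, qmatrix = NULL,
    out_dir = ".",
    population_labels = c("GB", "Irish1", "Irish2"),
    sample_sizes = c(91, 414, 40),
    n_loci = 14,
    priors = default_priors(),
    n_per_scenario = 10000,
    chunk_size = 1000,
    tolerance = 0.01,
    generation_time = 6,
    motif = 2,
    q_threshold = 0.85,
    seed = 1)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

# provenance header + config echo written next to every command's output
write_run_log <- function(config, stage, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# badgerabc ", as.character(packageVersion("badgerabc")),
           " | stage: ", stage),
    paste0("# date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("# seed: ", config$seed),
    "# config:",
    paste0("#   ", names(unclass(config)), " = ",
           vapply(unclass(config), function(v)
             paste(utils::capture.output(str(v, give.head = FALSE)),
                   collapse = " "), ""))), con)
  invisible(path)
}

stage_out <- function(config, filename) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  file.path(config$out_dir, filename)
}

#' Pipeline commands
#'
#' Thin orchestration layer tying the modules into the study workflow.
#' Each command reads its inputs from the configuration, writes delimited
#' outputs plus a provenance log (`<stage>.log`) into `out_dir`, and is
#' idempotent given a seed.
#'
#' * `run_synth()` generates the synthetic dataset and writes GENEPOP,
#'   FASTA and metadata files.
#' * `run_stats()` writes the per-population summary-index table.
#' * `run_haplo()` assigns haplotypes and writes per-group frequencies.
#' * `run_simulate()` builds the ABC reference table.
#' * `run_abc()` runs rejection, scenario choice and parameter posteriors.
#' * `run_evanno()` writes the delta-K table.
#'
#' @param config a [run_config()].
#' @param reference_table for `run_abc()`, a reference table data frame or
#'   the path written by `run_simulate()`.
#' @return Each command returns its main result invisibly (and writes
#'   files); see the individual sections.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_synth <- function(config) {
  set.seed(config$seed)
  design <- study_design(n_gb = config$sample_sizes[1],
                         n_irish1 = config$sample_sizes[2],
                         n_irish2 = config$sample_sizes[3],
                         n_loci = config$n_loci, seed = config$seed)
  ds <- generate_dataset(design)
  write_genepop(ds$genotypes, stage_out(config, "synthetic.genepop"))
  write_fasta(ds$sequences, stage_out(config, "synthetic_mtdna.fasta"))
  write.table(ds$metadata, stage_out(config, "synthetic_metadata.csv"),
              sep = ",", row.names = FALSE, quote = FALSE)
  write_run_log(config, "synth", stage_out(config, "synth.log"))
  invisible(ds)
}

#' @rdname pipeline
#' @export
run_stats <- function(config) {
  if (is.null(config$genepop)) stop("stats stage: config$genepop is not set")
  tab <- read_genepop(config$genepop)
  pops <- populations(tab)
  out <- population_summary(tab)
  write.table(out, stage_out(config, "population_summary.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write_run_log(config, "stats", stage_out(config, "stats.log"))
  invisible(out)
}

#' @rdname pipeline
#' @export
run_haplo <- function(config) {
  if (is.null(config$fasta)) stop("haplo stage: config$fasta is not set")
  seqs <- read_fasta(config$fasta)
  assign <- assign_haplotypes(seqs, synthetic_haplotype_catalogue())
  groups <- if (!is.null(config$metadata)) {
    md <- read_metadata(config$metadata)
    md$region[match(assign$individual_id, md$id)]
  } else rep("all", nrow(assign))
  freq <- haplotype_frequencies(assign, groups)
  write.table(freq, stage_out(config, "haplotype_frequencies.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write_run_log(config, "haplo", stage_out(config, "haplo.log"))
  invisible(freq)
}

#' @rdname pipeline
#' @export
run_simulate <- function(config) {
  specs <- list(scenario_spec("divergence", config$priors),
                scenario_spec("admixture", config$priors))
  ref <- build_reference_table(specs, config$n_per_scenario,
                               config$sample_sizes, config$n_loci,
                               seed = config$seed,
                               chunk_size = config$chunk_size,
                               motif = config$motif)
  write.table(ref, stage_out(config, "reference_table.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write_run_log(config, "simulate", stage_out(config, "simulate.log"))
  invisible(ref)
}

#' @rdname pipeline
#' @export
run_abc <- function(config, reference_table = NULL) {
  if (is.null(config$genepop)) stop("abc stage: config$genepop is not set")
  if (is.null(reference_table))
    reference_table <- stage_out(config, "reference_table.tsv")
  ref <- if (is.character(reference_table))
    read.table(reference_table, header = TRUE, sep = "\t")
  else reference_table
  tab <- read_genepop(config$genepop)
  obs <- compute_observed_summaries(tab, populations(tab)[1:3],
                                    motif = config$motif)
  rej <- abc_rejection(ref, obs, tolerance = config$tolerance)
  scen <- scenario_posterior(rej$accepted, rej$distances, obs)
  winner <- scen$scenario[which.max(scen$posterior)]
  acc_w <- rej$accepted$scenario == winner
  par_post <- NULL
  if (sum(acc_w) >= 50) {
    par_post <- parameter_posterior(rej$accepted[acc_w, ],
                                    rej$distances[acc_w], obs,
                                    priors = config$priors)
    par_tab <- par_post$summary
    time_rows <- par_tab$parameter %in% c("t_recent", "t_deep")
    years <- par_tab[time_rows, ]
    years[, c("mean", "median", "q025", "q975")] <-
      generations_to_years(years[, c("mean", "median", "q025", "q975")],
                           config$generation_time)
    years$parameter <- paste0(years$parameter, "_years")
  } else {
    warning("fewer than 50 accepted rows for scenario ", winner,
            "; parameter posteriors skipped")
    par_tab <- years <- NULL
  }
  write.table(scen, stage_out(config, "scenario_posterior.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  if (!is.null(par_tab))
    write.table(rbind(par_tab, years),
                stage_out(config, "parameter_posterior.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  write_run_log(config, "abc", stage_out(config, "abc.log"))
  invisible(list(scenario = scen, parameters = par_post,
                 rejection = rej, observed = obs))
}

#' @rdname pipeline
#' @export
run_evanno <- function(config) {
  if (is.null(config$loglik)) stop("evanno stage: config$loglik is not set")
  tbl <- read_loglik_table(config$loglik)
  dk <- evanno_delta_k(tbl)
  write.table(dk, stage_out(config, "delta_k.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write_run_log(config, "evanno", stage_out(config, "evanno.log"))
  invisible(dk)
}
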