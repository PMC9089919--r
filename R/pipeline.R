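# End-to-end pipeline: allele calling -> subpopulation statistics ->
# partitioned dN/dS -> codon site models (-> trans-species polymorphism when
# a multi-species panel is supplied), with a machine-readable JSON report.

#' Pipeline configuration with study defaults
#'
#' Defaults reproduce the study settings: 242-nt amplicon, 80 codons after a
#' 2-nt frame offset, admixed individuals merged into the northern
#' subpopulation, the packaged 18-codon ABS mask, 1000 bootstrap replicates.
#'
#' @param clones A `clone_set` (or path to a clone FASTA).
#' @param labels Named character vector individual -> subpop (or path to a
#'   labels TSV).
#' @param out_dir Output directory (NULL: no files written).
#' @param frame_offset,n_codons,expected_length Amplicon geometry.
#' @param merge_admixed_into Subpopulation receiving admixed individuals.
#' @param mask_path ABS mask file (NULL: packaged default).
#' @param bootstrap_reps Codon-bootstrap replicates for dN/dS SEs.
#' @param models Site models to fit.
#' @param restarts Optimizer starts per site model.
#' @param freq Codon frequency model for site models.
#' @param species_panel Optional named sequence vector (`Species|Allele`
#'   headers) for the trans-species polymorphism stage.
#' @param seed Integer seed for every stochastic stage.
#' @param prefix Allele naming prefix.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(clones, labels, out_dir = NULL,
                            frame_offset = 2L, n_codons = 80L,
                            expected_length = 3L * n_codons + frame_offset,
                            merge_admixed_into = "north", mask_path = NULL,
                            bootstrap_reps = 1000L,
                            models = c("M1a", "M2a", "M7", "M8"),
                            restarts = 3L, freq = "f3x4",
                            species_panel = NULL, seed = 1L,
                            prefix = "Gugu") {
  if (is.character(clones) && length(clones) == 1L) clones <- read_clone_fasta(clones)
  if (is.character(labels) && length(labels) == 1L) labels <- read_labels(labels)
  cfg <- list(clones = clones, labels = labels, out_dir = out_dir,
              frame_offset = as.integer(frame_offset),
              n_codons = as.integer(n_codons),
              expected_length = as.integer(expected_length),
              merge_admixed_into = merge_admixed_into, mask_path = mask_path,
              bootstrap_reps = as.integer(bootstrap_reps), models = models,
              restarts = as.integer(restarts), freq = freq,
              species_panel = species_panel, seed = as.integer(seed),
              prefix = prefix)
  stopifnot(cfg$frame_offset >= 0L, cfg$n_codons > 0L,
            cfg$expected_length > 0L, cfg$bootstrap_reps >= 0L,
            cfg$merge_admixed_into %in% c("north", "east"),
            all(cfg$models %in% c("M0", "M1a", "M2a", "M7", "M8")))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Stages: allele calling, subpopulation statistics, NG86 partitioned dN/dS,
#' codon site models with LRTs and selected-site identification, and (when a
#' species panel is configured) the trans-species polymorphism analysis.
#' Every stochastic stage is seeded from the config, so identical configs
#' give identical reports.
#'
#' @param config A `pipeline_config`.
#' @return A report list (also written as JSON plus per-stage TSVs when
#'   `out_dir` is set).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(tool = "drbdiv",
                 version = as.character(utils::packageVersion("drbdiv")),
                 seed = config$seed,
                 config_hash = .config_hash(config))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  calling <- stage("call-alleles", call_alleles(
    config$clones, config$labels, n_codons = config$n_codons,
    frame_offset = config$frame_offset,
    expected_length = config$expected_length, prefix = config$prefix))
  gm <- calling$genotypes
  report$alleles <- list(
    n_functional = sum(attr(calling$alleles, "status") == "functional"),
    n_pseudogene = sum(attr(calling$alleles, "status") == "pseudogene"),
    n_rejected_singletons = length(calling$rejected_singletons),
    names = names(calling$alleles))

  report$stats <- stage("stats", .stats_stage(gm, config$merge_admixed_into))

  fn_alleles <- calling$alleles[attr(calling$alleles, "status") == "functional"]
  mask <- load_abs_mask(config$mask_path, config$n_codons)
  inframe <- vapply(fn_alleles, function(s) {
    paste0(inframe_codons(s, config$frame_offset), collapse = "")
  }, character(1))
  report$dnds <- stage("dnds", partitioned_rates(
    inframe, mask, bootstrap_reps = config$bootstrap_reps, seed = config$seed))

  if (length(inframe) >= 3L) {
    report$site_models <- stage("sitemodels", .site_model_stage(
      inframe, config$models, config$restarts, config$freq, config$seed, mask))
  }

  if (!is.null(config$species_panel)) {
    report$tsp <- stage("tsp", .tsp_stage(config$species_panel))
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(calling$alleles, file.path(config$out_dir, "alleles.fasta"))
    write_genotype_tsv(gm, file.path(config$out_dir, "genotypes.tsv"))
    utils::write.table(report$dnds, file.path(config$out_dir, "dnds.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(.report_json(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

.config_hash <- function(config) {
  flat <- config[setdiff(names(config),
                         c("clones", "labels", "species_panel", "out_dir"))]
  key <- paste(vapply(flat, function(x) paste(format(x), collapse = ","), ""),
               collapse = ";")
  # small deterministic fingerprint without extra dependencies
  sprintf("%08x", sum(utf8ToInt(key) * seq_along(utf8ToInt(key))) %% .Machine$integer.max)
}

.stats_stage <- function(gm, merge_into) {
  div <- summarize_diversity(gm, merge_into)
  fn <- names(gm$status)[gm$status == "functional"]
  # linked-pair contrast: the two most frequent co-occurring alleles after
  # the top allele, matching the study's *02/*03 test when present
  out <- list(mean_functional = as.list(div$mean_functional),
              mean_pseudogene = as.list(div$mean_pseudogene),
              max_alleles = div$max_alleles,
              locus_lower_bound = div$locus_lower_bound)
  if (length(fn) >= 3L) {
    cc <- carrier_counts(gm, fn[2:3], mode = "all", merge_admixed_into = merge_into)
    tab <- cbind(cc$carriers, cc$n - cc$carriers)
    if (sum(tab) > 0 && nrow(tab) == 2L) {
      out$pair_contrast <- list(alleles = fn[2:3],
                                carriers = stats::setNames(cc$carriers, cc$subpop),
                                n = stats::setNames(cc$n, cc$subpop),
                                fisher_p = fisher_exact_two_sided(tab))
    }
  }
  sp <- unname(merge_admixed(gm, merge_into)$subpop)
  counts <- rowSums(gm$presence[, gm$status == "functional", drop = FALSE])
  sps <- sort(unique(sp))
  if (length(sps) == 2L &&
      stats::var(counts[sp == sps[1]]) + stats::var(counts[sp == sps[2]]) > 0) {
    wt <- welch_t_test(counts[sp == sps[1]], counts[sp == sps[2]])
    out$mean_alleles_t_test <- wt
  }
  out
}

.site_model_stage <- function(inframe, models, restarts, freq, seed, mask) {
  tree <- nj_tree_from_sequences(inframe)
  fits <- list()
  for (m in models) {
    fits[[m]] <- fit_site_model(inframe, tree = tree, model = m, freq = freq,
                                restarts = restarts, seed = seed)
  }
  out <- list(lnL = lapply(fits, `[[`, "lnL"),
              params = lapply(fits, `[[`, "params"))
  if (all(c("M1a", "M2a") %in% models)) {
    out$lrt_M1a_M2a <- likelihood_ratio_test(fits$M1a, fits$M2a)
  }
  if (all(c("M7", "M8") %in% models)) {
    out$lrt_M7_M8 <- likelihood_ratio_test(fits$M7, fits$M8)
  }
  # selected sites are interpreted only when the positive-selection model is
  # supported by its LRT; without that support the M1a-M2a ridge (omega2 ~ 1
  # absorbing the neutral class) makes class posteriors meaningless
  lrt_of <- list(M2a = out$lrt_M1a_M2a, M7 = NULL, M8 = out$lrt_M7_M8)
  for (m in intersect(c("M2a", "M8"), models)) {
    supported <- is.null(lrt_of[[m]]) || lrt_of[[m]]$p < 0.05
    sel <- if (supported) {
      identify_selected_sites(fits[[m]], threshold = 0.95, method = "NEB")
    } else {
      data.frame(site = integer(0), posterior = numeric(0))
    }
    out$selected_sites[[m]] <- list(
      lrt_supported = supported, sites = sel$site, posterior = sel$posterior,
      in_abs_mask = sel$site %in% mask$positions)
  }
  out
}

.tsp_stage <- function(panel) {
  groups <- identical_allele_groups(panel, overlap_rule = "trimmed")
  shared <- Filter(function(g) isTRUE(attr(g, "tsp_detected")), groups)
  # one tip per distinct sequence for the tree (identical records collapse)
  rep_ix <- !duplicated(unname(panel))
  tree_aln <- panel[rep_ix]
  species <- vapply(strsplit(names(panel), "|", fixed = TRUE), `[[`, "", 1L)
  names(species) <- names(panel)
  tree <- nj_tree_from_sequences(tree_aln)
  mono <- species_monophyly(tree, species[names(tree_aln)])
  list(n_groups = length(groups),
       shared_groups = lapply(shared, function(g) {
         paste(g$species, g$allele, sep = "|")
       }),
       monophyly = mono,
       tsp_detected = isTRUE(attr(mono, "tsp_detected")) || length(shared) > 0L)
}

# drop non-serializable bulk before writing JSON
.report_json <- function(report) {
  report$site_models$fits <- NULL
  report
}
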