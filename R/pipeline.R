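#' @name cli_pipeline
#' @title End-to-end discovery and evolution runs
#'
#' @description
#' Orchestration of the full chain: simulate a cohort, sequence it, call
#' alleles with replicate confirmation, annotate ORFs, and (separately)
#' run the evolutionary analyses — tree + lineage table + exon-partition
#' dN/dS report + recurrent-event catalogue. One global seed fans out to
#' per-stage seeds through a fixed deterministic derivation, so a rerun at
#' the same seed reproduces every artifact byte for byte. A thin command
#' line wrapper is installed under `inst/scripts/mhcfkit.R`.
NULL

#' Build a pipeline configuration
#'
#' @param profile a [species_profile()].
#' @param n_animals cohort size.
#' @param depth,error_rate,chimera_rate,n_replicates read simulation
#'   parameters.
#' @param min_identity,min_cluster_size,max_barcode_mismatch calling
#'   thresholds.
#' @param library_fraction fraction of the repertoire preloaded as the
#'   known-allele library (the rest must be rediscovered de novo).
#' @param chimerism_rate fraction of animals with a chimeric twin.
#' @param seed global seed; all stage seeds derive from it.
#' @param outdir optional output directory for artifact files.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(profile, n_animals = 10, depth = 50,
                            error_rate = 0.005, chimera_rate = 0,
                            n_replicates = 2, min_identity = 0.98,
                            min_cluster_size = 5, max_barcode_mismatch = 1,
                            library_fraction = 0, chimerism_rate = 0,
                            seed = 1, outdir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

write_artifacts <- function(artifacts, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(artifacts)) {
    a <- artifacts[[nm]]
    p <- file.path(outdir, nm)
    if (is.data.frame(a)) {
      write.table(a, p, sep = "\t", quote = FALSE, row.names = FALSE)
    } else if (is.character(a) && !is.null(names(a))) {
      write_fasta(a, p)
    } else if (inherits(a, "phylo")) {
      ape::write.tree(a, p)
    } else next
    paths <- c(paths, p)
  }
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(outdir, "MANIFEST.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest
}

#' Run the allele-discovery half of the pipeline
#'
#' simulate -> sequence -> call -> annotate. Returns the truth objects next
#' to the calls so that recovery can be audited; when `outdir` is set, the
#' genotype table, novel-allele FASTA, annotation report and a hash manifest
#' are written as TSV/FASTA.
#'
#' @param config a [pipeline_config()].
#' @return list with `repertoire`, `cohort`, `reads`, `calls`,
#'   `annotation` (per confirmed call), `recovery` (per-animal comparison
#'   with truth), and `manifest` when files were written.
#' @export
run_discovery <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  prof <- config$profile
  prof$seed <- derive_seed(config$seed, "repertoire")
  rep <- generate_repertoire(prof)
  cohort <- generate_cohort(rep, n_animals = config$n_animals,
                            chimerism_rate = config$chimerism_rate,
                            seed = derive_seed(config$seed, "cohort"))
  sim <- simulate_amplicon_reads(cohort, rep, depth = config$depth,
                                 error_rate = config$error_rate,
                                 chimera_rate = config$chimera_rate,
                                 n_replicates = config$n_replicates,
                                 seed = derive_seed(config$seed, "reads"))
  library <- character(0)
  if (config$library_fraction > 0) {
    k <- max(1, floor(config$library_fraction * nrow(rep$alleles)))
    library <- setNames(rep$alleles$sequence[seq_len(k)],
                        rep$alleles$allele_id[seq_len(k)])
  }
  calls <- call_alleles(sim$reads, sim$manifest, sim$primers,
                        library = library,
                        min_identity = config$min_identity,
                        min_cluster_size = config$min_cluster_size,
                        max_barcode_mismatch = config$max_barcode_mismatch,
                        min_replicates = 2)
  accepted <- calls[calls$status %in% c("known_match", "confirmed_novel"), ,
                    drop = FALSE]
  ann <- lapply(unique(accepted$sequence), function(s)
    tryCatch(classify_orf(s, reference = rep$reference),
             error = function(e) NULL))
  names(ann) <- unique(accepted$sequence)
  ann_df <- do.call(rbind, lapply(unique(accepted$sequence), function(s) {
    a <- ann[[s]]
    data.frame(sequence = s,
               status = if (is.null(a)) NA_character_ else a$status,
               name_suffix = if (is.null(a)) NA_character_ else a$name_suffix,
               stringsAsFactors = FALSE)
  }))
  seq_of <- setNames(rep$alleles$sequence, rep$alleles$allele_id)
  recovery <- do.call(rbind, lapply(cohort$animals$animal_id, function(a) {
    truth <- sort(unique(unname(
      seq_of[cohort$genotypes$allele_id[cohort$genotypes$animal_id == a]])))
    called <- sort(unique(accepted$sequence[accepted$animal_id == a]))
    data.frame(animal_id = a, n_truth = length(truth),
               n_called = length(called),
               n_false = length(setdiff(called, truth)),
               n_missed = length(setdiff(truth, called)),
               exact = identical(truth, called), stringsAsFactors = FALSE)
  }))
  out <- list(repertoire = rep, cohort = cohort, reads = sim, calls = calls,
              annotation = ann_df, recovery = recovery)
  if (!is.null(config$outdir)) {
    novel <- accepted[accepted$status == "confirmed_novel", , drop = FALSE]
    novel_fa <- setNames(unique(novel$sequence),
                         sprintf("novel_%02d", seq_along(unique(novel$sequence))))
    out$manifest <- write_artifacts(list(
      "genotypes.tsv" = calls,
      "recovery.tsv" = recovery,
      "annotation.tsv" = ann_df,
      "novel_alleles.fasta" = novel_fa), config$outdir)
  }
  out
}

#' Run the evolutionary half of the pipeline
#'
#' From an annotated allele set: NJ tree with bootstrap, lineage table,
#' dN/dS report over the two exon partitions, and the recurrent-event
#' catalogue. Degenerate inputs degrade cleanly (tree skipped below three
#' sequences; dN/dS errors below two).
#'
#' @param alleles named character vector of allele CDS sequences (one
#'   species/gene for the dN/dS report).
#' @param exon_map exon map shared by the alleles.
#' @param events optional per-animal event table for [catalogue_events()].
#' @param model,B,seed tree options.
#' @param outdir optional output directory.
#' @return list with `tree`, `support`, `dnds`, `catalogue`, `manifest`.
#' @export
run_evolution <- function(alleles, exon_map, events = NULL, model = "jc",
                          B = 100, seed = 1, outdir = NULL) {
  tree <- NULL; support <- NULL
  if (length(alleles) >= 3) {
    bs <- bootstrap_support(alleles, model = model, B = B,
                            seed = derive_seed(seed, "tree"))
    tree <- bs$tree; support <- bs$support
  } else {
    warning("fewer than 3 sequences: tree stage skipped")
  }
  dnds <- if (length(alleles) >= 2)
    dnds_report(alleles, exon_map, B = max(100, B),
                seed = derive_seed(seed, "dnds"))
  else {
    warning("fewer than 2 sequences: dN/dS undefined")
    NULL
  }
  cat_tab <- catalogue_events(events)
  out <- list(tree = tree, support = support, dnds = dnds,
              catalogue = cat_tab)
  if (!is.null(outdir)) {
    art <- list("dnds_report.tsv" = dnds,
                "event_catalogue.tsv" = cat_tab$recurrent,
                "event_artifacts.tsv" = cat_tab$artifacts)
    if (!is.null(tree)) art[["tree.nwk"]] <- tree
    out$manifest <- write_artifacts(art, outdir)
  }
  out
}
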