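## Single programmatic entry point tying the modules together: one seeded,
## validated run of a named step, with a manifest recording inputs
## (checksummed), parameters and outputs.

.read_two_col <- function(path, what = c("seqid", "value")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expected two columns in ", path)
  stats::setNames(tab[[2]], tab[[1]])
}

.require_files <- function(paths) {
  paths <- unlist(paths, use.names = FALSE)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("missing input file(s): ",
                            paste(missing, collapse = ", "))
  invisible(paths)
}

#' Run one pipeline step from a configuration list
#'
#' Steps: `simulate`, `content`, `architecture`, `synteny`, `kmer_filter`,
#' `classify_scaffolds`, `polymorphism`, `markers_qc`. The configuration is
#' a named list with `step`, `outdir`, optional `seed` (default 1), and the
#' step's parameters; unknown keys are rejected. All outputs land in
#' `outdir` together with a `manifest.json` naming every input (with md5),
#' the effective parameters, the seed and every output file.
#'
#' @param config named list as described.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$step), !is.null(config$outdir))
  step <- config$step
  outdir <- config$outdir
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  allowed <- list(
    simulate = c("params"),
    content = c("gff", "repeats", "classes", "mode"),
    architecture = c("gff", "classes", "orthologs"),
    synteny = c("orthologs", "species_a", "species_b", "join_distance",
                "homology_map"),
    kmer_filter = c("r1", "r2", "k", "max_singletons", "high_count_threshold",
                    "max_high_count_kmers", "pair_mode"),
    classify_scaffolds = c("fasta", "coverage", "labels", "threshold"),
    polymorphism = c("vcf", "gff", "repeats", "classes", "tss_window",
                     "max_depth", "min_quality"),
    markers_qc = c("genotypes", "map", "freq_hi", "freq_lo",
                   "max_flagged_per_scaffold", "min_lines"))
  if (!step %in% names(allowed)) stop("unknown step: ", step)
  extra <- setdiff(names(config), c("step", "outdir", "seed", allowed[[step]]))
  if (length(extra)) stop("unknown config key(s) for step '", step, "': ",
                          paste(extra, collapse = ", "))
  set.seed(seed)
  inputs <- character()
  outputs <- character()
  out <- function(f) file.path(outdir, f)

  if (step == "simulate") {
    pargs <- if (is.null(config$params)) list() else config$params
    pargs$seed <- seed
    sim <- simulate_genomes(do.call(architecture_params, pargs))
    write_synthetic(sim, outdir)
    outputs <- list.files(outdir, full.names = TRUE)
  } else if (step == "content") {
    inputs <- .require_files(config[c("gff", "repeats", "classes")])
    cls <- if (!is.null(config$classes)) .read_two_col(config$classes)
    reps <- if (!is.null(config$repeats)) read_repeats_bed(config$repeats)
    ann <- read_gff3(config$gff, chrom_class = cls, repeats = reps)
    mode <- if (is.null(config$mode)) "summed" else config$mode
    cs <- summarize_content(ann, mode = mode)
    tab <- as.data.frame(cs[setdiff(names(cs), "mode")])
    tab$mode <- cs$mode
    utils::write.table(tab, out("content.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <- out("content.tsv")
  } else if (step == "architecture") {
    stopifnot(!is.null(names(config$gff)))
    inputs <- .require_files(c(config$gff, config$classes, config$orthologs))
    anns <- lapply(names(config$gff), function(sp) {
      cls <- if (!is.null(config$classes[[sp]])) .read_two_col(config$classes[[sp]])
      read_gff3(config$gff[[sp]], chrom_class = cls)
    })
    names(anns) <- names(config$gff)
    orth <- if (!is.null(config$orthologs)) read_orthologs(config$orthologs)
    rep <- compare_architecture(anns, orthologs = orth)
    utils::write.table(rep$summary, out("architecture_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tests <- rbind(rep$within_species, rep$between_species)
    utils::write.table(tests, out("architecture_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(out("architecture_summary.tsv"), out("architecture_tests.tsv"))
  } else if (step == "synteny") {
    inputs <- .require_files(config["orthologs"])
    orth <- read_orthologs(config$orthologs)
    pairs <- ortholog_pairs(orth, config$species_a, config$species_b)
    jd <- if (is.null(config$join_distance)) 50000 else config$join_distance
    hmap <- NULL
    if (!is.null(config$homology_map)) {
      inputs <- c(inputs, .require_files(config["homology_map"]))
      hmap <- .read_two_col(config$homology_map)
    }
    blocks <- chain_blocks(pairs, join_distance = jd)
    blocks <- filter_single_translocations(blocks, homology_map = hmap)
    ret <- chromosome_retention(pairs, homology_map = hmap)
    btab <- blocks[setdiff(names(blocks), "members")]
    btab$members <- vapply(blocks$members, paste, "", collapse = ",")
    utils::write.table(btab, out("synteny_blocks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(ret[c("retention", "n_same", "n_total", "n_unassigned")],
                         out("retention.json"), auto_unbox = TRUE)
    outputs <- c(out("synteny_blocks.tsv"), out("retention.json"))
  } else if (step == "kmer_filter") {
    inputs <- .require_files(config[c("r1", "r2")])
    k <- if (is.null(config$k)) 15 else config$k
    pol_args <- config[intersect(names(config),
                                 c("max_singletons", "high_count_threshold",
                                   "max_high_count_kmers", "pair_mode"))]
    pol <- do.call(filter_policy, pol_args)
    spec <- build_spectrum(c(config$r1, config$r2), k = k)
    res <- filter_reads(config$r1, config$r2, spec, pol)
    write_fastq(Biostrings::DNAStringSet(res$r1), out("kept_1.fastq"))
    write_fastq(Biostrings::DNAStringSet(res$r2), out("kept_2.fastq"))
    jsonlite::write_json(res$report, out("kmer_filter_report.json"),
                         auto_unbox = TRUE)
    outputs <- c(out("kept_1.fastq"), out("kept_2.fastq"),
                 out("kmer_filter_report.json"))
  } else if (step == "classify_scaffolds") {
    inputs <- .require_files(config[c("fasta", "coverage", "labels")])
    cov <- .read_two_col(config$coverage)
    labs <- .read_two_col(config$labels)
    prof <- profile_scaffolds(read_fasta(config$fasta), cov,
                              homology_labels = labs[labs != "none"])
    train_lab <- labs[labs %in% c("target", "contaminant")]
    model <- train_classifier(prof[prof$scaffold %in% names(train_lab), ],
                              train_lab[prof$scaffold[prof$scaffold %in% names(train_lab)]])
    thr <- if (is.null(config$threshold)) 0.2 else config$threshold
    res <- classify_scaffolds(model, prof, retain_threshold = thr)
    utils::write.table(res, out("scaffold_classification.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outputs <- out("scaffold_classification.tsv")
  } else if (step == "polymorphism") {
    inputs <- .require_files(config[c("vcf", "gff", "repeats", "classes")])
    cls <- if (!is.null(config$classes)) .read_two_col(config$classes)
    reps <- if (!is.null(config$repeats)) read_repeats_bed(config$repeats)
    ann <- read_gff3(config$gff, chrom_class = cls, repeats = reps)
    tw <- if (is.null(config$tss_window)) 200 else config$tss_window
    cmap <- classify_sites(ann, tss_window_bp = tw)
    sites <- read_vcf_sites(config$vcf)
    md <- if (is.null(config$max_depth)) 600 else config$max_depth
    mq <- if (is.null(config$min_quality)) 10 else config$min_quality
    tal <- polymorphism_by_class(sites, cmap, max_depth = md, min_quality = mq)
    utils::write.table(as.data.frame(tal), out("polymorphism.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(genic_percent = attr(tal, "genic_percent"),
                              genic_assayed = attr(tal, "genic_assayed"),
                              n_filtered = attr(tal, "n_filtered")),
                         out("polymorphism.json"), auto_unbox = TRUE)
    outputs <- c(out("polymorphism.tsv"), out("polymorphism.json"))
  } else if (step == "markers_qc") {
    inputs <- .require_files(config[c("genotypes", "map")])
    g <- read_genotypes(config$genotypes)
    smap <- .read_two_col(config$map)
    qargs <- config[intersect(names(config),
                              c("freq_hi", "freq_lo",
                                "max_flagged_per_scaffold", "min_lines"))]
    rep <- do.call(marker_qc, c(list(genotypes = g, scaffold_map = smap), qargs))
    jsonlite::write_json(rep[c("input_markers", "dropped_by_scaffold_distortion",
                               "dropped_low_representation",
                               "dropped_duplicate_only", "retained_markers",
                               "flagged_scaffolds")],
                         out("marker_qc.json"), auto_unbox = TRUE)
    writeLines(rep$retained, out("retained_markers.txt"))
    outputs <- c(out("marker_qc.json"), out("retained_markers.txt"))
  }

  manifest <- list(step = step, seed = seed,
                   parameters = config[setdiff(names(config), c("step", "outdir", "seed"))],
                   inputs = if (length(inputs))
                     as.list(tools::md5sum(inputs)) else list(),
                   outputs = as.character(outputs))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
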