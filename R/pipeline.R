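#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]. All of the model's
#' constants live here with the defaults the modeled study used — assignment
#' thresholds 2.05/2.35/2.36/0.80/0.75 (flower, seed, root, shoot,
#' whole plant), presence thresholds 0.60 (0.50 for whole plant), similarity
#' cutoff 0.60, scan theta 0.8, novelty alpha 0.001, 60/40 split — and they
#' are never hard-coded in stage logic.
#'
#' @param genome path to the genome FASTA
#' @param annotations path to the BED6 gene annotation
#' @param expression path to the expression TSV (`gene` + sample columns)
#' @param sample_map path to the sample-to-structure TSV
#' @param motifs optional path to a motif file (MEME minimal); when `NULL`,
#'   motifs are discovered de novo per structure
#' @param motif_format format of `motifs` (`"meme"` or `"jaspar"`)
#' @param reference_library optional path to a reference motif library for
#'   known/novel calls
#' @param truth_labels optional path to a planted-truth label TSV for
#'   end-of-run evaluation
#' @param assignment_thresholds named per-structure thresholds for
#'   [assign_genes()]; a single unnamed value is recycled
#' @param presence_thresholds named per-structure presence thresholds for
#'   [build_pattern()]; a single unnamed value is recycled
#' @param similarity_cutoff promoter-identity cutoff for [similarity_filter()]
#' @param theta scan threshold fraction
#' @param alpha novelty cutoff for [compare_motifs()]
#' @param split_prop model-build fraction of each structure set
#' @param n_clusters `"auto"` or an integer for [cluster_motifs()]
#' @param kmer k for [pfm_kmer_vector()]
#' @param max_motifs cap on discovered motifs per structure
#' @param seed integer master seed for every random stage
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(genome, annotations, expression, sample_map,
                            motifs = NULL, motif_format = "meme",
                            reference_library = NULL, truth_labels = NULL,
                            assignment_thresholds = c(flower = 2.05, seed = 2.35,
                                                      root = 2.36, shoot = 0.80,
                                                      whole_plant = 0.75),
                            presence_thresholds = c(flower = 0.60, seed = 0.60,
                                                    root = 0.60, shoot = 0.60,
                                                    whole_plant = 0.50),
                            similarity_cutoff = 0.60, theta = 0.8,
                            alpha = 0.001, split_prop = 0.6,
                            n_clusters = "auto", kmer = 4L, max_motifs = 5L,
                            seed = 1L) {
  for (p in c(genome, annotations, expression, sample_map, motifs,
              reference_library, truth_labels)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  if (similarity_cutoff <= 0 || similarity_cutoff > 1)
    stop("similarity_cutoff must lie in (0, 1]")
  if (theta <= 0 || theta > 1) stop("theta must lie in (0, 1]")
  if (split_prop <= 0 || split_prop >= 1) stop("split_prop must lie in (0, 1)")
  structure(list(
    genome = genome, annotations = annotations, expression = expression,
    sample_map = sample_map, motifs = motifs, motif_format = motif_format,
    reference_library = reference_library, truth_labels = truth_labels,
    assignment_thresholds = assignment_thresholds,
    presence_thresholds = presence_thresholds,
    similarity_cutoff = similarity_cutoff, theta = theta, alpha = alpha,
    split_prop = split_prop, n_clusters = n_clusters, kmer = as.integer(kmer),
    max_motifs = as.integer(max_motifs), seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()].
#' @param path YAML file
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              null = "null", digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

recycle_threshold <- function(x, structures, what) {
  if (length(x) == 1 && is.null(names(x)))
    return(stats::setNames(rep(x, length(structures)), structures))
  missing <- setdiff(structures, names(x))
  if (length(missing) > 0)
    stop(what, " missing for structure(s): ", paste(missing, collapse = ", "))
  x[structures]
}

#' Run the whole promoter-architecture pipeline
#'
#' Chains every stage for each plant structure found in the sample map:
#' structure assignment, 60/40 split, promoter extraction, motif discovery
#' (or a supplied motif file), redundancy removal by k-mer-vector clustering
#' with group-specificity representatives, known/novel comparison against a
#' reference library, distance-feature construction, SVM leave-one-out
#' cross-validation, pattern building from true positives, the genome-wide
#' similarity filter and pattern scan, and (when truth labels are supplied)
#' confusion-matrix evaluation. Every intermediate is written to `out_dir`
#' together with a `manifest.json` recording the configuration, its hash and
#' seeds; re-running with the same configuration reproduces all outputs
#' byte-identically.
#'
#' @param config a [pipeline_config()]
#' @param out_dir output directory (created if needed)
#' @param quiet suppress progress messages
#' @return invisibly, a list of per-structure results plus output paths
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[promarch] ", ...)

  genome <- read_genome(config$genome)
  ann <- read_bed(config$annotations)
  ex <- read_expression(config$expression, config$sample_map)
  structures <- unique(ex$sample_map$structure)
  a_thr <- recycle_threshold(config$assignment_thresholds, structures,
                             "assignment threshold")
  p_thr <- recycle_threshold(config$presence_thresholds, structures,
                             "presence threshold")
  supplied_motifs <- if (!is.null(config$motifs))
    read_motifs(config$motifs, config$motif_format) else NULL
  ref_lib <- if (!is.null(config$reference_library))
    read_motifs(config$reference_library, config$motif_format) else NULL
  truth <- if (!is.null(config$truth_labels))
    readr::read_tsv(config$truth_labels, show_col_types = FALSE,
                    progress = FALSE) else NULL

  say("assigning genes to structures")
  ps_avg <- ps_average(ex$expression, ex$sample_map)
  assignments <- assign_genes(ps_avg, a_thr)
  splits <- split_sets(assignments, prop = config$split_prop,
                       seed = substream_seed(config$seed, "split"))
  readr::write_tsv(assignments, file.path(out_dir, "assignments.tsv"))
  readr::write_tsv(splits, file.path(out_dir, "splits.tsv"))

  all_prom <- extract_promoters(ann, genome, L = 200L)

  results <- list()
  for (s in structures) {
    say("structure: ", s)
    sdir <- file.path(out_dir, s)
    dir.create(sdir, showWarnings = FALSE)
    ss <- dplyr::filter(splits, .data$structure == s)
    if (nrow(ss) < 5) {
      say("  too few assigned genes (", nrow(ss), "), skipped")
      next
    }
    mb <- sort(ss$gene[ss$role == "model_build"])
    mp <- sort(ss$gene[ss$role == "motif_prediction"])
    prom_mb <- extract_promoters(ann, genome, genes = mb, L = 200L)
    prom_mp <- extract_promoters(ann, genome, genes = mp, L = 200L)
    write_promoters(prom_mb, file.path(sdir, "promoters_model_build.fa"))
    write_promoters(prom_mp, file.path(sdir, "promoters_motif_prediction.fa"))

    if (is.null(supplied_motifs)) {
      say("  discovering motifs")
      motifs <- discover_motifs(
        prom_mp, max_motifs = config$max_motifs,
        seed = substream_seed(config$seed, paste0("discover_", s)))
      if (length(motifs) == 0) {
        say("  no over-represented motifs found, structure skipped")
        next
      }
      motifs <- lapply(seq_along(motifs), function(i) {
        m <- motifs[[i]]; m$id <- sprintf("%s_%02d", s, i); m
      })
    } else motifs <- supplied_motifs
    write_motifs(motifs, file.path(sdir, "motifs_candidates.meme"))

    scan_par <- scan_params(bg = base_composition(prom_mb$seq),
                            theta = config$theta)

    say("  scoring specificity and removing redundancy")
    group_prom <- dplyr::bind_rows(prom_mb, prom_mp)
    spec <- score_motif_specificity(motifs, group_prom, all_prom, scan_par)
    readr::write_tsv(spec, file.path(sdir, "specificity.tsv"))
    if (length(motifs) > 1) {
      vecs <- lapply(motifs, pfm_kmer_vector, k = config$kmer)
      names(vecs) <- vapply(motifs, `[[`, "", "id")
      D <- motif_distance_matrix(vecs)
      clusters <- cluster_motifs(D, k = config$n_clusters)
      reps <- select_representatives(clusters, spec)
      readr::write_tsv(dplyr::left_join(clusters, spec[c("motif", "score")],
                                        by = "motif"),
                       file.path(sdir, "clusters.tsv"))
      ids <- vapply(motifs, `[[`, "", "id")
      motifs <- motifs[match(reps$motif, ids)]
    }
    write_motifs(motifs, file.path(sdir, "motifs_selected.meme"))

    if (!is.null(ref_lib)) {
      say("  comparing against the reference library")
      comp <- purrr::map_dfr(motifs, function(m)
        tidy(compare_motifs(m, ref_lib, alpha = config$alpha,
                            seed = substream_seed(config$seed,
                                                  paste0("compare_", m$id)))))
      readr::write_tsv(comp, file.path(sdir, "comparison.tsv"))
    } else comp <- NULL

    say("  building features and running LOOCV")
    bg_prom <- sample_background(ann, genome, exclude = c(mb, mp),
                                 m = nrow(prom_mb), L = 200L,
                                 seed = substream_seed(config$seed,
                                                       paste0("background_", s)))
    tm <- build_training_matrix(prom_mb, bg_prom, motifs, scan_par)
    readr::write_tsv(tm, file.path(sdir, "training_matrix.tsv"))
    cv <- svm_loocv(tm)
    readr::write_tsv(tidy(cv), file.path(sdir, "loocv.tsv"))
    tp <- true_positives(cv)

    say("  building the motif pattern from ", length(tp), " true positives")
    if (length(tp) == 0) {
      say("  no true positives, structure skipped")
      next
    }
    prom_tp <- prom_mb[prom_mb$gene %in% tp, ]
    presence <- bin_presence(prom_tp, motifs, scan_par)
    readr::write_tsv(presence, file.path(sdir, "presence.tsv"))
    pattern <- build_pattern(presence, threshold = p_thr[[s]],
                             motifs = motifs, structure = s)
    write_pattern(pattern, file.path(sdir, "pattern.txt"))

    if (nrow(pattern$cells) > 0) {
      say("  genome-wide scan")
      scan <- genome_scan(genome, ann, pattern, scan_par,
                          similarity_cutoff = config$similarity_cutoff)
      predicted <- scan$gene[scan$matched]
      readr::write_tsv(tibble::tibble(gene = predicted),
                       file.path(sdir, "predictions.tsv"))
      evalu <- if (!is.null(truth))
        evaluate_predictions(predicted, truth, positive_structures = s)
      else NULL
      if (!is.null(evalu))
        readr::write_tsv(evalu, file.path(sdir, "evaluation.tsv"))
    } else { scan <- NULL; predicted <- character(0); evalu <- NULL }

    results[[s]] <- list(motifs = motifs, specificity = spec,
                         comparison = comp, training_matrix = tm, loocv = cv,
                         true_positives = tp, presence = presence,
                         pattern = pattern, predicted = predicted,
                         evaluation = evalu)
  }

  manifest <- list(
    package = "promarch",
    version = as.character(utils::packageVersion("promarch")),
    config = unclass(config),
    config_hash = config_hash(config),
    seed = config$seed,
    structures = structures,
    outputs = sort(list.files(out_dir, recursive = TRUE))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(results = results, out_dir = out_dir, manifest = manifest))
}
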