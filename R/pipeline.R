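#' Pipeline configuration
#'
#' Collects every stage toggle, parameter and seed for [run_pipeline].
#' Defaults follow per-dataset conventions: preset `crypt10`
#' uses median-scaling + log10 normalization, mvp variable genes and k-means;
#' `immune9`/`organoid7` use the 10k-target + natural-log normalization and
#' their own QC thresholds.
#'
#' @param preset Preset name for the simulate stage (see [make_preset]), or
#'   `NULL` when `input_dir` is given.
#' @param input_dir Optional directory with a pre-existing triplet +
#'   hashtags.tsv (alternative to simulating).
#' @param out_dir Output directory; stage outputs are written beneath it.
#' @param seed Master integer seed; stage seeds are derived from it.
#' @param stages Character vector of stages to run, in pipeline order.
#' @param qc A [qc_thresholds] (default depends on preset).
#' @param normalize_mode,log_base,normalize_target Normalization parameters.
#' @param hvg_method `"mvp"` or `"vst"`.
#' @param n_pcs Number of principal components.
#' @param cluster_method `"kmeans"` or `"snn"`.
#' @param k Number of k-means clusters (default: number of preset types).
#' @param n_init K-means restarts.
#' @param min_reads,presence_fraction Demux parameters.
#' @param level Confidence level for composition statistics.
#' @param lfc_min,alpha Marker-selection thresholds.
#' @param min_mean sseq mean floor.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(preset = "immune9", input_dir = NULL,
                            out_dir = tempfile("cryptshift"), seed = 1L,
                            stages = c("simulate", "demux", "downsample",
                                       "qc", "normalize", "hvg", "pca",
                                       "cluster", "annotate", "markers",
                                       "enrichment", "composition"),
                            qc = NULL, normalize_mode = NULL,
                            log_base = NULL, normalize_target = NULL,
                            hvg_method = NULL, n_pcs = 20L,
                            cluster_method = "kmeans", k = NULL,
                            n_init = 10L, min_reads = 10L,
                            presence_fraction = 0.2, level = 0.95,
                            lfc_min = 2, alpha = 0.05, min_mean = 0.1) {
  check_fraction(alpha, "alpha", lo_open = TRUE, hi_open = TRUE)
  preset_name <- if (inherits(preset, "synthetic_spec")) preset$name else preset
  crypt <- identical(preset_name, "crypt10")
  if (is.null(qc))
    qc <- if (identical(preset_name, "organoid7"))
      qc_thresholds(0L, .Machine$integer.max, Inf, 20)
    else qc_thresholds(200L, 1500L, 5000, 8)
  if (is.null(normalize_mode))
    normalize_mode <- if (crypt) "scale_to_median" else "scale_to_target"
  if (is.null(log_base)) log_base <- if (crypt) 10 else exp(1)
  if (is.null(normalize_target) && normalize_mode == "scale_to_target")
    normalize_target <- 1e4
  if (is.null(hvg_method))
    hvg_method <- if (identical(preset_name, "organoid7")) "vst" else "mvp"
  structure(list(preset = preset, input_dir = input_dir, out_dir = out_dir,
                 seed = as.integer(seed), stages = stages, qc = qc,
                 normalize_mode = normalize_mode, log_base = log_base,
                 normalize_target = normalize_target,
                 hvg_method = hvg_method, n_pcs = n_pcs,
                 cluster_method = cluster_method, k = k, n_init = n_init,
                 min_reads = min_reads,
                 presence_fraction = presence_fraction, level = level,
                 lfc_min = lfc_min, alpha = alpha, min_mean = min_mean),
            class = "pipeline_config")
}

pipeline_log <- function(state, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...))
  state$log <- c(state$log, line)
  message(line)
  state
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order: simulate (or load) -> demux ->
#' downsample -> qc -> normalize -> hvg -> pca -> cluster -> annotate ->
#' markers -> enrichment -> composition. Each stage's output is written as
#' TSV/JSON under `config$out_dir`; the run report records every parameter
#' and seed. Reruns with the same config are identical.
#'
#' @param config A [pipeline_config].
#' @return Invisibly, a list with the in-memory stage results (`matrix`,
#'   `truth`, `demux`, `normalized`, `hvg`, `embedding`, `clusters`,
#'   `markers`, `enrichment`, `composition`, `report`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- new.env(parent = emptyenv())
  st$log <- character()
  on_stage <- function(name) name %in% config$stages
  seed <- config$seed
  res <- list(config = config)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      cs_stop("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  if (on_stage("simulate")) {
    run_stage("simulate", {
      spec <- if (inherits(config$preset, "synthetic_spec")) config$preset
      else make_preset(config$preset)
      sim <- simulate_counts(spec, seed)
      hash <- simulate_hashtags(sim$truth$cells, n_tags = spec$n_tags,
                                seed = seed + 1L)
      res$spec <- spec; res$matrix <- sim$matrix
      res$truth <- hash$truth; res$odds_ratios <- sim$truth$odds_ratios
      res$hashtags <- hash$hashtags
      pipeline_log(st, "simulate: %d cells x %d genes (preset %s, seed %d)",
                   nrow(res$matrix$counts), ncol(res$matrix$counts),
                   spec$name, seed)
    })
  } else if (!is.null(config$input_dir)) {
    run_stage("load", {
      res$matrix <- read_10x_triplet(config$input_dir)
      hp <- file.path(config$input_dir, "hashtags.tsv")
      if (file.exists(hp)) {
        ht <- read.delim(hp, check.names = FALSE)
        hm <- as.matrix(ht[, -1, drop = FALSE])
        rownames(hm) <- ht[[1]]
        res$hashtags <- hashtag_counts(hm)
      }
      res$spec <- NULL
      pipeline_log(st, "load: %d cells x %d genes from %s",
                   nrow(res$matrix$counts), ncol(res$matrix$counts),
                   config$input_dir)
    })
  } else cs_stop("no input: enable the simulate stage or give input_dir")

  if (on_stage("demux") && !is.null(res$hashtags)) {
    run_stage("demux", {
      dm <- classify_hashtags(res$hashtags, config$min_reads,
                              config$presence_fraction)
      write.table(dm, file.path(config$out_dir, "demux.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      singles <- dm$cell_id[dm$category == "single"]
      res$demux <- dm
      res$matrix <- subset_umi(res$matrix, cells = singles)
      pipeline_log(st, "demux: %d/%d cells single", length(singles),
                   nrow(dm))
    })
  }

  if (on_stage("downsample")) {
    run_stage("downsample", {
      res$matrix <- downsample_to_common_depth(res$matrix, seed + 2L)
      pipeline_log(st, "downsample: per-sample medians now %s",
                   paste(round(tapply(cell_totals(res$matrix),
                                      res$matrix$sample_label, median)),
                         collapse = "/"))
    })
  }

  if (on_stage("qc")) {
    run_stage("qc", {
      before <- nrow(res$matrix$counts)
      res$matrix <- filter_cells_qc(res$matrix, config$qc)
      rep <- attr(res$matrix, "qc_report")
      jsonlite::write_json(rep[c("n_in", "n_out", "removed_genes",
                                 "removed_umi", "removed_mito")],
                           file.path(config$out_dir, "qc_report.json"),
                           auto_unbox = TRUE)
      pipeline_log(st, "qc: %d -> %d cells", before,
                   nrow(res$matrix$counts))
    })
  }

  if (on_stage("normalize")) {
    run_stage("normalize", {
      res$normalized <- normalize_log(res$matrix,
                                      mode = config$normalize_mode,
                                      log_base = config$log_base,
                                      target = config$normalize_target)
      pipeline_log(st, "normalize: %s (log base %.3g)",
                   config$normalize_mode, config$log_base)
    })
  }

  if (on_stage("hvg")) {
    run_stage("hvg", {
      res$hvg <- if (config$hvg_method == "mvp")
        select_hvg_mvp(res$normalized)
      else select_hvg_vst(res$matrix,
                          n_select = min(2000L, ncol(res$matrix$counts)))
      pipeline_log(st, "hvg (%s): %d genes", config$hvg_method,
                   length(res$hvg$selected))
    })
  }

  if (on_stage("pca")) {
    run_stage("pca", {
      genes <- if (!is.null(res$hvg)) res$hvg$selected else NULL
      res$embedding <- run_pca(res$normalized, genes = genes,
                               n_components = config$n_pcs)
      write.table(round(res$embedding$scores, 6),
                  file.path(config$out_dir, "embedding.tsv"), sep = "\t",
                  quote = FALSE, col.names = NA)
      pipeline_log(st, "pca: %d components", ncol(res$embedding$scores))
    })
  }

  if (on_stage("cluster")) {
    run_stage("cluster", {
      k <- config$k
      if (is.null(k))
        k <- if (!is.null(res$spec)) length(res$spec$cell_types) else 9L
      res$clusters <- if (config$cluster_method == "snn")
        snn_cluster(res$embedding, seed = seed + 3L)
      else kmeans_cluster(res$embedding, k = k, n_init = config$n_init,
                          seed = seed + 3L)
      pipeline_log(st, "cluster (%s): %d clusters", config$cluster_method,
                   res$clusters$k)
    })
  }

  if (on_stage("annotate")) {
    run_stage("annotate", {
      ref <- if (!is.null(res$spec)) {
        gene_set_collection(lapply(res$spec$marker_map, `[[`, "genes"))
      } else cs_stop("annotation needs a marker reference")
      res$clusters <- annotate_clusters(res$normalized, res$clusters, ref)
      write.table(
        data.frame(cell_id = res$clusters$cell_ids,
                   cluster = res$clusters$labels,
                   cell_type = res$clusters$annotation[
                     as.character(res$clusters$labels)]),
        file.path(config$out_dir, "clusters.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
      write.table(round(res$clusters$annotation_scores, 4),
                  file.path(config$out_dir, "annotation_scores.tsv"),
                  sep = "\t", quote = FALSE, col.names = NA)
      pipeline_log(st, "annotate: %s",
                   paste(unique(res$clusters$annotation), collapse = ","))
    })
  }

  if (on_stage("markers")) {
    run_stage("markers", {
      tabs <- lapply(sort(unique(res$clusters$labels)), function(cl)
        sseq_exact_test(res$matrix, res$clusters, cl,
                        min_mean = config$min_mean))
      all_rows <- do.call(rbind, tabs)
      sel <- select_markers(all_rows, config$lfc_min, config$alpha)
      write.table(sel, file.path(config$out_dir, "markers.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      res$markers <- all_rows
      res$selected_markers <- sel
      pipeline_log(st, "markers: %d selected of %d tested rows",
                   nrow(sel), nrow(all_rows))
    })
  }

  if (on_stage("enrichment")) {
    run_stage("enrichment", {
      sets <- if (!is.null(res$spec)) res$spec$gene_sets else NULL
      if (!is.null(sets)) {
        z <- zscale(normalized_values(res$normalized))
        groups <- res$normalized$condition_label
        enr <- lapply(names(sets), function(nm)
          tryCatch(score_set(z, sets[[nm]], unit = "cell", groups = groups,
                             set_name = nm),
                   error = function(e) NULL))
        enr <- Filter(Negate(is.null), enr)
        tab <- do.call(rbind, lapply(enr, function(e)
          data.frame(set = e$set, unit = e$unit,
                     mean_a = e$group_means[1], mean_b = e$group_means[2],
                     statistic = e$statistic, p_value = e$p_value)))
        write.table(tab, file.path(config$out_dir, "enrichment.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        res$enrichment <- tab
        pipeline_log(st, "enrichment: %d sets scored", nrow(tab))
      }
    })
  }

  if (on_stage("composition")) {
    run_stage("composition", {
      tab <- tabulate_composition(res$clusters,
                                  res$matrix$condition_label,
                                  conditions = rev(unique(
                                    res$matrix$condition_label)))
      res$composition <- composition_report(tab, level = config$level)
      write.table(res$composition,
                  file.path(config$out_dir, "composition.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      pipeline_log(st, "composition: %d cell types", nrow(res$composition))
    })
  }

  report <- list(
    package_version = as.character(utils::packageVersion("cryptshift")),
    seed = config$seed,
    preset = if (inherits(config$preset, "synthetic_spec"))
      config$preset$name else config$preset,
    stages = config$stages,
    parameters = config[!vapply(config, is.null, TRUE) &
                          !names(config) %in% c("qc", "preset")],
    qc = unclass(config$qc), log = st$log)
  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, force = TRUE, digits = NA)
  invisible(res)
}
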