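#' Default pipeline configuration
#'
#' Assembles the run configuration consumed by [run_pipeline()]: stage
#' toggles plus every stage parameter at its documented default.
#'
#' @param out_dir Output directory for all stages.
#' @param seed Seed propagated to every stochastic stage.
#' @param stages Character vector of stages to run, in dependency order.
#' @param ... Overrides for any default parameter (see Details in the
#'   package vignette): `min_tpm`, `alpha_ref`, `total_ref`, `fit_range`,
#'   `max_gap`, `r_min`, `inflation`, `pairing_max_gap`, `window_half`,
#'   `tss_dist`, `exon_dist`, `lambda`, `sim` (a [sim_config()]).
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c("simulate", "normalize", "network",
                                       "enrich", "enhancers", "mara"),
                            ...) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
              min_tpm = 10, alpha_ref = 1.25, total_ref = 1e6,
              fit_range = c(10, 1000), max_gap = 20, max_tss_dist = 500,
              r_min = 0.85, inflation = 1.7,
              pairing_max_gap = 400, window_half = 200,
              tss_dist = 500, exon_dist = 100,
              lambda = "gcv", sim = NULL)
  dots <- list(...)
  cfg[names(dots)] <- dots
  if (is.null(cfg$sim)) cfg$sim <- sim_config(seed = cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full CAGE analysis cascade
#'
#' Executes the requested stages in dependency order on one output
#' directory: `simulate` (synthetic genome + CTSS tracks),
#' `normalize` (read, aggregate, power-law normalize, TPM, filter,
#' annotate, replicate-average), `network` (correlation graph + MCL +
#' cluster profiles), `enrich` (gene-set hypergeometric tests; the default
#' synthetic gene set is the decline-archetype genes, standing in for a
#' curated cell-cycle list), `enhancers` (bidirectional loci, two
#' stringency tiers, annotation masking, overlap with the planted truth
#' windows) and `mara` (ridge-regression motif activities from the truth
#' promoter x motif design). Each stage writes TSV outputs and the run
#' ends with a JSON manifest of per-stage record counts and file
#' checksums; rerunning an identical config reproduces an identical
#' manifest.
#'
#' @param config A [pipeline_config()] object, or the path to a YAML file
#'   of the same fields.
#' @return Invisibly, the manifest (list of class `run_manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    y <- yaml::read_yaml(config)
    sim <- y$sim
    y$sim <- NULL
    config <- do.call(pipeline_config, y)
    if (!is.null(sim)) config$sim <- do.call(sim_config, sim)
  }
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("cagecascade")),
                   seed = config$seed, stages = list(), files = list())
  tsv <- function(x, name) {
    p <- file.path(out, name)
    write.table(x, p, sep = "\t", quote = FALSE, col.names = NA)
    p
  }
  stage_files <- character(0)

  need <- function(path, stage) {
    if (!file.exists(path))
      stop("stage '", stage, "' needs missing upstream file: ", path)
    path
  }

  if ("simulate" %in% config$stages) {
    sim <- simulate_timecourse(config$sim, out)
    manifest$stages$simulate <- list(
      n_samples = nrow(sim$metadata),
      n_promoters = config$sim$n_promoters,
      n_enhancers = config$sim$n_enhancers)
    stage_files <- c(stage_files, sim$paths$gtf, sim$paths$genome)
  }

  samples_path <- file.path(out, "samples.tsv")
  gtf_path <- file.path(out, "annotation.gtf")

  if ("normalize" %in% config$stages) {
    meta <- read.table(need(samples_path, "normalize"), header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
    meta$path <- file.path(out, "ctss", paste0(meta$sample_id, ".bed"))
    ctss <- read_ctss(meta$path, meta)
    # normalize at CTSS level, then aggregate the normalized values
    ctss_norm <- ctss
    ctss_norm$counts <- normalize_power_law(ctss$counts,
                                            alpha_ref = config$alpha_ref,
                                            total_ref = config$total_ref,
                                            fit_range = config$fit_range)
    tc <- aggregate_ctss(ctss_norm, max_gap = config$max_gap)
    tpm <- to_tpm(tc$counts)
    expr <- filter_expressed(tpm, min_tpm = config$min_tpm)
    tc <- annotate_clusters(tc, need(gtf_path, "normalize"),
                            max_tss_dist = config$max_tss_dist)
    avg <- average_replicates(expr, meta)
    genes <- setNames(tc$clusters$gene, tc$clusters$cluster_id)
    stage_files <- c(stage_files,
                     tsv(tc$clusters, "tag_clusters.tsv"),
                     tsv(tpm, "expression_tpm.tsv"),
                     tsv(avg, "expression_mean_by_time.tsv"),
                     tsv(data.frame(cluster_id = names(genes), gene = genes),
                         "cluster_genes.tsv"))
    manifest$stages$normalize <- list(
      n_ctss = nrow(ctss$sites), n_tag_clusters = nrow(tc$clusters),
      n_filtered = nrow(expr), n_time_points = ncol(avg))
  }

  if ("network" %in% config$stages) {
    avg <- as.matrix(read.table(need(file.path(out, "expression_mean_by_time.tsv"),
                                     "network"), header = TRUE, sep = "\t",
                                row.names = 1, check.names = FALSE))
    g <- build_correlation_graph(avg, r_min = config$r_min, axis = "genes")
    res <- mcl_cluster(g, inflation = config$inflation)
    prof <- cluster_mean_profiles(res, avg)
    stage_files <- c(stage_files,
                     tsv(g$edges, "network_edges.tsv"),
                     tsv(data.frame(node = names(res$membership),
                                    cluster = res$membership),
                         "network_membership.tsv"),
                     tsv(prof, "cluster_mean_profiles.tsv"))
    manifest$stages$network <- list(
      n_nodes = length(g$nodes), n_edges = nrow(g$edges),
      n_excluded = length(g$excluded),
      n_clusters = length(res$sizes),
      n_clusters_ge10 = sum(res$sizes >= 10),
      converged = res$converged)
  }

  if ("enrich" %in% config$stages) {
    memb <- read.table(need(file.path(out, "network_membership.tsv"),
                            "enrich"), header = TRUE, sep = "\t",
                       row.names = 1, stringsAsFactors = FALSE)
    membership <- setNames(memb$cluster, memb$node)
    gmap <- read.table(need(file.path(out, "cluster_genes.tsv"), "enrich"),
                       header = TRUE, sep = "\t", row.names = 1,
                       stringsAsFactors = FALSE)
    node_genes <- setNames(gmap$gene, gmap$cluster_id)
    gs_path <- file.path(out, "geneset.txt")
    if (!file.exists(gs_path)) {
      # default synthetic gene set: the decline-archetype genes (the
      # synthetic analogue of a curated cell-cycle list)
      truth <- read.table(need(file.path(out, "truth_promoters.tsv"),
                               "enrich"), header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
      writeLines(truth$gene[truth$archetype == "decline"], gs_path)
    }
    gs <- read_geneset(gs_path)
    enr <- test_cluster_enrichment(membership, node_genes, gs)
    stage_files <- c(stage_files, tsv(enr, "enrichment.tsv"))
    manifest$stages$enrich <- list(
      geneset = gs$name, n_universe = enr$N[1], n_set = enr$K[1],
      m_tests = enr$m_tests[1],
      n_significant = sum(enr$p_bonferroni <= 0.05))
  }

  if ("enhancers" %in% config$stages) {
    meta <- read.table(need(samples_path, "enhancers"), header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
    meta$path <- file.path(out, "ctss", paste0(meta$sample_id, ".bed"))
    ctss <- read_ctss(meta$path, meta)
    loci <- find_bidirectional_loci(ctss,
                                    pairing_max_gap = config$pairing_max_gap,
                                    window_half = config$window_half)
    ann <- read_annotation(need(gtf_path, "enhancers"))
    tiers <- lapply(c(stringent = "stringent", lenient = "lenient"),
                    function(lv) mask_annotated(apply_stringency(loci, lv),
                                                ann, config$tss_dist,
                                                config$exon_dist))
    for (lv in names(tiers)) {
      d <- tiers[[lv]]$loci
      bed <- data.frame(d$chrom, d$midpoint - d$window_half,
                        d$midpoint + d$window_half, d$locus_id,
                        pmin(1000, round(1000 * (d$F_total + d$R_total) /
                                           max(1, max(d$F_total + d$R_total)))),
                        ".")
      p <- file.path(out, paste0("enhancers_", lv, ".bed"))
      write.table(bed, p, sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
      stage_files <- c(stage_files, p,
                       tsv(tiers[[lv]]$F, paste0("enhancers_", lv, "_F.tsv")),
                       tsv(tiers[[lv]]$R, paste0("enhancers_", lv, "_R.tsv")))
    }
    manifest$stages$enhancers <- list(
      n_candidates = nrow(loci$loci),
      n_stringent = nrow(tiers$stringent$loci),
      n_lenient = nrow(tiers$lenient$loci))
    truth_enh <- file.path(out, "truth_enhancers.tsv")
    if (file.exists(truth_enh)) {
      te <- read.table(truth_enh, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
      ref <- data.frame(chrom = te$chrom, start = te$pos - 200,
                        end = te$pos + 200)
      ov <- overlap_reference(tiers$lenient, ref)
      recall <- sum(vapply(seq_len(nrow(ref)), function(i)
        any(tiers$lenient$loci$chrom == ref$chrom[i] &
              abs(tiers$lenient$loci$midpoint - te$pos[i]) <=
                config$window_half), logical(1))) / nrow(ref)
      manifest$stages$enhancers$lenient_overlap_count <- ov$count
      manifest$stages$enhancers$planted_recall_lenient <- recall
    }
  }

  if ("mara" %in% config$stages) {
    avg <- as.matrix(read.table(need(file.path(out, "expression_mean_by_time.tsv"),
                                     "mara"), header = TRUE, sep = "\t",
                                row.names = 1, check.names = FALSE))
    gmap <- read.table(need(file.path(out, "cluster_genes.tsv"), "mara"),
                       header = TRUE, sep = "\t", row.names = 1,
                       stringsAsFactors = FALSE)
    Npath <- need(file.path(out, "truth_motif_counts.tsv"), "mara")
    N <- as.matrix(read.table(Npath, header = TRUE, sep = "\t",
                              row.names = 1, check.names = FALSE))
    # map tag clusters to simulated promoters via the annotated gene;
    # promoter ids and gene symbols share the locus index by construction
    node_genes <- setNames(gmap$gene, gmap$cluster_id)
    genes <- node_genes[rownames(avg)]
    prom_id <- sub("^GENE", "prom", genes)
    keep <- !is.na(genes) & prom_id %in% rownames(N) & !duplicated(prom_id)
    E <- log2(avg[keep, , drop = FALSE] + 1)
    rownames(E) <- prom_id[keep]
    fit <- fit_mara(E, N[rownames(E), , drop = FALSE],
                    lambda = config$lambda)
    act_cl <- cluster_activities(fit)
    stage_files <- c(stage_files,
                     tsv(fit$activities, "motif_activities.tsv"),
                     tsv(fit$zscores, "motif_zscores.tsv"))
    manifest$stages$mara <- list(
      n_promoters = nrow(E), n_motifs = nrow(fit$activities),
      lambda = fit$lambda,
      n_activity_clusters = if (is.null(act_cl$result)) 0L
                            else length(act_cl$result$sizes))
  }

  manifest$files <- as.list(md5sum(unique(stage_files)))
  names(manifest$files) <- basename(names(manifest$files))
  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest), file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline manifest (seed ", x$seed, "):\n", sep = "")
  for (st in names(x$stages)) {
    cat("  ", st, ": ", sep = "")
    cat(paste(names(x$stages[[st]]), unlist(x$stages[[st]]), sep = "="),
        sep = ", ")
    cat("\n")
  }
  invisible(x)
}

#' Export per-target expression time profiles
#'
#' Writes one TSV per target gene (one row per time point, one column per
#' CTSS of the gene, so multiple promoters stack) and, optionally, a
#' stacked bar plot. Enhancer loci are exported as paired series with
#' reverse-strand values negative.
#'
#' @param targets Character vector of gene symbols and/or enhancer locus
#'   ids.
#' @param expr Annotated replicate-averaged expression matrix (rows = tag
#'   clusters).
#' @param genes Named vector tag-cluster id -> gene symbol.
#' @param out_dir Output directory.
#' @param enhancers Optional `bidir_loci` object for locus targets.
#' @param plot Write PNG bar plots; default TRUE.
#' @return Invisibly, the written file paths.
#' @export
export_profiles <- function(targets, expr, genes, out_dir, enhancers = NULL,
                            plot = TRUE) {
  if (length(targets) == 0) stop("empty target list")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genes <- genes[rownames(expr)]
  written <- character(0)
  for (tg in targets) {
    rows <- which(!is.na(genes) & genes == tg)
    if (length(rows)) {
      prof <- t(expr[rows, , drop = FALSE])
      colnames(prof) <- rownames(expr)[rows]
      df <- data.frame(time = rownames(prof), prof, check.names = FALSE)
    } else if (!is.null(enhancers) && tg %in% enhancers$loci$locus_id) {
      fw <- enhancers$F[tg, ]; rv <- -enhancers$R[tg, ]
      df <- data.frame(time = names(fw), forward = fw, reverse = rv)
      prof <- cbind(forward = fw, reverse = rv)
    } else {
      near <- c(unique(na.omit(genes)),
                if (!is.null(enhancers)) enhancers$loci$locus_id)
      hint <- agrep(tg, near, max.distance = 0.3, value = TRUE)
      stop("unknown target '", tg, "'",
           if (length(hint)) paste0("; near matches: ",
                                    paste(head(hint, 5), collapse = ", ")))
    }
    p <- file.path(out_dir, paste0("profile_", tg, ".tsv"))
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, p)
    if (plot) {
      pngp <- file.path(out_dir, paste0("profile_", tg, ".png"))
      png(pngp, width = 900, height = 500)
      barplot(t(prof), beside = FALSE, names.arg = rownames(prof),
              las = 2, main = tg, ylab = "TPM",
              col = seq_len(ncol(prof)) + 1)
      dev.off()
      written <- c(written, pngp)
    }
  }
  invisible(written)
}
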