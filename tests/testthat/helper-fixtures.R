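# Shared fixture builders (everything generated in code at test time).

# A reduced simulation configuration for fast structural tests; the
# full-size default configuration is exercised in the acceptance suite.
small_config <- function(...) {
  args <- list(genome_length = 6e5, n_chromosomes = 1,
               time_points_h = c(0, 2, 4, 8, 12, 24, 48, 96),
               replicates_per_time = 2, n_promoters = 60, n_enhancers = 5,
               n_motifs = 4, seed = 42L)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# Write per-sample CTSS BED6 files from a list of data frames
# (chrom, pos, strand, count) and return a read_ctss() table.
make_ctss <- function(per_sample, time_h = seq_along(per_sample),
                      replicate = rep(1, length(per_sample))) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  paths <- character(length(per_sample))
  for (i in seq_along(per_sample)) {
    d <- per_sample[[i]]
    paths[i] <- file.path(dir, sprintf("s%02d.bed", i))
    if (nrow(d) == 0) {
      file.create(paths[i])
    } else {
      write.table(data.frame(d$chrom, d$pos, d$pos + 1, ".", d$count,
                             d$strand),
                  paths[i], sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    }
  }
  meta <- data.frame(sample_id = sprintf("s%02d", seq_along(per_sample)),
                     time_h = time_h, replicate = replicate,
                     stringsAsFactors = FALSE)
  read_ctss(paths, meta)
}

# One cached full-default simulation shared by the heavier tests.
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "cagecascade-default-sim")
      cache <<- simulate_timecourse(sim_config(), dir)
    }
    cache
  }
})

# Run the standard normalization path on a simulation, returning the
# replicate-averaged annotated expression matrix plus lookups.
normalize_sim <- function(sim) {
  meta <- sim$metadata
  meta$path <- sim$paths$ctss
  ctss <- read_ctss(meta$path, meta)
  cn <- ctss
  cn$counts <- normalize_power_law(ctss$counts)
  tc <- aggregate_ctss(cn)
  expr <- filter_expressed(to_tpm(tc$counts))
  ann <- annotate_clusters(aggregate_ctss(ctss), sim$paths$gtf)
  genes <- setNames(ann$clusters$gene, ann$clusters$cluster_id)
  avg <- average_replicates(expr, meta)
  list(ctss = ctss, avg = avg, genes = genes, meta = meta)
}
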