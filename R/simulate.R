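#' Configuration for the synthetic CAGE time course
#'
#' Builds and validates the parameter set driving [simulate_timecourse()].
#' Defaults emulate a dense differentiation time course: samples taken hourly
#' from 0 to 12 h, two-hourly from 12 to 18 h, and then at 24, 36, 48 and
#' 96 h (20 time points), with three replicates per time point. Promoter
#' baseline expression is heavy-tailed (Pareto) so per-sample CTSS count
#' marginals follow a power law, promoters follow one of five temporal
#' archetypes, and enhancers are low-abundance balanced bidirectional loci
#' whose pulse precedes the pulse of their linked promoter.
#'
#' @param genome_length Total genome size in bp, split across chromosomes.
#' @param n_chromosomes Number of chromosomes.
#' @param time_points_h Strictly increasing sampling times in hours,
#'   starting at 0.
#' @param replicates_per_time Replicates per time point (>= 1).
#' @param n_promoters,n_enhancers Numbers of loci to place.
#' @param archetype_mix Named proportions over
#'   `c("early_pulse","mid_pulse","decline","rise","flat")`; must sum to 1.
#' @param pareto_alpha Tail exponent of the baseline expression distribution.
#' @param nb_dispersion Negative binomial size parameter (smaller = more
#'   overdispersed replicate noise).
#' @param erna_lead_h Hours by which an enhancer's eRNA pulse peak precedes
#'   the pulse peak of its linked promoter.
#' @param n_motifs Number of motifs in the ground-truth regulatory design.
#' @param motif_amplitude Amplitude (log2 units) of ground-truth motif
#'   activities.
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_timecourse()], [simulate_motif_design()]
#' @export
sim_config <- function(genome_length = 3e6,
                       n_chromosomes = 2,
                       time_points_h = c(0:12, 14, 16, 18, 24, 36, 48, 96),
                       replicates_per_time = 3,
                       n_promoters = 500,
                       n_enhancers = 20,
                       archetype_mix = c(early_pulse = 0.15, mid_pulse = 0.15,
                                         decline = 0.25, rise = 0.25,
                                         flat = 0.20),
                       pareto_alpha = 1.25,
                       nb_dispersion = 20,
                       erna_lead_h = 2,
                       n_motifs = 8,
                       motif_amplitude = 1,
                       seed = 1L) {
  arch_names <- c("early_pulse", "mid_pulse", "decline", "rise", "flat")
  if (!all(arch_names %in% names(archetype_mix)))
    stop("archetype_mix must be named with: ", paste(arch_names, collapse = ", "))
  archetype_mix <- archetype_mix[arch_names]
  if (abs(sum(archetype_mix) - 1) > 1e-8)
    stop("archetype_mix proportions must sum to 1")
  if (any(diff(time_points_h) <= 0) || time_points_h[1] != 0)
    stop("time_points_h must be strictly increasing and start at 0")
  stopifnot(genome_length >= 1, n_chromosomes >= 1, replicates_per_time >= 1,
            n_promoters >= 1, n_enhancers >= 0, pareto_alpha > 0,
            nb_dispersion > 0, erna_lead_h >= 0, n_motifs >= 1)
  if (n_promoters < 10 * n_motifs)
    stop("need n_promoters >= 10 * n_motifs for an identifiable motif design")
  cfg <- list(genome_length = genome_length, n_chromosomes = n_chromosomes,
              time_points_h = time_points_h,
              replicates_per_time = replicates_per_time,
              n_promoters = n_promoters, n_enhancers = n_enhancers,
              archetype_mix = archetype_mix, pareto_alpha = pareto_alpha,
              nb_dispersion = nb_dispersion, erna_lead_h = erna_lead_h,
              n_motifs = n_motifs, motif_amplitude = motif_amplitude,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic CAGE time-course configuration\n")
  cat(sprintf("  genome: %g bp over %d chromosome(s)\n",
              x$genome_length, x$n_chromosomes))
  cat(sprintf("  %d time points (%g..%g h), %d replicates each\n",
              length(x$time_points_h), min(x$time_points_h),
              max(x$time_points_h), x$replicates_per_time))
  cat(sprintf("  %d promoters, %d enhancers, %d motifs, seed %d\n",
              x$n_promoters, x$n_enhancers, x$n_motifs, x$seed))
  invisible(x)
}

# Temporal archetype multiplier m(t) in [~0, 1]; the pulse shapes mirror the
# transiently induced clusters of a differentiation time course (an early
# pulse peaking ~2 h, a mid pulse peaking ~6 h), plus monotone decline,
# monotone rise and a flat background class.
archetype_profile <- function(archetype, t, peak = NULL) {
  switch(archetype,
    early_pulse = 0.08 + 0.92 * exp(-0.5 * ((t - 2) / 1.8)^2),
    mid_pulse   = 0.08 + 0.92 * exp(-0.5 * ((t - 6) / 2.5)^2),
    decline     = 0.05 + 0.95 * exp(-t / 16),
    rise        = 1 - 0.95 * exp(-t / 16),
    flat        = rep(1, length(t)),
    pulse_at    = 0.05 + 0.95 * exp(-0.5 * ((t - peak) / 2.5)^2),
    stop("unknown archetype: ", archetype)
  )
}

# Peak time (h) of each archetype profile, used to position eRNA leads.
archetype_peak <- function(archetype) {
  switch(archetype, early_pulse = 2, mid_pulse = 6, decline = 0, rise = 96,
         flat = NA_real_)
}

#' Simulate a ground-truth promoter-by-motif regulatory design
#'
#' Draws a nonnegative promoter x motif count matrix `N` (full column rank)
#' and a smooth ground-truth motif x time activity matrix `A` with rows
#' centered to zero across time points. [simulate_timecourse()] multiplies
#' promoter means by `2^(N %*% A)` so that [fit_mara()] can recover `A`.
#'
#' @param config A [sim_config()] object.
#' @return List with `N` (promoters x motifs), `A` (motifs x time points,
#'   rows sum to 0) and `shapes` (the activity shape assigned to each motif).
#' @export
simulate_motif_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 104729L)  # independent stream from the count draws
  P <- config$n_promoters; M <- config$n_motifs
  tp <- config$time_points_h
  for (attempt in seq_len(5)) {
    N <- matrix(rbinom(P * M, size = 3, prob = 0.3), nrow = P,
                dimnames = list(sprintf("prom%04d", seq_len(P)),
                                sprintf("motif%02d", seq_len(M))))
    if (qr(scale(N, center = TRUE, scale = FALSE))$rank == M) break
    warning("rank-deficient motif count matrix; resampling")
    if (attempt == 5) stop("failed to sample a full-rank motif design in 5 attempts")
  }
  shapes <- rep(c("rise", "fall", "pulse_early", "pulse_late"), length.out = M)
  A <- t(vapply(seq_len(M), function(m) {
    s <- switch(shapes[m],
                rise  = (tp / 96)^0.7,
                fall  = -(tp / 96)^0.7,
                pulse_early = exp(-0.5 * ((tp - 4) / 3)^2),
                pulse_late  = exp(-0.5 * ((tp - 24) / 10)^2))
    s <- s * config$motif_amplitude * runif(1, 0.8, 1.2)
    s - mean(s)
  }, numeric(length(tp))))
  dimnames(A) <- list(colnames(N), sprintf("t%03d", tp))
  list(N = N, A = A, shapes = shapes)
}

#' Simulate a CAGE differentiation time course with known ground truth
#'
#' Writes a toy genome (FASTA), a gene annotation (GTF), one CTSS track
#' (BED6, score = tag count) per sample, and the simulation truth
#' (TSV + JSON). Promoters emit unidirectional negative-binomial counts at
#' three closely spaced CTSS positions, with mean
#' `baseline * archetype(t) * 2^(N A)`; enhancers emit low, balanced counts
#' from two divergent CTSS 180 bp apart, pulsing `erna_lead_h` hours before
#' their linked promoter's peak. Loci are placed >= 1 kb apart; promoters get
#' GTF gene/transcript/exon records, enhancers are unannotated.
#'
#' @param config A [sim_config()] object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with file `paths`, the sample `metadata`
#'   data frame (sample_id, time_h, replicate), and the `truth` list
#'   (per-locus archetype and baseline, enhancer links and peak times, motif
#'   design `N` and `A`).
#' @export
simulate_timecourse <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ctss_dir <- file.path(out_dir, "ctss")
  dir.create(ctss_dir, showWarnings = FALSE)

  design <- simulate_motif_design(config)
  set.seed(config$seed)

  tp <- config$time_points_h
  nrep <- config$replicates_per_time
  samples <- data.frame(
    sample_id = sprintf("t%03d_r%d", rep(tp, each = nrep),
                        rep(seq_len(nrep), length(tp))),
    time_h = rep(tp, each = nrep),
    replicate = rep(seq_len(nrep), length(tp)),
    stringsAsFactors = FALSE)

  ## --- genome and locus placement (>= 1 kb spacing, 2 kb margins) ---------
  chrom_len <- rep(floor(config$genome_length / config$n_chromosomes),
                   config$n_chromosomes)
  chroms <- sprintf("chrS%d", seq_len(config$n_chromosomes))
  n_loci <- config$n_promoters + config$n_enhancers
  per_chrom <- diff(floor(seq(0, n_loci, length.out = config$n_chromosomes + 1)))
  pos_list <- vector("list", config$n_chromosomes)
  for (i in seq_len(config$n_chromosomes)) {
    k <- per_chrom[i]
    if (k == 0) { pos_list[[i]] <- integer(0); next }
    usable <- chrom_len[i] - 4000
    spacing <- floor(usable / k)
    if (spacing < 1000)
      stop("genome too short to place ", n_loci,
           " loci >= 1 kb apart with 2 kb margins; increase genome_length")
    base <- 2000 + spacing * (seq_len(k) - 1)
    jit <- floor(runif(k, 0, max(1, spacing - 1000)))
    pos_list[[i]] <- base + jit
  }
  loci <- data.frame(chrom = rep(chroms, per_chrom),
                     pos = unlist(pos_list), stringsAsFactors = FALSE)
  idx <- sample.int(n_loci)  # shuffle which slots become promoters/enhancers
  prom_rows <- sort(idx[seq_len(config$n_promoters)])
  enh_rows <- sort(setdiff(seq_len(n_loci), prom_rows))

  ## --- promoters ----------------------------------------------------------
  P <- config$n_promoters
  prom <- loci[prom_rows, , drop = FALSE]
  prom$promoter_id <- sprintf("prom%04d", seq_len(P))
  prom$gene <- sprintf("GENE%04d", seq_len(P))
  prom$strand <- sample(c("+", "-"), P, replace = TRUE)
  n_arch <- floor(config$archetype_mix * P)
  rem <- P - sum(n_arch)
  if (rem > 0)  # distribute rounding remainder over the largest classes
    n_arch[order(config$archetype_mix, decreasing = TRUE)[seq_len(rem)]] <-
      n_arch[order(config$archetype_mix, decreasing = TRUE)[seq_len(rem)]] + 1
  prom$archetype <- sample(rep(names(n_arch), n_arch))
  # Pareto(xm = 20, alpha), truncated at 300 * xm so that no single locus
  # dominates the library composition while the fit window [10, 1000]
  # stays well clear of the truncation point
  u_min <- (1 / 300)^config$pareto_alpha
  prom$baseline <- 20 * runif(P, min = u_min)^(-1 / config$pareto_alpha)

  ## --- enhancers linked to pulsed promoters -------------------------------
  Eh <- config$n_enhancers
  enh <- loci[enh_rows, , drop = FALSE]
  if (Eh > 0) {
    enh$enhancer_id <- sprintf("enh%03d", seq_len(Eh))
    pulsed <- prom$promoter_id[prom$archetype %in% c("mid_pulse", "early_pulse")]
    # prefer mid-pulse links so the led enhancer peak stays positive
    mid <- prom$promoter_id[prom$archetype == "mid_pulse"]
    pool <- if (length(mid) >= Eh) mid else pulsed
    if (length(pool) < Eh)
      stop("not enough pulsed promoters to link ", Eh, " enhancers")
    enh$linked_promoter <- sample(pool, Eh)
    enh$promoter_peak_h <- vapply(enh$linked_promoter, function(p)
      archetype_peak(prom$archetype[match(p, prom$promoter_id)]), numeric(1))
    enh$peak_h <- pmax(0, enh$promoter_peak_h - config$erna_lead_h)
    enh$mean_level <- runif(Eh, 4, 8)
    enh$asym <- runif(Eh, -0.1, 0.1)  # keeps |directionality| < 0.3 in expectation
  }

  ## --- per-CTSS expected means -------------------------------------------
  # promoters: 3 CTSS (dominant + two minor) offset along the strand
  ctss_off <- c(0, 5, 12); ctss_w <- c(0.7, 0.2, 0.1)
  sgn <- ifelse(prom$strand == "+", 1L, -1L)
  prom_ctss <- data.frame(
    chrom = rep(prom$chrom, each = 3),
    pos = rep(prom$pos, each = 3) + rep(sgn, each = 3) * rep(ctss_off, P),
    strand = rep(prom$strand, each = 3),
    promoter_id = rep(prom$promoter_id, each = 3),
    w = rep(ctss_w, P), stringsAsFactors = FALSE)

  arch_m <- vapply(prom$archetype, function(a) archetype_profile(a, tp),
                   numeric(length(tp)))           # time x promoter
  motif_m <- 2^(design$N %*% design$A)            # promoter x time
  prom_mean_t <- t(arch_m) * motif_m * prom$baseline  # promoter x time
  rownames(prom_mean_t) <- prom$promoter_id

  ## --- emit counts and write one BED6 per sample --------------------------
  nS <- nrow(samples)
  all_keys <- character(0)
  paths <- character(nS)
  for (s in seq_len(nS)) {
    ti <- match(samples$time_h[s], tp)
    mu_p <- prom_mean_t[prom_ctss$promoter_id, ti] * prom_ctss$w
    cnt_p <- rnbinom(length(mu_p), mu = mu_p, size = config$nb_dispersion)
    bed <- data.frame(chrom = prom_ctss$chrom, start = prom_ctss$pos,
                      end = prom_ctss$pos + 1,
                      name = sprintf("%s_c%d", prom_ctss$promoter_id,
                                     rep(1:3, P)),
                      score = cnt_p, strand = prom_ctss$strand,
                      stringsAsFactors = FALSE)
    if (Eh > 0) {
      pulse <- vapply(enh$peak_h, function(pk)
        archetype_profile("pulse_at", tp[ti], peak = pk), numeric(1))
      muF <- enh$mean_level * (1 + enh$asym) * pulse
      muR <- enh$mean_level * (1 - enh$asym) * pulse
      cF <- rnbinom(Eh, mu = muF, size = config$nb_dispersion)
      cR <- rnbinom(Eh, mu = muR, size = config$nb_dispersion)
      bed <- rbind(bed,
        data.frame(chrom = enh$chrom, start = enh$pos + 90,
                   end = enh$pos + 91,
                   name = paste0(enh$enhancer_id, "_F"), score = cF,
                   strand = "+", stringsAsFactors = FALSE),
        data.frame(chrom = enh$chrom, start = enh$pos - 90,
                   end = enh$pos - 89,
                   name = paste0(enh$enhancer_id, "_R"), score = cR,
                   strand = "-", stringsAsFactors = FALSE))
    }
    bed <- bed[bed$score > 0, , drop = FALSE]
    bed <- bed[order(bed$chrom, bed$start, bed$strand), , drop = FALSE]
    paths[s] <- file.path(ctss_dir, paste0(samples$sample_id[s], ".bed"))
    write.table(bed, paths[s], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }

  ## --- genome FASTA -------------------------------------------------------
  genome <- Biostrings::DNAStringSet(vapply(chrom_len, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1)))
  names(genome) <- chroms
  fasta_path <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(genome, fasta_path, width = 80L)

  ## --- GTF annotation (1-based inclusive) ---------------------------------
  gtf_path <- file.path(out_dir, "annotation.gtf")
  tx_start <- ifelse(prom$strand == "+", prom$pos + 1, prom$pos + 1 - 400)
  tx_end <- ifelse(prom$strand == "+", prom$pos + 1 + 400, prom$pos + 1)
  gtf_lines <- unlist(lapply(seq_len(P), function(i) {
    attr9 <- sprintf('gene_id "%s"; transcript_id "%s.t1"; gene_name "%s";',
                     prom$gene[i], prom$gene[i], prom$gene[i])
    sprintf("%s\tcagecascade_sim\t%s\t%d\t%d\t.\t%s\t.\t%s",
            prom$chrom[i], c("gene", "transcript", "exon"),
            tx_start[i], tx_end[i], prom$strand[i], attr9)
  }))
  writeLines(gtf_lines, gtf_path)

  ## --- truth --------------------------------------------------------------
  truth <- list(promoters = prom, enhancers = if (Eh > 0) enh else NULL,
                motif_N = design$N, motif_A = design$A,
                time_points_h = tp)
  write.table(prom, file.path(out_dir, "truth_promoters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (Eh > 0)
    write.table(enh, file.path(out_dir, "truth_enhancers.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  write.table(design$N, file.path(out_dir, "truth_motif_counts.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  write.table(design$A, file.path(out_dir, "truth_motif_activity.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  jsonlite::write_json(
    list(promoters = prom, enhancers = if (Eh > 0) enh else list(),
         time_points_h = tp),
    file.path(out_dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  write.table(samples, file.path(out_dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  invisible(list(
    paths = list(genome = fasta_path, gtf = gtf_path, ctss = paths,
                 out_dir = out_dir),
    metadata = samples, truth = truth, config = config))
}
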