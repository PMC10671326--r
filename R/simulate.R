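# Run `expr` under a fixed RNG seed without disturbing the caller's RNG.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
            else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
    set.seed(seed)
  }
  force(expr)
}

#' Simulate RIP-Seq count tables with planted binders
#'
#' Emulates the statistical shape of a three-replicate RIP-Seq experiment:
#' negative-binomial fragment counts with log-normal baseline means shared
#' between the RIP pull-down and the non-specific-antibody control, a
#' planted subset of binders whose RIP means are scaled by `2^log2_effect`,
#' and per-transcript read intervals that put intronic reads only on
#' co-transcriptionally bound transcripts.
#'
#' @param n_transcripts Number of transcripts (default 500).
#' @param n_replicates Paired RIP/control replicates (default 3).
#' @param binder_fraction Fraction of transcripts planted as binders
#'   (default 0.10).
#' @param log2_effect Planted log2 enrichment of binders (default 2:
#'   four-fold).
#' @param dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`; default 0.05, typical of cell-line
#'   replicates).
#' @param library_size Total mapped fragments per library (default 1e6).
#' @param intronic_rate_co Per-read probability that a read from a
#'   co-transcriptionally bound transcript falls in an intron (default
#'   0.15); post-transcriptional binders get none.
#' @param mean_log,sd_log Log-normal parameters of the baseline means
#'   (defaults `log(50)`, 1.2).
#' @param seed RNG seed.
#' @return List: `models` (named list of [transcript_model()]),
#'   `rip_samples`, `ctrl_samples` (lists of [quant_sample()]),
#'   `read_intervals` (named list of interval matrices, RIP replicate 1),
#'   `truth` (`data.frame`: `transcript_id`, `binder`, `intron_class`).
#' @export
gen_rip_counts <- function(n_transcripts = 500, n_replicates = 3,
                           binder_fraction = 0.10, log2_effect = 2,
                           dispersion = 0.05, library_size = 1e6,
                           intronic_rate_co = 0.15,
                           mean_log = log(50), sd_log = 1.2, seed = 1) {
  stopifnot(binder_fraction >= 0, binder_fraction <= 1, dispersion > 0)
  .with_seed(seed, {
    ids <- sprintf("TX%04d", seq_len(n_transcripts))
    n_binders <- round(binder_fraction * n_transcripts)
    binder <- c(rep(TRUE, n_binders), rep(FALSE, n_transcripts - n_binders))
    intron_class <- rep(NA_character_, n_transcripts)
    if (n_binders > 0) {
      n_co <- floor(n_binders / 2)
      intron_class[seq_len(n_binders)] <-
        c(rep("co_transcriptional", n_co),
          rep("post_transcriptional", n_binders - n_co))
    }
    models <- vector("list", n_transcripts)
    for (i in seq_len(n_transcripts)) {
      # co-transcriptional binders need introns, hence >= 2 exons
      n_ex <- if (identical(intron_class[i], "co_transcriptional"))
        sample(2:8, 1) else sample(1:8, 1)
      ex_len <- round(stats::rlnorm(n_ex, log(300), 0.5))
      in_len <- if (n_ex > 1) round(stats::rlnorm(n_ex - 1, log(800), 0.6))
                else integer(0)
      starts <- cumsum(c(0, ex_len[-n_ex] + in_len))
      models[[i]] <- transcript_model(ids[i],
        biotype = if (stats::runif(1) < 0.9) "mRNA" else "lncRNA",
        exon_starts = starts, exon_ends = starts + ex_len)
    }
    names(models) <- ids
    mu0 <- stats::rlnorm(n_transcripts, mean_log, sd_log)
    mu_rip <- mu0 * ifelse(binder, 2^log2_effect, 1)
    size <- 1 / dispersion
    draw <- function(mu) {
      cts <- stats::rnbinom(n_transcripts, mu = mu, size = size)
      names(cts) <- ids
      cts
    }
    rip_samples <- ctrl_samples <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      rip_samples[[r]] <- quant_sample(sprintf("RIP_%d", r), "RIP", r,
                                       draw(mu_rip),
                                       total_mapped_fragments = library_size)
      ctrl_samples[[r]] <- quant_sample(sprintf("CTRL_%d", r), "control", r,
                                        draw(mu0),
                                        total_mapped_fragments = library_size)
    }
    # read intervals (RIP replicate 1): 100 nt reads placed in exons, plus
    # intronic reads for co-transcriptional binders
    read_len <- 100
    read_intervals <- vector("list", n_transcripts)
    for (i in seq_len(n_transcripts)) {
      n_reads <- min(rip_samples[[1L]]$counts[i], 300L)
      if (n_reads == 0L) {
        read_intervals[[i]] <- cbind(start = numeric(0), end = numeric(0))
        next
      }
      rate <- if (identical(intron_class[i], "co_transcriptional"))
        intronic_rate_co else 0
      n_in <- stats::rbinom(1, n_reads, rate)
      place <- function(ivs, k) {
        if (k == 0L || nrow(ivs) == 0L)
          return(cbind(start = numeric(0), end = numeric(0)))
        row <- sample.int(nrow(ivs), k, replace = TRUE,
                          prob = ivs[, 2] - ivs[, 1])
        s <- ivs[row, 1] + floor(stats::runif(k) *
                                   pmax(ivs[row, 2] - ivs[row, 1] - 1, 1))
        # clip to the containing interval so an exonic read never spills
        # into an intron (and vice versa)
        cbind(start = s, end = pmin(s + read_len, ivs[row, 2]))
      }
      read_intervals[[i]] <- rbind(place(models[[i]]$exons, n_reads - n_in),
                                   place(introns(models[[i]]), n_in))
    }
    names(read_intervals) <- ids
    list(models = models, rip_samples = rip_samples,
         ctrl_samples = ctrl_samples, read_intervals = read_intervals,
         truth = data.frame(transcript_id = ids, binder = binder,
                            intron_class = intron_class,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate an MST dilution series
#'
#' Builds capillary traces from the piecewise-exponential three-phase trace
#' model ([mst_trace_model()]) whose T-jump and thermophoresis amplitudes
#' are linear in the mass-action fraction bound at each ligand
#' concentration, adds Gaussian noise, and scales to a raw fluorescence
#' level of 300-500 counts. With `aggregation_mode = TRUE` the top-quartile
#' concentrations receive an instability artifact (10x noise plus random
#' spikes) starting 10 s into the MST-on window, emulating aggregate
#' formation at high protein concentration: the late thermophoresis phase
#' is corrupted while the early T-jump remains evaluable.
#'
#' @param true_kd_M Generating dissociation constant (molar).
#' @param labeled_conc_M Labeled RNA concentration (default 5e-9 M).
#' @param n_points Number of capillaries (default 16).
#' @param top_conc_M Highest ligand concentration (default 40e-6 M).
#' @param dilution Serial dilution factor (default 2).
#' @param noise_sd Gaussian noise SD on the normalized scale (default
#'   0.002).
#' @param aggregation_mode Plant the high-concentration instability
#'   artifact (default FALSE).
#' @param flat Generate a zero-amplitude (non-binding) series: the trace no
#'   longer depends on concentration (default FALSE).
#' @param rna_id Label for the series.
#' @param config An [mst_config()].
#' @param seed RNG seed.
#' @return An [mst_series()] with raw-count traces. The generating
#'   parameters are attached as attribute `"truth"`.
#' @export
gen_mst_series <- function(true_kd_M, labeled_conc_M = 5e-9, n_points = 16,
                           top_conc_M = 40e-6, dilution = 2,
                           noise_sd = 0.002, aggregation_mode = FALSE,
                           flat = FALSE, rna_id = "RNA",
                           config = mst_config(), seed = 1) {
  stopifnot(true_kd_M > 0, n_points >= 6)
  .with_seed(seed, {
    conc <- top_conc_M / dilution^(seq_len(n_points) - 1)
    total <- config$t_before_s + config$t_on_s + config$t_after_s
    time_s <- seq(0, total, by = 1 / config$sampling_hz)
    t0 <- config$t_before_s
    nq <- max(1L, floor(n_points / 4))
    traces <- vector("list", n_points)
    for (i in seq_len(n_points)) {
      fb <- if (flat) 0 else fraction_bound(conc[i], labeled_conc_M, true_kd_M)
      f <- mst_trace_model(time_s, fb, config)
      noise <- if (noise_sd > 0) stats::rnorm(length(time_s), 0, noise_sd)
               else 0
      f <- f + noise
      if (aggregation_mode && i <= nq) {
        # aggregates form as the spot heats: gross flicker (20x noise) and
        # transient bumps over the late MST-on phase; the early T-jump
        # phase stays evaluable
        late <- time_s >= t0 + 10 & time_s < t0 + config$t_on_s
        f[late] <- f[late] + stats::rnorm(sum(late), 0, 20 * noise_sd)
        n_spk <- 15L
        at <- sample(which(late), n_spk)
        f[at] <- f[at] + sample(c(-1, 1), n_spk, replace = TRUE) *
          stats::runif(n_spk, 0.03, 0.08)
      }
      scale <- stats::runif(1, 300, 500)
      traces[[i]] <- mst_trace(conc[i], time_s, scale * f, config)
    }
    out <- mst_series(traces, labeled_conc_M, rna_id = rna_id)
    attr(out, "truth") <- list(true_kd_M = true_kd_M, noise_sd = noise_sd,
                               aggregation_mode = aggregation_mode,
                               flat = flat)
    out
  })
}
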