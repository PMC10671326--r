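#' Transcript models
#'
#' A transcript model holds the exon structure of one transcript in 0-based,
#' half-open coordinates (internal convention; GTF input is converted on
#' read). Introns are the gaps between consecutive exons.
#'
#' @param transcript_id Character scalar.
#' @param biotype One of `"mRNA"`, `"lncRNA"`, `"snRNA"`, `"scaRNA"`,
#'   `"snoRNA"`, `"other"`.
#' @param exon_starts,exon_ends Integer vectors of equal length: exon
#'   intervals `[start, end)`, 0-based. Must be sorted and non-overlapping.
#' @return An object of class `transcript_model` with fields
#'   `transcript_id`, `biotype`, `exons` (two-column matrix `start`,`end`),
#'   and `length_nt` (sum of exon widths).
#' @export
transcript_model <- function(transcript_id, biotype = "mRNA",
                             exon_starts, exon_ends) {
  biotype <- match.arg(biotype,
                       c("mRNA", "lncRNA", "snRNA", "scaRNA", "snoRNA", "other"))
  if (length(exon_starts) != length(exon_ends) || length(exon_starts) < 1L)
    stop("exon_starts and exon_ends must be non-empty and of equal length")
  if (any(exon_ends <= exon_starts))
    stop("each exon must have end > start (0-based half-open)")
  o <- order(exon_starts)
  exon_starts <- exon_starts[o]; exon_ends <- exon_ends[o]
  if (length(exon_starts) > 1L &&
      any(exon_starts[-1L] < exon_ends[-length(exon_ends)]))
    stop("exons overlap: ", transcript_id)
  ex <- cbind(start = as.numeric(exon_starts), end = as.numeric(exon_ends))
  structure(list(transcript_id = as.character(transcript_id),
                 biotype = biotype,
                 exons = ex,
                 length_nt = sum(ex[, "end"] - ex[, "start"])),
            class = "transcript_model")
}

#' Intron intervals of a transcript model
#'
#' @param model A [transcript_model()].
#' @return Two-column matrix of `[start, end)` intron intervals; zero rows
#'   for single-exon transcripts.
#' @export
introns <- function(model) {
  ex <- model$exons
  n <- nrow(ex)
  if (n < 2L)
    return(cbind(start = numeric(0), end = numeric(0)))
  cbind(start = ex[-n, "end"], end = ex[-1L, "start"])
}

#' Per-sample quantification
#'
#' One sequencing library: per-transcript fragment counts plus the library
#' size used for FPKM normalization.
#'
#' @param sample_id Character scalar.
#' @param role One of `"RIP"`, `"control"`, `"input"`.
#' @param replicate_index Integer >= 1.
#' @param counts Named non-negative integer vector, names = transcript ids.
#' @param total_mapped_fragments Positive scalar; defaults to `sum(counts)`.
#' @return Object of class `quant_sample`.
#' @export
quant_sample <- function(sample_id, role, replicate_index, counts,
                         total_mapped_fragments = sum(counts)) {
  role <- match.arg(role, c("RIP", "control", "input"))
  if (is.null(names(counts)) || any(names(counts) == ""))
    stop("counts must be a named vector keyed by transcript_id")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (total_mapped_fragments <= 0) stop("total_mapped_fragments must be > 0")
  if (total_mapped_fragments < sum(counts))
    stop("total_mapped_fragments < sum(counts)")
  structure(list(sample_id = as.character(sample_id), role = role,
                 replicate_index = as.integer(replicate_index),
                 counts = counts,
                 total_mapped_fragments = as.numeric(total_mapped_fragments)),
            class = "quant_sample")
}

#' FPKM from fragment counts
#'
#' FPKM = count * 1e9 / (length_nt * total_mapped_fragments): fragments per
#' kilobase of transcript per million mapped fragments. A zero count gives
#' FPKM 0 regardless of length.
#'
#' @param sample A [quant_sample()].
#' @param models Named list of [transcript_model()] objects (names =
#'   transcript ids) covering every counted transcript.
#' @return Named numeric vector of FPKM values, one per counted transcript.
#' @export
compute_fpkm <- function(sample, models) {
  ids <- names(sample$counts)
  missing <- setdiff(ids, names(models))
  if (length(missing) > 0L)
    stop("no transcript model for: ", paste(missing, collapse = ", "))
  len <- vapply(models[ids], function(m) m$length_nt, numeric(1))
  if (any(len <= 0)) stop("transcript length must be > 0")
  fpkm <- sample$counts * 1e9 / (len * sample$total_mapped_fragments)
  fpkm[sample$counts == 0] <- 0
  fpkm
}

#' Call enriched transcripts from paired RIP/control replicates
#'
#' Per replicate a transcript is a positive hit when its FPKM in the RIP
#' sample strictly exceeds the FPKM in the matched negative control. The
#' per-replicate fold change is computed with a pseudocount so transcripts
#' absent from the control (FPKM 0) still get a finite ranking value. A
#' transcript is called *stringent* when its fold change exceeds 2 in at
#' least two replicates.
#'
#' @param rip_samples,ctrl_samples Lists of [quant_sample()]; paired by
#'   `replicate_index` (the sets of indices must match).
#' @param models Named list of transcript models.
#' @param pseudocount FPKM pseudocount added to numerator and denominator of
#'   the fold change (default 0.1).
#' @param min_fpkm Optional expression floor: a replicate only counts as
#'   positive if the RIP FPKM is also `>= min_fpkm`. Default 0 (off).
#' @return A `data.frame` with one row per transcript: `transcript_id`,
#'   matrix columns `fpkm_rip`, `fpkm_ctrl`, `fold_change` (one column per
#'   replicate, in increasing replicate order), `positive` (logical matrix),
#'   `n_positive_replicates`, and `stringent`.
#' @export
call_enrichment <- function(rip_samples, ctrl_samples, models,
                            pseudocount = 0.1, min_fpkm = 0) {
  rip_idx <- vapply(rip_samples, `[[`, integer(1), "replicate_index")
  ctrl_idx <- vapply(ctrl_samples, `[[`, integer(1), "replicate_index")
  if (!setequal(rip_idx, ctrl_idx) || anyDuplicated(rip_idx) ||
      anyDuplicated(ctrl_idx))
    stop("RIP and control samples must be paired 1:1 by replicate_index")
  ord <- sort(unique(rip_idx))
  rip_samples <- rip_samples[match(ord, rip_idx)]
  ctrl_samples <- ctrl_samples[match(ord, ctrl_idx)]
  ids <- sort(unique(unlist(c(lapply(rip_samples, function(s) names(s$counts)),
                              lapply(ctrl_samples, function(s) names(s$counts))))))
  n_rep <- length(ord)
  fr <- fc <- matrix(0, length(ids), n_rep,
                     dimnames = list(ids, paste0("rep", ord)))
  for (k in seq_len(n_rep)) {
    fpkm_r <- compute_fpkm(rip_samples[[k]], models)
    fpkm_c <- compute_fpkm(ctrl_samples[[k]], models)
    fr[names(fpkm_r), k] <- fpkm_r
    fc[names(fpkm_c), k] <- fpkm_c
  }
  fold <- (fr + pseudocount) / (fc + pseudocount)
  positive <- (fr > fc) & (fr >= min_fpkm)
  n_pos <- rowSums(positive)
  stringent <- rowSums(fold > 2) >= 2L
  out <- data.frame(transcript_id = ids, stringsAsFactors = FALSE)
  out$fpkm_rip <- fr
  out$fpkm_ctrl <- fc
  out$fold_change <- fold
  out$positive <- positive
  out$n_positive_replicates <- as.integer(n_pos)
  out$stringent <- stringent
  rownames(out) <- NULL
  out
}

#' Replicate-overlap (Venn) summary of positive calls
#'
#' Counts transcripts positive in each exact subset of replicates. Cells are
#' disjoint: a transcript positive in replicates 1 and 2 only is counted in
#' the `"1&2"` cell and nowhere else. Cells over all non-empty subsets sum
#' to the number of transcripts positive in at least one replicate.
#'
#' @param records Result of [call_enrichment()] (uses its `positive`
#'   matrix), or a logical matrix transcripts x replicates.
#' @param n_replicates Number of replicates (>= 2); defaults to the matrix
#'   width.
#' @return Named integer vector over all non-empty replicate subsets, names
#'   like `"1"`, `"1&3"`, `"1&2&3"`.
#' @export
replicate_overlap <- function(records, n_replicates = NULL) {
  pos <- if (is.matrix(records)) records else records$positive
  if (is.null(n_replicates)) n_replicates <- ncol(pos)
  if (n_replicates < 2L) stop("n_replicates must be >= 2")
  if (!is.null(pos) && ncol(pos) != n_replicates)
    stop("positive matrix width does not match n_replicates")
  subsets <- lapply(seq_len(n_replicates), function(k)
    utils::combn(n_replicates, k, simplify = FALSE))
  subsets <- unlist(subsets, recursive = FALSE)
  cells <- vapply(subsets, function(s) {
    if (is.null(pos) || nrow(pos) == 0L) return(0L)
    inside <- rowSums(pos[, s, drop = FALSE]) == length(s)
    outside <- if (length(s) == n_replicates) rep(FALSE, nrow(pos))
               else rowSums(pos[, -s, drop = FALSE]) > 0L
    sum(inside & !outside)
  }, integer(1))
  names(cells) <- vapply(subsets, paste, character(1), collapse = "&")
  cells
}

#' Classify co- vs post-transcriptional binding from intron coverage
#'
#' A read interval is intronic when it overlaps any intron of the transcript
#' by at least one base; otherwise it is exonic when it overlaps any exon.
#' Transcripts whose intron segments carry fewer than `min_intronic_reads`
#' reads (default 1, i.e. "no reads in introns") while exonic reads exist
#' are called post-transcriptionally bound; intron coverage at or above the
#' threshold is called co-transcriptional; no reads at all is undetected.
#' Single-exon transcripts have no introns and are post-transcriptional by
#' construction whenever exonic reads exist (annotated `single_exon`).
#'
#' @param transcript A [transcript_model()].
#' @param read_intervals Two-column matrix (start, end), 0-based half-open,
#'   same coordinate system as the exons. May have zero rows.
#' @param min_intronic_reads Integer threshold (default 1).
#' @return List with `transcript_id`, `exonic_reads`, `intronic_reads`,
#'   `call` (one of `"co_transcriptional"`, `"post_transcriptional"`,
#'   `"undetected"`), and `single_exon` flag.
#' @export
classify_intron_binding <- function(transcript, read_intervals,
                                    min_intronic_reads = 1L) {
  if (is.null(read_intervals) || NROW(read_intervals) == 0L)
    read_intervals <- cbind(start = numeric(0), end = numeric(0))
  if (is.data.frame(read_intervals)) read_intervals <- as.matrix(read_intervals)
  intr <- introns(transcript)
  ex <- transcript$exons
  overlaps_any <- function(reads, ivs) {
    if (nrow(reads) == 0L || nrow(ivs) == 0L)
      return(rep(FALSE, nrow(reads)))
    vapply(seq_len(nrow(reads)), function(i)
      any(reads[i, 1L] < ivs[, 2L] & reads[i, 2L] > ivs[, 1L]), logical(1))
  }
  is_intronic <- overlaps_any(read_intervals, intr)
  is_exonic <- overlaps_any(read_intervals, ex) & !is_intronic
  n_in <- sum(is_intronic); n_ex <- sum(is_exonic)
  call <- if (n_in + n_ex == 0L) "undetected"
          else if (n_in >= min_intronic_reads) "co_transcriptional"
          else "post_transcriptional"
  list(transcript_id = transcript$transcript_id,
       exonic_reads = n_ex, intronic_reads = n_in, call = call,
       single_exon = nrow(ex) == 1L)
}

#' RIP-qPCR fold enrichment (delta-delta-Ct)
#'
#' Input-normalized Ct differences between the specific and the non-specific
#' (control antibody) immunoprecipitation. The input Ct is first adjusted
#' for the input dilution (`log2(1/input_fraction)` cycles, 3.32 for a 10%
#' input); the adjustment cancels in the final fold enrichment, which
#' reduces to `2^(ct_control_ip - ct_specific_ip)`.
#'
#' @param ct_specific_ip,ct_control_ip,ct_input Ct values (cycles, finite,
#'   within 0-45). `ct_input` is accepted for interface completeness; it
#'   cancels algebraically.
#' @param input_fraction Fraction of lysate kept as input, in (0, 1]
#'   (default 0.10).
#' @return Fold enrichment (specific over control IP), a positive scalar.
#' @export
qpcr_fold_enrichment <- function(ct_specific_ip, ct_control_ip,
                                 ct_input = NA_real_, input_fraction = 0.10) {
  stopifnot(is.finite(ct_specific_ip), is.finite(ct_control_ip))
  .check_ct(c(ct_specific_ip, ct_control_ip))
  adj <- if (is.finite(ct_input)) ct_input - log2(1 / input_fraction) else 0
  dct_spec <- ct_specific_ip - adj
  dct_ctrl <- ct_control_ip - adj
  2^(-(dct_spec - dct_ctrl))
}

#' RIP-qPCR yield as percent of input
#'
#' `%input = 100 * 2^((ct_input - log2(1/input_fraction)) - ct_specific_ip)`:
#' the input Ct is shifted down by the dilution correction (3.32 cycles for
#' a 10% input) to represent 100% of the material, then compared with the IP.
#'
#' @inheritParams qpcr_fold_enrichment
#' @return Percent of input recovered in the IP (0-100 scale, can exceed 100
#'   for super-recovery artifacts).
#' @export
qpcr_percent_input <- function(ct_specific_ip, ct_input,
                               input_fraction = 0.10) {
  stopifnot(is.finite(ct_specific_ip), is.finite(ct_input),
            input_fraction > 0, input_fraction <= 1)
  .check_ct(c(ct_specific_ip, ct_input))
  100 * 2^((ct_input - log2(1 / input_fraction)) - ct_specific_ip)
}

.check_ct <- function(ct) {
  if (any(ct < 0 | ct > 45))
    stop("Ct values must lie within [0, 45] cycles")
  invisible(TRUE)
}
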