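#' Read a long-format RIP-Seq count table
#'
#' TSV with columns `sample_id`, `role` (RIP/control/input), `replicate`,
#' `transcript_id`, `count`, and optionally `total_mapped_fragments` (library
#' size per sample; computed as the column sum per sample when absent).
#'
#' @param path TSV path.
#' @return List of [quant_sample()] objects split by role:
#'   `rip_samples`, `ctrl_samples`, `input_samples`.
#' @export
read_count_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "role", "replicate", "transcript_id", "count")
  if (!all(need %in% names(tab)))
    stop("count table must have columns: ", paste(need, collapse = ", "))
  samples <- lapply(split(tab, tab$sample_id), function(sub) {
    role <- match.arg(tolower(sub$role[1L]), c("rip", "control", "input"))
    cts <- stats::setNames(sub$count, sub$transcript_id)
    tot <- if ("total_mapped_fragments" %in% names(sub))
      max(sub$total_mapped_fragments) else sum(cts)
    quant_sample(sub$sample_id[1L],
                 switch(role, rip = "RIP", control = "control",
                        input = "input"),
                 sub$replicate[1L], cts, tot)
  })
  roles <- vapply(samples, `[[`, character(1), "role")
  list(rip_samples = unname(samples[roles == "RIP"]),
       ctrl_samples = unname(samples[roles == "control"]),
       input_samples = unname(samples[roles == "input"]))
}

#' Write count tables for a simulated RIP experiment
#'
#' @param sim Result of [gen_rip_counts()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(sim, path) {
  rows <- lapply(c(sim$rip_samples, sim$ctrl_samples), function(s)
    data.frame(sample_id = s$sample_id, role = s$role,
               replicate = s$replicate_index,
               transcript_id = names(s$counts), count = unname(s$counts),
               total_mapped_fragments = s$total_mapped_fragments,
               stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read transcript models from a flattened exon TSV
#'
#' TSV with one row per exon: `transcript_id`, `biotype`, `exon_start`,
#' `exon_end` (0-based half-open, the internal convention).
#'
#' @param path TSV path.
#' @return Named list of [transcript_model()] objects.
#' @export
read_transcript_models_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  models <- lapply(split(tab, tab$transcript_id), function(sub)
    transcript_model(sub$transcript_id[1L], sub$biotype[1L],
                     sub$exon_start, sub$exon_end))
  models[order(names(models))]
}

#' Write transcript models to a flattened exon TSV
#'
#' @param models Named list of [transcript_model()] objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_transcript_models_tsv <- function(models, path) {
  rows <- lapply(models, function(m)
    data.frame(transcript_id = m$transcript_id, biotype = m$biotype,
               exon_start = m$exons[, "start"], exon_end = m$exons[, "end"],
               stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read transcript models from a GTF file
#'
#' Uses `rtracklayer` when available. GTF coordinates (1-based inclusive)
#' are converted to the internal 0-based half-open convention; exon records
#' are grouped by `transcript_id`. Biotype is taken from
#' `transcript_biotype`/`gene_biotype` when present and mapped to the
#' internal enum (`protein_coding` -> `mRNA`, `lncRNA` kept, everything
#' else `other`).
#'
#' @param path GTF path.
#' @return Named list of [transcript_model()] objects.
#' @export
read_transcript_models_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GTF requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  df <- data.frame(transcript_id = gr$transcript_id,
                   start = BiocGenerics::start(gr) - 1L,  # to 0-based
                   end = BiocGenerics::end(gr),
                   biotype = if (!is.null(gr$transcript_biotype))
                     gr$transcript_biotype
                   else if (!is.null(gr$gene_biotype)) gr$gene_biotype
                   else "other",
                   stringsAsFactors = FALSE)
  df$biotype <- ifelse(df$biotype == "protein_coding", "mRNA",
                ifelse(df$biotype %in% c("lncRNA", "lincRNA"), "lncRNA",
                ifelse(df$biotype %in% c("snRNA", "scaRNA", "snoRNA"),
                       df$biotype, "other")))
  models <- lapply(split(df, df$transcript_id), function(sub)
    transcript_model(sub$transcript_id[1L], sub$biotype[1L],
                     sub$start, sub$end))
  models[order(names(models))]
}

#' Write enrichment records to TSV
#'
#' Flattens the matrix columns of a [call_enrichment()] result to
#' per-replicate columns (`fpkm_rip_rep1`, ...).
#'
#' @param records [call_enrichment()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(records, path) {
  flat <- data.frame(transcript_id = records$transcript_id,
                     stringsAsFactors = FALSE)
  for (col in c("fpkm_rip", "fpkm_ctrl", "fold_change", "positive")) {
    m <- records[[col]]
    colnames(m) <- paste0(col, "_", colnames(m))
    flat <- cbind(flat, as.data.frame(m))
  }
  flat$n_positive_replicates <- records$n_positive_replicates
  flat$stringent <- records$stringent
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write MST traces and a JSON manifest for a series
#'
#' One CSV (`time_s`, `fluorescence`, `capillary_id`) plus a JSON manifest
#' holding the per-capillary ligand concentrations, the labeled-species
#' concentration, and the instrument timing.
#'
#' @param series An [mst_series()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_mst_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(series$traces), function(i) {
    tr <- series$traces[[i]]
    data.frame(time_s = tr$time_s, fluorescence = tr$fluorescence,
               capillary_id = i)
  })
  utils::write.csv(do.call(rbind, rows),
                   file.path(dir, "traces.csv"), row.names = FALSE)
  cfg <- series$traces[[1L]]$config
  manifest <- list(rna_id = series$rna_id,
                   labeled_conc_M = series$labeled_conc_M,
                   ligand_conc_M = vapply(series$traces, `[[`, numeric(1),
                                          "ligand_conc_M"),
                   config = unclass(cfg))
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

#' Read an MST series written by [write_mst_series()]
#'
#' @param dir Directory containing `traces.csv` and `manifest.json`.
#' @return An [mst_series()].
#' @export
read_mst_series <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- do.call(mst_config, as.list(manifest$config))
  tab <- utils::read.csv(file.path(dir, "traces.csv"))
  traces <- lapply(seq_along(manifest$ligand_conc_M), function(i) {
    sub <- tab[tab$capillary_id == i, , drop = FALSE]
    mst_trace(manifest$ligand_conc_M[i], sub$time_s, sub$fluorescence, cfg)
  })
  mst_series(traces, manifest$labeled_conc_M, rna_id = manifest$rna_id)
}

#' Format per-RNA Kd fits as a three-readout table
#'
#' @param fits_by_rna List (one element per RNA) of lists of `kd_fit`
#'   objects.
#' @return `data.frame` with one row per RNA and `"n.d."` strings for
#'   not-determined cells.
#' @export
kd_table <- function(fits_by_rna) {
  do.call(rbind, lapply(fits_by_rna, function(f) classify_binding(f)$table))
}

#' Write a contact-frequency map and its filter report
#'
#' @param cfm A [contact_frequency()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_contact_map <- function(cfm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cfm$map, file.path(dir, "contact_frequency.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(cfm$report),
                       file.path(dir, "filter_report.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
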