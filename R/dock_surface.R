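#' Docked pose ensemble
#'
#' Bundles a rigid receptor, a list of docked RNA poses sharing the
#' receptor frame, and an optional reference complex used for clash
#' filtering (e.g. the receptor modeled inside its larger multi-subunit
#' assembly). Pose RNA is held as atom tables; the receptor is assumed
#' superposed across poses (docking programs emit poses in the receptor
#' frame). When poses carry their own receptor copy, a residual-RMSD guard
#' (> 0.1 Angstrom fails) should be applied upstream.
#'
#' @param receptor Protein atom `data.frame` ([read_structure()] layout).
#' @param poses Named list of RNA atom `data.frame`s, one per pose.
#' @param reference_complex Optional atom `data.frame` of the reference
#'   assembly in the same frame; chains matching the receptor are excluded
#'   from clash tests automatically via `reference_partner_chains`.
#' @param reference_partner_chains Chains of `reference_complex` that
#'   belong to the partner subunits (not the receptor itself). Default: all
#'   chains whose id differs from the receptor chain ids.
#' @return Object of class `pose_ensemble`.
#' @export
pose_ensemble <- function(receptor, poses, reference_complex = NULL,
                          reference_partner_chains = NULL) {
  stopifnot(nrow(receptor) > 0, length(poses) > 0)
  if (is.null(names(poses)))
    names(poses) <- sprintf("pose_%03d", seq_along(poses))
  if (!is.null(reference_complex)) {
    if (is.null(reference_partner_chains))
      reference_partner_chains <-
        setdiff(unique(reference_complex$chain_id), unique(receptor$chain_id))
    reference_complex <-
      reference_complex[reference_complex$chain_id %in%
                          reference_partner_chains, , drop = FALSE]
  }
  structure(list(receptor = receptor, poses = poses,
                 reference_complex = reference_complex),
            class = "pose_ensemble")
}

#' @export
print.pose_ensemble <- function(x, ...) {
  cat(sprintf("Pose ensemble: %d poses, receptor %d atoms / %d residues, reference %s\n",
              length(x$poses), nrow(x$receptor),
              length(unique(paste(x$receptor$chain_id, x$receptor$residue_index))),
              if (is.null(x$reference_complex)) "absent" else "present"))
  invisible(x)
}

# atoms of the first and last residue of each RNA chain
.terminal_atoms <- function(rna_atoms) {
  keep <- unlist(lapply(split(seq_len(nrow(rna_atoms)), rna_atoms$chain_id),
    function(i) {
      ri <- rna_atoms$residue_index[i]
      i[ri == min(ri) | ri == max(ri)]
    }), use.names = FALSE)
  rna_atoms[keep, , drop = FALSE]
}

#' Terminal-proximity filter
#'
#' Drops a pose when the receptor binds too close to an RNA end: any
#' receptor atom strictly within `threshold_A` of any atom of a terminal
#' (first or last per chain) nucleotide. Such poses are artifacts of
#' docking against trimmed RNA cores, where a free end is not a real
#' feature of the molecule. A single-nucleotide chain is all-terminal.
#'
#' @param rna_atoms RNA atom `data.frame` of the pose.
#' @param receptor Receptor atom `data.frame`.
#' @param threshold_A Distance threshold in Angstroms (default 5; drop at
#'   strictly less than the threshold).
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
filter_terminal_proximity <- function(rna_atoms, receptor, threshold_A = 5) {
  term <- .terminal_atoms(rna_atoms)
  min_distance(term, receptor) >= threshold_A
}

#' Reference-complex clash filter
#'
#' Drops a pose when its RNA overlaps partner polypeptide chains of a
#' reference assembly: any RNA heavy atom strictly within `clash_A` of any
#' partner heavy atom. The default 2.5 Angstroms is below the minimum
#' non-bonded heavy-atom approach, so only unambiguous overlap trips it.
#' With no reference the filter is a no-op (keep).
#'
#' @param rna_atoms RNA atom `data.frame` of the pose.
#' @param reference_partner Partner-chain atoms of the reference complex
#'   (receptor chains already excluded), or `NULL`.
#' @param clash_A Clash threshold in Angstroms (default 2.5).
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
filter_reference_clash <- function(rna_atoms, reference_partner,
                                   clash_A = 2.5) {
  if (is.null(reference_partner) || nrow(reference_partner) == 0L)
    return(TRUE)
  min_distance(rna_atoms, reference_partner) >= clash_A
}

#' Receptor residues contacted by a pose
#'
#' A receptor residue is in contact when any of its atoms lies strictly
#' within `contact_A` of any RNA atom of the pose.
#'
#' @param rna_atoms RNA atom `data.frame` of the pose.
#' @param receptor Receptor atom `data.frame`.
#' @param contact_A Contact threshold in Angstroms (default 5, strict `<`).
#' @return Sorted integer vector of contacted `residue_index` values
#'   (receptor assumed single-chain for indexing; multi-chain receptors are
#'   keyed `chain:index`).
#' @export
residue_contact_set <- function(rna_atoms, receptor, contact_A = 5) {
  d2 <- .row_min_dist2(.xyz(receptor), .xyz(rna_atoms))
  hit <- d2 < contact_A^2
  keys <- if (length(unique(receptor$chain_id)) > 1L)
    paste0(receptor$chain_id, ":", receptor$residue_index)
  else receptor$residue_index
  out <- unique(keys[hit])
  if (is.numeric(out)) sort(out) else sort(out)
}

#' Filter an ensemble and map per-residue contact frequencies
#'
#' Applies the terminal-proximity filter and the reference-clash filter
#' (order-independent: each pose is tested against both rules), then counts,
#' for every receptor residue, the fraction of retained poses in which the
#' residue contacts the RNA.
#'
#' @param ensemble A [pose_ensemble()].
#' @param terminal_A,clash_A,contact_A Thresholds in Angstroms (defaults
#'   5 / 2.5 / 5).
#' @return Object of class `contact_frequency_map`: list with
#'   `map` (`data.frame`: `residue_index`, `residue_name`, `contact_count`,
#'   `frequency`), `n_retained`, `report` (named counts: `n_input`,
#'   `dropped_terminal`, `dropped_clash`, `dropped_both`, `retained`), and
#'   `retained_poses` (names). All-dropped ensembles return an empty map
#'   with a warning.
#' @export
contact_frequency <- function(ensemble, terminal_A = 5, clash_A = 2.5,
                              contact_A = 5) {
  stopifnot(inherits(ensemble, "pose_ensemble"))
  rec <- ensemble$receptor
  ref <- ensemble$reference_complex
  keep_term <- vapply(ensemble$poses, filter_terminal_proximity,
                      logical(1), receptor = rec, threshold_A = terminal_A)
  keep_clash <- vapply(ensemble$poses, filter_reference_clash,
                       logical(1), reference_partner = ref, clash_A = clash_A)
  retained <- keep_term & keep_clash
  report <- c(n_input = length(retained),
              dropped_terminal = sum(!keep_term & keep_clash),
              dropped_clash = sum(keep_term & !keep_clash),
              dropped_both = sum(!keep_term & !keep_clash),
              retained = sum(retained))
  res_tab <- unique(data.frame(residue_index = rec$residue_index,
                               residue_name = rec$residue_name,
                               stringsAsFactors = FALSE))
  res_tab <- res_tab[order(res_tab$residue_index), , drop = FALSE]
  counts <- integer(nrow(res_tab))
  names(counts) <- as.character(res_tab$residue_index)
  if (sum(retained) == 0L) {
    warning("all poses removed by the filters; empty contact map")
  } else {
    for (p in ensemble$poses[retained]) {
      hit <- as.character(residue_contact_set(p, rec, contact_A = contact_A))
      counts[hit] <- counts[hit] + 1L
    }
  }
  res_tab$contact_count <- unname(counts)
  res_tab$frequency <- if (sum(retained) > 0L)
    res_tab$contact_count / sum(retained) else 0
  rownames(res_tab) <- NULL
  structure(list(map = res_tab, n_retained = sum(retained),
                 report = report,
                 retained_poses = names(ensemble$poses)[retained]),
            class = "contact_frequency_map")
}

#' @export
print.contact_frequency_map <- function(x, ...) {
  cat(sprintf("Contact-frequency map: %d/%d poses retained (terminal: %d, clash: %d, both: %d dropped)\n",
              x$report["retained"], x$report["n_input"],
              x$report["dropped_terminal"], x$report["dropped_clash"],
              x$report["dropped_both"]))
  top <- x$map[order(-x$map$frequency), ][seq_len(min(5L, nrow(x$map))), ]
  cat("Top residues:\n")
  print(top, row.names = FALSE)
  invisible(x)
}

#' Write a receptor PDB with contact frequencies in the B-factor column
#'
#' @param ensemble A [pose_ensemble()].
#' @param cfm A [contact_frequency()] result for that ensemble.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_frequency_pdb <- function(ensemble, cfm, path) {
  freq <- cfm$map$frequency[match(ensemble$receptor$residue_index,
                                  cfm$map$residue_index)]
  freq[is.na(freq)] <- 0
  write_pdb(ensemble$receptor, path, bfactor = round(100 * freq, 2))
}
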