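# Small fixtures built in code, shared across test files.

# two-exon transcript: exons [0,500) and [1500,2000), intron [500,1500)
fix_model2 <- function(id = "TX1", biotype = "mRNA")
  transcript_model(id, biotype, exon_starts = c(0, 1500),
                   exon_ends = c(500, 2000))

fix_model1 <- function(id = "TX2")
  transcript_model(id, "lncRNA", exon_starts = 0, exon_ends = 900)

# quant sample with given counts on the two fixture transcripts
fix_sample <- function(counts, role = "RIP", rep = 1L, total = 1e6)
  quant_sample(paste0(role, rep), role, rep, counts, total)

# samples realizing target per-replicate FPKMs on a 1 kb transcript with a
# 1e6-fragment library (FPKM == count there)
fix_paired_samples <- function(fpkm_rip, fpkm_ctrl) {
  models <- list(TX = transcript_model("TX", "mRNA", 0, 1000))
  rip <- lapply(seq_along(fpkm_rip), function(r)
    quant_sample(paste0("R", r), "RIP", r, c(TX = fpkm_rip[r]), 1e6))
  ctrl <- lapply(seq_along(fpkm_ctrl), function(r)
    quant_sample(paste0("C", r), "control", r, c(TX = fpkm_ctrl[r]), 1e6))
  list(models = models, rip = rip, ctrl = ctrl)
}

# brute-force Venn cells from a logical matrix, by direct enumeration
brute_venn <- function(pos) {
  n <- ncol(pos)
  subsets <- unlist(lapply(seq_len(n), function(k)
    utils::combn(n, k, simplify = FALSE)), recursive = FALSE)
  out <- vapply(subsets, function(s) {
    sum(apply(pos, 1, function(row)
      all(row[s]) && !any(row[setdiff(seq_len(n), s)])))
  }, numeric(1))
  names(out) <- vapply(subsets, paste, character(1), collapse = "&")
  out
}

# all-pairs brute-force residue contact set (independent of package internals)
brute_contact_set <- function(rna, receptor, contact_A = 5) {
  hit <- logical(nrow(receptor))
  for (i in seq_len(nrow(receptor))) {
    d <- sqrt((rna$x - receptor$x[i])^2 + (rna$y - receptor$y[i])^2 +
                (rna$z - receptor$z[i])^2)
    hit[i] <- any(d < contact_A)
  }
  sort(unique(receptor$residue_index[hit]))
}

# minimal hand-written PDB text (3 atoms, known coordinates)
fix_pdb_lines <- function() c(
  "HEADER    TEST",
  "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       2.500  -1.250   0.000  1.00  0.00           C",
  "ATOM      3  O   HOH A   2       9.000   9.000   9.000  1.00  0.00           O",
  "ATOM      4  P     A R   1       0.000   0.000   5.000  1.00  0.00           P",
  "END")
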