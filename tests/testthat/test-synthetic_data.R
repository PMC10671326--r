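test_that("generators are deterministic given a seed and leave the RNG alone", {
  a <- gen_rip_counts(n_transcripts = 50, seed = 7)
  b <- gen_rip_counts(n_transcripts = 50, seed = 7)
  expect_identical(a$rip_samples[[1]]$counts, b$rip_samples[[1]]$counts)
  expect_identical(a$truth, b$truth)
  c_ <- gen_rip_counts(n_transcripts = 50, seed = 8)
  expect_false(identical(a$rip_samples[[1]]$counts,
                         c_$rip_samples[[1]]$counts))
  expect_identical(names(a$truth), names(c_$truth))

  set.seed(123); before <- runif(1)
  set.seed(123); invisible(gen_mst_series(1e-6, seed = 3)); after <- runif(1)
  expect_identical(before, after)

  s1 <- gen_mst_series(1e-6, seed = 3)
  s2 <- gen_mst_series(1e-6, seed = 3)
  expect_identical(s1$traces[[1]]$fluorescence, s2$traces[[1]]$fluorescence)

  g1 <- gen_pose_ensemble(n_poses = 5, seed = 3)
  g2 <- gen_pose_ensemble(n_poses = 5, seed = 3)
  expect_identical(g1$ensemble$poses[[1]], g2$ensemble$poses[[1]])
})

test_that("null RIP model: fold changes concentrate near 1", {
  meds <- vapply(1:5, function(sd) {
    sim <- gen_rip_counts(n_transcripts = 300, binder_fraction = 0, seed = sd)
    rec <- call_enrichment(sim$rip_samples, sim$ctrl_samples, sim$models)
    median(rec$fold_change)
  }, numeric(1))
  expect_true(all(meds > 0.8 & meds < 1.25))
})

test_that("planted binders carry the planted effect size", {
  # mean empirical fold change of binders ~ 2^log2_effect over seeds
  ratios <- vapply(1:20, function(sd) {
    sim <- gen_rip_counts(n_transcripts = 200, seed = sd)
    b <- sim$truth$binder
    mr <- rowMeans(vapply(sim$rip_samples, `[[`, numeric(200), "counts"))
    mc <- rowMeans(vapply(sim$ctrl_samples, `[[`, numeric(200), "counts"))
    keep <- b & mc > 5
    mean(mr[keep] / mc[keep])
  }, numeric(1))
  expect_gt(mean(ratios), 4 * 0.85)
  expect_lt(mean(ratios), 4 * 1.15)
})

test_that("intronic_rate_co = 0 degenerates all binders to post-transcriptional", {
  sim <- gen_rip_counts(n_transcripts = 100, intronic_rate_co = 0, seed = 2)
  idx <- which(sim$truth$binder)
  calls <- vapply(idx, function(i)
    classify_intron_binding(sim$models[[i]], sim$read_intervals[[i]])$call,
    character(1))
  expect_true(all(calls %in% c("post_transcriptional", "undetected")))
})

test_that("RIP tables round-trip through the TSV readers", {
  sim <- gen_rip_counts(n_transcripts = 40, seed = 5)
  d <- withr::local_tempdir()
  cpath <- file.path(d, "counts.tsv")
  mpath <- file.path(d, "models.tsv")
  write_count_table(sim, cpath)
  write_transcript_models_tsv(sim$models, mpath)
  back <- read_count_table(cpath)
  models <- read_transcript_models_tsv(mpath)
  expect_length(back$rip_samples, 3)
  expect_length(back$ctrl_samples, 3)
  # same enrichment calls from the round-tripped inputs
  r1 <- call_enrichment(sim$rip_samples, sim$ctrl_samples, sim$models)
  r2 <- call_enrichment(back$rip_samples, back$ctrl_samples, models)
  r2 <- r2[match(r1$transcript_id, r2$transcript_id), ]
  expect_equal(r1$stringent, r2$stringent)
  expect_equal(unname(r1$fold_change), unname(r2$fold_change))
})

test_that("MST series round-trips through CSV/JSON and refits identically", {
  s <- gen_mst_series(2e-6, n_points = 8, seed = 9)
  d <- withr::local_tempdir()
  write_mst_series(s, d)
  back <- read_mst_series(d)
  expect_equal(length(back$traces), 8)
  expect_equal(back$labeled_conc_M, s$labeled_conc_M)
  f1 <- fit_isotherm(s, "tjump")
  f2 <- fit_isotherm(back, "tjump")
  expect_equal(f2$kd_M, f1$kd_M, tolerance = 1e-6)
})

test_that("MST generator: Kd ordering shows in half-saturation and truth attr", {
  weak <- gen_mst_series(15.5e-6, noise_sd = 0, seed = 1)
  tight <- gen_mst_series(0.87e-6, noise_sd = 0, seed = 1)
  half_conc <- function(s) {
    tr <- lapply(s$traces, normalize_trace)
    L <- vapply(tr, `[[`, numeric(1), "ligand_conc_M")
    y <- vapply(tr, extract_readout, numeric(1), readout = "tjump")
    yn <- (y - max(y)) / (min(y) - max(y))   # 0 at free, 1 at bound
    L[which.min(abs(yn - 0.5))]
  }
  expect_gt(half_conc(weak), half_conc(tight))
  expect_equal(attr(weak, "truth")$true_kd_M, 15.5e-6)
})

test_that("pose generator plants violations exactly, hotspots recoverably", {
  # planted clash poses are exactly the dropped-by-clash set
  g <- gen_pose_ensemble(n_poses = 10, clash_fraction = 0.3,
                         terminal_contact_fraction = 0, seed = 13)
  keep <- vapply(g$ensemble$poses, filter_reference_clash, logical(1),
                 reference_partner = g$ensemble$reference_complex)
  expect_setequal(names(which(!keep)),
                  g$truth$pose_id[g$truth$class == "clash"])
  expect_length(which(!keep), 3)

  # near-uniform map without bias: hotspot and background comparable
  hot_idx <- function(g) {
    ca <- g$ensemble$receptor[g$ensemble$receptor$atom_name == "CA", ]
    ca$residue_index[order(ca$x)][1:8]
  }
  freq_by_class <- function(bias, seeds) {
    hs <- NULL; fh <- fb <- 0
    for (sd in seeds) {
      g <- gen_pose_ensemble(n_poses = 30, clash_fraction = 0,
                             terminal_contact_fraction = 0,
                             hotspot_bias = bias, seed = sd)
      hs <- hot_idx(g)
      cfm <- contact_frequency(g$ensemble)
      fh <- fh + mean(cfm$map$frequency[cfm$map$residue_index %in% hs])
      fb <- fb + mean(cfm$map$frequency[!cfm$map$residue_index %in% hs])
    }
    c(hot = fh, bg = fb) / length(seeds)
  }
  f0 <- freq_by_class(0, 1:6)
  expect_lt(f0["hot"] / f0["bg"], 2.5)
  f3 <- freq_by_class(3, 1:6)
  expect_gt(f3["hot"], 1.5 * f3["bg"])
})

test_that("hotspot membership correlates with contact frequency (20 seeds)", {
  tot <- NULL; hs <- NULL
  for (sd in 1:20) {
    g <- gen_pose_ensemble(n_poses = 12, clash_fraction = 0,
                           terminal_contact_fraction = 0,
                           hotspot_bias = 4, seed = sd)
    cfm <- contact_frequency(g$ensemble)
    if (is.null(tot)) {
      tot <- cfm$map$frequency
      ca <- g$ensemble$receptor[g$ensemble$receptor$atom_name == "CA", ]
      hs <- cfm$map$residue_index %in% ca$residue_index[order(ca$x)][1:8]
    } else tot <- tot + cfm$map$frequency
  }
  ct <- suppressWarnings(
    cor.test(tot, as.numeric(hs), method = "spearman",
             alternative = "greater"))
  expect_lt(ct$p.value, 0.01)
})

test_that("pose ensembles round-trip through PDB files", {
  g <- gen_pose_ensemble(n_poses = 3, clash_fraction = 0,
                         terminal_contact_fraction = 0, seed = 17)
  d <- withr::local_tempdir()
  write_pdb(g$ensemble$receptor, file.path(d, "receptor.pdb"))
  write_pdb(g$ensemble$poses[[1]], file.path(d, "pose1.pdb"))
  rec <- read_structure(file.path(d, "receptor.pdb"))
  pose <- read_structure(file.path(d, "pose1.pdb"))
  s1 <- residue_contact_set(g$ensemble$poses[[1]], g$ensemble$receptor)
  s2 <- residue_contact_set(pose, rec)
  expect_identical(as.integer(s1), as.integer(s2))
})
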