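# -- synthetic structures -----------------------------------------------------
# Coarse stand-ins for a receptor domain, a partner subunit, and docked RNA.
# Only inter-atomic distances matter to the stage under test, so residues are
# laid out on a Fibonacci sphere (receptor/partner) and the RNA is a two-atom-
# per-nucleotide A-form-like helix trace. All are deterministic (no RNG).

#' Synthetic receptor structure
#'
#' A ~100-residue synthetic protein shell: alpha carbons on a Fibonacci
#' sphere (every residue surface-exposed) with three additional backbone
#' heavy atoms per residue. This is a geometric stand-in, not a real fold.
#'
#' @param n_res Number of residues (default 100).
#' @param radius_A Shell radius (default 12).
#' @param center Numeric length-3 center (default origin).
#' @param chain_id Chain identifier (default "A").
#' @return Atom `data.frame` in [read_structure()] layout.
#' @export
synthetic_receptor <- function(n_res = 100, radius_A = 12,
                               center = c(0, 0, 0), chain_id = "A") {
  i <- seq_len(n_res)
  golden <- (1 + sqrt(5)) / 2
  z <- 1 - (2 * i - 1) / n_res
  theta <- 2 * pi * i / golden
  r <- sqrt(pmax(1 - z^2, 0))
  ca <- radius_A * cbind(r * cos(theta), r * sin(theta), z)
  offs <- rbind(N = c(-1.2, 0.6, 0.2), CA = c(0, 0, 0),
                C = c(1.2, 0.5, -0.2), O = c(1.9, -0.5, 0.4))
  xyz <- do.call(rbind, lapply(i, function(k)
    sweep(offs, 2, ca[k, ] + center, "+")))
  aa <- rep_len(.AA3[1:20], n_res)
  data.frame(atom_name = rep(rownames(offs), n_res),
             element = rep(c("N", "C", "C", "O"), n_res),
             residue_index = rep(i, each = 4L),
             residue_name = rep(aa, each = 4L),
             chain_id = chain_id,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             molecule_class = "protein",
             stringsAsFactors = FALSE)
}

#' Synthetic reference complex (receptor plus partner subunit)
#'
#' The receptor (chain A, at the origin) rigidly assembled with a synthetic
#' 60-residue partner subunit (chain B) centered 40 Angstroms away along +x,
#' emulating a modeled multi-subunit assembly used for clash filtering.
#'
#' @param receptor Receptor atoms (default [synthetic_receptor()]).
#' @return Atom `data.frame` of the two-chain complex.
#' @export
synthetic_reference_complex <- function(receptor = synthetic_receptor()) {
  partner <- synthetic_receptor(n_res = 60, radius_A = 10,
                                center = c(40, 0, 0), chain_id = "B")
  rbind(receptor, partner)
}

#' Synthetic RNA pose geometry
#'
#' A phosphate-trace helix: per nucleotide a P and a C4' atom on an A-form
#' like helix (radius 9 A, rise 2.81 A, twist 32.7 degrees), centered at the
#' origin with the helix axis along z, residues 5'-to-3' by index.
#'
#' @param n_nt Number of nucleotides (default 40).
#' @param chain_id RNA chain id (default "R").
#' @return Atom `data.frame` in [read_structure()] layout.
#' @export
rna_pose_helix <- function(n_nt = 40, chain_id = "R") {
  i <- seq_len(n_nt)
  ang <- (i - 1) * 32.7 * pi / 180
  zz <- (i - 1) * 2.81
  P <- cbind(9 * cos(ang), 9 * sin(ang), zz)
  C4 <- cbind(7.4 * cos(ang + 0.25), 7.4 * sin(ang + 0.25), zz + 1.2)
  xyz <- rbind(P, C4)[rep(i, each = 2L) + c(0L, n_nt), , drop = FALSE]
  xyz <- sweep(xyz, 2, colMeans(xyz))
  data.frame(atom_name = rep(c("P", "C4'"), n_nt),
             element = rep(c("P", "C"), n_nt),
             residue_index = rep(i, each = 2L),
             residue_name = rep_len(c("A", "U", "G", "C"), n_nt)[rep(i, each = 2L)],
             chain_id = chain_id,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             molecule_class = "rna",
             stringsAsFactors = FALSE)
}

# rotation matrix sending z to unit vector u, with spin about u
.rot_z_to <- function(u, spin = 0) {
  u <- u / sqrt(sum(u^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * u[3] - z[3] * u[2], z[3] * u[1] - z[1] * u[3],
         z[1] * u[2] - z[2] * u[1])
  s <- sqrt(sum(v^2)); cth <- sum(z * u)
  R <- if (s < 1e-12) diag(3) * sign(cth) else {
    vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    diag(3) + vx + vx %*% vx * (1 - cth) / s^2
  }
  cs <- cos(spin); sn <- sin(spin)
  Rz <- matrix(c(cs, sn, 0, -sn, cs, 0, 0, 0, 1), 3, 3)
  R %*% Rz
}

.apply_rigid <- function(atoms, R, shift) {
  xyz <- .xyz(atoms) %*% t(R)
  atoms$x <- xyz[, 1] + shift[1]
  atoms$y <- xyz[, 2] + shift[2]
  atoms$z <- xyz[, 3] + shift[3]
  atoms
}

# translate pose along direction u until min distance to target is ~gap
.settle_gap <- function(atoms, target_xyz, u, gap, iters = 8L) {
  for (k in seq_len(iters)) {
    d <- min_distance(.xyz(atoms), target_xyz)
    if (abs(d - gap) < 0.2) break
    atoms <- .apply_rigid(atoms, diag(3), (gap - d) * u)
  }
  atoms
}

#' Simulate a docked-pose ensemble with planted filter violations
#'
#' Generates `n_poses` rigid placements of a synthetic RNA helix around a
#' synthetic receptor, with known planted classes:
#' * `clean` poses dock tangentially at 3.5-4.5 A from the receptor surface,
#'   terminals kept beyond 5.5 A of the receptor and all atoms beyond 3.5 A
#'   of the reference partner, so neither filter fires;
#' * `terminal` poses approach the receptor end-on, a terminal nucleotide at
#'   4 A (tripping the terminal-proximity rule only);
#' * `clash` poses are buried in the reference partner subunit (tripping the
#'   clash rule only; they sit > 13 A from the receptor).
#'
#' Clean-pose anchor residues are drawn with weight `1 + hotspot_bias` for
#' hotspot residues, planting a contact hotspot recoverable from the
#' frequency map.
#'
#' @param n_poses Ensemble size (default 70).
#' @param rna_length_nt Nucleotides per pose (default 40).
#' @param hotspot_residues Receptor residue indices forming the planted
#'   hotspot; default: the 8 residues nearest the -x pole.
#' @param hotspot_bias Extra anchor weight for hotspot residues (>= 0,
#'   default 0).
#' @param clash_fraction Fraction of poses planted as clashes (default 0.2).
#' @param terminal_contact_fraction Fraction planted as terminal violations
#'   (default 0.3).
#' @param seed RNG seed.
#' @return List: `ensemble` (a [pose_ensemble()] with reference complex) and
#'   `truth` (`data.frame`: `pose_id`, `class`, `anchor_residue`).
#' @export
gen_pose_ensemble <- function(n_poses = 70, rna_length_nt = 40,
                              hotspot_residues = NULL, hotspot_bias = 0,
                              clash_fraction = 0.2,
                              terminal_contact_fraction = 0.3, seed = 1) {
  stopifnot(clash_fraction >= 0, terminal_contact_fraction >= 0,
            clash_fraction + terminal_contact_fraction <= 1, hotspot_bias >= 0)
  .with_seed(seed, {
    receptor <- synthetic_receptor()
    reference <- synthetic_reference_complex(receptor)
    partner <- reference[reference$chain_id == "B", , drop = FALSE]
    partner_xyz <- .xyz(partner)
    rec_xyz <- .xyz(receptor)
    rna0 <- rna_pose_helix(rna_length_nt)
    ca <- receptor[receptor$atom_name == "CA", , drop = FALSE]
    if (is.null(hotspot_residues))
      hotspot_residues <- ca$residue_index[order(ca$x)][1:8]
    w <- 1 + hotspot_bias * (ca$residue_index %in% hotspot_residues)

    n_clash <- round(clash_fraction * n_poses)
    n_term <- round(terminal_contact_fraction * n_poses)
    classes <- sample(c(rep("clash", n_clash), rep("terminal", n_term),
                        rep("clean", n_poses - n_clash - n_term)))
    poses <- vector("list", n_poses)
    anchors <- integer(n_poses)
    for (p in seq_len(n_poses)) {
      cls <- classes[p]
      ok <- FALSE
      for (try_i in 1:100) {
        if (cls == "clash") {
          q <- partner_xyz[sample.int(nrow(partner_xyz), 1), ]
          r_idx <- which(rna0$residue_index == ceiling(rna_length_nt / 2))[1]
          R <- .rot_z_to(.rand_unit(), stats::runif(1, 0, 2 * pi))
          pose <- .apply_rigid(rna0, R, c(0, 0, 0))
          rvec <- .xyz(pose)[r_idx, ]
          pose <- .apply_rigid(pose, diag(3),
                               q + 0.8 * .rand_unit() - rvec)
          ok <- min_distance(.xyz(pose), partner_xyz) < 2.0 &&
            min_distance(.xyz(pose), rec_xyz) > 5.5
          anchors[p] <- NA_integer_
        } else {
          a <- sample.int(nrow(ca), 1, prob = w)
          anchors[p] <- ca$residue_index[a]
          u <- c(ca$x[a], ca$y[a], ca$z[a])
          u <- u / sqrt(sum(u^2))
          if (cls == "terminal") {
            # end-on approach: helix axis radial, 5' end toward the receptor
            R <- .rot_z_to(u, stats::runif(1, 0, 2 * pi))
            pose <- .apply_rigid(rna0, R, u * (12 + rna_length_nt * 2.81))
            pose <- .settle_gap(pose, rec_xyz, u, 4.0)
            term <- .terminal_atoms(pose)
            ok <- min_distance(.xyz(term), rec_xyz) < 5 &&
              min_distance(.xyz(pose), partner_xyz) > 3.5
          } else {
            tv <- .rand_unit()
            tv <- tv - sum(tv * u) * u
            tv <- tv / sqrt(sum(tv^2))
            R <- .rot_z_to(tv, stats::runif(1, 0, 2 * pi))
            gap <- stats::runif(1, 3.5, 4.5)
            pose <- .apply_rigid(rna0, R, u * 25)
            pose <- .settle_gap(pose, rec_xyz, u, gap)
            term <- .terminal_atoms(pose)
            d_all <- min_distance(.xyz(pose), rec_xyz)
            ok <- min_distance(.xyz(term), rec_xyz) >= 5.5 &&
              min_distance(.xyz(pose), partner_xyz) >= 3.5 &&
              d_all < 5 && d_all >= 3.0
          }
        }
        if (ok) break
      }
      if (!ok) stop("could not place pose ", p, " (class ", cls, ")")
      poses[[p]] <- pose
    }
    names(poses) <- sprintf("pose_%03d", seq_len(n_poses))
    ens <- pose_ensemble(receptor, poses, reference_complex = reference)
    list(ensemble = ens,
         truth = data.frame(pose_id = names(poses), class = classes,
                            anchor_residue = anchors,
                            stringsAsFactors = FALSE))
  })
}

.rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}
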