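# Deterministic, seeded generators producing inputs with known ground
# truth for every metric family.  Each generator seeds its own RNG
# stream and restores the caller's, so fixture calls never perturb
# process-global randomness.

with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Simulate a ddG benchmark dataset with a known population correlation
#'
#' Experimental values are drawn from a normal distribution with mean
#' 1.0 and standard deviation 2.0 kcal/mol (a realistic spread for
#' point-mutant thermostability data, where most mutations are mildly
#' destabilizing).  Predictions are generated on the same scale as
#' `pred = 1 + 2 * (r * z + sqrt(1 - r^2) * e)` with `z` the
#' standardized experimental value and `e` independent standard
#' normal noise, so the population correlation is exactly
#' `target_correlation` and the expected mean absolute error has the
#' closed form `sigma * sqrt(2/pi)` with
#' `sigma^2 = 4 * ((1 - r)^2 + 1 - r^2)`.
#'
#' With `planted_violations = TRUE` the last four records are
#' replaced by curation-filter violations: one non-2.5-Angstrom
#' resolution record, one transmembrane record, and one
#' replicate-discrepancy pair (two records of one mutation whose
#' experimental values differ by 3 kcal/mol).
#'
#' @param n number of records (>= 8 when planting violations).
#' @param target_correlation population Pearson correlation between
#'   experimental and predicted values, in `[-1, 1]`.
#' @param seed RNG seed.
#' @param planted_violations plant the three curation violations
#'   (four records) at the end of the dataset.
#' @return a [ddg_dataset()].
#' @export
simulate_ddg_dataset <- function(n, target_correlation = 0.7, seed = 1,
                                 planted_violations = FALSE) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  r <- target_correlation
  if (!is.finite(r) || abs(r) > 1) stop("|target_correlation| must be <= 1",
                                        call. = FALSE)
  if (planted_violations && n < 8) {
    stop("need n >= 8 to plant violations", call. = FALSE)
  }
  with_local_seed(seed, {
    z <- rnorm(n)
    e <- rnorm(n)
    exp_ddg <- 1 + 2 * z
    pred <- 1 + 2 * (r * z + sqrt(1 - r^2) * e)
    aa <- sample(AA_ALPHABET, n, replace = TRUE)
    mut <- vapply(aa, function(a) sample(setdiff(AA_ALPHABET, a), 1),
                  character(1))
    df <- data.frame(
      record_id = sprintf("R%05d", seq_len(n)),
      pdb_id = sprintf("1%s", paste0(
        matrix(sample(LETTERS, 3 * n, replace = TRUE), ncol = 3)[, 1],
        matrix(sample(LETTERS, 3 * n, replace = TRUE), ncol = 3)[, 2],
        matrix(sample(LETTERS, 3 * n, replace = TRUE), ncol = 3)[, 3])),
      chain = "A",
      residue_id = as.character(seq_len(n) + 10L),  # unique: no replicate keys
      wildtype_aa = aa,
      mutant_aa = unname(mut),
      ddg_experimental = exp_ddg,
      ddg_predicted = pred,
      resolution = round(runif(n, 1.2, 2.4), 2),
      method = "xray",
      is_transmembrane = FALSE,
      references = "synthetic",
      stringsAsFactors = FALSE)
    if (planted_violations) {
      i <- n - 3L
      df$resolution[i] <- 3.0                       # filter (i)
      df$is_transmembrane[i + 1L] <- TRUE           # filter (iii)
      # filter (ii): replicate pair of one mutation, range 3.0 kcal/mol
      for (k in c(i + 2L, i + 3L)) {
        df$pdb_id[k] <- "1DUP"; df$chain[k] <- "A"; df$residue_id[k] <- "42"
        df$wildtype_aa[k] <- "L"; df$mutant_aa[k] <- "A"
      }
      df$ddg_experimental[i + 2L] <- 0.5
      df$ddg_experimental[i + 3L] <- 3.5
    }
    ddg_dataset(df)
  })
}

#' Expected mean absolute error of the ddG simulation
#'
#' Closed-form expectation of `|experimental - predicted|` under the
#' generative model of [simulate_ddg_dataset()].
#'
#' @param target_correlation the correlation the dataset was
#'   simulated at.
#' @param sd_experimental standard deviation of the experimental
#'   values (2.0 kcal/mol in the generator).
#' @return expected MAE in kcal/mol.
#' @export
expected_simulated_mae <- function(target_correlation, sd_experimental = 2.0) {
  r <- target_correlation
  sigma <- sd_experimental * sqrt((1 - r)^2 + 1 - r^2)
  sigma * sqrt(2 / pi)
}

#' Simulate an alignment with planted covarying position pairs
#'
#' Background columns are i.i.d. draws from `composition` (uniform
#' over the 20 amino acids by default).  For each planted pair
#' `(i, j)`, column `i` is drawn from the composition and column `j`
#' copies column `i`'s residue with probability `coupling_strength`
#' (identical-symbol coupling), drawing independently otherwise.
#' With coupling 1 the two columns are identical, so their mutual
#' information equals the column entropy exactly; with coupling 0
#' they are independent.
#'
#' @param n_seqs number of sequences.
#' @param length number of columns.
#' @param planted_pairs two-column matrix (or list of length-2
#'   vectors) of disjoint position pairs.
#' @param coupling_strength copy probability in `[0, 1]`.
#' @param seed RNG seed.
#' @param composition background amino-acid distribution.
#' @return an [msa()] with attribute `planted_pairs`.
#' @export
simulate_msa <- function(n_seqs, length, planted_pairs = NULL,
                         coupling_strength = 0.9, seed = 1,
                         composition = uniform_background()) {
  if (coupling_strength < 0 || coupling_strength > 1) {
    stop("coupling_strength must be in [0, 1]", call. = FALSE)
  }
  pairs <- if (is.null(planted_pairs)) {
    matrix(integer(0), ncol = 2)
  } else if (is.list(planted_pairs)) {
    do.call(rbind, planted_pairs)
  } else planted_pairs
  if (nrow(pairs) > 0) {
    pos <- as.vector(pairs)
    if (anyDuplicated(pos)) stop("planted pairs must be disjoint", call. = FALSE)
    if (any(pos < 1 | pos > length)) stop("planted pair out of range",
                                          call. = FALSE)
  }
  with_local_seed(seed, {
    draw <- function(n) sample(AA_ALPHABET, n, replace = TRUE,
                               prob = composition)
    mat <- matrix("", nrow = n_seqs, ncol = length)
    for (j in seq_len(length)) mat[, j] <- draw(n_seqs)
    if (nrow(pairs) > 0) {
      for (k in seq_len(nrow(pairs))) {
        i <- pairs[k, 1]; j <- pairs[k, 2]
        copy <- runif(n_seqs) < coupling_strength
        mat[copy, j] <- mat[copy, i]
      }
    }
    out <- msa(sprintf("seq%04d", seq_len(n_seqs)),
               apply(mat, 1, paste, collapse = ""))
    attr(out, "planted_pairs") <- pairs
    out
  })
}

#' Simulate scored designed sequences consistent with a target PWM
#'
#' Sequences are sampled uniformly over the alphabet at each position
#' (the proposal), and each sequence is assigned the energy
#' `E = -kT * sum(log p_i(a_i))` under the target PWM.  Boltzmann
#' reweighting of a uniform sample by `exp(-E/kT) = prod p_i(a_i)`
#' is then an unbiased importance-sampling estimator of the target
#' PWM, so [boltzmann_pwm()] at the same `kT` recovers the truth in
#' expectation.  The uniform proposal is drawn balanced: each amino
#' acid appears (near-)equally often in every column, in random row
#' order, which removes the multinomial letter-count noise from the
#' estimator without affecting its expectation.
#'
#' @param pwm_truth target `"pwm"` with strictly positive entries.
#' @param n number of sequences.
#' @param kT temperature used to encode the energies (default 1.0).
#' @param seed RNG seed.
#' @return a list with `sequences` and `energies`.
#' @export
simulate_scored_sequences <- function(pwm_truth, n, kT = 1.0, seed = 1) {
  pwm_truth <- as_pwm(unclass(pwm_truth))
  if (any(pwm_truth <= 0)) {
    stop("pwm_truth must be strictly positive everywhere", call. = FALSE)
  }
  if (kT <= 0) stop("kT must be positive", call. = FALSE)
  L <- ncol(pwm_truth)
  with_local_seed(seed, {
    idx <- vapply(seq_len(L), function(j) sample(rep_len(1:20, n)),
                  integer(n))
    if (n == 1) idx <- matrix(idx, nrow = 1)
    logp <- log(pwm_truth)
    picked <- matrix(logp[cbind(as.vector(idx), rep(seq_len(L), each = n))],
                     nrow = n)
    energies <- -kT * rowSums(picked)
    sequences <- apply(idx, 1, function(i) paste(AA_ALPHABET[i], collapse = ""))
    list(sequences = sequences, energies = energies)
  })
}

#' Simulate an idealized protein backbone
#'
#' Generates a single-chain coil of `n_residues` with backbone atoms
#' N, CA, C, O at fixed offsets from CA positions laid out on a
#' gently curving path.  The geometry is deliberately schematic: it
#' provides non-collinear, well-separated frames for superposition
#' and RMSD tests, not physically realistic stereochemistry.
#'
#' @param n_residues chain length.
#' @param chain chain identifier.
#' @return a [structure_coords()].
#' @export
simulate_protein_backbone <- function(n_residues, chain = "A") {
  k <- seq_len(n_residues)
  ca <- cbind(3.8 * k, 2.5 * sin(k / 2), 2.5 * cos(k / 3))
  one <- function(atom, off) {
    data.frame(chain = chain, resno = k, icode = "", resname = "ALA",
               atom = atom,
               x = ca[, 1] + off[1], y = ca[, 2] + off[2],
               z = ca[, 3] + off[3], stringsAsFactors = FALSE)
  }
  df <- rbind(one("N", c(-1.2, 0.5, 0.0)),
              one("CA", c(0, 0, 0)),
              one("C", c(1.2, 0.5, 0.0)),
              one("O", c(1.4, 1.6, 0.3)))
  structure_coords(df[order(df$resno, match(df$atom, BACKBONE_HEAVY)), ])
}

#' Simulate a loop-model ensemble with known RMSD ground truth
#'
#' Each model copies the native structure and displaces every atom of
#' the loop residues by independent Gaussian offsets of standard
#' deviation `perturbation_scale` per coordinate (frame atoms are
#' untouched, so the frame superposition is exact).  Pseudo-energies
#' are generated to correlate with the true loop backbone RMSD at
#' level `energy_rmsd_correlation`; at correlation 1 the
#' lowest-energy model is exactly the minimum-RMSD model.
#'
#' @param native native [structure_coords()].
#' @param loop loop residues (see [loop_rmsd()]).
#' @param n_models ensemble size.
#' @param perturbation_scale per-coordinate Gaussian scale in
#'   Angstrom (0 reproduces the native loop in every model).
#' @param energy_rmsd_correlation correlation between pseudo-energy
#'   and true RMSD, in `[-1, 1]` (default 0.8).
#' @param seed RNG seed.
#' @return a [loop_case()] with an extra element `true_rmsds`.
#' @export
simulate_loop_ensemble <- function(native, loop, n_models,
                                   perturbation_scale = 1.0,
                                   energy_rmsd_correlation = 0.8,
                                   seed = 1) {
  if (perturbation_scale < 0) stop("perturbation scale must be >= 0",
                                   call. = FALSE)
  rho <- energy_rmsd_correlation
  if (abs(rho) > 1) stop("|energy_rmsd_correlation| must be <= 1", call. = FALSE)
  loop_keys <- loop_res_keys(loop)
  nat <- as.data.frame(native)
  rid <- paste(nat$chain, nat$resno, nat$icode, sep = "|")
  if (!all(loop_keys %in% rid)) {
    stop("loop residues not present in native", call. = FALSE)
  }
  in_loop <- rid %in% loop_keys
  bb_loop <- in_loop & nat$atom %in% BACKBONE_HEAVY
  with_local_seed(seed, {
    models <- vector("list", n_models)
    true_rmsds <- numeric(n_models)
    for (m in seq_len(n_models)) {
      mod <- nat
      off <- matrix(rnorm(3 * sum(in_loop), sd = perturbation_scale),
                    ncol = 3)
      mod[in_loop, c("x", "y", "z")] <- mod[in_loop, c("x", "y", "z")] + off
      bb_off <- off[bb_loop[in_loop], , drop = FALSE]
      true_rmsds[m] <- sqrt(mean(rowSums(bb_off^2)))
      models[[m]] <- structure_coords(mod)
    }
    z <- if (n_models > 1 && isTRUE(sd(true_rmsds) > 0)) {
      (true_rmsds - mean(true_rmsds)) / sd(true_rmsds)
    } else rep(0, n_models)
    energies <- rho * z + sqrt(1 - rho^2) * rnorm(n_models)
    case <- loop_case("synthetic", native, loop, models, energies)
    case$true_rmsds <- true_rmsds
    case
  })
}

#' Simulate a pseudo-structure with analytically known neighbor counts
#'
#' Emits one CA and one CB pseudo-atom per residue.  With
#' `packing = "line"` residues are spaced `spacing` Angstrom apart on
#' a line (no neighbors at the default 8-Angstrom burial radius when
#' `spacing > 8`); with `packing = "cluster"` all CB atoms fall
#' inside a ball of radius 3.5 Angstrom, so every residue neighbors
#' every other.
#'
#' @param n_residues number of residues.
#' @param packing `"cluster"` or `"line"`.
#' @param seed RNG seed (cluster placement only).
#' @param spacing line spacing in Angstrom.
#' @return a [structure_coords()].
#' @export
simulate_structure <- function(n_residues, packing = c("cluster", "line"),
                               seed = 1, spacing = 10.0) {
  packing <- match.arg(packing)
  if (n_residues < 1) stop("n_residues must be >= 1", call. = FALSE)
  cb <- if (packing == "line") {
    cbind(spacing * seq_len(n_residues), 0, 0)
  } else {
    with_local_seed(seed, {
      # rejection-sample points in a ball of radius 3.5 A
      pts <- matrix(numeric(0), ncol = 3)
      while (nrow(pts) < n_residues) {
        cand <- matrix(runif(3 * n_residues * 2, -3.5, 3.5), ncol = 3)
        cand <- cand[rowSums(cand^2) <= 3.5^2, , drop = FALSE]
        pts <- rbind(pts, cand)
      }
      pts[seq_len(n_residues), , drop = FALSE]
    })
  }
  k <- seq_len(n_residues)
  df <- rbind(
    data.frame(chain = "A", resno = k, icode = "", resname = "ALA",
               atom = "CA", x = cb[, 1], y = cb[, 2] + 1.5, z = cb[, 3],
               stringsAsFactors = FALSE),
    data.frame(chain = "A", resno = k, icode = "", resname = "ALA",
               atom = "CB", x = cb[, 1], y = cb[, 2], z = cb[, 3],
               stringsAsFactors = FALSE))
  structure_coords(df[order(df$resno), ])
}
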