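# Recognition-specificity metrics: Boltzmann-weighted predicted PWMs
# from scored designed sequences, and the four PWM-comparison metrics
# (AAD, Frobenius distance, AUC, rank-top).

#' Boltzmann-weighted position weight matrix from scored sequences
#'
#' Each sequence contributes weight `exp(-(E - E_min)/kT)` (the
#' minimum energy is subtracted before exponentiation to guard
#' against overflow; the weights are invariant to any common energy
#' shift).  Column frequencies are the weighted fractions of each
#' amino acid at each position.  As `kT -> 0` the PWM collapses onto
#' the minimum-energy sequence; as `kT -> Inf` it converges to the
#' unweighted frequencies.
#'
#' @param sequences character vector of equal-length designed
#'   sequences over the 20-letter alphabet.
#' @param energies numeric vector of per-sequence scores (lower =
#'   more favorable), same length as `sequences`.
#' @param kT Boltzmann temperature in score units (default 1.0).
#' @return a `"pwm"`: 20 x n_positions matrix, columns summing to 1.
#' @export
boltzmann_pwm <- function(sequences, energies, kT = 1.0) {
  if (kT <= 0) stop("kT must be positive", call. = FALSE)
  if (length(sequences) < 1) stop("need at least one sequence", call. = FALSE)
  if (length(sequences) != length(energies)) {
    stop("sequences and energies differ in length", call. = FALSE)
  }
  stopifnot_finite(energies, "energies")
  chars <- do.call(rbind, strsplit(sequences, ""))
  if (any(!(chars %in% AA_ALPHABET))) {
    stop("sequences must be over the 20-letter amino-acid alphabet",
         call. = FALSE)
  }
  w <- exp(-(energies - min(energies)) / kT)
  w <- w / sum(w)
  L <- ncol(chars)
  m <- matrix(0, nrow = 20, ncol = L,
              dimnames = list(AA_ALPHABET, seq_len(L)))
  for (j in seq_len(L)) {
    m[, j] <- vapply(AA_ALPHABET,
                     function(a) sum(w[chars[, j] == a]), numeric(1))
  }
  as_pwm(m)
}

check_same_shape <- function(E, P) {
  if (length(E) != length(P) ||
      (is.matrix(E) != is.matrix(P)) ||
      (is.matrix(E) && !all(dim(E) == dim(P)))) {
    stop("E and P must have the same shape", call. = FALSE)
  }
}

#' Average absolute deviation between two frequency profiles
#'
#' `AAD = mean(|E - P|)`.  For matrices the deviation is computed per
#' position (column) and macro-averaged; the per-column values are
#' attached as attribute `per_column`.
#'
#' @param E experimentally determined frequencies (vector or PWM).
#' @param P predicted frequencies of the same shape.
#' @return mean absolute deviation (0 iff `E == P`).
#' @export
aad <- function(E, P) {
  check_same_shape(E, P)
  if (is.matrix(E)) {
    per_col <- colMeans(abs(E - P))
    return(structure(mean(per_col), per_column = per_col))
  }
  mean(abs(E - P))
}

#' Frobenius distance between two frequency profiles
#'
#' `sqrt(sum((E - P)^2))`.  For matrices the distance is computed per
#' position (column) and macro-averaged, with per-column values in
#' attribute `per_column`; use vectors for the flattened variant.
#'
#' @param E,P frequency profiles of the same shape.
#' @return Frobenius distance (satisfies the triangle inequality).
#' @export
frobenius_distance <- function(E, P) {
  check_same_shape(E, P)
  if (is.matrix(E)) {
    per_col <- sqrt(colSums((E - P)^2))
    return(structure(mean(per_col), per_column = per_col))
  }
  sqrt(sum((E - P)^2))
}

# Rank-based (Wilcoxon/Mann-Whitney) AUC with midrank tie handling.
rank_auc <- function(labels, scores) {
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores)  # midranks
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' AUC of a predicted profile against experimental frequencies
#'
#' Amino acids with experimental frequency at or above
#' `positive_threshold` are the positive class; the predicted
#' frequencies are the ranking scores.  The AUC is the probability
#' that a positive outranks a negative, with ties contributing 0.5:
#' 0.5 indicates random predictions and 1.0 perfect ranking.  For
#' matrices the labeled (amino acid, position) entries of all columns
#' are pooled into one ranking (micro-averaging).
#'
#' @param E experimental frequency column or PWM.
#' @param P predicted column or PWM of the same shape.
#' @param positive_threshold experimental frequency defining the
#'   positive class (default 0.1).
#' @return AUC in `[0, 1]`, or an undefined-metric marker when the
#'   labels are degenerate (all positive or all negative).
#' @export
profile_auc <- function(E, P, positive_threshold = 0.1) {
  check_same_shape(E, P)
  labels <- as.vector(E) >= positive_threshold
  scores <- as.vector(P)
  auc <- rank_auc(labels, scores)
  if (is.na(auc)) {
    return(undefined_metric("degenerate labels: all positive or all negative"))
  }
  auc
}

#' Predicted rank of the experimentally most frequent amino acid
#'
#' For each position, the amino acid with the highest experimental
#' frequency is located in the prediction and its competition rank
#' reported (1 = highest predicted frequency; tied predictions share
#' the best rank, i.e. rank = 1 + number of strictly greater
#' entries).  Ties in the experimental maximum are broken in
#' alphabet order.
#'
#' @param E experimental frequency column or PWM.
#' @param P predicted column or PWM of the same shape.
#' @return a list with `per_position` (integer ranks, 1-20) and
#'   `mean`.
#' @export
rank_top <- function(E, P) {
  check_same_shape(E, P)
  if (!is.matrix(E)) { E <- matrix(E, ncol = 1); P <- matrix(P, ncol = 1) }
  ranks <- vapply(seq_len(ncol(E)), function(j) {
    target <- which.max(E[, j])
    1L + sum(P[, j] > P[target, j])
  }, integer(1))
  list(per_position = ranks, mean = mean(ranks))
}

#' Full metric panel comparing a predicted PWM to an experimental one
#'
#' @param E experimental PWM.
#' @param P predicted PWM of the same shape.
#' @param positive_threshold AUC positive-label threshold, see
#'   [profile_auc()].
#' @return a named list with `aad`, `frobenius`, `auc` and
#'   `rank_top_mean`.
#' @export
specificity_metrics <- function(E, P, positive_threshold = 0.1) {
  list(aad = as.numeric(aad(E, P)),
       frobenius = as.numeric(frobenius_distance(E, P)),
       auc = profile_auc(E, P, positive_threshold),
       rank_top_mean = rank_top(E, P)$mean)
}
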