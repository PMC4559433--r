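# Metrics and aggregation for stability-ddG and alanine-scanning
# benchmarks, plus the dataset-curation filters.
#
# Sign convention throughout: positive ddG = destabilizing (or weaker
# binding).  Experimental values are in kcal/mol; predictions are on
# the unit-agnostic score scale of whichever engine produced them.

#' Pearson correlation between experimental and predicted values
#'
#' @param x,y equal-length numeric vectors (>= 2 values each).
#' @return the correlation coefficient in `[-1, 1]`, or an
#'   undefined-metric marker when either vector has zero variance
#'   (see [is_undefined_metric()]).
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 paired values", call. = FALSE)
  stopifnot_finite(x, "x"); stopifnot_finite(y, "y")
  if (sd(x) == 0 || sd(y) == 0) {
    return(undefined_metric("zero variance"))
  }
  cor(x, y)
}

#' Mean absolute error
#'
#' @param x,y equal-length nonempty numeric vectors.
#' @return mean of `|x - y|` (kcal/mol scale when both inputs are).
#' @export
mean_absolute_error <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) == 0) stop("empty input", call. = FALSE)
  mean(abs(x - y))
}

#' Classify a ddG value as stabilizing, neutral or destabilizing
#'
#' Values within the closed interval `[-neutral_halfwidth,
#' +neutral_halfwidth]` are neutral; below it stabilizing; above it
#' destabilizing.  An asymmetric neutral range (e.g. the `[-3, 1.1]`
#' score-unit range some protocols use for predictions) can be given
#' via `bounds`, which overrides `neutral_halfwidth`.
#'
#' @param ddg numeric vector of ddG values.
#' @param neutral_halfwidth half-width of the symmetric neutral band
#'   (default 1.0 kcal/mol).
#' @param bounds optional length-2 numeric `c(lower, upper)` for an
#'   asymmetric neutral interval (both endpoints inclusive).
#' @return character vector over `{"stabilizing", "neutral",
#'   "destabilizing"}`.
#' @export
classify_stability <- function(ddg, neutral_halfwidth = 1.0, bounds = NULL) {
  stopifnot_finite(ddg, "ddg")
  if (is.null(bounds)) bounds <- c(-neutral_halfwidth, neutral_halfwidth)
  if (length(bounds) != 2 || bounds[1] > bounds[2]) {
    stop("bounds must be c(lower, upper) with lower <= upper", call. = FALSE)
  }
  ifelse(ddg < bounds[1], "stabilizing",
         ifelse(ddg > bounds[2], "destabilizing", "neutral"))
}

#' Stability classification accuracy (fraction correct)
#'
#' Fraction of mutations whose experimental and predicted stability
#' classes agree.  Experimental values use the symmetric +/- 1
#' kcal/mol neutral band by default; predictions default to a
#' symmetric +/- 1 score-unit band but accept an asymmetric override.
#'
#' @param exp experimental ddG values (kcal/mol).
#' @param pred predicted ddG values (score units).
#' @param exp_halfwidth,pred_halfwidth neutral half-widths.
#' @param pred_bounds optional asymmetric neutral interval for the
#'   predictions, `c(lower, upper)`.
#' @return fraction in `[0, 1]`.
#' @export
fraction_correct <- function(exp, pred, exp_halfwidth = 1.0,
                             pred_halfwidth = 1.0, pred_bounds = NULL) {
  if (length(exp) != length(pred)) stop("length mismatch", call. = FALSE)
  if (length(exp) == 0) stop("empty input", call. = FALSE)
  ce <- classify_stability(exp, exp_halfwidth)
  cp <- classify_stability(pred, pred_halfwidth, bounds = pred_bounds)
  mean(ce == cp)
}

#' Construct a wild-type/mutant scored model set
#'
#' @param case_id identifier for the mutation case.
#' @param wildtype_scores,mutant_scores numeric vectors of model
#'   energies (lower = more favorable).
#' @return an object of class `"scored_model_set"`.
#' @export
scored_model_set <- function(case_id, wildtype_scores, mutant_scores) {
  stopifnot_finite(wildtype_scores, "wildtype_scores")
  stopifnot_finite(mutant_scores, "mutant_scores")
  structure(list(case_id = case_id,
                 wildtype_scores = wildtype_scores,
                 mutant_scores = mutant_scores),
            class = "scored_model_set")
}

#' Ensemble ddG from the n best-scoring models
#'
#' Predicted ddG is the mean of the `n_best` lowest mutant model
#' scores minus the mean of the `n_best` lowest wild-type model
#' scores, the standard aggregation over an ensemble of paired
#' wild-type/mutant models.
#'
#' @param set a [scored_model_set()].
#' @param n_best number of best-scoring models averaged on each side
#'   (default 3).
#' @return predicted ddG in score units.
#' @export
aggregate_ensemble_ddg <- function(set, n_best = 3) {
  wt <- set$wildtype_scores
  mut <- set$mutant_scores
  if (length(wt) < n_best || length(mut) < n_best) {
    stop(sprintf("case %s: fewer than %d models on one side",
                 set$case_id, n_best), call. = FALSE)
  }
  mean(sort(mut)[seq_len(n_best)]) - mean(sort(wt)[seq_len(n_best)])
}

#' Construct a six-term binding energy decomposition
#'
#' @param case_id identifier.
#' @param dG_complex_mut,dG_partnerA_mut,dG_partnerB_mut total energies
#'   of the mutant complex and its two isolated partners (score units).
#' @param dG_complex_wt,dG_partnerA_wt,dG_partnerB_wt the wild-type
#'   counterparts.
#' @return an object of class `"binding_decomposition"`.
#' @export
binding_decomposition <- function(case_id, dG_complex_mut, dG_partnerA_mut,
                                  dG_partnerB_mut, dG_complex_wt,
                                  dG_partnerA_wt, dG_partnerB_wt) {
  vals <- c(dG_complex_mut, dG_partnerA_mut, dG_partnerB_mut,
            dG_complex_wt, dG_partnerA_wt, dG_partnerB_wt)
  if (length(vals) != 6 || !all(is.finite(vals))) {
    stop(sprintf("case %s: all six energy terms must be finite",
                 case_id), call. = FALSE)
  }
  structure(list(case_id = case_id,
                 dG_complex_mut = dG_complex_mut,
                 dG_partnerA_mut = dG_partnerA_mut,
                 dG_partnerB_mut = dG_partnerB_mut,
                 dG_complex_wt = dG_complex_wt,
                 dG_partnerA_wt = dG_partnerA_wt,
                 dG_partnerB_wt = dG_partnerB_wt),
            class = "binding_decomposition")
}

#' Alanine-scanning ddG of binding
#'
#' Computes
#' `(dG_complex^MUT - dG_A^MUT - dG_B^MUT) - (dG_complex^WT - dG_A^WT - dG_B^WT)`,
#' the change in binding free energy upon mutation to alanine, from a
#' six-term total-energy decomposition.  Positive values mean weaker
#' binding of the mutant.
#'
#' @param d a [binding_decomposition()].
#' @return ddG of binding in score units.
#' @export
alanine_ddg_bind <- function(d) {
  (d$dG_complex_mut - d$dG_partnerA_mut - d$dG_partnerB_mut) -
    (d$dG_complex_wt - d$dG_partnerA_wt - d$dG_partnerB_wt)
}

#' Curation thresholds for thermostability datasets
#'
#' @param max_resolution reject records whose structure was not solved
#'   by X-ray crystallography at this resolution or better (default
#'   2.5 Angstrom).
#' @param max_ddg_discrepancy reject all records of a mutation whose
#'   replicate experimental ddG values span more than this range
#'   (default 2.5 kcal/mol).
#' @param exclude_transmembrane reject transmembrane proteins
#'   (default `TRUE`).
#' @return an object of class `"curation_config"`.
#' @export
curation_config <- function(max_resolution = 2.5, max_ddg_discrepancy = 2.5,
                            exclude_transmembrane = TRUE) {
  if (max_resolution <= 0 || max_ddg_discrepancy <= 0) {
    stop("curation thresholds must be positive", call. = FALSE)
  }
  structure(list(max_resolution = max_resolution,
                 max_ddg_discrepancy = max_ddg_discrepancy,
                 exclude_transmembrane = exclude_transmembrane),
            class = "curation_config")
}

#' Apply the standard thermostability curation filters
#'
#' Rejects records where (i) there is no X-ray structure at the
#' required resolution (method not `"xray"`, resolution missing, or
#' resolution worse than `max_resolution`); (ii) replicate
#' experimental ddG values for the same mutation (keyed by pdb_id,
#' chain, residue_id, wildtype_aa, mutant_aa) span more than
#' `max_ddg_discrepancy` kcal/mol — all records of such a mutation are
#' rejected rather than reconciled; (iii) the protein is flagged
#' transmembrane.  A record violating several filters carries the
#' first applicable reason in the order resolution, discrepancy,
#' transmembrane.
#'
#' The filter is idempotent: curating the kept set again changes
#' nothing.
#'
#' @param records a [ddg_dataset()].
#' @param cfg a [curation_config()].
#' @return a list with elements `kept` (a [ddg_dataset()]) and
#'   `rejected` (the rejected rows with an added `reason` column over
#'   `{"resolution", "discrepancy", "transmembrane"}`).
#' @export
curate_dataset <- function(records, cfg = curation_config()) {
  df <- as.data.frame(records)
  n <- nrow(df)
  if (n == 0) {
    return(list(kept = records, rejected = cbind(df, reason = character(0))))
  }
  bad_res <- df$method != "xray" | is.na(df$resolution) |
    df$resolution > cfg$max_resolution
  key <- paste(df$pdb_id, df$chain, df$residue_id,
               df$wildtype_aa, df$mutant_aa, sep = "|")
  range_by_key <- tapply(df$ddg_experimental, key,
                         function(v) max(v) - min(v))
  bad_disc <- unname(range_by_key[key] > cfg$max_ddg_discrepancy)
  bad_tm <- if (cfg$exclude_transmembrane) df$is_transmembrane else rep(FALSE, n)
  reason <- rep(NA_character_, n)
  reason[bad_tm] <- "transmembrane"
  reason[bad_disc] <- "discrepancy"
  reason[bad_res] <- "resolution"
  keep <- is.na(reason)
  kept <- df[keep, , drop = FALSE]
  class(kept) <- class(records)
  rejected <- df[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  list(kept = kept, rejected = rejected)
}

#' Full metric panel for a ddG prediction benchmark
#'
#' @param exp experimental ddG values (kcal/mol).
#' @param pred predicted ddG values (score units).
#' @param exp_halfwidth,pred_halfwidth,pred_bounds neutral-band
#'   settings, see [fraction_correct()].
#' @return a named list with `pearson`, `mae` and `fraction_correct`.
#' @export
ddg_metrics <- function(exp, pred, exp_halfwidth = 1.0,
                        pred_halfwidth = 1.0, pred_bounds = NULL) {
  list(pearson = pearson_cor(exp, pred),
       mae = mean_absolute_error(exp, pred),
       fraction_correct = fraction_correct(exp, pred, exp_halfwidth,
                                           pred_halfwidth, pred_bounds))
}
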