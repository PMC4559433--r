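# Sequence-level design metrics: native sequence recovery, per-column
# amino-acid distributions and entropies, Jensen-Shannon profile
# similarity, mutual-information based covariation (MI -> MIp -> Zpx),
# high-covariation overlap, residue burial classification and
# composition breakdowns.
#
# All entropies and divergences are in bits (log base 2), which makes
# the mutual information of a perfectly coupled uniform binary pair
# exactly 1 bit.

#' Native sequence recovery
#'
#' Percent identity between a native and a designed sequence, over all
#' positions or a subset.  A gap compared against anything never
#' counts as a match.
#'
#' @param native,designed equal-length sequences (strings or character
#'   vectors).
#' @param positions optional integer vector of 1-based positions to
#'   score.
#' @return percent identity in `[0, 100]`.
#' @export
sequence_recovery <- function(native, designed, positions = NULL) {
  a <- if (length(native) == 1) strsplit(native, "")[[1]] else native
  b <- if (length(designed) == 1) strsplit(designed, "")[[1]] else designed
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  if (is.null(positions)) positions <- seq_along(a)
  if (any(positions < 1 | positions > length(a))) {
    stop("positions out of range", call. = FALSE)
  }
  a <- a[positions]; b <- b[positions]
  match <- a == b & a != "-" & b != "-"
  100 * mean(match)
}

#' Amino-acid distribution of one alignment column
#'
#' Counts are normalized over the 20 amino acids; gaps (`-`) and
#' unknowns (`X`) are excluded and the column renormalized (default
#' policy).  A column with no scorable residues is returned as an
#' all-zero vector flagged empty (`attr(x, "empty")`).
#'
#' @param msa an [msa()].
#' @param col 1-based column index.
#' @return an amino-acid distribution: named numeric vector of length
#'   20 in the order `ACDEFGHIKLMNPQRSTVWY`, with attribute `n` (the
#'   number of residues counted).
#' @export
column_distribution <- function(msa, col) {
  if (col < 1 || col > msa$length) stop("column index out of range", call. = FALSE)
  residues <- msa$seqs[, col]
  residues <- residues[residues %in% AA_ALPHABET]
  counts <- table(factor(residues, levels = AA_ALPHABET))
  p <- as.numeric(counts)
  names(p) <- AA_ALPHABET
  n <- sum(p)
  if (n == 0) {
    attr(p, "empty") <- TRUE
  } else {
    p <- p / n
  }
  attr(p, "n") <- n
  p
}

#' Shannon entropy of an amino-acid distribution, in bits
#'
#' @param p a nonnegative frequency vector summing to 1 (zero terms
#'   contribute 0 by the convention `0 log 0 = 0`).
#' @return entropy in bits, in `[0, log2(length(p))]`.
#' @export
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Jensen-Shannon divergence (base 2)
#'
#' `JSD(p, q) = KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2` and
#' logarithms base 2, so the divergence lies in `[0, 1]`, is 0 iff
#' `p == q` and 1 iff the supports are disjoint.
#'
#' @param p,q equal-length frequency vectors summing to 1.
#' @return divergence in `[0, 1]`.
#' @export
js_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("length mismatch", call. = FALSE)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Jensen-Shannon profile similarity between two distributions
#'
#' `0.5 * (1 - JSD(p || q)) * (1 + JSD(r || P0))` with `r = (p + q)/2`
#' and `P0` a background distribution.  A position scores high when
#' its natural and designed distributions agree with each other
#' (first factor) and differ from the background (second factor).
#' When `p == q == P0` the score is exactly 0.5.
#'
#' Both factors use the Jensen-Shannon divergence, which stays finite
#' even where `r` and the background have disjoint support (the
#' mixture midpoint is positive wherever either argument is), so a
#' restricted-support background is allowed and yields the maximal
#' score 1 for `p = q` fully disjoint from `P0`.
#'
#' @param p,q amino-acid distributions at corresponding positions.
#' @param background the background distribution `P0` (default
#'   uniform over the 20 amino acids).
#' @return similarity score in `[0, 1]`.
#' @export
profile_similarity <- function(p, q, background = uniform_background()) {
  r <- (p + q) / 2
  0.5 * (1 - js_divergence(p, q)) * (1 + js_divergence(r, background))
}

#' Uniform background amino-acid distribution
#'
#' @return the uniform distribution (1/20 per amino acid).
#' @export
uniform_background <- function() {
  p <- rep(1 / 20, 20)
  names(p) <- AA_ALPHABET
  p
}

#' Average profile similarity between two alignments
#'
#' Computes [profile_similarity()] between the column distributions of
#' a natural and a designed alignment at every position and averages
#' over the columns where both distributions are non-empty.
#'
#' @param natural,designed [msa()] objects of equal length.
#' @param background background distribution `P0`.
#' @return a list with `mean` and the `per_column` scores (`NA` where
#'   a column is empty on either side).
#' @export
average_profile_similarity <- function(natural, designed,
                                       background = uniform_background()) {
  if (natural$length != designed$length) {
    stop("alignments have different lengths", call. = FALSE)
  }
  per_col <- vapply(seq_len(natural$length), function(j) {
    p <- column_distribution(natural, j)
    q <- column_distribution(designed, j)
    if (isTRUE(attr(p, "empty")) || isTRUE(attr(q, "empty"))) return(NA_real_)
    profile_similarity(p, q, background)
  }, numeric(1))
  list(mean = mean(per_col, na.rm = TRUE), per_column = per_col)
}

# Entropy in bits from a vector of counts.
entropy_from_counts <- function(counts) {
  n <- sum(counts)
  counts <- counts[counts > 0]
  log2(n) - sum(counts * log2(counts)) / n
}

#' Mutual information between all column pairs of an alignment
#'
#' For each pair of columns i, j the mutual information is
#' `MI_ij = H_i + H_j - H_ij` (bits), with all three entropies
#' computed as empirical plug-in estimates from the sequences that
#' carry a standard amino acid at *both* columns (gaps and unknowns
#' excluded pairwise), so the marginals and the joint share one
#' sample space and `MI >= 0`.
#'
#' No sequence weighting or pseudocounts are applied by default.
#'
#' @param msa an [msa()] with depth >= 2.
#' @return a symmetric `length x length` matrix of MI values in bits;
#'   the diagonal is `NA` (self-information is excluded from all
#'   downstream means).
#' @export
mutual_information <- function(msa) {
  if (msa$depth < 2) stop("alignment depth must be >= 2", call. = FALSE)
  L <- msa$length
  cols <- lapply(seq_len(L), function(j) {
    v <- msa$seqs[, j]
    ifelse(v %in% AA_ALPHABET, v, NA_character_)
  })
  mi <- matrix(NA_real_, L, L)
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      ok <- !is.na(cols[[i]]) & !is.na(cols[[j]])
      if (sum(ok) < 2) next
      a <- cols[[i]][ok]; b <- cols[[j]][ok]
      joint <- table(a, b)
      hij <- entropy_from_counts(as.numeric(joint))
      hi <- entropy_from_counts(rowSums(joint))
      hj <- entropy_from_counts(colSums(joint))
      mi[i, j] <- mi[j, i] <- max(hi + hj - hij, 0)
    }
  }
  mi
}

#' Average-product correction of a mutual-information matrix
#'
#' `MIp_ij = MI_ij - (MImean_i * MImean_j) / MImean`, where `MImean_i`
#' is the mean MI of column i with all other columns and `MImean` the
#' grand mean, all excluding the diagonal.  This subtracts the
#' background MI due to random noise and shared ancestry.  When the
#' grand mean is 0 (all MI zero) the correction is a no-op.
#'
#' @param mi a symmetric MI matrix (diagonal ignored).
#' @return a list with `mip` (the corrected matrix, `NA` diagonal),
#'   `column_means` and `grand_mean`.
#' @export
mip_correction <- function(mi) {
  L <- nrow(mi)
  if (L < 3 || L != ncol(mi)) {
    stop("MI matrix must be square with >= 3 columns", call. = FALSE)
  }
  m <- mi
  diag(m) <- NA
  col_means <- rowMeans(m, na.rm = TRUE)
  grand <- mean(m[upper.tri(m)], na.rm = TRUE)
  mip <- m
  if (is.finite(grand) && grand > 0) {
    apc <- outer(col_means, col_means) / grand
    mip <- m - apc
    diag(mip) <- NA
  }
  list(mip = mip, column_means = col_means, grand_mean = grand)
}

#' Zpx covariation scores from an MIp matrix
#'
#' Each MIp entry is standardized against the off-diagonal mean and
#' standard deviation of each of its two columns, the two z-scores are
#' multiplied, and the product is mapped through a signed square root:
#' `Zpx_ij = sign(Z) * sqrt(|Z|)` with
#' `Z = z_i(MIp_ij) * z_j(MIp_ij)`.  This normalization reduces
#' sensitivity to misaligned regions, which otherwise yield
#' artificially high raw MI.
#'
#' Columns whose off-diagonal MIp has zero standard deviation have no
#' defined z-score; their pairs are returned as `NA` with a warning.
#'
#' @param mip an MIp matrix as returned by [mip_correction()]`$mip`.
#' @return a symmetric Zpx matrix with `NA` diagonal.
#' @export
zpx_scores <- function(mip) {
  L <- nrow(mip)
  if (L < 3 || L != ncol(mip)) {
    stop("MIp matrix must be square with >= 3 columns", call. = FALSE)
  }
  m <- mip
  diag(m) <- NA
  mu <- rowMeans(m, na.rm = TRUE)
  sigma <- apply(m, 1, sd, na.rm = TRUE)
  if (any(sigma == 0, na.rm = TRUE)) {
    warning("column(s) with zero MIp standard deviation; their pairs are NA")
    sigma[sigma == 0] <- NA
  }
  zi <- (m - mu) / sigma          # standardize within row i
  zj <- t((t(m) - mu) / sigma)    # standardize within column j
  z <- zi * zj
  zpx <- sign(z) * sqrt(abs(z))
  diag(zpx) <- NA
  zpx
}

#' Covariation analysis of an alignment
#'
#' Convenience wrapper running [mutual_information()],
#' [mip_correction()] and [zpx_scores()] in sequence.
#'
#' @param msa an [msa()].
#' @return a list with `mi`, `mip`, `zpx`, `column_means` and
#'   `grand_mean`.
#' @export
covariation_matrices <- function(msa) {
  mi <- mutual_information(msa)
  ap <- mip_correction(mi)
  list(mi = mi, mip = ap$mip, zpx = zpx_scores(ap$mip),
       column_means = ap$column_means, grand_mean = ap$grand_mean)
}

#' Highly covarying position pairs
#'
#' Pairs whose score exceeds `mean + z * sd`, with mean and standard
#' deviation taken over all off-diagonal upper-triangle entries of the
#' score matrix.
#'
#' @param scores a symmetric score matrix (e.g. Zpx).
#' @param z number of standard deviations above the mean (default 2).
#' @return a two-column integer matrix of pairs `(i, j)` with `i < j`;
#'   empty (with a warning) when the scores have zero spread.
#' @export
high_covariation_pairs <- function(scores, z = 2.0) {
  L <- nrow(scores)
  ut <- which(upper.tri(scores), arr.ind = TRUE)
  vals <- scores[ut]
  ok <- is.finite(vals)
  vals <- vals[ok]; ut <- ut[ok, , drop = FALSE]
  s <- sd(vals)
  if (!is.finite(s) || s == 0) {
    warning("zero spread in covariation scores; no pairs selected")
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  }
  thr <- mean(vals) + z * s
  sel <- ut[vals > thr, , drop = FALSE]
  colnames(sel) <- c("i", "j")
  sel[order(sel[, 1], sel[, 2]), , drop = FALSE]
}

#' Percent overlap of highly covarying pairs
#'
#' Fraction (as a percent) of the natural alignment's highly covarying
#' pairs that are also highly covarying in the designed alignment.
#' With `denominator = "jaccard"` the intersection is instead divided
#' by the union of the two sets.
#'
#' @param natural,designed score matrices of equal dimension (e.g.
#'   Zpx of the natural and designed alignments).
#' @param z selection threshold in standard deviations, see
#'   [high_covariation_pairs()].
#' @param denominator `"natural"` (recovery semantics, default) or
#'   `"jaccard"`.
#' @return percent overlap in `[0, 100]`, or an undefined-metric
#'   marker when the natural set is empty.
#' @export
covariation_overlap <- function(natural, designed, z = 2.0,
                                denominator = c("natural", "jaccard")) {
  denominator <- match.arg(denominator)
  if (!all(dim(natural) == dim(designed))) {
    stop("score matrices have different dimensions", call. = FALSE)
  }
  pk <- function(m) paste(m[, 1], m[, 2], sep = "-")
  nat <- pk(high_covariation_pairs(natural, z))
  des <- pk(high_covariation_pairs(designed, z))
  if (length(nat) == 0) {
    return(undefined_metric("no highly covarying pairs in the natural set"))
  }
  inter <- length(intersect(nat, des))
  denom <- if (denominator == "natural") length(nat) else
    length(union(nat, des))
  100 * inter / denom
}

#' Burial classification thresholds
#'
#' @param neighbor_atom atom used for neighbor counting (default
#'   `"CB"`; glycine falls back to `fallback_atom`).
#' @param fallback_atom stand-in for residues lacking the neighbor
#'   atom (default `"CA"`).
#' @param radius neighbor radius in Angstrom (default 8).
#' @param buried_min_neighbors a position is buried when it has
#'   strictly more than this many neighbors (default 14).
#' @param exposed_max_neighbors a position is exposed when it has at
#'   most this many neighbors (default 8).
#' @return an object of class `"burial_config"`.
#' @export
burial_config <- function(neighbor_atom = "CB", fallback_atom = "CA",
                          radius = 8.0, buried_min_neighbors = 14,
                          exposed_max_neighbors = 8) {
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  if (exposed_max_neighbors >= buried_min_neighbors) {
    stop("exposed_max_neighbors must be below buried_min_neighbors",
         call. = FALSE)
  }
  structure(list(neighbor_atom = neighbor_atom, fallback_atom = fallback_atom,
                 radius = radius, buried_min_neighbors = buried_min_neighbors,
                 exposed_max_neighbors = exposed_max_neighbors),
            class = "burial_config")
}

#' Classify residue burial by neighbor counting
#'
#' For each residue the number of other residues whose C-beta atom
#' (C-alpha for glycine) lies within the configured radius of its own
#' is counted.  Positions with strictly more than 14 neighbors are
#' buried; positions with 0-8 neighbors are exposed; the rest are
#' intermediate.
#'
#' @param structure a [structure_coords()].
#' @param cfg a [burial_config()].
#' @return a data frame with one row per residue: `chain`, `resno`,
#'   `icode`, `resname`, `n_neighbors` and `burial` (one of
#'   `"buried"`, `"intermediate"`, `"exposed"`).  Residues lacking
#'   both the neighbor atom and the fallback are skipped with a
#'   warning.
#' @export
classify_burial <- function(structure, cfg = burial_config()) {
  df <- as.data.frame(structure)
  rid <- paste(df$chain, df$resno, df$icode, sep = "|")
  residues <- !duplicated(rid)
  res_keys <- rid[residues]
  pick <- function(key) {
    rows <- df[rid == key, , drop = FALSE]
    hit <- rows[rows$atom == cfg$neighbor_atom, , drop = FALSE]
    if (nrow(hit) == 0) hit <- rows[rows$atom == cfg$fallback_atom, , drop = FALSE]
    if (nrow(hit) == 0) return(NULL)
    hit[1, , drop = FALSE]
  }
  picked <- lapply(res_keys, pick)
  missing <- vapply(picked, is.null, logical(1))
  if (any(missing)) {
    warning(sprintf("%d residue(s) lack both %s and %s atoms; skipped",
                    sum(missing), cfg$neighbor_atom, cfg$fallback_atom))
  }
  picked <- do.call(rbind, picked[!missing])
  if (is.null(picked) || nrow(picked) == 0) {
    stop("no residues with usable neighbor atoms", call. = FALSE)
  }
  xyz <- as.matrix(picked[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  counts <- rowSums(d <= cfg$radius) - 1L
  burial <- ifelse(counts > cfg$buried_min_neighbors, "buried",
                   ifelse(counts <= cfg$exposed_max_neighbors,
                          "exposed", "intermediate"))
  data.frame(chain = picked$chain, resno = picked$resno,
             icode = picked$icode, resname = picked$resname,
             n_neighbors = as.integer(counts), burial = burial,
             stringsAsFactors = FALSE)
}

#' Amino-acid composition by category
#'
#' Percent occurrence of each category (default: the nonpolar / polar
#' / charged polarity partition) over all residues found at the given
#' positions across all sequences of the alignment.  Gaps and unknowns
#' are excluded; the percentages sum to 100.  With
#' `categories = NULL` the per-amino-acid percentages are returned.
#'
#' @param msa an [msa()].
#' @param positions 1-based column indices (default: all columns).
#' @param categories named list of character vectors that partition
#'   the 20-letter alphabet, or `NULL` for per-amino-acid mode.
#' @return named numeric vector of percentages summing to 100.
#' @export
composition_by_category <- function(msa, positions = NULL,
                                    categories = AA_POLARITY) {
  if (is.null(positions)) positions <- seq_len(msa$length)
  if (any(positions < 1 | positions > msa$length)) {
    stop("positions out of range", call. = FALSE)
  }
  residues <- as.vector(msa$seqs[, positions, drop = FALSE])
  residues <- residues[residues %in% AA_ALPHABET]
  if (length(residues) == 0) stop("no residues at the given positions", call. = FALSE)
  aa_pct <- 100 * as.numeric(table(factor(residues, levels = AA_ALPHABET))) /
    length(residues)
  names(aa_pct) <- AA_ALPHABET
  if (is.null(categories)) return(aa_pct)
  flat <- unlist(categories, use.names = FALSE)
  if (length(flat) != 20 || anyDuplicated(flat) ||
      !setequal(flat, AA_ALPHABET)) {
    stop("categories must partition the 20-letter alphabet", call. = FALSE)
  }
  vapply(categories, function(aas) sum(aa_pct[aas]), numeric(1))
}
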