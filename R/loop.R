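# Loop-reconstruction benchmark metrics: Kabsch superposition on the
# non-loop frame, loop backbone heavy-atom RMSD, per-case and
# benchmark-level medians, and the long-loop crystal-contact filter.

BACKBONE_HEAVY <- c("N", "CA", "C", "O")

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' `mobile` onto `reference` by singular value decomposition of the
#' cross-covariance of the centered point sets, with the determinant
#' sign corrected so the result is a rotation (det = +1), never a
#' reflection.
#'
#' @param mobile,reference n x 3 coordinate matrices (n >= 3) with
#'   corresponding rows.
#' @return a list with `rotation` (3 x 3, det +1), `translation`
#'   (length 3) and `rmsd`; the transformed coordinates are
#'   `mobile %*% rotation + translation` (row-wise).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3 ||
      ncol(reference) != 3) {
    stop("point sets must be n x 3 with equal n", call. = FALSE)
  }
  if (nrow(mobile) < 3) stop("need at least 3 points", call. = FALSE)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  if (max(svd(A)$d) < 1e-9) stop("degenerate (collapsed) geometry", call. = FALSE)
  s <- svd(crossprod(A, B))       # t(A) %*% B
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  t_vec <- cr - as.vector(cm %*% R)
  moved <- sweep(A %*% R, 2, cr, "+")
  rmsd <- sqrt(mean(rowSums((moved - sweep(B, 2, cr, "+"))^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

# Extract an n x 3 coordinate matrix for selected residues/atoms,
# keyed and ordered by (chain, resno, icode, atom).
coords_for <- function(structure, keys) {
  df <- as.data.frame(structure)
  have <- paste(df$chain, df$resno, df$icode, df$atom, sep = "|")
  idx <- match(keys, have)
  miss <- keys[is.na(idx)]
  if (length(miss) > 0) {
    stop(sprintf("missing atom(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  as.matrix(df[idx, c("x", "y", "z")])
}

residue_keys <- function(structure) {
  df <- as.data.frame(structure)
  unique(paste(df$chain, df$resno, df$icode, sep = "|"))
}

loop_res_keys <- function(loop) {
  if (is.data.frame(loop)) {
    icode <- if ("icode" %in% names(loop)) loop$icode else ""
    icode[is.na(icode)] <- ""
    paste(loop$chain, loop$resno, icode, sep = "|")
  } else {
    as.character(loop)
  }
}

#' Loop backbone heavy-atom RMSD after frame superposition
#'
#' The model is superposed onto the native structure using the
#' backbone atoms of all *non-loop* residues (the frame), and the
#' RMSD is then computed over the backbone heavy atoms (N, CA, C, O
#' by default) of the loop residues without further fitting — the
#' standard protocol for scoring reconstructed loops against a
#' crystal conformation.
#'
#' @param model,native [structure_coords()] objects sharing residue
#'   numbering.
#' @param loop the loop residues: a data frame with columns `chain`,
#'   `resno` and optional `icode`, or the string form parsed by
#'   [parse_loop_spec()].
#' @param backbone_atoms atoms used both for the frame fit and the
#'   loop RMSD (default `c("N","CA","C","O")`; set to
#'   `c("N","CA","C")` to exclude the carbonyl oxygen).
#' @return RMSD in Angstrom.
#' @export
loop_rmsd <- function(model, native, loop,
                      backbone_atoms = BACKBONE_HEAVY) {
  loop_keys <- loop_res_keys(loop)
  nat_res <- residue_keys(native)
  if (!all(loop_keys %in% nat_res)) {
    stop(sprintf("loop residue(s) not in native: %s",
                 paste(setdiff(loop_keys, nat_res), collapse = ", ")),
         call. = FALSE)
  }
  frame_res <- setdiff(nat_res, loop_keys)
  if (length(frame_res) < 3) {
    stop("need at least 3 non-loop residues for the frame fit", call. = FALSE)
  }
  # frame atoms present in both structures
  nat_df <- as.data.frame(native)
  nat_atoms <- paste(nat_df$chain, nat_df$resno, nat_df$icode, nat_df$atom,
                     sep = "|")
  mod_df <- as.data.frame(model)
  mod_atoms <- paste(mod_df$chain, mod_df$resno, mod_df$icode, mod_df$atom,
                     sep = "|")
  frame_keys <- as.vector(outer(frame_res, backbone_atoms, paste, sep = "|"))
  frame_keys <- intersect(intersect(frame_keys, nat_atoms), mod_atoms)
  if (length(frame_keys) < 3) {
    stop("fewer than 3 shared frame backbone atoms", call. = FALSE)
  }
  fit <- kabsch_superpose(coords_for(model, frame_keys),
                          coords_for(native, frame_keys))
  loop_atom_keys <- as.vector(t(outer(loop_keys, backbone_atoms,
                                      paste, sep = "|")))
  mob <- coords_for(model, loop_atom_keys)   # errors name missing atoms
  ref <- coords_for(native, loop_atom_keys)
  moved <- sweep(mob %*% fit$rotation, 2, fit$translation, "+")
  sqrt(mean(rowSums((moved - ref)^2)))
}

#' Parse a loop specification string
#'
#' @param spec a string `"chain:start-end"` (e.g. `"A:153-164"`);
#'   insertion codes are not expressible in this shorthand — pass a
#'   data frame to [loop_rmsd()] instead when they matter.
#' @param chain_default chain used when the spec omits one.
#' @return a data frame with columns `chain`, `resno`, `icode`.
#' @export
parse_loop_spec <- function(spec, chain_default = "A") {
  m <- regmatches(spec, regexec("^(?:([A-Za-z0-9]):)?(-?[0-9]+)-(-?[0-9]+)$",
                                spec))[[1]]
  if (length(m) == 0) stop(sprintf("cannot parse loop spec '%s'", spec),
                           call. = FALSE)
  chain <- if (m[2] == "") chain_default else m[2]
  data.frame(chain = chain, resno = seq(as.integer(m[3]), as.integer(m[4])),
             icode = "", stringsAsFactors = FALSE)
}

#' Construct a loop-reconstruction benchmark case
#'
#' @param case_id identifier.
#' @param native native [structure_coords()].
#' @param loop loop residues (see [loop_rmsd()]).
#' @param models list of model [structure_coords()].
#' @param energies numeric vector of model scores (lower = better),
#'   one per model.
#' @return an object of class `"loop_case"`.
#' @export
loop_case <- function(case_id, native, loop, models, energies) {
  if (length(models) < 1) stop("need at least one model", call. = FALSE)
  if (length(models) != length(energies)) {
    stop("models and energies differ in length", call. = FALSE)
  }
  stopifnot_finite(energies, "energies")
  structure(list(case_id = case_id, native = native, loop = loop,
                 models = models, energies = energies),
            class = "loop_case")
}

#' Per-case loop reconstruction metrics
#'
#' Computes the loop backbone RMSD of every model, then summarizes:
#' the RMSD of the single lowest-energy model; the lowest RMSD among
#' the 5 lowest-energy models (less susceptible to stochastic
#' fluctuations; undefined with fewer than 5 models); and the percent
#' of models with RMSD strictly below 1 Angstrom (sub-angstrom
#' models).  Energy ties are broken by model input order.
#'
#' @param case a [loop_case()].
#' @param backbone_atoms see [loop_rmsd()].
#' @param subangstrom_cutoff RMSD threshold in Angstrom (default 1.0,
#'   strict `<`).
#' @return a list with `rmsd_lowest_energy`, `rmsd_best_of_5_lowest`,
#'   `pct_subangstrom`, `n_models` and the per-model `rmsds`.
#' @export
case_metrics <- function(case, backbone_atoms = BACKBONE_HEAVY,
                         subangstrom_cutoff = 1.0) {
  rmsds <- vapply(case$models, loop_rmsd, numeric(1),
                  native = case$native, loop = case$loop,
                  backbone_atoms = backbone_atoms)
  summarize_case_rmsds(rmsds, case$energies, subangstrom_cutoff)
}

# Shared by case_metrics and the simulators (which know their RMSDs).
summarize_case_rmsds <- function(rmsds, energies, subangstrom_cutoff = 1.0) {
  ord <- order(energies)  # stable: ties keep input order
  best5 <- if (length(rmsds) >= 5) {
    min(rmsds[ord[1:5]])
  } else {
    undefined_metric("fewer than 5 models")
  }
  list(rmsd_lowest_energy = rmsds[ord[1]],
       rmsd_best_of_5_lowest = best5,
       pct_subangstrom = 100 * mean(rmsds < subangstrom_cutoff),
       n_models = length(rmsds),
       rmsds = rmsds)
}

#' Benchmark-level medians over loop cases
#'
#' Median over cases of each per-case metric; the median of an
#' even-length set is the mean of its two central values.
#'
#' @param case_list list of per-case metric lists as returned by
#'   [case_metrics()].
#' @return a list with `median_rmsd_lowest_energy`,
#'   `median_rmsd_best_of_5` (over the cases where it is defined) and
#'   `median_pct_subangstrom`.
#' @export
benchmark_metrics <- function(case_list) {
  if (length(case_list) == 0) stop("no cases", call. = FALSE)
  g <- function(field) vapply(case_list, function(cm) {
    v <- cm[[field]]
    if (is_undefined_metric(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  list(median_rmsd_lowest_energy = median(g("rmsd_lowest_energy")),
       median_rmsd_best_of_5 = median(g("rmsd_best_of_5_lowest"), na.rm = TRUE),
       median_pct_subangstrom = median(g("pct_subangstrom")))
}

#' Crystal-contact curation filter for loop benchmark cases
#'
#' Counts the loop residues having any heavy atom within `cutoff` of
#' any symmetry-mate heavy atom (distances inclusive of the cutoff).
#' Cases pass when at most `max_contact_residues` residues are in
#' contact, limiting the influence of crystal packing on the loop
#' conformation.  Atoms whose names begin with `H` are treated as
#' hydrogens and ignored.
#'
#' @param loop loop residues (see [loop_rmsd()]).
#' @param native native [structure_coords()].
#' @param symmetry_mates [structure_coords()] of the surrounding
#'   symmetry-mate environment; an empty set passes with a warning.
#' @param cutoff contact distance in Angstrom (default 6).
#' @param max_contact_residues maximum allowed contacting loop
#'   residues (default 5).
#' @return a list with `pass` (logical), `n_contact_residues` and
#'   `contact_residues` (their keys).
#' @export
crystal_contact_filter <- function(loop, native, symmetry_mates,
                                   cutoff = 6.0, max_contact_residues = 5) {
  loop_keys <- loop_res_keys(loop)
  nat <- as.data.frame(native)
  nat_rid <- paste(nat$chain, nat$resno, nat$icode, sep = "|")
  heavy <- function(df) df[!grepl("^H", df$atom), , drop = FALSE]
  mates <- heavy(as.data.frame(symmetry_mates))
  if (nrow(mates) == 0) {
    warning("empty symmetry-mate set; contact count is 0")
    return(list(pass = TRUE, n_contact_residues = 0L,
                contact_residues = character(0)))
  }
  mate_xyz <- as.matrix(mates[, c("x", "y", "z")])
  in_contact <- vapply(loop_keys, function(key) {
    res <- heavy(nat[nat_rid == key, , drop = FALSE])
    if (nrow(res) == 0) return(FALSE)
    xyz <- as.matrix(res[, c("x", "y", "z")])
    d2 <- outer(rowSums(xyz^2), rowSums(mate_xyz^2), "+") -
      2 * xyz %*% t(mate_xyz)
    any(d2 <= cutoff^2 + 1e-9)
  }, logical(1))
  n <- sum(in_contact)
  list(pass = n <= max_contact_residues,
       n_contact_residues = as.integer(n),
       contact_residues = loop_keys[in_contact])
}
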