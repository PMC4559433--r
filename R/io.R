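# Readers/writers for the external representations the toolkit touches:
# ddG benchmark record tables (CSV/JSON), FASTA alignments, PDB
# coordinates, PWM tables and metric reports.

DDG_REQUIRED_COLS <- c("record_id", "pdb_id", "chain", "residue_id",
                       "wildtype_aa", "mutant_aa", "ddg_experimental")
DDG_OPTIONAL_COLS <- c("ddg_predicted", "resolution", "method",
                       "is_transmembrane", "references")

#' Construct a validated ddG benchmark dataset
#'
#' A ddG dataset is a data frame with one row per mutation record:
#' identifiers (`record_id`, `pdb_id`, `chain`, `residue_id` in author
#' numbering with optional insertion code), the mutation
#' (`wildtype_aa`, `mutant_aa`, one-letter codes), the experimental
#' stability change `ddg_experimental` in kcal/mol (positive =
#' destabilizing), and optional columns `ddg_predicted` (score units),
#' `resolution` (Angstrom), `method` (`"xray"`, `"nmr"` or `"other"`),
#' `is_transmembrane` and `references`.  Additional columns are
#' preserved untouched.
#'
#' @param df a data frame holding at least the required columns.
#' @return the validated data frame with class `"ddg_dataset"`.
#' @export
ddg_dataset <- function(df) {
  missing <- setdiff(DDG_REQUIRED_COLS, names(df))
  if (length(missing) > 0) {
    stop(sprintf("ddG dataset is missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in c("ddg_predicted", "resolution")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  if (!"method" %in% names(df)) df$method <- "xray"
  if (!"is_transmembrane" %in% names(df)) df$is_transmembrane <- FALSE
  if (!"references" %in% names(df)) df$references <- ""
  df$ddg_experimental <- as.numeric(df$ddg_experimental)
  df$ddg_predicted <- as.numeric(df$ddg_predicted)
  df$resolution <- as.numeric(df$resolution)
  df$is_transmembrane <- as.logical(df$is_transmembrane)
  validate_ddg_dataset(df)
  class(df) <- c("ddg_dataset", "data.frame")
  df
}

validate_ddg_dataset <- function(df) {
  bad <- !is.finite(df$ddg_experimental)
  if (any(bad)) {
    stop(sprintf("unparseable or non-finite ddg_experimental for record(s): %s",
                 paste(df$record_id[bad], collapse = ", ")), call. = FALSE)
  }
  aa_ok <- df$wildtype_aa %in% AA_ALPHABET & df$mutant_aa %in% AA_ALPHABET
  if (any(!aa_ok)) {
    stop(sprintf("amino-acid code outside the 20-letter alphabet for record(s): %s",
                 paste(df$record_id[!aa_ok], collapse = ", ")), call. = FALSE)
  }
  same <- df$wildtype_aa == df$mutant_aa
  if (any(same)) {
    stop(sprintf("wildtype_aa equals mutant_aa for record(s): %s",
                 paste(df$record_id[same], collapse = ", ")), call. = FALSE)
  }
  bad_method <- !df$method %in% c("xray", "nmr", "other")
  if (any(bad_method)) {
    stop(sprintf("method must be one of xray/nmr/other for record(s): %s",
                 paste(df$record_id[bad_method], collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Read a ddG benchmark dataset from CSV or JSON
#'
#' The CSV dialect is comma-separated UTF-8 with a header row and `.`
#' decimals.  The JSON form is an array of objects with the same field
#' names.  Unknown columns/fields are preserved.
#'
#' @param path file to read.
#' @param format `"csv"` or `"json"`; inferred from the file extension
#'   when omitted.
#' @return a [ddg_dataset()].
#' @export
read_ddg_dataset <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- if (format == "csv") {
    read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  } else {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  }
  ddg_dataset(df)
}

#' Write a ddG benchmark dataset to CSV or JSON
#'
#' @param df a [ddg_dataset()] (or compatible data frame).
#' @param path destination file.
#' @param format `"csv"` or `"json"`; inferred from the extension when
#'   omitted.
#' @export
write_ddg_dataset <- function(df, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  out <- as.data.frame(df)
  if (format == "csv") {
    write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}

#' Construct a multiple sequence alignment object
#'
#' Sequences are stored upper-cased over the alphabet of 20 amino
#' acids, the gap character `-` and the unknown character `X`; the
#' legacy gap character `.` is normalized to `-`.
#'
#' @param ids character vector of sequence identifiers.
#' @param sequences character vector of aligned sequences, all the same
#'   length.
#' @return an object of class `"msa"`: a list with elements `ids`,
#'   `seqs` (a depth x length character matrix of residues), `depth`
#'   and `length`.
#' @export
msa <- function(ids, sequences) {
  if (length(ids) != length(sequences) || length(ids) < 1) {
    stop("ids and sequences must be non-empty and of equal length", call. = FALSE)
  }
  sequences <- chartr(".", "-", toupper(sequences))
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1) {
    ragged <- ids[lens != stats::median(lens)]
    stop(sprintf("ragged alignment; offending sequence id(s): %s",
                 paste(ragged, collapse = ", ")), call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(sequences, ""))
  rownames(mat) <- ids
  bad <- !(mat %in% c(AA_ALPHABET, "-", "X"))
  if (any(bad)) {
    stop(sprintf("alignment contains %d symbol(s) outside {20 amino acids, '-', 'X'}",
                 sum(bad)), call. = FALSE)
  }
  structure(list(ids = ids, seqs = mat,
                 depth = nrow(mat), length = ncol(mat)),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n", x$depth, x$length))
  invisible(x)
}

#' Read a FASTA multiple sequence alignment
#'
#' @param path FASTA file; all records must have equal aligned length.
#' @return an [msa()].
#' @export
read_fasta_msa <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  msa(names(set), as.character(set))
}

#' Write an alignment to FASTA
#'
#' @param x an [msa()].
#' @param path destination file.
#' @export
write_fasta_msa <- function(x, path) {
  seqs <- apply(x$seqs, 1, paste, collapse = "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- x$ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a labeled coordinate set
#'
#' @param df data frame with columns `chain`, `resno` (integer author
#'   numbering), `icode` (insertion code, `""` if none), `resname`
#'   (3-letter residue name), `atom` (atom name) and coordinates `x`,
#'   `y`, `z` in Angstrom.
#' @return the data frame with class `"structure_coords"`.
#' @export
structure_coords <- function(df) {
  need <- c("chain", "resno", "resname", "atom", "x", "y", "z")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop(sprintf("structure_coords missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!"icode" %in% names(df)) df$icode <- ""
  df$icode[is.na(df$icode)] <- ""
  stopifnot_finite(c(df$x, df$y, df$z), "atomic coordinates")
  key <- paste(df$chain, df$resno, df$icode, df$atom, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue, atom) keys in structure", call. = FALSE)
  }
  class(df) <- c("structure_coords", "data.frame")
  df
}

#' Read coordinates from a PDB file
#'
#' Only `ATOM` records are retained; alternate locations other than
#' `' '` or `'A'` are dropped so that downstream metrics see a single
#' conformer.  Residues keep author numbering and insertion codes.
#'
#' @param path PDB file.
#' @param model_index 1-based model to read from a multi-model file.
#' @return a [structure_coords()].
#' @export
read_pdb_coords <- function(path, model_index = 1) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type == "ATOM" & (is.na(at$alt) | at$alt %in% c("", " ", "A"))
  if (!any(keep)) stop("no ATOM records in structure", call. = FALSE)
  at <- at[keep, , drop = FALSE]
  if (model_index > 1) {
    if (is.null(pdb$xyz) || nrow(pdb$xyz) < model_index) {
      stop(sprintf("model %d not present in %s", model_index, path), call. = FALSE)
    }
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    xyz <- xyz[keep, , drop = FALSE]
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  structure_coords(data.frame(
    chain = at$chain, resno = at$resno,
    icode = ifelse(is.na(at$insert) | at$insert == " ", "", at$insert),
    resname = at$resid, atom = at$elety,
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE))
}

#' Read a position weight matrix from CSV
#'
#' The expected layout is 20 rows (amino acids in the order
#' `ACDEFGHIKLMNPQRSTVWY`, given in the first column) and one column
#' per position.
#'
#' @param path CSV file.
#' @return a `"pwm"`: a 20 x n numeric matrix with amino-acid rownames,
#'   each column summing to 1.
#' @export
read_pwm_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  as_pwm(m[AA_ALPHABET, , drop = FALSE])
}

#' Write a position weight matrix to CSV
#'
#' @param pwm a `"pwm"` matrix (see [read_pwm_csv()]).
#' @param path destination CSV.
#' @export
write_pwm_csv <- function(pwm, path) {
  df <- data.frame(aa = rownames(pwm), pwm, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

as_pwm <- function(m) {
  if (!is.matrix(m) || nrow(m) != 20) {
    stop("a PWM must be a 20-row matrix over the amino-acid alphabet", call. = FALSE)
  }
  if (is.null(rownames(m))) rownames(m) <- AA_ALPHABET
  if (!identical(rownames(m), AA_ALPHABET)) {
    stop("PWM rows must be the amino acids in order ACDEFGHIKLMNPQRSTVWY",
         call. = FALSE)
  }
  if (any(m < -1e-12)) stop("PWM entries must be nonnegative", call. = FALSE)
  sums <- colSums(m)
  if (any(abs(sums - 1) > 1e-9)) {
    stop("each PWM column must sum to 1 within 1e-9", call. = FALSE)
  }
  class(m) <- c("pwm", "matrix", "array")
  m
}

#' Assemble a metric report
#'
#' @param benchmark short name of the benchmark the metrics belong to.
#' @param metrics named list; each element is either a bare numeric
#'   value or a list with fields `value`, and optionally `units`, `n`
#'   and `notes`.  Undefined-metric markers become explicit
#'   null-with-reason entries.
#' @param provenance named list recording input paths, parameters and
#'   tool version.
#' @return an object of class `"metric_report"`.
#' @export
metric_report <- function(benchmark, metrics = list(), provenance = list()) {
  metrics <- lapply(metrics, function(m) {
    if (!is.list(m)) m <- list(value = m)
    v <- m$value
    if (is_undefined_metric(v)) {
      m$value <- NULL
      m$undefined <- attr(v, "undefined")
    } else {
      if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
        stop("metric values must be single finite numbers or undefined markers",
             call. = FALSE)
      }
      m$value <- as.numeric(v)
    }
    m
  })
  provenance$tool <- "macrobench"
  provenance$version <- as.character(packageVersion("macrobench"))
  if (length(metrics) > 0) metrics <- metrics[order(names(metrics))]
  structure(list(benchmark = benchmark,
                 metrics = metrics,
                 provenance = provenance),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> benchmark: %s\n", x$benchmark))
  for (nm in names(x$metrics)) {
    m <- x$metrics[[nm]]
    if (is.null(m$value)) {
      cat(sprintf("  %-28s undefined (%s)\n", nm, m$undefined))
    } else {
      cat(sprintf("  %-28s %s%s\n", nm, signif(m$value, 6),
                  if (!is.null(m$units)) paste0(" ", m$units) else ""))
    }
  }
  invisible(x)
}

#' Write a metric report to JSON or CSV
#'
#' Keys are written in stable (alphabetical) order and floats with six
#' significant digits.
#'
#' @param report a [metric_report()].
#' @param path destination file.
#' @param format `"json"` or `"csv"`; inferred from the extension when
#'   omitted.
#' @export
write_report <- function(report, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  if (format == "json") {
    out <- list(benchmark = report$benchmark,
                metrics = lapply(report$metrics, function(m) {
                  if (!is.null(m$value)) m$value <- signif(m$value, 6)
                  m
                }),
                provenance = report$provenance)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    rows <- lapply(names(report$metrics), function(nm) {
      m <- report$metrics[[nm]]
      data.frame(metric = nm,
                 value = if (is.null(m$value)) NA_real_ else signif(m$value, 6),
                 units = if (is.null(m$units)) "" else m$units,
                 n = if (is.null(m$n)) NA_integer_ else m$n,
                 notes = if (is.null(m$undefined)) "" else
                   paste0("undefined: ", m$undefined),
                 stringsAsFactors = FALSE)
    })
    write.csv(do.call(rbind, rows), path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a JSON metric report
#'
#' @param path JSON file written by [write_report()].
#' @return a [metric_report()]-shaped list.
#' @export
read_report <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  structure(x, class = "metric_report")
}
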