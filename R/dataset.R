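# Compound-table ingestion and curation.
#
# Curation applies, in a fixed order so exclusion counts are reproducible:
# parseable -> single fragment (mixture filter) -> contains carbon (inorganic
# filter) -> duplicate collapse (conflicting labels dropped as ambiguous) ->
# explicitly ambiguous rows dropped.

# Characters legal in SMILES; used as a strictness pre-check because the
# underlying toolkit silently repairs some malformed strings (e.g. an
# unclosed branch) instead of rejecting them.
.smiles_ok_syntax <- function(s) {
  if (!nzchar(s)) return(FALSE)
  if (grepl("[^A-Za-z0-9@+\\-\\[\\]()=#$:/\\\\.%*]", s)) return(FALSE)
  chars <- strsplit(s, "")[[1]]
  if (sum(chars == "(") != sum(chars == ")")) return(FALSE)
  if (sum(chars == "[") != sum(chars == "]")) return(FALSE)
  TRUE
}

.ob_canonical <- function(smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\n")),
    error = function(e) ""
  )
  out <- sub("[\t ]*\n?$", "", out)
  if (!nzchar(out) || grepl("\n", out)) return(NA_character_)
  out
}

#' Canonicalize SMILES strings
#'
#' Maps every way of writing a molecule to one canonical SMILES string, so
#' that duplicate structures can be recognized by string equality. Uses the
#' OpenBabel canonicalization exposed by ChemmineOB. Canonicalization is a
#' projection: applying it twice gives the same string as applying it once.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, same length and order.
#' @examples
#' canonicalize_smiles(c("OCC", "CCO"))  # identical outputs
#' @export
canonicalize_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) == 0)
    abort("smiles must be a non-empty character vector", "unparseable_smiles")
  out <- character(length(smiles))
  uniq <- unique(smiles)
  canon <- vapply(uniq, function(s) {
    if (!.smiles_ok_syntax(s)) NA_character_ else .ob_canonical(s)
  }, character(1))
  out <- canon[match(smiles, uniq)]
  bad <- which(is.na(out))
  if (length(bad) > 0)
    abort(sprintf("unparseable SMILES: %s", paste(smiles[bad], collapse = ", ")),
          "unparseable_smiles", offending = smiles[bad])
  unname(out)
}

# Like canonicalize_smiles but returns NA for failures instead of erroring.
.canonical_or_na <- function(smiles) {
  vapply(smiles, function(s) {
    if (!is.character(s) || length(s) != 1 || !.smiles_ok_syntax(s))
      return(NA_character_)
    .ob_canonical(s)
  }, character(1), USE.NAMES = FALSE)
}

.has_carbon <- function(canon) {
  # carbon appears as C, c (aromatic), or inside brackets [C..]/[c..];
  # exclude Cl/Ca/Cd/Co/Cu/Cr/Cs/Ce/Cf (two-letter elements starting with C)
  stripped <- gsub("Cl|Ca|Cd|Co|Cu|Cr|Cs|Ce|Cf|Cn|Cm", "", canon)
  grepl("[Cc]", stripped)
}

#' Read a compound table
#'
#' Reads CSV/TSV (with a header) or plain SMI (one `SMILES label` pair per
#' line, whitespace-separated, no header) into the raw-row data frame consumed
#' by [curate_compounds()].
#'
#' @param path file path.
#' @param format one of "csv", "tsv", "smi"; default guessed from extension.
#' @param smiles_col,label_col column names for CSV/TSV input.
#' @return data.frame with columns `smiles`, `label`, `source_id`.
#' @export
read_compound_table <- function(path, format = NULL,
                                smiles_col = "smiles", label_col = "label") {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", smi = "smi",
                     abort(sprintf("cannot guess format of '%s'", path), "schema_error"))
  }
  if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[ \t]+")
    df <- data.frame(
      smiles = vapply(parts, `[`, character(1), 1),
      label = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, character(1)),
      stringsAsFactors = FALSE
    )
  } else {
    df <- utils::read.table(path, header = TRUE, sep = if (format == "csv") "," else "\t",
                            stringsAsFactors = FALSE, comment.char = "")
    if (!all(c(smiles_col, label_col) %in% names(df)))
      abort(sprintf("columns '%s'/'%s' not found", smiles_col, label_col), "schema_error")
    df <- data.frame(smiles = as.character(df[[smiles_col]]),
                     label = as.character(df[[label_col]]),
                     stringsAsFactors = FALSE)
  }
  df$source_id <- paste0("row", seq_len(nrow(df)))
  df
}

#' Curate a labeled compound table
#'
#' Applies the curation rules in a fixed order: unparseable SMILES are
#' rejected; multi-fragment entries (a "." in the canonical form) are removed
#' as mixtures; entries without a carbon atom are removed as inorganic;
#' duplicate canonical structures are collapsed (agreeing labels keep one
#' copy, conflicting labels drop all copies as ambiguous); rows flagged
#' ambiguous in the input are dropped. Every excluded input row is logged with
#' exactly one reason code.
#'
#' @param rows data.frame with columns `smiles`, `label` (0, 1, or an
#'   ambiguous marker such as NA or "ambiguous"), optional `source_id`.
#' @return an object of class `curated_dataset`: list with `records`
#'   (data.frame `smiles`, `label`, `source_id`; canonical SMILES, unique) and
#'   `curation_log` (data.frame `input_row`, `smiles`, `reason` with reason in
#'   duplicate/mixture/inorganic/ambiguous/unparseable).
#' @export
curate_compounds <- function(rows) {
  if (!is.data.frame(rows) || nrow(rows) == 0)
    abort("empty input", "empty_dataset")
  if (!all(c("smiles", "label") %in% names(rows)))
    abort("rows must have 'smiles' and 'label' columns", "schema_error")
  n <- nrow(rows)
  if (is.null(rows$source_id)) rows$source_id <- paste0("row", seq_len(n))
  smiles_in <- as.character(rows$smiles)
  lab_raw <- rows$label
  lab <- suppressWarnings(as.numeric(as.character(lab_raw)))
  ambiguous_in <- is.na(lab) | !(lab %in% c(0, 1))

  reason <- rep(NA_character_, n)
  canon <- .canonical_or_na(smiles_in)
  reason[is.na(canon)] <- "unparseable"

  ok <- is.na(reason)
  reason[ok & grepl(".", canon, fixed = TRUE)] <- "mixture"
  ok <- is.na(reason)
  reason[ok & !.has_carbon(ifelse(is.na(canon), "", canon))] <- "inorganic"
  ok <- is.na(reason)
  # explicitly ambiguous labels
  reason[ok & ambiguous_in] <- "ambiguous"
  ok <- is.na(reason)

  # duplicate collapse on canonical SMILES among remaining rows
  idx <- which(ok)
  if (length(idx) > 0) {
    groups <- split(idx, canon[idx])
    for (g in groups) {
      if (length(g) > 1) {
        labs <- unique(lab[g])
        if (length(labs) == 1) {
          reason[g[-1]] <- "duplicate"     # keep the first copy
        } else {
          reason[g] <- "ambiguous"         # conflicting labels: drop all
        }
      }
    }
  }

  keep <- which(is.na(reason))
  log <- data.frame(
    input_row = which(!is.na(reason)),
    smiles = smiles_in[!is.na(reason)],
    reason = reason[!is.na(reason)],
    stringsAsFactors = FALSE
  )
  if (length(keep) == 0)
    abort("all rows excluded by curation", "empty_dataset", curation_log = log)
  records <- data.frame(
    smiles = canon[keep],
    label = as.integer(lab[keep]),
    source_id = as.character(rows$source_id[keep]),
    stringsAsFactors = FALSE
  )
  structure(list(records = records, curation_log = log),
            class = "curated_dataset")
}

#' @export
print.curated_dataset <- function(x, ...) {
  cat(sprintf("Curated compound set: %d records (%d positive, %d negative)\n",
              nrow(x$records), sum(x$records$label == 1), sum(x$records$label == 0)))
  if (nrow(x$curation_log) > 0) {
    tab <- table(x$curation_log$reason)
    cat(sprintf("Excluded %d input rows: %s\n", nrow(x$curation_log),
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  } else cat("No exclusions.\n")
  invisible(x)
}

#' Write curated records and the curation log to CSV
#'
#' @param dataset a `curated_dataset`.
#' @param records_path,log_path output file paths.
#' @return invisibly, the dataset.
#' @export
write_curated <- function(dataset, records_path, log_path = NULL) {
  stopifnot(inherits(dataset, "curated_dataset"))
  utils::write.csv(dataset$records, records_path, row.names = FALSE)
  if (!is.null(log_path))
    utils::write.csv(dataset$curation_log, log_path, row.names = FALSE)
  invisible(dataset)
}

#' Stratified train/test split
#'
#' Splits record indices into train and test sets preserving the class
#' proportions (each class is sampled separately), deterministically for a
#' given seed.
#'
#' @param labels integer vector of 0/1 labels (or a `curated_dataset`).
#' @param test_fraction proportion held out, in (0,1); default 0.2.
#' @param seed integer seed.
#' @return list with `train_idx`, `test_idx`, `seed`, `test_fraction`.
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = 1) {
  if (inherits(labels, "curated_dataset")) labels <- labels$records$label
  labels <- as.integer(labels)
  if (test_fraction <= 0 || test_fraction >= 1)
    abort("test_fraction must lie in (0,1)", "config_error")
  counts <- table(factor(labels, levels = c(0, 1)))
  if (any(counts < 2))
    abort("each class needs at least 2 members to stratify", "stratification_error")
  test_idx <- integer(0)
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      cls_idx <- which(labels == cls)
      n_test <- round(test_fraction * length(cls_idx))
      n_test <- max(1L, min(length(cls_idx) - 1L, n_test))
      test_idx <- c(test_idx, sample(cls_idx, n_test))
    }
  })
  test_idx <- sort(test_idx)
  list(train_idx = setdiff(seq_along(labels), test_idx),
       test_idx = test_idx, seed = seed, test_fraction = test_fraction)
}
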