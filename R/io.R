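#' Read / write an expression matrix as TSV
#'
#' Proteins as rows, samples as columns, first column holding the protein
#' id. Empty cells are missing values (`NA`), never zero; writing and
#' reading are mutually inverse on valid data.
#'
#' @param path File path.
#' @return For the reader, a numeric matrix with protein rownames and
#'   sample colnames.
#' @export
read_expression_matrix <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("read_expression_matrix: need a protein-id ",
                          "column plus at least one sample column")
  proteins <- raw[[1]]
  if (anyDuplicated(proteins)) {
    stop("read_expression_matrix: duplicate protein ids: ",
         paste(unique(proteins[duplicated(proteins)]), collapse = ", "))
  }
  samples <- colnames(raw)[-1]
  if (anyDuplicated(samples)) {
    stop("read_expression_matrix: duplicate sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  mat <- matrix(NA_real_, length(proteins), length(samples),
                dimnames = list(proteins, samples))
  for (j in seq_along(samples)) {
    cell <- trimws(raw[[j + 1]])
    empty <- is.na(cell) | cell == ""
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!empty & is.na(num))
    if (length(bad)) {
      stop("read_expression_matrix: malformed numeric cell at row ",
           bad[1], " (protein '", proteins[bad[1]], "'), column '",
           samples[j], "': '", cell[bad[1]], "'")
    }
    mat[, j] <- num
  }
  mat
}

#' @rdname read_expression_matrix
#' @param mat Numeric matrix with protein rownames and sample colnames.
#' @export
write_expression_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(protein = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata as TSV
#'
#' Required columns: `sample_id`, `patient_id`, `tissue_class` (one of
#' `tumor`, `healthy_tube`, `contralateral_tube`); optional `side` (`left`,
#' `right`, `na`).
#'
#' @param path File path.
#' @return Data frame of validated metadata.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  need <- c("sample_id", "patient_id", "tissue_class")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols)) {
    stop("read_metadata: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("read_metadata: duplicate sample ids: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
               collapse = ", "))
  }
  classes <- c("tumor", "healthy_tube", "contralateral_tube")
  bad <- setdiff(unique(meta$tissue_class), classes)
  if (length(bad)) {
    stop("read_metadata: unknown tissue_class value(s): ",
         paste(bad, collapse = ", "), " (expected ",
         paste(classes, collapse = ", "), ")")
  }
  if (!"side" %in% names(meta)) meta$side <- "na"
  bad_side <- setdiff(unique(meta$side), c("left", "right", "na"))
  if (length(bad_side)) {
    stop("read_metadata: unknown side value(s): ",
         paste(bad_side, collapse = ", "))
  }
  meta
}

#' @rdname read_metadata
#' @param meta Metadata data frame.
#' @export
write_metadata <- function(meta, path) {
  need <- c("sample_id", "patient_id", "tissue_class", "side")
  stopifnot(all(need %in% names(meta)))
  utils::write.table(meta[, need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write spot-level data as CSV
#'
#' Long format: `protein`, `sample_id`, `dilution_fraction` (0 marks buffer
#' blanks), `replicate`, `signal`; totals: `sample_id`, `total_signal`.
#'
#' @param path File path.
#' @return Data frame of spot records (or totals).
#' @export
read_spot_table <- function(path) {
  spots <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("protein", "sample_id", "dilution_fraction", "replicate",
            "signal")
  missing_cols <- setdiff(need, names(spots))
  if (length(missing_cols)) {
    stop("read_spot_table: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  spots
}

#' @rdname read_spot_table
#' @param spots Spot data frame as produced by [generate_spot_data()].
#' @export
write_spot_table <- function(spots, path) {
  utils::write.csv(spots, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_spot_table
#' @export
read_totals <- function(path) {
  tot <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "total_signal") %in% names(tot))) {
    stop("read_totals: need columns sample_id, total_signal")
  }
  tot
}

#' @rdname read_spot_table
#' @param totals Totals data frame (`sample_id`, `total_signal`).
#' @export
write_totals <- function(totals, path) {
  utils::write.csv(totals, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cross-check an expression matrix against its metadata
#'
#' Flags samples present in only one of the two inputs.
#'
#' @param mat Expression matrix.
#' @param meta Sample metadata.
#' @return List with `matrix_only` and `metadata_only` sample-id vectors.
#' @export
check_matrix_metadata <- function(mat, meta) {
  list(matrix_only = setdiff(colnames(mat), meta$sample_id),
       metadata_only = setdiff(meta$sample_id, colnames(mat)))
}

#' Load the packaged published-results fixture
#'
#' A transcription of the published tumor-vs-normal comparison for the
#' 36-protein panel: for each protein, the p-value and regulation direction
#' of the mean-profile analysis and of three repeated single-sample
#' analyses, plus a curated phosphoprotein flag taken from the antibody
#' panel (name-prefix heuristics would misclassify, e.g., "p38 MAPK" is
#' not a phosphoprotein). `n.s.` entries are parsed as missing p-values
#' (non-significant at the 5% level); one entry reported significant
#' without a printed direction carries an empty direction.
#'
#' @param path Override the packaged fixture file (testing only).
#' @return Data frame with 36 rows: `protein` (ASCII id), `protein_utf8`
#'   (display name with Greek letters), `is_phospho`, and
#'   `p_mean`/`dir_mean`, `p_s1`/`dir_s1`, ... (`p_*` numeric with `NA`
#'   for `n.s.`, `dir_*` in `"+"`, `"-"`, `NA`).
#' @export
load_table2_fixture <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table2_fixture.csv",
                        package = "rppaHet", mustWork = TRUE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", encoding = "UTF-8")
  need <- c("protein", "protein_utf8", "is_phospho",
            paste0(rep(c("p_", "dir_"), 4),
                   rep(c("mean", "s1", "s2", "s3"), each = 2)))
  if (!all(need %in% names(raw)) || nrow(raw) != 36 ||
      anyDuplicated(raw$protein)) {
    stop("load_table2_fixture: fixture is corrupted (wrong columns, row ",
         "count, or duplicated proteins)")
  }
  out <- data.frame(protein = raw$protein, protein_utf8 = raw$protein_utf8,
                    is_phospho = raw$is_phospho == "1",
                    stringsAsFactors = FALSE)
  for (a in c("mean", "s1", "s2", "s3")) {
    pcol <- paste0("p_", a); dcol <- paste0("dir_", a)
    pv <- raw[[pcol]]
    pv[pv == "n.s."] <- NA
    out[[pcol]] <- as.numeric(pv)
    dv <- raw[[dcol]]
    dv[dv == ""] <- NA
    if (!all(dv %in% c("+", "-", NA))) {
      stop("load_table2_fixture: fixture is corrupted (bad direction code)")
    }
    out[[dcol]] <- dv
  }
  if (sum(out$is_phospho) != 15) {
    stop("load_table2_fixture: fixture is corrupted (expected 15 ",
         "phosphoprotein flags, found ", sum(out$is_phospho), ")")
  }
  out
}

#' Convert the fixture to differential-expression result tables
#'
#' Reshapes [load_table2_fixture()] output into the `mean_results` /
#' `single_results` pair consumed by [classify_concordance()]. `n.s.`
#' p-values stay `NA` (treated as non-significant at any alpha up to the
#' publication's 5% threshold).
#'
#' @param fixture Data frame from [load_table2_fixture()].
#' @param alpha Significance level for the `significant` column.
#' @return List with `mean_results` and `single_results` data frames.
#' @export
table2_results <- function(fixture = load_table2_fixture(), alpha = 0.05) {
  dir_map <- c("+" = "up", "-" = "down")
  to_rows <- function(a, label) {
    p <- fixture[[paste0("p_", a)]]
    d <- unname(dir_map[fixture[[paste0("dir_", a)]]])
    data.frame(protein = fixture$protein, analysis = label, p_value = p,
               direction = d, significant = !is.na(p) & p <= alpha,
               stringsAsFactors = FALSE)
  }
  list(mean_results = to_rows("mean", "mean"),
       single_results = rbind(to_rows("s1", "single_1"),
                              to_rows("s2", "single_2"),
                              to_rows("s3", "single_3")))
}
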