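#' Column dialect of a MaxQuant-style phosphosite table
#'
#' Maps the canonical record fields onto the column names of a
#' tab-separated phosphosite export. The default dialect matches the tables
#' written by [write_phosphosite_table()].
#'
#' @param protein,gene,position,residue,sequence_window,localization_prob,ratio_rep1,ratio_rep2
#'   column names in the file.
#' @param rep2_swapped whether the replicate-2 ratio column holds the raw
#'   heavy/light value of a label-swapped run (needing inversion).
#' @return named list of class `phosphosite_dialect`.
#' @export
phosphosite_dialect <- function(protein = "protein",
                                gene = "gene",
                                position = "position",
                                residue = "residue",
                                sequence_window = "sequence_window",
                                localization_prob = "localization_prob",
                                ratio_rep1 = "ratio_rep1",
                                ratio_rep2 = "ratio_rep2",
                                rep2_swapped = TRUE) {
  structure(list(protein = protein, gene = gene, position = position,
                 residue = residue, sequence_window = sequence_window,
                 localization_prob = localization_prob,
                 ratio_rep1 = ratio_rep1, ratio_rep2 = ratio_rep2,
                 rep2_swapped = isTRUE(rep2_swapped)),
            class = "phosphosite_dialect")
}

#' Read a phosphosite TSV table
#'
#' One record per row. Rows whose numeric cells (position, localization
#' probability, ratios) fail to parse are dropped with a single warning
#' reporting the count; missing ratio cells (empty or "-" or "NA") are kept
#' as `NA` so that the dual-replicate rule can handle them.
#'
#' @param path file path.
#' @param dialect a [phosphosite_dialect()].
#' @return phosphosite data.frame (class `phosphosite_records`) with
#'   canonical columns and `rep2_swapped` / `harmonized` attributes; the
#'   number of dropped rows is available as attribute `n_malformed`.
#' @export
read_phosphosite_table <- function(path, dialect = phosphosite_dialect()) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, na.strings = c("NA", "", "-"))
  mapped <- unlist(dialect[c("protein", "gene", "position", "residue",
                             "sequence_window", "localization_prob",
                             "ratio_rep1", "ratio_rep2")])
  missing_cols <- setdiff(mapped, names(raw))
  if (length(missing_cols) > 0)
    stop("missing mapped column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  num <- function(x) suppressWarnings(as.numeric(x))
  rec <- data.frame(
    protein = as.character(raw[[dialect$protein]]),
    gene = as.character(raw[[dialect$gene]]),
    position = num(raw[[dialect$position]]),
    residue = as.character(raw[[dialect$residue]]),
    sequence_window = as.character(raw[[dialect$sequence_window]]),
    localization_prob = num(raw[[dialect$localization_prob]]),
    ratio_rep1 = num(raw[[dialect$ratio_rep1]]),
    ratio_rep2 = num(raw[[dialect$ratio_rep2]]),
    stringsAsFactors = FALSE
  )
  # malformed: a non-empty cell that failed numeric parsing, or an
  # unusable position/probability
  was_na <- function(col) is.na(raw[[dialect[[col]]]])
  bad <- (is.na(rec$position) | is.na(rec$localization_prob)) |
    (is.na(rec$ratio_rep1) & !was_na("ratio_rep1")) |
    (is.na(rec$ratio_rep2) & !was_na("ratio_rep2"))
  if (any(bad))
    warning(sum(bad), " malformed row(s) dropped from ", basename(path))
  rec <- rec[!bad, , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "rep2_swapped") <- dialect$rep2_swapped
  attr(rec, "harmonized") <- !dialect$rep2_swapped
  attr(rec, "n_malformed") <- sum(bad)
  class(rec) <- c("phosphosite_records", "data.frame")
  rec
}

#' Write a phosphosite TSV table
#'
#' @param records phosphosite data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phosphosite_table <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT layout: one set per line, tab-separated
#' `name <tab> description <tab> member...`.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("GMT line with no members: ", substr(l, 1, 40), call. = FALSE)
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GCT 1.2 expression matrix
#'
#' Validates the dimension header against the body.
#'
#' @param path file path.
#' @return numeric matrix with probe rownames and sample colnames;
#'   descriptions kept as attribute `description`.
#' @export
read_gct <- function(path) {
  header <- readLines(path, n = 2L)
  if (!startsWith(header[1], "#1.2"))
    stop("not a GCT 1.2 file: ", path, call. = FALSE)
  dims <- as.integer(strsplit(header[2], "\t")[[1]][1:2])
  body <- utils::read.delim(path, skip = 2, stringsAsFactors = FALSE,
                            check.names = FALSE)
  if (nrow(body) != dims[1] || ncol(body) - 2L != dims[2])
    stop(sprintf("GCT dimension mismatch: header says %d x %d, body is %d x %d",
                 dims[1], dims[2], nrow(body), ncol(body) - 2L), call. = FALSE)
  m <- as.matrix(body[, -(1:2), drop = FALSE])
  rownames(m) <- body[[1]]
  attr(m, "description") <- body[[2]]
  m
}

#' Write a GCT 1.2 expression matrix
#'
#' @param matrix numeric matrix (probes x samples) with dimnames.
#' @param path output path.
#' @param description per-probe description column (defaults to rownames).
#' @return `path`, invisibly.
#' @export
write_gct <- function(matrix, path, description = rownames(matrix)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(matrix), ncol(matrix), sep = "\t")), con)
  body <- data.frame(NAME = rownames(matrix), Description = description,
                     matrix, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the end-to-end phosphoproteomic regulation workflow
#'
#' Chains class-I filtering, label-swap harmonization, empirical-null
#' fitting, threshold derivation, dual-replicate regulation calling, and
#' summarization for one dataset; when a second dataset is supplied the
#' shared regulated sites are intersected per direction.
#'
#' @param records phosphosite data.frame (or a path to a TSV readable with
#'   `dialect`).
#' @param records_b optional second dataset (e.g. a second cell line).
#' @param k sigma multiplier for thresholds (default 2.5).
#' @param min_prob class-I localization cutoff (default 0.75).
#' @param mode null-fitting mode, see [fit_gaussian_null()].
#' @param thresholds optional explicit [threshold_set()] overriding the
#'   fitted one (applied to dataset A only when two datasets are given).
#' @param dialect reader dialect used when `records` is a path.
#' @param output_dir if non-NULL, calls and summary CSVs are written there.
#' @return list of class `phospho_report`: `null`, `thresholds`, `calls`,
#'   `summary`, `composition`, `n_class1`, and (two-dataset runs)
#'   `report_b`, `overlap_down`, `overlap_up`.
#' @export
run_phospho_workflow <- function(records, records_b = NULL, k = 2.5,
                                 min_prob = 0.75,
                                 mode = "pooled_single_ratios",
                                 thresholds = NULL,
                                 dialect = phosphosite_dialect(),
                                 output_dir = NULL) {
  one <- function(rec, thr_override) {
    if (is.character(rec)) rec <- read_phosphosite_table(rec, dialect)
    rec <- filter_class1(rec, min_prob = min_prob)
    rec <- harmonize_label_swap(rec)
    null <- fit_gaussian_null(rec, mode = mode)
    thr <- if (is.null(thr_override)) derive_thresholds(null, k = k)
           else thr_override
    calls <- call_regulation(rec, thr)
    list(null = null, thresholds = thr, calls = calls,
         summary = summarize_regulation(calls),
         composition = residue_composition(rec),
         n_class1 = nrow(rec))
  }
  rep_a <- one(records, thresholds)
  out <- rep_a
  if (!is.null(records_b)) {
    rep_b <- one(records_b, NULL)
    out$report_b <- rep_b
    out$overlap_down <- overlap_regulated(rep_a$calls, rep_b$calls, "down")
    out$overlap_up <- overlap_regulated(rep_a$calls, rep_b$calls, "up")
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out$calls, file.path(output_dir, "regulation_calls.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(metric = c("mu_log2", "sigma_log2", "up_thr", "down_thr",
                            "n_down_sites", "n_down_proteins",
                            "n_up_sites", "n_up_proteins"),
                 value = c(out$null$mu_log2, out$null$sigma_log2,
                           out$thresholds$up_thr, out$thresholds$down_thr,
                           out$summary$n_down_sites, out$summary$n_down_proteins,
                           out$summary$n_up_sites, out$summary$n_up_proteins)),
      file.path(output_dir, "regulation_summary.csv"), row.names = FALSE)
  }
  class(out) <- "phospho_report"
  out
}

#' @export
print.phospho_report <- function(x, ...) {
  print(x$null)
  print(x$thresholds)
  print(x$summary)
  if (!is.null(x$overlap_down))
    cat(sprintf("Shared down-regulated sites across datasets: %d\n",
                nrow(x$overlap_down)))
  invisible(x)
}
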