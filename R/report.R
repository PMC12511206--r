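# End-to-end audit runs and table rendering.

#' Run a full cohort dose audit
#'
#' Reads (or accepts) two patient cohorts, computes per-patient effective
#' doses, and assembles the audit report: the stratified cohort comparison
#' of every quantity, the stratified CT-proportion table, and metadata
#' (sample sizes, blood-volume exclusion counts, input checksums). The
#' report is deterministic for fixed inputs.
#'
#' @param cohort_a,cohort_b Paths to cohort CSV files (see
#'   [read_cohort()]) or patient tables; `cohort_a` is the reference
#'   (conventional-scanner) cohort.
#' @param config Optional path to a YAML dose-scheme file
#'   ([read_dose_scheme()]); defaults to [default_dose_scheme()].
#' @param output_dir Optional directory; when given, the report is also
#'   written there via [write_audit_report()].
#' @return An object of class `audit_report`: list with `comparison`
#'   (tibble from [compare_cohorts()]), `ct_proportion` (tibble from
#'   [ct_proportion_table()]) and `metadata`.
#' @export
run_audit <- function(cohort_a, cohort_b, config = NULL, output_dir = NULL) {
  load_side <- function(x) {
    if (is.character(x)) {
      list(records = read_cohort(x), path = x,
           md5 = unname(tools::md5sum(x)))
    } else {
      list(records = validate_patient_records(x), path = NA_character_,
           md5 = NA_character_)
    }
  }
  a <- load_side(cohort_a)
  b <- load_side(cohort_b)
  scheme <- if (is.null(config)) default_dose_scheme() else read_dose_scheme(config)

  comparison <- compare_cohorts(a$records, b$records, scheme)
  proportion <- ct_proportion_table(a$records, b$records, scheme)

  height_n <- function(r) if ("height" %in% names(r)) sum(!is.na(r$height)) else 0L
  metadata <- list(
    cohort_a = unique(a$records$cohort), cohort_b = unique(b$records$cohort),
    n_a = nrow(a$records), n_b = nrow(b$records),
    height_recorded_a = height_n(a$records),
    height_recorded_b = height_n(b$records),
    bv_excluded_a = nrow(a$records) - height_n(a$records),
    bv_excluded_b = nrow(b$records) - height_n(b$records),
    dlp_conversion = scheme$dlp_conversion,
    input_a = a$path, input_b = b$path,
    md5_a = a$md5, md5_b = b$md5,
    config = if (is.null(config)) "default scheme" else config)

  small <- comparison$stratum != "ALL" & (comparison$n_a < 5 | comparison$n_b < 5)
  if (any(small)) {
    warning(sprintf(
      "%d stratum/quantity cells have n < 5; their medians are unstable",
      sum(small)), call. = FALSE)
  }

  report <- structure(list(comparison = comparison, ct_proportion = proportion,
                           metadata = metadata), class = "audit_report")
  if (!is.null(output_dir)) write_audit_report(report, output_dir)
  report
}

fmt_num <- function(x, digits = 1) {
  ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"), x))
}

fmt_p <- function(p, alpha = 0.05) {
  ifelse(is.na(p), "",
         paste0(sprintf("%.3g", p), ifelse(p < alpha, "*", "")))
}

#' Render comparison rows as an aligned Markdown table
#'
#' Values are rounded to one decimal for display (full precision stays in
#' the underlying tibble / CSV); p-values below 0.05 carry a `*`; absent
#' statistics render as empty cells.
#'
#' @param rows Tibble from [compare_cohorts()] or [ct_proportion_table()].
#' @param style `"markdown"` (pipe table) or `"csv"`.
#' @return A single character string.
#' @export
render_table <- function(rows, style = c("markdown", "csv")) {
  style <- match.arg(style)
  if (nrow(rows) == 0) abort_empty("no rows to render")
  if ("quantity" %in% names(rows)) {
    disp <- tibble::tibble(
      Quantity = rows$quantity,
      Stratum = rows$stratum,
      `n A` = as.character(rows$n_a),
      `Median A (IQR)` = ifelse(is.na(rows$median_a), "",
        sprintf("%s (%s–%s)", fmt_num(rows$median_a),
                fmt_num(rows$q1_a), fmt_num(rows$q3_a))),
      `n B` = as.character(rows$n_b),
      `Median B (IQR)` = ifelse(is.na(rows$median_b), "",
        sprintf("%s (%s–%s)", fmt_num(rows$median_b),
                fmt_num(rows$q1_b), fmt_num(rows$q3_b))),
      `% diff` = fmt_num(rows$percent_difference),
      p = fmt_p(rows$p_value))
  } else {
    disp <- tibble::tibble(
      Stratum = rows$stratum,
      `n A` = as.character(rows$n_a),
      `CT share A (%)` = fmt_num(rows$proportion_a),
      `n B` = as.character(rows$n_b),
      `CT share B (%)` = fmt_num(rows$proportion_b))
  }
  if (style == "csv") {
    con <- textConnection("out", "w", local = TRUE)
    write.csv(disp, con, row.names = FALSE)
    close(con)
    return(paste(out, collapse = "\n"))
  }
  widths <- vapply(seq_along(disp),
                   function(i) max(nchar(c(names(disp)[i], disp[[i]]))),
                   numeric(1))
  pad <- function(x, w) formatC(x, width = w, flag = "-")
  line <- function(vals) paste0("| ", paste(Map(pad, vals, widths),
                                            collapse = " | "), " |")
  paste(c(line(names(disp)),
          line(lapply(widths, function(w) strrep("-", w))),
          vapply(seq_len(nrow(disp)),
                 function(r) line(as.list(disp[r, ])), character(1))),
        collapse = "\n")
}

#' Write an audit report to disk
#'
#' Writes `comparison.csv` and `ct_proportion.csv` at full precision plus
#' `report.md` with the rendered tables and run metadata.
#'
#' @param report An `audit_report` from [run_audit()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_audit_report <- function(report, dir) {
  if (!inherits(report, "audit_report")) {
    abort_invalid("`report` must be an audit_report")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$comparison, file.path(dir, "comparison.csv"),
            row.names = FALSE, na = "")
  write.csv(report$ct_proportion, file.path(dir, "ct_proportion.csv"),
            row.names = FALSE, na = "")
  md <- report$metadata
  writeLines(c(
    "# PET/CT effective-dose audit",
    "",
    sprintf("Cohort A: %s (n = %d, height recorded %d, blood-volume excluded %d)",
            md$cohort_a, md$n_a, md$height_recorded_a, md$bv_excluded_a),
    sprintf("Cohort B: %s (n = %d, height recorded %d, blood-volume excluded %d)",
            md$cohort_b, md$n_b, md$height_recorded_b, md$bv_excluded_b),
    sprintf("DLP conversion: %g mSv/(mGy cm); config: %s",
            md$dlp_conversion, md$config),
    "",
    "## Cohort comparison (A = reference)",
    "",
    render_table(report$comparison),
    "",
    "## CT share of weight-scaled total dose",
    "",
    render_table(report$ct_proportion)),
    file.path(dir, "report.md"))
  invisible(dir)
}

#' Re-read a written audit report
#'
#' Reads the CSV pair written by [write_audit_report()] back into an
#' `audit_report` (metadata is not round-tripped). Values are recovered at
#' full double precision.
#'
#' @param dir Directory written by [write_audit_report()].
#' @return An `audit_report` with `comparison` and `ct_proportion`.
#' @export
read_audit_report <- function(dir) {
  cmp <- file.path(dir, "comparison.csv")
  prp <- file.path(dir, "ct_proportion.csv")
  if (!file.exists(cmp) || !file.exists(prp)) {
    abort_config(paste0("no audit report found in ", dir))
  }
  comparison <- tibble::as_tibble(read.csv(cmp, stringsAsFactors = FALSE))
  comparison$significant <- as.logical(comparison$significant)
  structure(list(comparison = comparison,
                 ct_proportion = tibble::as_tibble(
                   read.csv(prp, stringsAsFactors = FALSE)),
                 metadata = list()),
            class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  md <- x$metadata
  if (length(md)) {
    cat(sprintf("<audit_report> %s (n = %d) vs %s (n = %d)\n\n",
                md$cohort_a, md$n_a, md$cohort_b, md$n_b))
  } else {
    cat("<audit_report>\n\n")
  }
  overall <- x$comparison[x$comparison$stratum == "ALL", ]
  cat(render_table(overall), "\n\n")
  cat("CT share of weight-scaled total dose (medians):\n")
  cat(render_table(x$ct_proportion), "\n")
  invisible(x)
}
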