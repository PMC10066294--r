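html_table <- function(df, digits = 4) {
  fmt <- function(v) {
    if (is.numeric(v)) formatC(v, digits = digits, format = "g") else v
  }
  cells <- vapply(seq_len(nrow(df)), function(i) {
    paste0("<tr>", paste0("<td>", vapply(df[i, , drop = FALSE], fmt,
                                         character(1)), "</td>",
                          collapse = ""), "</tr>")
  }, character(1))
  paste0("<table border='1' cellpadding='3' cellspacing='0'>\n<tr>",
         paste0("<th>", names(df), "</th>", collapse = ""), "</tr>\n",
         paste(cells, collapse = "\n"), "\n</table>")
}

#' Write an evaluation report (JSON + CSV + HTML)
#'
#' Emits three deterministic artifacts into `out_dir`: `summary.json`
#' (RMSD table and self-evaluation fractions), `per_patient.csv` (clinical
#' dose, ensemble recommendation with uncertainty, q-value, outcomes and
#' self-evaluation label per patient), and a static `report.html` rendering
#' the summary tables, the outcome-space reward surface of the disease's
#' goal scheme and, when a cohort is supplied, per-feature population
#' histograms. Re-running with identical inputs reproduces `summary.json`
#' byte for byte.
#'
#' @param summary an [evaluate_cohort()] result.
#' @param out_dir output directory (created if missing).
#' @param cohort optional `rt_cohort` for the population histograms.
#' @return invisible character vector of file paths.
#' @export
write_report <- function(summary, out_dir, cohort = NULL) {
  stopifnot(inherits(summary, "eval_summary"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(out_dir, "summary.json")
  csv_path <- file.path(out_dir, "per_patient.csv")
  html_path <- file.path(out_dir, "report.html")
  payload <- list(disease = summary$disease, n_members = summary$n_members,
                  n_patients = nrow(summary$per_patient),
                  rmsd = summary$rmsd, self_eval = summary$self_eval)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  utils::write.csv(summary$per_patient, csv_path, row.names = FALSE, na = "")

  sections <- c(
    sprintf("<h1>Adaptive-dose decision report: %s</h1>", summary$disease),
    sprintf("<p>%d ensemble members, %d evaluated patients.</p>",
            summary$n_members, nrow(summary$per_patient)),
    "<h2>RMSD vs clinical decisions (Gy/frac)</h2>",
    html_table(summary$rmsd),
    "<h2>Self-evaluation fractions</h2>",
    html_table(do.call(rbind, lapply(names(summary$self_eval), function(s) {
      f <- summary$self_eval[[s]]
      data.frame(stratum = s, Good = f$Good, Bad = f$Bad,
                 NotSure = f$NotSure)
    }))),
    "<h2>Per-patient recommendations</h2>",
    html_table(summary$per_patient))
  if (!is.null(cohort)) {
    M <- cohort_node_matrix(cohort)
    hist_rows <- do.call(rbind, lapply(colnames(M), function(nm) {
      h <- graphics::hist(M[, nm], breaks = 12, plot = FALSE)
      data.frame(feature = nm,
                 bins = paste(formatC(h$mids, digits = 3, format = "g"),
                              collapse = " "),
                 counts = paste(h$counts, collapse = " "))
    }))
    sections <- c(sections, "<h2>Population feature histograms</h2>",
                  html_table(hist_rows))
  }
  writeLines(c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
               sprintf("<title>%s decision report</title></head><body>",
                       summary$disease),
               sections, "</body></html>"), html_path)
  invisible(c(json = json_path, csv = csv_path, html = html_path))
}
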