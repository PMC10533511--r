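# Rendering of analysis reports: clinical-table text formatting (half-up
# one-decimal percentages, two-decimal odds ratios with confidence
# intervals), full-precision JSON, and per-table CSV export.

#' Format an odds ratio with its confidence interval
#'
#' Two decimals, half-up, in the conventional `"OR (low, high)"` layout.
#'
#' @param or,ci_low,ci_high numeric (vectorised).
#' @return character vector, e.g. `"1.42 (1.17, 1.73)"`.
#' @export
format_or_ci <- function(or, ci_low, ci_high) {
  f <- function(x) formatC(round_half_up(x, 2), format = "f", digits = 2)
  ifelse(is.na(or), "-", sprintf("%s (%s, %s)", f(or), f(ci_low), f(ci_high)))
}

#' Format a percentage at one decimal, half-up
#'
#' @param pct numeric percentage (vectorised).
#' @return character vector, e.g. `"9.6"`.
#' @export
format_pct <- function(pct) {
  ifelse(is.na(pct), "-",
    formatC(round_half_up(pct, 1), format = "f", digits = 1)
  )
}

fmt_mean_sd <- function(mean, sd, digits = 1) {
  ifelse(is.na(mean), "-", sprintf(
    paste0("%.", digits, "f ± %.", digits, "f"), mean, sd
  ))
}

#' @export
print.faor_report <- function(x, ...) {
  cat(sprintf(
    "<faor_report: %d records in, %d included%s>\n",
    x$n_input, x$n_included,
    if (!is.null(x$n_biometry)) sprintf(", %d with mid-gestation biometry", x$n_biometry) else ""
  ))
  if (!is.null(x$thresholds)) print(x$thresholds)
  cat("Exclusion log:\n")
  print(as.data.frame(x$exclusion_log), row.names = FALSE)
  invisible(x)
}

#' Render an analysis report
#'
#' Writes the report as plain text (clinical-table formatting), JSON (full
#' precision, deterministic field order) or a directory of CSV files.
#'
#' @param report an `faor_report` from [run_study()].
#' @param format `"text"`, `"json"` or `"csv"`.
#' @param path output file (`text`/`json`) or directory (`csv`).
#' @return `path`, invisibly. For `format = "text"` with `path = NULL`,
#'   the lines are returned visibly instead.
#' @export
render_report <- function(report, format = c("text", "json", "csv"),
                          path = NULL) {
  stopifnot(inherits(report, "faor_report"))
  format <- match.arg(format)
  if (format == "json") {
    if (is.null(path)) abort("`path` is required for JSON output.")
    out <- report_to_list(report)
    jsonlite::write_json(out, path,
      auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
    )
    return(invisible(path))
  }
  if (format == "csv") {
    if (is.null(path)) abort("`path` (a directory) is required for CSV output.")
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) {
      if (!is.null(df)) readr::write_csv(df, file.path(path, paste0(name, ".csv")))
    }
    wr(report$exclusion_log, "exclusion_log")
    wr(report$table1$summary, "table1_summary")
    wr(report$table1$pairwise, "table1_pairwise")
    wr(report$table2$summary, "table2_summary")
    wr(report$table2$pairwise, "table2_pairwise")
    wr(report$table3$cells, "table3_cells")
    wr(report$table3$continuous$summary, "table3_continuous")
    wr(report$table4, "table4_fao_or")
    wr(report$table5, "table5_outcome_or")
    wr(report$table6$continuous, "table6_continuous")
    wr(report$table6$categorical, "table6_categorical")
    return(invisible(path))
  }
  lines <- report_text_lines(report)
  if (is.null(path)) {
    return(lines)
  }
  writeLines(lines, path)
  invisible(path)
}

report_to_list <- function(report) {
  out <- unclass(report)
  for (nm in c("thresholds", "thresholds_near")) {
    if (!is.null(out[[nm]])) out[[nm]] <- unclass(out[[nm]])
  }
  out
}

report_text_lines <- function(report) {
  lines <- c(
    "Cohort analysis report",
    "======================",
    sprintf("Records in: %d; included after exclusions: %d", report$n_input, report$n_included),
    "",
    "Exclusion log:",
    sprintf(
      "  %-24s in %6d  excluded %5d  (%s)",
      report$exclusion_log$stage, report$exclusion_log$n_in,
      report$exclusion_log$n_excluded, report$exclusion_log$reason
    )
  )
  if (is.null(report$table1)) {
    return(c(lines, "", "No included records; tables empty."))
  }
  th <- report$thresholds
  lines <- c(
    lines, "",
    sprintf(
      "FAOR cutoffs (level %.2f): GA-AC/GA-LMP >= %.4f, GA-AC/GA-BPD >= %.4f, GA-AC/GA-FL >= %.4f",
      th$level, th$cut_lmp, th$cut_bpd, th$cut_fl
    ),
    sprintf("Records with mid-gestation biometry: %d", report$n_biometry),
    ""
  )
  sum_block <- function(tab, title) {
    s <- tab$summary
    header <- c(title, strrep("-", nchar(title)))
    body <- vapply(unique(s$variable), function(v) {
      rows <- s[s$variable == v, ]
      cells <- vapply(c("Total", group_levels), function(g) {
        r <- rows[rows$group == g, ]
        fmt_mean_sd(r$mean, r$sd, 2)
      }, character(1))
      sprintf("  %-20s %s", v, paste(sprintf("%18s", cells), collapse = " "))
    }, character(1))
    c(header, sprintf(
      "  %-20s %s", "",
      paste(sprintf("%18s", c("Total", group_levels)), collapse = " ")
    ), body, "")
  }
  lines <- c(
    lines,
    sum_block(report$table1, "Clinical and biochemical characteristics (mean ± sd)"),
    sum_block(report$table2, "Fetal biometry and FAORs (mean ± sd)")
  )
  cells <- report$table3$cells
  lines <- c(lines, "Prevalences (% [k/n])", "---------------------")
  for (v in unique(cells$variable)) {
    rows <- cells[cells$variable == v, ]
    txt <- vapply(c("Total", group_levels), function(g) {
      r <- rows[rows$group == g, ]
      sprintf("%s [%d/%d]", format_pct(r$pct), r$k, r$n)
    }, character(1))
    lines <- c(lines, sprintf("  %-28s %s", v, paste(sprintf("%16s", txt), collapse = " ")))
  }
  or_block <- function(tab, id_col, title) {
    out <- c("", title, strrep("-", nchar(title)))
    for (id in unique(tab[[id_col]])) {
      rows <- tab[tab[[id_col]] == id, ]
      out <- c(out, sprintf("  %s (vs G1; n = %s)", id, rows$n_used[1]))
      out <- c(out, sprintf(
        "    %-4s %s", rows$level,
        format_or_ci(rows$estimate, rows$ci_low, rows$ci_high)
      ))
    }
    out
  }
  lines <- c(
    lines,
    or_block(report$table4, "criterion", "Adjusted odds ratios for FAO by criterion"),
    or_block(report$table5, "outcome", "Adjusted odds ratios for delivery outcomes")
  )
  t6 <- report$table6
  lines <- c(
    lines, "",
    sprintf(
      "FAO-absent (n = %d) vs FAO-present (n = %d), mid-gestation biometry subset",
      t6$n_absent, t6$n_present
    ),
    sprintf(
      "  %-26s %14s %14s %10s", "variable", "FAO (-)", "FAO (+)", "p"
    )
  )
  for (i in seq_len(nrow(t6$continuous))) {
    r <- t6$continuous[i, ]
    lines <- c(lines, sprintf(
      "  %-26s %14s %14s %10.4g", r$variable,
      fmt_mean_sd(r$mean_absent, r$sd_absent, 2),
      fmt_mean_sd(r$mean_present, r$sd_present, 2), r$p_raw
    ))
  }
  for (i in seq_len(nrow(t6$categorical))) {
    r <- t6$categorical[i, ]
    lines <- c(lines, sprintf(
      "  %-26s %14s %14s %10.4g", r$variable,
      format_pct(r$pct_absent), format_pct(r$pct_present), r$p_raw
    ))
  }
  lines
}
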