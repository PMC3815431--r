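#' Write a static HTML adherence report
#'
#' Renders the clinician listing as one self-contained HTML file: per
#' patient, a medication table (name, drug class, first/last fill,
#' current MPR, status glyph) ordered like [assess_patient()], and under
#' it one inline SVG possession plot per medication — gray rectangles
#' for gaps, a blue running-MPR polyline, circles at fill events and a
#' dashed line at the adherence threshold. Each plot's JSON payload (see
#' [export_plot_data()]) is embedded next to it in a
#' `<script type="application/json">` block. The output contains no
#' timestamps or other run-dependent content, so identical inputs yield
#' byte-identical reports.
#'
#' @param assessments Assessment tibble.
#' @param histories Histories tibble from [fulfillment_histories()]
#'   covering the assessed medications.
#' @param path Output HTML path.
#' @param options The [adherence_options()] used for the assessment.
#' @return `path`, invisibly.
#' @export
write_html_report <- function(assessments, histories, path,
                              options = adherence_options()) {
  glyph <- c(RED = "&#9888; RED", YELLOW = "&#9888; YELLOW",
             GREEN = "&#10004; GREEN", NONE = "&#8212;")
  colour <- c(RED = "#c0392b", YELLOW = "#d4a017",
              GREEN = "#1e8449", NONE = "#777777")
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/>",
    "<title>Medication adherence report</title>",
    "<style>",
    "body{font-family:sans-serif;margin:2em;max-width:60em}",
    "table{border-collapse:collapse;margin-bottom:1em}",
    "td,th{border:1px solid #ccc;padding:0.3em 0.8em;text-align:left}",
    "h2{border-bottom:2px solid #444}",
    "</style></head><body>",
    "<h1>Medication adherence report</h1>"
  )
  for (pid in unique(assessments$patient_id)) {
    pa <- assessments[assessments$patient_id == pid, ]
    lines <- c(lines, sprintf("<h2>Patient %s</h2>", esc(pid)),
               "<table><tr><th>Medication</th><th>Drug class</th>",
               "<th>First fill</th><th>Last fill</th><th>Current MPR</th>",
               "<th>Status</th></tr>")
    for (i in seq_len(nrow(pa))) {
      st <- pa$status[i]
      lines <- c(lines, sprintf(
        "<tr><td>%s</td><td>%s</td><td>%s</td><td>%s</td><td>%s</td><td style=\"color:%s\"><b>%s</b></td></tr>",
        esc(pa$medication_name[i]),
        esc(ifelse(is.na(pa$drug_class[i]), "&#8212;", pa$drug_class[i])),
        format(pa$first_fill_date[i]), format(pa$last_fill_date[i]),
        ifelse(is.na(pa$current_mpr[i]), "&#8212;",
               sprintf("%.3f", pa$current_mpr[i])),
        colour[[st]], glyph[[st]]
      ))
    }
    lines <- c(lines, "</table>")
    for (i in seq_len(nrow(pa))) {
      hist_row <- histories[histories$patient_id == pid &
                              histories$medication_id == pa$medication_id[i], ]
      if (nrow(hist_row) == 0L) next
      h <- hist_row$history[[1L]]
      if (h$horizon < 1L) next
      payload <- export_plot_data(h, assessment = pa[i, ], options = options,
                                  series_type = "dense")
      lines <- c(
        lines,
        sprintf("<h3>%s</h3>", esc(pa$medication_name[i])),
        svg_possession_plot(payload),
        sprintf("<script type=\"application/json\" id=\"payload-%s-%s\">",
                esc(pid), esc(pa$medication_id[i])),
        as.character(jsonlite::toJSON(unclass(payload), auto_unbox = TRUE,
                                      digits = 6, na = "null")),
        "</script>"
      )
    }
  }
  lines <- c(lines, "</body></html>")
  writeLines(lines, path)
  invisible(path)
}

# deterministic inline SVG of one possession plot
svg_possession_plot <- function(payload, width = 640, height = 220) {
  margin <- 35
  horizon <- max(payload$meta$horizon, 1L)
  ymax <- max(1.2, payload$series$mpr, na.rm = TRUE)
  sx <- function(d) margin + (width - 2 * margin) * d / horizon
  sy <- function(v) height - margin - (height - 2 * margin) * v / ymax
  parts <- sprintf(
    "<svg width=\"%d\" height=\"%d\" xmlns=\"http://www.w3.org/2000/svg\">",
    width, height)
  parts <- c(parts, sprintf(
    "<rect x=\"%d\" y=\"%d\" width=\"%d\" height=\"%d\" fill=\"none\" stroke=\"#999\"/>",
    margin, margin, width - 2 * margin, height - 2 * margin))
  g <- payload$gaps
  for (j in seq_len(nrow(g))) {
    parts <- c(parts, sprintf(
      "<rect x=\"%.2f\" y=\"%d\" width=\"%.2f\" height=\"%d\" fill=\"#aaaaaa\" fill-opacity=\"%s\"/>",
      sx(g$start[j]), margin, sx(g$end[j]) - sx(g$start[j]),
      height - 2 * margin, if (g$alert[j]) "0.55" else "0.30"))
  }
  thr_y <- sy(payload$threshold)
  parts <- c(parts, sprintf(
    "<line x1=\"%d\" y1=\"%.2f\" x2=\"%d\" y2=\"%.2f\" stroke=\"#c0392b\" stroke-dasharray=\"5,4\"/>",
    margin, thr_y, width - margin, thr_y))
  s <- payload$series
  if (nrow(s) > 0L) {
    pts <- paste(sprintf("%.2f,%.2f", sx(s$day), sy(pmin(s$mpr, ymax))),
                 collapse = " ")
    parts <- c(parts, sprintf(
      "<polyline points=\"%s\" fill=\"none\" stroke=\"#1f77e0\" stroke-width=\"1.5\"/>",
      pts))
  }
  f <- payload$fills
  for (j in seq_len(nrow(f))) {
    parts <- c(parts, sprintf(
      "<circle cx=\"%.2f\" cy=\"%.2f\" r=\"3.5\" fill=\"white\" stroke=\"#1f77e0\"/>",
      sx(f$day[j]), sy(pmin(f$mpr[j], ymax))))
  }
  parts <- c(parts,
             sprintf("<text x=\"%d\" y=\"%d\" font-size=\"11\">day 0</text>",
                     margin, height - margin + 15),
             sprintf("<text x=\"%d\" y=\"%d\" font-size=\"11\" text-anchor=\"end\">day %d</text>",
                     width - margin, height - margin + 15, horizon),
             sprintf("<text x=\"%d\" y=\"%.2f\" font-size=\"11\" text-anchor=\"end\">%.1f</text>",
                     margin - 4, thr_y + 4, payload$threshold),
             "</svg>")
  paste(parts, collapse = "\n")
}
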