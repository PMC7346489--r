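#' Write a candidate report
#'
#' One row per (candidate gene, evidence item), in the flattened layout of
#' [as.data.frame.candidate_screen()]. The TSV form is lossless — numeric
#' columns are written at full double precision and [read_candidate_report()]
#' restores an identical `data.frame`. The markdown form is a human-readable
#' rendering (distances as rounded cM / formatted bp labels) and does not
#' round-trip.
#'
#' @param candidates A `candidate_screen` or an already-flattened
#'   `data.frame` in the same layout.
#' @param path Output path.
#' @param format `"tsv"` or `"markdown"`.
#' @return Invisibly, `path`.
#' @export
write_candidate_report <- function(candidates, path,
                                   format = c("tsv", "markdown")) {
  format <- match.arg(format)
  df <- if (inherits(candidates, "candidate_screen")) {
    as.data.frame(candidates)
  } else {
    candidates
  }
  if (format == "tsv") {
    out <- df
    for (col in c("distance_cm", "peak_cm", "ci_lo_cm", "ci_hi_cm",
                  "distance_bp", "pos_bp", "p_min", "p_max")) {
      out[[col]] <- num2str(out[[col]])
    }
    out$within_ci <- ifelse(is.na(df$within_ci), "NA",
                            ifelse(df$within_ci, "TRUE", "FALSE"))
    write_tsv_raw(out, path)
  } else {
    dist <- ifelse(df$evidence_type == "QTL",
                   paste0(formatC(round_half_away(df$distance_cm, 1),
                                  format = "f", digits = 1), " cM"),
                   df$distance_label)
    md <- data.frame(gene = df$gene, DEG = df$deg_evidence,
                     evidence = df$evidence_type, id = df$evidence_id,
                     trait = df$evidence_trait, distance = dist,
                     stringsAsFactors = FALSE)
    header <- paste0("| ", paste(names(md), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(md)), collapse = "|"), "|")
    body <- apply(md, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    writeLines(c(header, sep, body), path)
  }
  invisible(path)
}

#' Read back a TSV candidate report
#'
#' Inverse of [write_candidate_report()] with `format = "tsv"`.
#'
#' @param path Path to the TSV report.
#' @return The flattened evidence `data.frame`.
#' @export
read_candidate_report <- function(path) {
  raw <- read_tsv_raw(path)
  require_columns(raw, c("gene", "deg_evidence", "traits", "evidence_type",
                         "evidence_id", "evidence_trait", "distance_cm",
                         "within_ci", "peak_cm", "ci_lo_cm", "ci_hi_cm",
                         "distance_bp", "distance_label", "pos_bp",
                         "p_min", "p_max"), "candidate report")
  lines <- seq_len(nrow(raw)) + 1L
  df <- raw
  for (col in c("distance_cm", "peak_cm", "ci_lo_cm", "ci_hi_cm",
                "distance_bp", "pos_bp", "p_min", "p_max")) {
    df[[col]] <- parse_num(raw[[col]], col, lines)
  }
  df$within_ci <- ifelse(is.na(raw$within_ci) | raw$within_ci == "NA", NA,
                         raw$within_ci == "TRUE")
  df$distance_label[!is.na(df$distance_label) &
                      df$distance_label == "NA"] <- NA_character_
  df
}
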