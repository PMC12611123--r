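#' Write a panel to long-format CSV
#'
#' One row per site-month; columns `site_id, date, altitude_m, temp_c,
#' precip_mm, soil_moisture, fvc, irrigation_pct, planting_density,
#' survival_pct`.  Missing cells are written as empty fields.  Values are
#' written with full double precision (17 significant digits) so a
#' write/read round trip is lossless.
#'
#' @param panel A `vegr_panel`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  rows <- do.call(rbind, lapply(panel, function(s) {
    s[, PANEL_COLUMNS]
  }))
  num <- vapply(rows, is.numeric, TRUE)
  for (v in names(rows)[num]) rows[[v]] <- sprintf_num(rows[[v]])
  write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

sprintf_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

#' Read a long-format panel CSV
#'
#' Validates the schema of [write_panel_csv()] and rebuilds the per-site
#' `vegr_panel` structure; empty cells become `NA` (missing).
#'
#' @param path CSV path.
#' @return A `vegr_panel`.
#' @export
read_panel_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(site_id = "character", date = "character"))
  missing_cols <- setdiff(PANEL_COLUMNS, names(df))
  if (length(missing_cols))
    stop("panel CSV is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  sites <- split(df, df$site_id)
  panel <- lapply(sites, function(s) {
    s <- s[order(s$date), ]
    if (anyDuplicated(s$date))
      stop(sprintf("site %s has duplicated months", s$site_id[1]))
    s$month_index <- seq_len(nrow(s)) - 1L
    rownames(s) <- NULL
    structure(s, class = c("site_series", "data.frame"))
  })
  structure(panel, class = "vegr_panel")
}
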