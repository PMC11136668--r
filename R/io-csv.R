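## Affinity metadata CSV I/O. Columns: entry_id, affinity_value (nM),
## affinity_type (Ki/Kd/IC50, case-insensitive), protein_group,
## publication_id, has_site_cofactor_or_metal.

#' Read an affinity metadata table from CSV
#'
#' One record per row; the affinity type is normalized case-insensitively.
#' Missing `publication_id` / cofactor columns are filled with `NA` / `FALSE`.
#'
#' @param path CSV file with a header row.
#' @return an [affinity_table()].
#' @export
read_affinity_table <- function(path) {
  if (!file.exists(path))
    stop_ligdyn("format", "affinity table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("entry_id", "affinity_value", "affinity_type", "protein_group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_ligdyn("format", "affinity table %s lacks column(s): %s",
                path, paste(miss, collapse = ", "))
  if (is.null(df$publication_id)) df$publication_id <- NA_character_
  if (is.null(df$has_site_cofactor_or_metal))
    df$has_site_cofactor_or_metal <- FALSE
  affinity_table(df$entry_id, df$affinity_value, df$affinity_type,
                 df$protein_group, df$publication_id,
                 as.logical(df$has_site_cofactor_or_metal))
}

#' Write an affinity metadata table to CSV
#'
#' @param table an [affinity_table()].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_affinity_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
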