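# Delimited-text readers and writers. All outputs are plain text with a
# header row; lines starting with '#' carry run metadata (e.g. the seed) and
# are skipped on read. Comma is the default delimiter; tab is accepted.

write_delim_table <- function(df, path, sep = ",", header_lines = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header_lines))
    writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}

read_delim_table <- function(path, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(path, n = 20L)
    first <- first[!startsWith(first, "#")][1]
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read the ZCTA covariate table
#'
#' @param zctas ZCTA data.frame.
#' @param path file path.
#' @param sep field delimiter, `","` (default) or `"\t"`; on read the
#'   delimiter is sniffed when not given.
#' @param seed optional seed recorded in the file header.
#' @return the path (write) or the data.frame (read).
#' @export
write_zcta_table <- function(zctas, path, sep = ",", seed = NULL) {
  hdr <- c("zcta covariate table",
           if (!is.null(seed)) sprintf("seed=%d", seed))
  write_delim_table(zctas, path, sep, hdr)
}

#' @rdname write_zcta_table
#' @export
read_zcta_table <- function(path, sep = NULL) {
  df <- read_delim_table(path, sep)
  need <- c("zcta_id", "pop_year1", "pop_year2")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_input("read_zcta_table: missing column(s): %s",
               paste(missing, collapse = ", "))
  df$zcta_id <- as.character(df$zcta_id)
  df
}

#' Write / read the episode-level encounter table
#'
#' @param visits encounter data.frame.
#' @inheritParams write_zcta_table
#' @return the path (write) or the data.frame (read).
#' @export
write_visit_table <- function(visits, path, sep = ",", seed = NULL) {
  hdr <- c("ED encounter table",
           if (!is.null(seed)) sprintf("seed=%d", seed))
  write_delim_table(visits, path, sep, hdr)
}

#' @rdname write_visit_table
#' @export
read_visit_table <- function(path, sep = NULL) {
  df <- read_delim_table(path, sep)
  need <- c("encounter_id", "zcta_id", "age", "payer", "condition", "year")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_input("read_visit_table: missing column(s): %s",
               paste(missing, collapse = ", "))
  df$zcta_id <- as.character(df$zcta_id)
  df
}

#' Write / read the generator ground-truth sidecar
#'
#' Plain YAML key-value file holding the latent quintiles, the effect
#' specification and the planted counts.
#'
#' @param truth a `ground_truth`.
#' @param path file path.
#' @return the path (write) or a `ground_truth` (read).
#' @export
write_ground_truth <- function(truth, path) {
  obj <- list(
    latent_quintile = as.list(truth$latent_quintile),
    quintile_sizes = as.integer(truth$quintile_sizes),
    effect_spec = as.list(truth$effect_spec),
    qualifying_count = truth$qualifying_count,
    noise_count = truth$noise_count
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  obj <- yaml::read_yaml(path)
  es <- as.data.frame(obj$effect_spec, stringsAsFactors = FALSE)
  structure(
    list(latent_quintile = unlist(obj$latent_quintile),
         quintile_sizes = as.integer(obj$quintile_sizes),
         effect_spec = es, covariate_slopes = NULL,
         expected_rates = NULL, planted_counts = NULL,
         qualifying_count = obj$qualifying_count,
         noise_count = obj$noise_count),
    class = "ground_truth"
  )
}
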