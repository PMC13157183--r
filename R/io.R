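#' @title Plain-text readers and writers
#' @description Long-format lane TSVs, cohort metadata CSVs, gene x sample
#'   count TSVs with sample metadata, and Ct CSVs -- the interchange formats
#'   of the analysis scripts.
#' @name eposwitch_io
NULL

#' @rdname eposwitch_io
#' @param lanes long `LaneProfile` table (`lane_id`, `lane_kind`, `position`,
#'   `intensity`).
#' @param path file path.
#' @export
write_lanes <- function(lanes, path) {
  utils::write.table(lanes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname eposwitch_io
#' @export
read_lanes <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname eposwitch_io
#' @param records cohort records data frame.
#' @export
write_cohort <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname eposwitch_io
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname eposwitch_io
#' @param counts gene x sample matrix; written with a leading `gene` column.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname eposwitch_io
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  m
}
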