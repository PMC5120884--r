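#' Assemble a deterministic consolidated analysis report
#'
#' Collects stage outputs (motility metrics, transition-rate tables, epoch
#' run statistics, enrichment summaries, group comparisons ...) into a
#' single named list with fixed ordering, embedded configuration/seed
#' metadata and the package version, and optionally writes it as JSON.
#' Identical inputs always produce byte-identical JSON; empty optional
#' sections are omitted.
#'
#' @param sections Named list of stage outputs; every element must be
#'   non-NULL to be included.
#' @param config Optional named list of configuration values/seeds to
#'   embed.
#' @param path Optional path; when given, the report is written as
#'   pretty-printed JSON.
#' @return The report list (invisibly when `path` is given).
#' @export
build_report <- function(sections, config = NULL, path = NULL) {
  if (!is.list(sections) || is.null(names(sections)) ||
      any(names(sections) == ""))
    stopf("sections must be a fully named list")
  sections <- sections[order(names(sections))]
  sections <- sections[!vapply(sections, is.null, logical(1))]
  empty <- vapply(sections, function(s) length(s) == 0L, logical(1))
  sections <- sections[!empty]
  report <- list(
    tool = "wormstate",
    version = as.character(utils::packageVersion("wormstate")),
    config = config,
    sections = sections
  )
  if (is.null(config)) report$config <- NULL
  if (!is.null(path)) {
    json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE, na = "null", force = TRUE)
    writeLines(json, path)
    return(invisible(report))
  }
  report
}

#' Write / read a gene x sample count matrix with metadata as TSV
#'
#' The counts file is genes (rows, first column `gene`) by samples; the
#' metadata file has columns `sample`, `genotype`, `fraction`,
#' `replicate`.
#'
#' @param design A list with `counts` and `meta` (see [simulate_counts()]).
#' @param counts_path,meta_path Output TSV paths.
#' @return `write_counts_tsv` returns the paths invisibly;
#'   `read_counts_tsv` returns a `list(counts, meta)`.
#' @export
write_counts_tsv <- function(design, counts_path, meta_path) {
  df <- data.frame(gene = rownames(design$counts), design$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(design$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts = counts_path, meta = meta_path))
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(counts_path, meta_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  storage.mode(counts) <- "integer"
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  need <- c("sample", "genotype", "fraction", "replicate")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stopf("metadata missing: %s", paste(miss, collapse = ", "))
  if (!all(colnames(counts) == meta$sample))
    stopf("count columns and metadata samples disagree")
  list(counts = counts, meta = meta)
}
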