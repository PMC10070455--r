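# Readers/writers for the small plain-text genomics formats the pipeline
# exchanges: BED / BED6 / bedGraph (via rtracklayer) and GMT gene sets.
# All interval tables in this package are 0-based half-open (BED convention).

.gr_to_bed_df <- function(gr, extra = NULL) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  if (!is.null(extra)) df <- cbind(df, extra)
  df
}

#' Read a BED / BED6 file
#'
#' @param path File path (headerless BED; 3-6 columns).
#' @return Data.frame with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand` (0-based half-open coordinates).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  extra <- NULL
  md <- S4Vectors::mcols(gr)
  if ("name" %in% colnames(md)) extra <- data.frame(name = md$name)
  if ("score" %in% colnames(md))
    extra <- cbind(extra, data.frame(score = md$score))
  df <- .gr_to_bed_df(gr, extra)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand != "*")) df$strand <- strand
  df
}

#' Write a BED / BED6 file
#'
#' Writes `chrom`, `start`, `end` plus `name`, `score`, `strand` when the
#' input has them. An empty table yields a valid empty (header-less) file.
#'
#' @param df Data.frame with at least `chrom`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  if (nrow(df) == 0) {
    file.create(path)
    return(invisible(path))
  }
  gr <- .df_to_gr(df)
  if (!is.null(df$name)) gr$name <- df$name
  if (!is.null(df$score)) gr$score <- df$score
  if (!is.null(df$strand)) GenomicRanges::strand(gr) <- df$strand
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a bedGraph track
#'
#' @param path File path.
#' @return Data.frame `chrom`, `start`, `end`, `value` (0-based half-open).
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  .gr_to_bed_df(gr, data.frame(value = gr$score))
}

#' Write a bedGraph track
#'
#' @param df Data.frame `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(df, path) {
  if (nrow(df) == 0) {
    file.create(path)
    return(invisible(path))
  }
  gr <- .df_to_gr(df)
  gr$score <- df$value
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: `name <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#'
#' @param path File path.
#' @return Named list of character vectors of gene identifiers.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) .fail("malformed GMT line: %s", substr(l, 1, 40))
    unique(parts[-c(1, 2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}
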