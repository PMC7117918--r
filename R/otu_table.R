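#' Construct an OTU count table
#'
#' The universal currency of the package: an integer matrix of sequence
#' counts with taxa (OTUs) as rows and samples as columns. The constructor
#' validates the invariants every downstream stage relies on: unique taxon
#' and sample IDs, non-negative integral counts, and at least one taxon and
#' one sample.
#'
#' @param counts numeric matrix (or data frame) of non-negative integer
#'   counts with taxon row names and sample column names.
#' @return an `otu_table`: a numeric matrix with class `"otu_table"`.
#' @export
#' @examples
#' m <- matrix(c(5, 0, 2, 8, 0, 1), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("OTU_1", "OTU_2", "OTU_3"), c("S1", "S2")))
#' otu_table(m)
otu_table <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix")
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("an OTU table needs at least one taxon and one sample")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must carry taxon row names and sample column names")
  dup <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup))
    stop("duplicate taxon ID: ", paste(dup, collapse = ", "))
  dup <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup))
    stop("duplicate sample ID: ", paste(dup, collapse = ", "))
  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) stop("counts must be non-negative")
  off <- abs(counts - round(counts)) > 1e-8
  if (any(off)) {
    i <- which(off, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer count at taxon '%s', sample '%s'",
                 rownames(counts)[i[1L]], colnames(counts)[i[2L]]))
  }
  counts <- round(counts)
  storage.mode(counts) <- "double"  # large pooled totals can exceed int range
  structure(counts, class = c("otu_table", "matrix", "array"))
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d taxa x %d samples, %s reads total\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  invisible(x)
}

# strip the otu_table class for plain-matrix arithmetic
count_matrix <- function(x) {
  class(x) <- c("matrix", "array")
  x
}

#' Read an OTU table from TSV or BIOM v1 JSON
#'
#' The TSV dialect is the QIIME-era flat table: tab-separated, header row of
#' sample IDs with first cell `#OTU_ID`, no quoting. BIOM support targets
#' the JSON (v1) dialect, sparse or dense, via the biomformat package.
#'
#' @param path file path.
#' @param orientation `"taxa_rows"` (default) or `"samples_rows"` for TSV
#'   input; BIOM files carry their own orientation and ignore this.
#' @param format `"auto"` (by file extension), `"tsv"`, or `"biom"`.
#' @return an [otu_table()] in taxa-rows orientation.
#' @export
read_otu_table <- function(path,
                           orientation = c("taxa_rows", "samples_rows"),
                           format = c("auto", "tsv", "biom")) {
  orientation <- match.arg(orientation)
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(biom|json)$", path, ignore.case = TRUE))
      "biom" else "tsv"
  if (format == "biom") {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(otu_table(m))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("expected an ID column plus at least one data column")
  ids <- df[[1L]]
  raw <- as.matrix(df[, -1L, drop = FALSE])
  m <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                               dimnames = list(ids, colnames(raw))))
  bad <- which(is.na(m) & !is.na(raw), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                 raw[bad[1L, 1L], bad[1L, 2L]],
                 ids[bad[1L, 1L]], colnames(raw)[bad[1L, 2L]]))
  }
  if (orientation == "samples_rows") m <- t(m)
  # distinguish duplicate-ID errors by axis before generic validation
  if (anyDuplicated(rownames(m)))
    stop("duplicate taxon ID: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  otu_table(m)
}

#' Write an OTU table to TSV or BIOM v1 JSON
#'
#' @param x an [otu_table()].
#' @param path output path; `.biom`/`.json` extensions select BIOM unless
#'   `format` overrides.
#' @param format `"auto"`, `"tsv"`, or `"biom"`.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path, format = c("auto", "tsv", "biom")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(biom|json)$", path, ignore.case = TRUE))
      "biom" else "tsv"
  if (format == "biom") {
    b <- biomformat::make_biom(count_matrix(x))
    biomformat::write_biom(b, path)
    return(invisible(path))
  }
  df <- data.frame("#OTU_ID" = rownames(x), count_matrix(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Discard samples below a sequencing-depth threshold
#'
#' Mirrors the standard post-filtration depth cut: samples whose total read
#' count is strictly below `min_total` are dropped (a sample with exactly
#' `min_total` reads is kept).
#'
#' @param x an [otu_table()].
#' @param min_total minimum column total to keep; default 8000 reads.
#' @param drop_empty_taxa drop taxa whose counts become all-zero? Default
#'   `FALSE`: denominators downstream are easier to reason about when the
#'   taxon set is stable.
#' @return filtered [otu_table()]; a message reports how many samples were
#'   removed.
#' @export
filter_min_reads <- function(x, min_total = 8000, drop_empty_taxa = FALSE) {
  stopifnot(inherits(x, "otu_table"), min_total >= 0)
  totals <- colSums(x)
  keep <- totals >= min_total
  if (!any(keep))
    stop("no samples survive depth filter (min_total = ", min_total, ")")
  if (any(!keep))
    message(sum(!keep), " sample(s) below ", min_total, " reads removed: ",
            paste(colnames(x)[!keep], collapse = ", "))
  m <- count_matrix(x)[, keep, drop = FALSE]
  if (drop_empty_taxa) m <- m[rowSums(m) > 0, , drop = FALSE]
  otu_table(m)
}

#' Convert counts to per-sample relative abundances
#'
#' @param x an [otu_table()] whose columns all have positive totals.
#' @return numeric matrix of the same shape; every column sums to 1.
#' @export
to_relative_abundance <- function(x) {
  totals <- colSums(x)
  zero <- totals == 0
  if (any(zero))
    stop("zero-total sample(s): ", paste(colnames(x)[zero], collapse = ", "))
  sweep(count_matrix(x), 2L, totals, "/")
}

#' Read a sample metadata table
#'
#' Tab-separated, header row, with at least `sample_id` and `group` columns.
#'
#' @param path file path.
#' @param groups optional character vocabulary; group labels outside it are
#'   an error.
#' @return data frame with character columns.
#' @export
read_sample_metadata <- function(path, groups = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (!is.null(groups)) {
    bad <- setdiff(unique(df$group), groups)
    if (length(bad))
      stop("group label(s) outside declared vocabulary: ",
           paste(bad, collapse = ", "))
  }
  df
}
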