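# Plain-text interchange formats: counts / metadata TSV, gene lists, GMT.
# All tables are tab-separated; lines starting with '#' are parameter
# comments written by the pipeline and skipped on read.

#' Read a gene-by-sample count matrix from TSV
#'
#' Expects a header row with `gene_id` as the first column and sample
#' identifiers as the remaining columns.
#'
#' @param path path to a TSV file.
#' @return Integer matrix with gene row names and sample column names.
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, comment.char = "#")
  if (names(df)[1] != "gene_id") {
    stop("counts file ", path, " must have first column 'gene_id'")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  m
}

#' Write a count matrix to TSV
#' @param counts gene-by-sample matrix.
#' @param path output path.
#' @param comments optional character vector written as leading `#` lines.
#' @export
write_counts <- function(counts, path, comments = NULL) {
  write_tsv(data.frame(gene_id = rownames(counts), counts,
                       check.names = FALSE), path, comments)
}

#' Read sample metadata (sample_id, condition, tissue) from TSV
#' @param path path to a TSV file.
#' @return data.frame with columns `sample_id`, `condition`, `tissue`.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, check.names = FALSE, comment.char = "#",
                   colClasses = "character")
  need <- c("sample_id", "condition", "tissue")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("metadata file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  bad <- setdiff(unique(df$condition), c("case", "control"))
  if (length(bad)) {
    stop("metadata condition must be 'case' or 'control'; found: ",
         paste(bad, collapse = ", "))
  }
  df
}

#' Read a one-symbol-per-line gene list
#' @param path path to a plain-text file.
#' @return Character vector of unique, non-empty symbols.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Write a gene list, one symbol per line
#' @param genes character vector.
#' @param path output path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. The description field is
#' used by the pipeline to carry the regulator type (TF/miRNA/lncRNA) for
#' regulator-target collections.
#'
#' @param path path to a GMT file.
#' @return Named list of character vectors, with a `description` attribute
#'   (named character vector) alongside.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop("malformed GMT line ", i, " in ", path,
           ": expected at least 3 tab-separated fields, found ", length(f))
    }
    sets[[f[1]]] <- unique(f[-(1:2)])
    desc[[f[1]]] <- f[2]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named character vector of set descriptions
#'   (defaults to the set name).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(!is.null(names(sets)), all(nzchar(names(sets))))
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions)) {
      descriptions[[nm]]
    } else nm
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

# Write a data.frame as TSV with optional '#' comment header.
write_tsv <- function(df, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, check.names = FALSE, comment.char = "#")
}
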