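#' Read a gene-by-sample expression matrix
#'
#' Reads a tab-separated expression matrix (first column gene identifiers,
#' header row sample identifiers) or a GCT v1.2 file into a numeric matrix
#' with genes in rows and samples in columns.
#'
#' Duplicate gene identifiers are collapsed by keeping, for each identifier,
#' the row with the highest mean expression (the usual microarray probe
#' convention); a message reports how many rows were dropped.
#'
#' @param path Path to the file.
#' @param format Either `"tsv"` (default) or `"gct"`.
#' @return Numeric matrix (genes x samples) with unique `rownames` and
#'   `colnames` and attribute `value_scale = "raw"`.
#' @export
read_expression <- function(path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "gct") {
    lines <- readLines(path)
    if (length(lines) < 3L || !startsWith(lines[1L], "#1.2"))
      stop("malformed GCT header: expected '#1.2' version line")
    dims <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
    if (length(dims) < 2L) stop("malformed GCT header: missing dimension line")
    nr <- suppressWarnings(as.integer(dims[1L]))
    nc <- suppressWarnings(as.integer(dims[2L]))
    if (is.na(nr) || is.na(nc)) stop("malformed GCT header: non-integer dimensions")
    body <- utils::read.delim(textConnection(lines[-(1:2)]),
                              check.names = FALSE, stringsAsFactors = FALSE)
    if (nrow(body) != nr)
      stop("GCT format error: declared ", nr, " rows but found ", nrow(body))
    if (ncol(body) - 2L != nc)
      stop("GCT format error: declared ", nc, " samples but found ", ncol(body) - 2L)
    ids <- as.character(body[[1L]])
    vals <- body[, -(1:2), drop = FALSE]
  } else {
    body <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(body) < 2L) stop("malformed TSV: need a gene-id column and >=1 sample")
    ids <- as.character(body[[1L]])
    vals <- body[, -1L, drop = FALSE]
  }
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "NA")
      if (length(bad))
        stop("parse error: non-numeric value at row ", bad[1L],
             ", column '", names(vals)[j], "'")
      v <- num
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (anyDuplicated(ids)) {
    keep <- collapse_duplicate_rows(m)
    message("collapsed ", nrow(m) - length(keep),
            " duplicate gene rows (kept max-mean row per gene)")
    m <- m[keep, , drop = FALSE]
  }
  if (anyDuplicated(colnames(m))) stop("duplicate sample identifiers")
  attr(m, "value_scale") <- "raw"
  m
}

# indices of rows to keep: for each duplicated id, the row with highest mean;
# original file order preserved
collapse_duplicate_rows <- function(m) {
  means <- rowMeans(m, na.rm = TRUE)
  ord <- order(-means) # stable, so first occurrence wins exact ties
  keep <- ord[!duplicated(rownames(m)[ord])]
  sort(keep)
}

#' Write an expression matrix
#'
#' Writes a gene-by-sample matrix as TSV (first column `gene_id`, one column
#' per sample). `read_expression()` on the result reproduces identifiers
#' exactly and values to full double precision.
#'
#' @param m Numeric matrix with rownames (genes) and colnames (samples).
#' @param path Output path.
#' @export
write_expression <- function(m, path) {
  if (is.null(dim(m)) || nrow(m) == 0L || ncol(m) == 0L)
    stop("cannot write an empty expression matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("matrix must carry gene rownames and sample colnames")
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then tab-separated gene symbols.
#' Duplicate genes within a line are removed with a warning.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors; each element carries a
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT format error at line ", i, ": fewer than 3 fields")
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("duplicate genes in set '", f[1L], "' deduplicated")
      genes <- unique(genes)
    }
    s <- genes
    attr(s, "description") <- f[2L]
    sets[[f[1L]]] <- s
  }
  if (anyDuplicated(names(sets))) stop("duplicate set names in collection")
  sets
}

#' Write a GMT gene-set collection
#'
#' @param collection Named list of character vectors (optionally carrying a
#'   `description` attribute each).
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  if (is.null(names(collection)) || any(!nzchar(names(collection))))
    stop("all gene sets must be named")
  lines <- vapply(names(collection), function(nm) {
    s <- collection[[nm]]
    desc <- attr(s, "description")
    if (is.null(desc)) desc <- nm
    paste(c(nm, desc, as.character(s)), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical annotation table
#'
#' TSV with required columns `sample_id`, `os_time`, `os_event`; any further
#' columns are kept as covariates. Rows with missing survival time or event
#' are dropped (samples without prognostic information are excluded, never
#' imputed) and the drop count is reported.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with unique `sample_id`, non-negative `os_time`,
#'   binary `os_event`, and an attribute `n_dropped`.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("sample_id", "os_time", "os_event")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("clinical schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  df$os_time <- suppressWarnings(as.numeric(df$os_time))
  df$os_event <- suppressWarnings(as.numeric(df$os_event))
  drop <- is.na(df$os_time) | is.na(df$os_event)
  n_dropped <- sum(drop)
  if (n_dropped) {
    message("dropped ", n_dropped, " samples without prognostic information")
    df <- df[!drop, , drop = FALSE]
  }
  if (any(df$os_time < 0)) stop("clinical schema error: negative os_time")
  if (!all(df$os_event %in% c(0, 1)))
    stop("clinical schema error: os_event must be 0/1")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in clinical table")
  rownames(df) <- NULL
  attr(df, "n_dropped") <- n_dropped
  df
}
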