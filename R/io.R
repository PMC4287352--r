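## File formats
##
## Matrices travel as tab-delimited text: first column = feature id, header
## row = sample ids, '#' comment lines carry tool version and parameters.
## Annotation is BED-like: 0-based half-open intervals on disk, converted to
## 1-based positions internally (probe position = start + 1 of a width-1
## interval).  Missing phenotype values are encoded as "NA".

io_header <- function(what, extra = NULL) {
  c(sprintf("# methcausal %s; %s", as.character(packageVersion("methcausal")), what),
    if (!is.null(extra)) paste0("# ", extra))
}

#' Read / write a feature-by-sample matrix
#'
#' Tab-delimited text with the feature id in the first column and sample ids
#' in the header row.  Comment lines start with `#`; `write_matrix` records
#' the modality and per-sample group labels there and `read_matrix` restores
#' them.  Duplicated ids, non-numeric cells, short rows and (for
#' methylation) beta values outside \[0, 1\] are rejected with the offending
#' location named.
#'
#' @param path file path.
#' @param modality `"expression"` or `"methylation-beta"`; when reading, the
#'   value stored in the file header (if any) takes precedence.
#' @param group optional per-sample group labels (see [omics_matrix()]).
#' @return `read_matrix` returns an [omics_matrix()]; `write_matrix`
#'   invisibly returns `path`.
#' @export
read_matrix <- function(path, modality = c("expression", "methylation-beta"),
                        group = NULL) {
  modality <- match.arg(modality)
  hdr <- read_comment_header(path)
  if (!is.null(hdr$modality)) modality <- hdr$modality
  if (is.null(group) && !is.null(hdr$group)) group <- hdr$group
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = NA, fill = FALSE)
  if (ncol(df) < 2L) stop("matrix file needs a feature column and >=1 sample")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate feature id: ", ids[duplicated(ids)][1L])
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !vals[[j]] %in% c("NA", ""))
    if (length(bad) > 0L)
      stop(sprintf("non-numeric cell at feature '%s', sample '%s'",
                   ids[bad[1L]], colnames(vals)[j]))
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  omics_matrix(m, modality, group = group)
}

#' @rdname read_matrix
#' @param x an [omics_matrix()] to write.
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "omics_matrix"))
  hdr <- io_header(sprintf("modality=%s", x$modality),
                   if (!is.null(x$group))
                     sprintf("group=%s", paste(x$group, collapse = ",")))
  writeLines(hdr, path)
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

read_comment_header <- function(path) {
  out <- list()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L || !startsWith(ln, "#")) break
    if (grepl("modality=", ln))
      out$modality <- sub(".*modality=([^;[:space:]]+).*", "\\1", ln)
    if (grepl("group=", ln))
      out$group <- strsplit(sub(".*group=", "", ln), ",")[[1L]]
  }
  out
}

#' Read / write probe annotation (BED-like)
#'
#' Probe files hold five tab-separated columns: chromosome, start, end
#' (0-based half-open), probe name, CpG-island flag (0/1).  Positions are
#' converted to 1-based internally: a width-1 interval `[99, 100)` becomes
#' position 100.  An empty file yields an empty annotation.
#'
#' @param path file path.
#' @return A data frame with columns `probe_id`, `chromosome`, `position`
#'   (1-based), `cpg_island` (logical), plus empty `gene_id` /
#'   `tss_distance` columns filled by [map_probes()].
#' @export
read_probe_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  empty <- data.frame(probe_id = character(0), chromosome = character(0),
                      position = integer(0), cpg_island = logical(0),
                      gene_id = character(0), tss_distance = integer(0),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 5L))
    stop("malformed probe BED line ", which(nf != 5L)[1L], ": expected 5 fields")
  m <- do.call(rbind, parts)
  start <- suppressWarnings(as.integer(m[, 2L]))
  flag <- m[, 5L]
  if (any(is.na(start)))
    stop("malformed probe BED line ", which(is.na(start))[1L],
         ": non-integer start")
  if (!all(flag %in% c("0", "1")))
    stop("malformed probe BED line ", which(!flag %in% c("0", "1"))[1L],
         ": island flag must be 0 or 1")
  data.frame(probe_id = m[, 4L], chromosome = m[, 1L],
             position = start + 1L, cpg_island = flag == "1",
             gene_id = NA_character_, tss_distance = NA_integer_,
             stringsAsFactors = FALSE)
}

#' @rdname read_probe_bed
#' @param probes a probe annotation data frame (1-based positions).
#' @export
write_probe_bed <- function(probes, path) {
  hdr <- io_header("probe annotation; coordinates 0-based half-open (BED)")
  writeLines(hdr, path)
  df <- data.frame(probes$chromosome, probes$position - 1L, probes$position,
                   probes$probe_id, as.integer(probes$cpg_island))
  suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = FALSE,
                               append = TRUE))
  invisible(path)
}

#' Read / write gene annotation
#'
#' Tab-delimited columns: gene id, chromosome, TSS (1-based), strand.
#'
#' @param path file path.
#' @return A data frame with columns `gene_id`, `chromosome`, `tss`,
#'   `strand`.
#' @export
read_gene_table <- function(path) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE, fill = FALSE)
  need <- c("gene_id", "chromosome", "tss", "strand")
  if (!all(need %in% colnames(df)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id: ", df$gene_id[duplicated(df$gene_id)][1L])
  if (!all(df$strand %in% c("+", "-")))
    stop("malformed gene table line ",
         which(!df$strand %in% c("+", "-"))[1L], ": strand must be + or -")
  df
}

#' @rdname read_gene_table
#' @param genes gene annotation data frame.
#' @export
write_gene_table <- function(genes, path) {
  writeLines(io_header("gene annotation; tss 1-based"), path)
  suppressWarnings(write.table(genes, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Read / write sample tables (covariates, phenotypes)
#'
#' Tab-delimited with a `sample_id` column; phenotype tables may contain
#' `NA` for unmeasured traits.
#'
#' @param path file path.
#' @return A data frame with a `sample_id` column.
#' @export
read_sample_table <- function(path) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE, fill = FALSE)
  if (!"sample_id" %in% colnames(df))
    stop("sample table must have a 'sample_id' column")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ", df$sample_id[duplicated(df$sample_id)][1L])
  df
}

#' @rdname read_sample_table
#' @param df data frame with a `sample_id` column.
#' @export
write_sample_table <- function(df, path) {
  writeLines(io_header("sample table; missing values as NA"), path)
  suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path file path.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0L)
    stop("malformed GMT line ", bad[1L], ": need name, description, >=1 gene")
  setNames(lapply(parts, function(p) unique(p[-(1:2)])),
           vapply(parts, `[[`, "", 1L))
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, ds, gs) paste(c(nm, ds, gs), collapse = "\t"),
                  names(sets), descriptions, sets)
  writeLines(unname(lines), path)
  invisible(path)
}
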