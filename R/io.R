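#' Read a count matrix from tab-separated text
#'
#' The expected dialect is a header line whose first cell is `gene_id` and
#' whose remaining cells are `sample:condition` (the text after the last
#' colon is the condition label), followed by one row per gene.  Counts must
#' be nonnegative integers; violations are reported with the offending gene
#' and sample.
#'
#' @param path Path to the file.
#' @return A [count_matrix()].
#' @seealso [write_counts()] for the inverse.
#' @export
read_counts <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("count file has no data rows", call. = FALSE)
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(hdr) < 2L || hdr[1L] != "gene_id")
    stop("malformed header: first column must be 'gene_id' and at least ",
         "one 'sample:condition' column must follow", call. = FALSE)
  cells <- hdr[-1L]
  pos <- regexpr(":[^:]*$", cells)
  if (any(pos < 0))
    stop("malformed header: sample column(s) without ':condition': ",
         paste(cells[pos < 0], collapse = ", "), call. = FALSE)
  samples <- substr(cells, 1L, pos - 1L)
  condition <- substring(cells, pos + 1L)
  tab <- utils::read.table(text = lines[-1L], sep = "\t",
                           colClasses = c("character",
                                          rep("numeric", length(cells))),
                           col.names = c("gene_id", samples),
                           check.names = FALSE)
  if (anyDuplicated(tab$gene_id))
    stop("duplicate gene id: ", tab$gene_id[anyDuplicated(tab$gene_id)],
         call. = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab$gene_id
  bad <- which(is.na(m) | m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad))
    stop("invalid count (negative, missing or non-integer) at gene '",
         rownames(m)[bad[1L, 1L]], "', sample '", samples[bad[1L, 2L]], "'",
         call. = FALSE)
  count_matrix(m, condition)
}

#' Write a count matrix as tab-separated text
#'
#' @param counts A [count_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  stopifnot(inherits(counts, "count_matrix"))
  hdr <- paste(c("gene_id", paste0(colnames(counts$counts), ":",
                                   as.character(counts$condition))),
               collapse = "\t")
  body <- paste(rownames(counts$counts),
                apply(counts$counts, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write simulation truth as tab-separated text
#'
#' @param truth Truth data frame from [simulate_counts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a list of known non-DE gene ids
#'
#' One id per line; `#` starts a comment; blank lines are skipped;
#' duplicates are collapsed.
#'
#' @param path Path to the file.
#' @param counts Optional [count_matrix()]; ids absent from it are dropped
#'   with a warning reporting how many.
#' @return Character vector of unique gene ids.
#' @export
read_gene_list <- function(path, counts = NULL) {
  ids <- sub("#.*$", "", readLines(path))
  ids <- trimws(ids)
  ids <- unique(ids[nzchar(ids)])
  if (length(ids) == 0L)
    stop("gene list '", path, "' contains no gene ids", call. = FALSE)
  if (!is.null(counts)) {
    absent <- setdiff(ids, rownames(counts$counts))
    if (length(absent)) {
      warning(length(absent), " gene id(s) from '", path,
              "' not found in the count matrix and dropped", call. = FALSE)
      ids <- setdiff(ids, absent)
      if (length(ids) == 0L)
        stop("no gene id from '", path, "' is present in the count matrix",
             call. = FALSE)
    }
  }
  ids
}

#' Write a detection report
#'
#' Writes the per-gene table of an [sfmeb()] fit as tab-separated text,
#' preceded by a `#`-commented header block recording the chosen kernel
#' scale, penalty, squared radius, achieved training reject rate and
#' training-set size, so the run can be audited from the file alone.
#'
#' @param fit An `"sfmeb"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(fit, path) {
  stopifnot(inherits(fit, "sfmeb"))
  hdr <- c(
    sprintf("# nu\t%.10g", fit$tuning$chosen_nu),
    sprintf("# C\t%.10g", fit$C),
    sprintf("# r_squared\t%.10g", fit$model$r_squared),
    sprintf("# target_reject\t%.10g", fit$target_reject),
    sprintf("# achieved_reject\t%.10g", fit$tuning$train_reject),
    sprintf("# n_train\t%d", length(fit$train_genes)))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(fit$report, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an AUC table
#'
#' @param tab Data frame from [run_study()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_auc_table <- function(tab, path) {
  utils::write.table(tab[, c("method", "rep", "auc")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
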