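#' Count matrix container
#'
#' A light container for a gene-by-sample matrix of raw read counts with a
#' condition label per sample.  Counts must be nonnegative integers; no
#' normalization of any kind is applied or stored.
#'
#' @param counts Numeric matrix, genes in rows (rownames are gene ids),
#'   samples in columns.
#' @param condition Vector of length `ncol(counts)` giving each sample's
#'   condition (coerced to factor; two conditions for a DE analysis).
#' @return An object of class `"count_matrix"` with elements `counts` and
#'   `condition`.
#' @export
count_matrix <- function(counts, condition) {
  counts <- as.matrix(counts)
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be nonnegative and complete", call. = FALSE)
  if (any(counts != floor(counts)))
    stop("counts must be integers", call. = FALSE)
  if (max(counts) <= .Machine$integer.max) storage.mode(counts) <- "integer"
  if (length(condition) != ncol(counts))
    stop("'condition' must have one entry per sample", call. = FALSE)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene id: ",
         rownames(counts)[anyDuplicated(rownames(counts))], call. = FALSE)
  structure(list(counts = counts, condition = factor(condition)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("  conditions: ",
      paste(sprintf("%s (n=%d)", levels(x$condition),
                    tabulate(x$condition)), collapse = ", "), "\n", sep = "")
  cat("  library sizes: ", paste(colSums(x$counts), collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Detect DE genes with the scaling-free minimum enclosing ball
#'
#' The full detection pipeline: select the RBF scale by reject-rate matching
#' on the known non-DE training genes ([meb_tune()]), fit the soft-margin
#' ball at the chosen scale, and score every gene of the count matrix by its
#' signed distance to the ball boundary ([score_genes()]).  Genes outside
#' the ball (positive score) are called DE; larger scores rank as more
#' confidently DE.  No library-size normalization is performed at any point;
#' the raw counts are the features.
#'
#' The reported score is the raw signed decision value, not a p-value: the
#' method yields a dichotomous in/out decision plus a ranking, and no
#' p-value is fabricated from it.  The achieved training reject rate is
#' reported so the implied type-I control can be audited.
#'
#' @param counts A [count_matrix()] (or plain matrix of nonnegative integer
#'   counts with gene ids as rownames).
#' @param train_genes Character vector of known non-DE gene ids present in
#'   `counts` (housekeeping genes, or conserved orthologs across species).
#'   With the default `C = 0.1` at least 10 are required.
#' @param C Soft-margin penalty (default 0.1).
#' @param nu_grid Candidate RBF scales, see [default_nu_grid()].
#' @param target_reject Target training reject rate; overridden by `preset`.
#' @param preset `"same_species"` (target reject 0.10, the default) or
#'   `"cross_species"` (0.20, for noisier conserved-ortholog training sets).
#' @param log1p Optional `log1p` transform of all counts (off by default).
#' @return An object of class `"sfmeb"`: `model` (the fitted `"meb"`),
#'   `tuning` (the `"meb_tune"` result), `report` (per-gene data frame with
#'   `gene_id`, `score`, `call`, `rank`), `train_genes`, and the parameters
#'   used.
#' @examples
#' sim <- simulate_counts(sim_config(G = 300, pi0 = 0.5, d = 4, seed = 7))
#' train <- select_training_genes(sim$truth, 50, seed = 7)
#' fit <- sfmeb(sim$counts, train)
#' fit
#' head(subset(fit$report, call == "DE"))
#' @export
sfmeb <- function(counts, train_genes, C = 0.1, nu_grid = default_nu_grid(),
                  target_reject = NULL,
                  preset = c("same_species", "cross_species"),
                  log1p = FALSE) {
  preset <- match.arg(preset)
  if (is.null(target_reject))
    target_reject <- switch(preset, same_species = 0.10, cross_species = 0.20)
  if (!inherits(counts, "count_matrix"))
    counts <- count_matrix(counts,
                           condition = rep(1L, ncol(as.matrix(counts))))
  train_genes <- unique(as.character(train_genes))
  missing <- setdiff(train_genes, rownames(counts$counts))
  if (length(missing))
    stop(length(missing), " training gene id(s) not found in the count ",
         "matrix (e.g. ", missing[1L], ")", call. = FALSE)
  n_min <- ceiling(1 / C)
  if (length(train_genes) < n_min)
    stop("the training set has ", length(train_genes), " genes but C = ", C,
         " requires at least ", n_min, call. = FALSE)
  x <- counts$counts[train_genes, , drop = FALSE]
  tuning <- meb_tune(x, C = C, nu_grid = nu_grid,
                     target_reject = target_reject, log1p = log1p)
  report <- score_genes(tuning$model, counts)
  structure(
    list(model = tuning$model, tuning = tuning, report = report,
         train_genes = train_genes, counts = counts, C = C,
         target_reject = target_reject, preset = preset, log1p = log1p),
    class = "sfmeb")
}

#' @export
print.sfmeb <- function(x, ...) {
  cat("SFMEB differential expression detection\n")
  cat("  genes scored: ", nrow(x$report),
      "   training non-DE genes: ", length(x$train_genes), "\n", sep = "")
  cat("  chosen nu: ", format(x$tuning$chosen_nu),
      "   C: ", format(x$C),
      "   R^2: ", format(x$model$r_squared), "\n", sep = "")
  cat("  target reject rate: ", format(x$target_reject),
      "   achieved: ", format(round(x$tuning$train_reject, 4)), "\n",
      sep = "")
  cat("  DE calls: ", sum(x$report$call == "DE"), " of ", nrow(x$report),
      " genes\n", sep = "")
  invisible(x)
}

#' @export
summary.sfmeb <- function(object, ...) {
  out <- list(fit = object,
              n_de = sum(object$report$call == "DE"),
              score = summary(object$report$score),
              top = utils::head(
                object$report[order(object$report$rank), ], 10L))
  class(out) <- "summary.sfmeb"
  out
}

#' @export
print.summary.sfmeb <- function(x, ...) {
  print(x$fit)
  cat("\nScore distribution:\n"); print(x$score)
  cat("\nTop-ranked genes:\n"); print(x$top, row.names = FALSE)
  invisible(x)
}

#' @export
coef.sfmeb <- function(object, ...) coef(object$model)

#' @export
predict.sfmeb <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

#' Discrimination plot of a fitted detector
#'
#' For two-sample data, plots each gene's counts in condition 1 against
#' condition 2, colored by the DE call, with training genes overdrawn --
#' the standard way to visualize what the ball accepted.  With replicates,
#' per-condition mean counts are plotted instead.
#'
#' @param x An `"sfmeb"` fit.
#' @param max_count Only genes with all plotted coordinates below this value
#'   are shown, for readability (default 600).
#' @param ... Passed to [plot()].
#' @export
plot.sfmeb <- function(x, max_count = 600, ...) {
  cm <- x$counts
  cond <- cm$condition
  if (nlevels(cond) != 2L)
    stop("plotting needs exactly two conditions", call. = FALSE)
  m1 <- rowMeans(cm$counts[, cond == levels(cond)[1L], drop = FALSE])
  m2 <- rowMeans(cm$counts[, cond == levels(cond)[2L], drop = FALSE])
  keep <- m1 <= max_count & m2 <= max_count
  de <- x$report$call == "DE"
  plot(m1[keep], m2[keep], col = ifelse(de[keep], "firebrick", "grey60"),
       pch = 20, cex = 0.5,
       xlab = paste("mean count,", levels(cond)[1L]),
       ylab = paste("mean count,", levels(cond)[2L]), ...)
  tr <- rownames(cm$counts) %in% x$train_genes & keep
  points(m1[tr], m2[tr], col = "dodgerblue", pch = 1, cex = 0.8)
  legend("topleft", legend = c("DE", "nonDE", "training"), bty = "n",
         col = c("firebrick", "grey60", "dodgerblue"), pch = c(20, 20, 1))
  invisible(x)
}
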