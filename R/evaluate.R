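#' ROC curve and AUC of a gene ranking
#'
#' Sweeps the decision threshold over the distinct score values (larger
#' score = more DE-like) and returns the operating points from (0, 0) to
#' (1, 1) together with the trapezoidal area under them.  Tied scores are
#' grouped into a single sweep step, which makes the trapezoidal area equal
#' the Mann-Whitney statistic
#' \eqn{P(S_{DE} > S_{nonDE}) + \tfrac12 P(S_{DE} = S_{nonDE})}.
#'
#' @param scores Numeric vector of per-gene scores.
#' @param truth Binary DE labels (logical, 0/1, or a factor whose second
#'   level is the positive class), aligned with `scores`.
#' @return An object of class `"roc_result"`: `points`, a data frame of
#'   `fpr`, `tpr`, and the scalar `auc`.
#' @export
roc_auc <- function(scores, truth) {
  if (is.factor(truth)) truth <- as.integer(truth) == 2L
  truth <- as.logical(truth)
  if (length(scores) != length(truth) || anyNA(scores) || anyNA(truth))
    stop("'scores' and 'truth' must be complete and aligned", call. = FALSE)
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC needs at least one DE and one non-DE gene in 'truth'",
         call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  last <- cumsum(rle(s)$lengths)  # one sweep step per distinct score
  tp <- cumsum(y)[last]; fp <- cumsum(!y)[last]
  fpr <- c(0, fp / n_neg); tpr <- c(0, tp / n_pos)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC: ", nrow(x$points), " operating points, AUC = ",
      format(x$auc, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "l", xlab = "FPR", ylab = "TPR",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  abline(0, 1, lty = 3, col = "grey")
  invisible(x)
}

#' Library-size baseline test for differential expression
#'
#' The naive comparator that uses raw counts and library sizes only: for
#' each gene, an exact two-sided binomial test of the condition-1 total
#' against the combined total, with null success probability equal to the
#' condition-1 share of the total library size.  Genes are ranked by
#' ascending p-value.  Replicates are pooled by summation within condition
#' (or by rounded per-replicate means with `pool = "mean"`).
#'
#' @param counts A [count_matrix()] with exactly two conditions.
#' @param pool `"sum"` (default) or `"mean"` pooling of replicates.
#' @return Numeric vector of per-gene two-sided p-values, named by gene id;
#'   genes with zero total count get p = 1.
#' @export
library_size_test <- function(counts, pool = c("sum", "mean")) {
  pool <- match.arg(pool)
  stopifnot(inherits(counts, "count_matrix"))
  cond <- counts$condition
  if (nlevels(cond) != 2L)
    stop("the library-size test needs exactly two conditions", call. = FALSE)
  agg <- function(j) {
    m <- counts$counts[, cond == levels(cond)[j], drop = FALSE]
    if (pool == "sum") rowSums(m) else round_half_up(rowMeans(m))
  }
  x1 <- agg(1L); x2 <- agg(2L)
  p0 <- sum(x1) / (sum(x1) + sum(x2))
  tot <- x1 + x2
  p <- rep(1, length(tot))
  nz <- tot > 0
  p[nz] <- vapply(which(nz), function(i)
    stats::binom.test(x1[i], tot[i], p0)$p.value, numeric(1))
  names(p) <- rownames(counts$counts)
  p
}

#' Count known non-DE genes among the top detections
#'
#' Given a ranking of genes from most to least DE-like and a set of genes
#' known to be non-DE (housekeeping genes, conserved orthologs), counts how
#' many of the known non-DE genes appear among the `k` top-ranked
#' detections -- a false-discovery proxy usable on real data where full
#' truth is unknown.
#'
#' @param ranking Character vector of gene ids, most significant first.
#' @param known_nonDE Character vector (or set) of known non-DE gene ids.
#' @param k Number of top detections to inspect, `0 <= k <= length(ranking)`.
#' @return Integer count of known non-DE genes among the top `k`.
#' @export
false_discovery_count <- function(ranking, known_nonDE, k) {
  if (k < 0 || k > length(ranking))
    stop("'k' must be between 0 and the ranking length (",
         length(ranking), ")", call. = FALSE)
  sum(utils::head(ranking, k) %in% known_nonDE)
}

#' Run a replicated simulation study
#'
#' For each replicate: simulate counts (combining two blocks when the
#' design is heterogeneous), draw a training set of known non-DE genes,
#' tune and fit the minimum enclosing ball, score every gene, and compute
#' the AUC against the simulation truth (any gene that is not `nonDE`
#' counts as truly DE, including uniquely expressed genes).  The
#' library-size baseline is scored by `-p` so that small p-values rank
#' first.  Fully reproducible from `seed`.
#'
#' @param cfg A [sim_config()], or a list of two to be combined into a
#'   heterogeneous dataset (as returned by [study_config()]).
#' @param methods Subset of `c("sfmeb", "library_size")`.
#' @param n_reps Number of simulation replicates.
#' @param seed Integer master seed; replicate seeds are derived from it.
#' @param n_train Number of simulated non-DE genes used for training.
#' @param C,nu_grid,target_reject Passed to [meb_tune()].
#' @return Data frame with columns `method`, `rep`, `auc`; the per-method
#'   mean AUCs are attached as attribute `"summary"`.
#' @export
run_study <- function(cfg, methods = c("sfmeb", "library_size"),
                      n_reps = 5, seed = 1L, n_train = 200, C = 0.1,
                      nu_grid = default_nu_grid(), target_reject = 0.10) {
  methods <- match.arg(methods, several.ok = TRUE)
  single <- inherits(cfg, "sim_config")
  rows <- list()
  for (r in seq_len(n_reps)) {
    rs <- seed * 1000L + r
    dat <- if (single) {
      c1 <- cfg; c1$seed <- rs
      simulate_counts(c1)
    } else {
      c1 <- cfg[[1L]]; c1$seed <- rs
      c2 <- cfg[[2L]]; c2$seed <- rs + 500L
      combine_heterogeneous(simulate_counts(c1), simulate_counts(c2))
    }
    is_de <- dat$truth$label != "nonDE"
    for (m in methods) {
      sc <- if (m == "sfmeb") {
        train <- select_training_genes(dat$truth, n_train, seed = rs)
        tn <- meb_tune(dat$counts$counts[train, , drop = FALSE], C = C,
                       nu_grid = nu_grid, target_reject = target_reject)
        predict(tn$model, dat$counts$counts)
      } else {
        -library_size_test(dat$counts)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(method = m, rep = r, auc = roc_auc(sc, is_de)$auc,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- stats::aggregate(auc ~ method, out, mean)
  out
}
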