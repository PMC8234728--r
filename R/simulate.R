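#' Configuration for the synthetic RNA-seq count generator
#'
#' Describes one simulated two-condition dataset.  Baseline expected
#' expression per gene is drawn from a log-normal distribution (heavy-tailed,
#' like empirical read proportions); differential expression is imposed as a
#' symmetric split of a log2 fold change between the two conditions, so the
#' ratio of condition means is exactly `2^d` for a DE gene.  Uniquely
#' expressed genes have expected count exactly 0 in the absent condition.
#' Sequencing-depth factors multiply all expected counts of a condition,
#' creating the library-size confounding that normalization-based methods
#' must estimate away and that this method ignores by design.
#'
#' @param G Number of genes excluding the uniquely expressed ones.
#' @param pi0 Proportion of `G` that is differentially expressed.
#' @param d Log2 fold change magnitude of DE genes (exact when
#'   `fc_mode = "fixed"`, a lower bound when `"at_least"`).
#' @param p_up2 Proportion of DE genes up-regulated in condition 2 (the rest
#'   are up-regulated in condition 1).
#' @param u Length-2 vector: numbers of genes uniquely expressed in
#'   conditions 1 and 2.
#' @param reps Length-2 vector of replicate counts per condition.
#' @param depth Length-2 vector of sequencing-depth (scaling) factors; the
#'   default `c(1, 1.5)` keeps library-size confounding present.
#' @param dist `"poisson"` or `"nb"` (negative binomial).
#' @param nb_dispersion NB dispersion `phi` in `var = mu + phi * mu^2`.
#' @param fc_mode `"fixed"`: every DE gene changes by exactly `d` log2
#'   units; `"at_least"`: by `d + E` with `E` exponential (rate
#'   `fc_excess_rate`) truncated at 2, so all fold changes are "no less
#'   than" `d`.
#' @param fc_excess_rate Rate of the truncated exponential excess.
#' @param mu_meanlog,mu_sdlog Parameters (natural log) of the log-normal
#'   baseline mean distribution.
#' @param s Length-2 vector of unmapped-gene counts per condition; only used
#'   by [simulate_two_species()], where each condition is a species.
#' @param seed Integer seed; every draw of the generator flows through it.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(G = 15000, pi0 = 0.6, d = 2, p_up2 = 0.9,
                       u = c(0, 0), reps = c(1, 1), depth = c(1, 1.5),
                       dist = c("poisson", "nb"), nb_dispersion = 0.1,
                       fc_mode = c("fixed", "at_least"), fc_excess_rate = 1,
                       mu_meanlog = 4, mu_sdlog = 1.5, s = c(0, 0),
                       seed = 1L) {
  dist <- match.arg(dist)
  fc_mode <- match.arg(fc_mode)
  stopifnot(G >= 1, pi0 >= 0, pi0 <= 1, d > 0, p_up2 >= 0, p_up2 <= 1,
            length(u) == 2L, all(u >= 0), length(reps) == 2L,
            all(reps >= 1), length(depth) == 2L, all(depth > 0),
            nb_dispersion > 0, fc_excess_rate > 0, length(s) == 2L,
            all(s >= 0))
  structure(list(G = as.integer(G), pi0 = pi0, d = d, p_up2 = p_up2,
                 u = as.integer(u), reps = as.integer(reps), depth = depth,
                 dist = dist, nb_dispersion = nb_dispersion,
                 fc_mode = fc_mode, fc_excess_rate = fc_excess_rate,
                 mu_meanlog = mu_meanlog, mu_sdlog = mu_sdlog,
                 s = as.integer(s), seed = as.integer(seed)),
            class = "sim_config")
}

round_half_up <- function(x) floor(x + 0.5)

# exponential(rate) truncated to [0, cap], by inverse CDF
rtexp <- function(n, rate, cap = 2) {
  -log(1 - stats::runif(n) * (1 - exp(-rate * cap))) / rate
}

#' Simulate a two-condition RNA-seq count matrix with ground truth
#'
#' Generates counts per the design in a [sim_config()].  Label bookkeeping
#' is exact by construction: with `n_de = round(G * pi0)` DE genes, exactly
#' `round(n_de * p_up2)` are up-regulated in condition 2 and the rest in
#' condition 1, and exactly `u[1]` / `u[2]` genes are uniquely expressed in
#' condition 1 / 2 (all-zero counts in the other condition).  Counts are
#' drawn independently per gene and replicate from
#' `Poisson(mu_ij * depth_j)` or `NB(mean = mu_ij * depth_j, dispersion)`.
#'
#' @param cfg A [sim_config()].
#' @return List with `counts` (a [count_matrix()]) and `truth`, a data frame
#'   with columns `gene_id`, `label` (one of `nonDE`, `DE_up1`, `DE_up2`,
#'   `unique1`, `unique2`) and `lfc`, the true log2 fold change of the
#'   condition-2 over condition-1 mean (`Inf`/`-Inf` for unique genes).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_de <- round_half_up(cfg$G * cfg$pi0)
  n_up2 <- round_half_up(n_de * cfg$p_up2)
  n_up1 <- n_de - n_up2
  n_non <- cfg$G - n_de
  label <- rep(c("nonDE", "DE_up1", "DE_up2", "unique1", "unique2"),
               c(n_non, n_up1, n_up2, cfg$u[1L], cfg$u[2L]))
  N <- length(label)
  mu <- stats::rlnorm(N, cfg$mu_meanlog, cfg$mu_sdlog)
  delta <- numeric(N)
  is_de <- label %in% c("DE_up1", "DE_up2")
  delta[is_de] <- if (cfg$fc_mode == "fixed") cfg$d else
    cfg$d + rtexp(sum(is_de), cfg$fc_excess_rate)
  half <- 2^(delta / 2)
  mu1 <- mu; mu2 <- mu
  up2 <- label == "DE_up2"; up1 <- label == "DE_up1"
  mu1[up2] <- mu[up2] / half[up2]; mu2[up2] <- mu[up2] * half[up2]
  mu1[up1] <- mu[up1] * half[up1]; mu2[up1] <- mu[up1] / half[up1]
  mu2[label == "unique1"] <- 0
  mu1[label == "unique2"] <- 0
  draw <- function(m) {
    if (cfg$dist == "poisson") stats::rpois(length(m), m)
    else stats::rnbinom(length(m), mu = m, size = 1 / cfg$nb_dispersion)
  }
  cols <- list()
  condition <- integer(0)
  for (j in 1:2) {
    m_j <- (if (j == 1L) mu1 else mu2) * cfg$depth[j]
    for (r in seq_len(cfg$reps[j])) {
      cols[[length(cols) + 1L]] <- draw(m_j)
      condition <- c(condition, j)
    }
  }
  counts <- do.call(cbind, cols)
  colnames(counts) <- paste0("c", condition, "_r",
                             unlist(lapply(cfg$reps, seq_len)))
  rownames(counts) <- sprintf("g%05d", seq_len(N))
  lfc <- ifelse(mu1 == 0, Inf, ifelse(mu2 == 0, -Inf, log2(mu2 / mu1)))
  list(counts = count_matrix(counts, condition),
       truth = data.frame(gene_id = rownames(counts), label = label,
                          lfc = lfc, stringsAsFactors = FALSE))
}

#' Combine two simulated datasets into one heterogeneous dataset
#'
#' Row-binds two simulated datasets that share the same sample layout.  The
#' two blocks were generated with their own depth factors and designs, so
#' the combined data has two scaling factors: the heterogeneity that defeats
#' any single normalization constant.  Gene ids are disambiguated when they
#' clash; within-block gene order is preserved.
#'
#' @param a,b Lists with `counts` and `truth` as from [simulate_counts()].
#' @return A list with combined `counts` and `truth`.
#' @export
combine_heterogeneous <- function(a, b) {
  if (!identical(as.character(a$counts$condition),
                 as.character(b$counts$condition)))
    stop("datasets have different sample layouts", call. = FALSE)
  ids <- make.unique(c(rownames(a$counts$counts), rownames(b$counts$counts)),
                     sep = "_")
  counts <- rbind(a$counts$counts, b$counts$counts)
  rownames(counts) <- ids
  truth <- rbind(a$truth, b$truth)
  truth$gene_id <- ids
  rownames(truth) <- NULL
  list(counts = count_matrix(counts, a$counts$condition), truth = truth)
}

#' Simulate ortholog counts for two species
#'
#' Builds a heterogeneous two-"condition" dataset where each condition is a
#' species, by combining two blocks as in [combine_heterogeneous()].  In
#' addition, each block contributes `s[1]` / `s[2]` unmapped genes that
#' exist in only one species: they are simulated (adding to that species'
#' sequencing depth) but excluded from the returned ortholog matrix, whose
#' per-sample unmapped read totals are reported separately.  A random subset
#' of the non-DE orthologs is returned as the conserved training surrogate,
#' standing in for a curated conserved-gene list.
#'
#' @param cfg1,cfg2 [sim_config()]s for the two blocks (their `s` fields
#'   give the unmapped-gene counts).
#' @param n_conserved Size of the conserved non-DE training subset.
#' @param seed Seed for the conserved-subset draw (defaults to `cfg1$seed`).
#' @return List with `counts`, `truth` (orthologs only), `conserved`
#'   (character vector of training gene ids) and `unmapped_libsize`
#'   (per-sample read totals of the excluded unmapped genes).
#' @export
simulate_two_species <- function(cfg1, cfg2, n_conserved = 500,
                                 seed = cfg1$seed) {
  comb <- combine_heterogeneous(simulate_counts(cfg1), simulate_counts(cfg2))
  n_samp <- ncol(comb$counts$counts)
  unmapped <- numeric(n_samp)
  for (blk in list(cfg1, cfg2)) {
    if (all(blk$s == 0)) next
    set.seed(blk$seed + 1L)
    cond <- as.integer(as.character(comb$counts$condition))
    for (j in 1:2) {
      if (blk$s[j] == 0) next
      mu_s <- stats::rlnorm(blk$s[j], blk$mu_meanlog, blk$mu_sdlog) *
        blk$depth[j]
      for (col in which(cond == j)) {
        cnt <- if (blk$dist == "poisson") stats::rpois(blk$s[j], mu_s)
               else stats::rnbinom(blk$s[j], mu = mu_s,
                                   size = 1 / blk$nb_dispersion)
        unmapped[col] <- unmapped[col] + sum(cnt)
      }
    }
  }
  conserved <- select_training_genes(comb$truth, n_conserved, seed = seed)
  c(comb, list(conserved = conserved, unmapped_libsize = unmapped))
}

#' Pick a training set of known non-DE genes from simulation truth
#'
#' Draws a uniform random subset of the genes labelled `nonDE`, standing in
#' for the housekeeping-gene or conserved-ortholog list a real analysis
#' would supply.
#'
#' @param truth Truth data frame from [simulate_counts()].
#' @param n Subset size; must not exceed the number of non-DE genes.
#' @param seed Integer seed making the draw reproducible.
#' @return Character vector of `n` gene ids.
#' @export
select_training_genes <- function(truth, n, seed = 1L) {
  pool <- truth$gene_id[truth$label == "nonDE"]
  if (n > length(pool))
    stop("requested ", n, " training genes but only ", length(pool),
         " non-DE genes are available", call. = FALSE)
  if (n == 0L) return(character(0))
  set.seed(seed)
  sample(pool, n)
}

#' Preset simulation designs
#'
#' Returns the parameter settings of the six standard study designs plus
#' the two-species design: Studies 1-2 are Poisson without replicates
#' (homogeneous / heterogeneous), Studies 3-4 the same with biological
#' replicates, Studies 5-6 negative binomial with replicates and
#' "at least d" fold changes, and `"species"` the two-species ortholog
#' design with unmapped genes.  Heterogeneous designs return a list of two
#' configs to be combined.
#'
#' @param study One of `1:6` or `"species"`.
#' @param pi0 Proportion of DE genes where the design varies it (study 1:
#'   0.3/0.5/0.7; study 2 and species: the second block's 0.1-0.5 or
#'   0.3-0.7).
#' @param reps Replicates per condition for studies 3-6 (2, 5 or 8).
#' @param seed Integer seed.
#' @return A `"sim_config"`, or a list of two for the heterogeneous and
#'   species designs.
#' @export
study_config <- function(study, pi0 = NULL, reps = 2, seed = 1L) {
  reps2 <- rep(reps, 2)
  switch(as.character(study),
    "1" = sim_config(G = 15000, pi0 = pi0 %||% 0.7, d = 2, p_up2 = 0.9,
                     u = c(1000, 500), reps = c(1, 1), seed = seed),
    "2" = list(
      sim_config(G = 15000, pi0 = 0.6, d = 2, p_up2 = 0.9,
                 u = c(1000, 500), reps = c(1, 1), seed = seed),
      sim_config(G = 10000, pi0 = pi0 %||% 0.3, d = 3, p_up2 = 0.1,
                 u = c(800, 1500), reps = c(1, 1), depth = c(1.2, 0.8),
                 seed = seed + 1L)),
    "3" = sim_config(G = 15000, pi0 = 0.6, d = 2, p_up2 = 1,
                     u = c(1000, 800), reps = reps2, seed = seed),
    "4" = list(
      sim_config(G = 15000, pi0 = 0.6, d = 2, p_up2 = 0.9,
                 u = c(1000, 800), reps = reps2, seed = seed),
      sim_config(G = 10000, pi0 = 0.4, d = 3, p_up2 = 0.1,
                 u = c(2000, 1000), reps = reps2, depth = c(1.2, 0.8),
                 seed = seed + 1L)),
    "5" = sim_config(G = 15000, pi0 = 0.6, d = 3, p_up2 = 1, u = c(0, 0),
                     reps = reps2, dist = "nb", fc_mode = "at_least",
                     seed = seed),
    "6" = list(
      sim_config(G = 15000, pi0 = 0.6, d = 2, p_up2 = 1, u = c(0, 0),
                 reps = reps2, dist = "nb", fc_mode = "at_least",
                 seed = seed),
      sim_config(G = 10000, pi0 = 0.4, d = 3, p_up2 = 0.1, u = c(0, 0),
                 reps = reps2, dist = "nb", fc_mode = "at_least",
                 depth = c(1.2, 0.8), seed = seed + 1L)),
    "species" = list(
      sim_config(G = 12000, pi0 = pi0 %||% 0.4, d = 3, p_up2 = 0.1,
                 u = c(1000, 1200), s = c(1000, 800), reps = c(1, 1),
                 seed = seed),
      sim_config(G = 10000, pi0 = pi0 %||% 0.4, d = 2, p_up2 = 0.9,
                 u = c(2000, 1000), s = c(3000, 2000), reps = c(1, 1),
                 depth = c(1.2, 0.8), seed = seed + 1L)),
    stop("unknown study: ", study, call. = FALSE))
}
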