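label_counts <- function(truth) table(factor(
  truth$label, c("nonDE", "DE_up1", "DE_up2", "unique1", "unique2")))

test_that("label bookkeeping is exact for the printed designs", {
  # homogeneous single-factor design
  s1 <- simulate_counts(sim_config(G = 15000, pi0 = 0.6, d = 2,
                                   p_up2 = 0.9, u = c(1000, 500),
                                   reps = c(1, 1), seed = 1))
  lc <- label_counts(s1$truth)
  expect_equal(nrow(s1$counts$counts), 16500)
  expect_equal(ncol(s1$counts$counts), 2)
  expect_equal(unname(lc[["DE_up1"]] + lc[["DE_up2"]]), 9000)
  expect_equal(unname(lc[["DE_up2"]]), 8100)
  expect_equal(unname(lc[["unique1"]]), 1000)
  expect_equal(unname(lc[["unique2"]]), 500)
  # heterogeneous two-factor design
  s2 <- combine_heterogeneous(
    s1, simulate_counts(sim_config(G = 10000, pi0 = 0.3, d = 3,
                                   p_up2 = 0.1, u = c(800, 1500),
                                   reps = c(1, 1), seed = 2)))
  expect_equal(nrow(s2$counts$counts), 16500 + 12300)
  lc2 <- label_counts(s2$truth)
  expect_equal(unname(lc2[["DE_up1"]] + lc2[["DE_up2"]]), 9000 + 3000)
  expect_equal(unname(lc2[["unique1"]]), 1800)
})

test_that("small-design arithmetic rounds half up", {
  s <- simulate_counts(sim_config(G = 100, pi0 = 0.5, d = 1, p_up2 = 0.5,
                                  u = c(10, 5), seed = 3))
  lc <- label_counts(s$truth)
  expect_equal(unname(lc[["DE_up1"]] + lc[["DE_up2"]]), 50)
  expect_equal(unname(lc[["DE_up2"]]), 25)
  expect_equal(unname(lc[["unique1"]]), 10)
})

test_that("uniquely expressed genes are all-zero in the absent condition", {
  s <- simulate_counts(sim_config(G = 200, pi0 = 0.2, u = c(10, 5),
                                  reps = c(3, 2), seed = 4))
  cm <- s$counts
  u1 <- s$truth$gene_id[s$truth$label == "unique1"]
  u2 <- s$truth$gene_id[s$truth$label == "unique2"]
  expect_equal(length(u1), 10)
  expect_true(all(cm$counts[u1, cm$condition == "2"] == 0))
  expect_true(all(cm$counts[u2, cm$condition == "1"] == 0))
  expect_true(any(cm$counts[u1, cm$condition == "1"] > 0))
})

test_that("generated fold changes hit 2^d on average", {
  cfg <- sim_config(G = 6000, pi0 = 0.5, d = 2, p_up2 = 1, u = c(0, 0),
                    depth = c(1, 1.5), seed = 5)
  s <- simulate_counts(cfg)
  up2 <- s$truth$label == "DE_up2"
  m1 <- s$counts$counts[up2, 1] / cfg$depth[1]
  m2 <- s$counts$counts[up2, 2] / cfg$depth[2]
  expect_equal(mean(m2) / mean(m1), 2^2, tolerance = 0.05)
  # at_least mode yields only fold changes >= d
  sa <- simulate_counts(sim_config(G = 2000, pi0 = 0.5, d = 2, p_up2 = 1,
                                   fc_mode = "at_least", seed = 6))
  expect_true(all(sa$truth$lfc[sa$truth$label == "DE_up2"] >= 2))
  expect_true(any(sa$truth$lfc[sa$truth$label == "DE_up2"] > 2))
})

test_that("NB mode is overdispersed relative to Poisson", {
  cfg <- sim_config(G = 4000, pi0 = 0, u = c(0, 0), reps = c(20, 1),
                    depth = c(1, 1), dist = "nb", nb_dispersion = 0.5,
                    seed = 7)
  s <- simulate_counts(cfg)
  x <- s$counts$counts[, 1:20]
  m <- rowMeans(x); v <- apply(x, 1, var)
  keep <- m > 20
  # var ~ mu + phi mu^2 >> mu
  expect_gt(median((v / m)[keep]), 2)
})

test_that("replicate seeds reproduce and library sizes track depth", {
  cfg <- sim_config(G = 8000, pi0 = 0, u = c(0, 0), depth = c(1, 1.5),
                    seed = 11)
  a <- simulate_counts(cfg); b <- simulate_counts(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  ls <- colSums(a$counts$counts)
  expect_equal(ls[2] / ls[1], 1.5, tolerance = 0.1, ignore_attr = TRUE)
})

test_that("combining a dataset with itself doubles every label count", {
  s <- simulate_counts(sim_config(G = 300, pi0 = 0.4, u = c(7, 3), seed = 8))
  both <- combine_heterogeneous(s, s)
  expect_equal(as.vector(label_counts(both$truth)),
               2 * as.vector(label_counts(s$truth)))
  # within-block order preserved, ids disambiguated
  n <- nrow(s$counts$counts)
  expect_equal(unname(both$counts$counts[seq_len(n), ]),
               unname(s$counts$counts))
  expect_false(anyDuplicated(both$truth$gene_id) > 0)
})

test_that("mismatched sample layouts cannot be combined", {
  a <- simulate_counts(sim_config(G = 50, pi0 = 0, u = c(0, 0),
                                  reps = c(1, 1), seed = 1))
  b <- simulate_counts(sim_config(G = 50, pi0 = 0, u = c(0, 0),
                                  reps = c(2, 2), seed = 1))
  expect_error(combine_heterogeneous(a, b), "layout")
})

test_that("two-species design excludes unmapped genes but reports them", {
  cfgs <- study_config("species", seed = 21)
  cfgs[[1]]$G <- 1200L; cfgs[[1]]$u <- c(100L, 120L); cfgs[[1]]$s <- c(100L, 80L)
  cfgs[[2]]$G <- 1000L; cfgs[[2]]$u <- c(200L, 100L); cfgs[[2]]$s <- c(300L, 200L)
  sp <- simulate_two_species(cfgs[[1]], cfgs[[2]], n_conserved = 50)
  expect_equal(nrow(sp$counts$counts), 1200 + 220 + 1000 + 300)
  expect_true(all(sp$unmapped_libsize > 0))
  expect_equal(length(sp$conserved), 50)
  expect_true(all(sp$truth$label[match(sp$conserved,
                                       sp$truth$gene_id)] == "nonDE"))
  # s = (0,0) reduces exactly to the same-species combination
  cfgs[[1]]$s <- c(0L, 0L); cfgs[[2]]$s <- c(0L, 0L)
  sp0 <- simulate_two_species(cfgs[[1]], cfgs[[2]], n_conserved = 50)
  same <- combine_heterogeneous(simulate_counts(cfgs[[1]]),
                                simulate_counts(cfgs[[2]]))
  expect_identical(sp0$counts$counts, same$counts$counts)
  expect_equal(sp0$unmapped_libsize, rep(0, 2))
})

test_that("training-gene selection is reproducible and label-pure", {
  s <- simulate_counts(sim_config(G = 400, pi0 = 0.5, seed = 9))
  g1 <- select_training_genes(s$truth, 30, seed = 5)
  g2 <- select_training_genes(s$truth, 30, seed = 5)
  expect_identical(g1, g2)
  expect_true(all(s$truth$label[match(g1, s$truth$gene_id)] == "nonDE"))
  expect_identical(select_training_genes(s$truth, 0), character(0))
  expect_error(select_training_genes(s$truth, 1e6), "available")
})

test_that("large fold changes are near-perfectly separable", {
  cfg <- sim_config(G = 800, pi0 = 0.5, d = 6, p_up2 = 0.9, u = c(0, 0),
                    reps = c(1, 1), seed = 10)
  s <- simulate_counts(cfg)
  train <- select_training_genes(s$truth, 100, seed = 10)
  tn <- suppressWarnings(meb_tune(s$counts$counts[train, ]))
  sc <- predict(tn$model, s$counts$counts)
  auc <- roc_auc(sc, s$truth$label != "nonDE")$auc
  expect_gt(auc, 0.95)
})
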