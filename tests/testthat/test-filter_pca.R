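test_that("set filtering follows the median-plus-spread rule", {
  # all identical scores: spread 0, nothing above the median, all kept
  tb <- make_score_table(c("s1", "s2", "s3"), n_per_set = 3, base_sd = 0,
                         seed = 1)
  res <- filter_sets(tb)
  expect_setequal(res$kept, c("s1", "s2", "s3"))
  expect_length(res$discarded, 0)
  # hand-computed arithmetic example
  tb2 <- data.frame(model_id = paste0("m", 1:9),
                    set_id = rep(c("A", "B", "C"), each = 3),
                    score = c(1.6, 1.7, 1.8, 2.8, 2.9, 3.0, 1.7, 1.7, 1.7))
  res2 <- filter_sets(tb2)
  expect_equal(res2$stats$median, 1.7)
  expect_equal(res2$stats$spread, sd(tb2$score))
  expect_identical(res2$discarded, "B")
  expect_setequal(res2$kept, c("A", "C"))
  # a single set cannot be discarded
  expect_warning(res3 <- filter_sets(tb2[tb2$set_id == "B", ]),
                 "only one set")
  expect_identical(res3$kept, "B")
  # row order and labels do not matter
  perm <- tb2[sample(9), ]
  expect_identical(filter_sets(perm)$discarded, "B")
})

test_that("set filtering equals the arithmetic oracle on seeded tables", {
  for (s in 1:10) {
    tb <- make_score_table(paste0("s", 1:6), n_per_set = 5,
                           base_sd = 0.4, seed = s)
    res <- filter_sets(tb)
    cut <- median(tb$score) + sd(tb$score)
    means <- tapply(tb$score, tb$set_id, mean)
    expect_setequal(res$discarded, names(means)[means > cut])
    # SEM semantics behind the flag
    res_sem <- filter_sets(tb, spread = "sem")
    cut_sem <- median(tb$score) + sd(tb$score) / sqrt(nrow(tb))
    expect_setequal(res_sem$discarded, names(means)[means > cut_sem])
  }
})

test_that("relative quality score is the normalized excess over the minimum", {
  expect_equal(relative_mp(1.6, 1.6), 0)
  expect_equal(relative_mp(2.0, 1.6), 0.25)
  v <- c(1.6, 1.8, 2.4)
  expect_equal(relative_mp(v, min(v)), (v - 1.6) / 1.6)
  expect_error(relative_mp(2, 0), "> 0")
})

test_that("clash proxy is zero on extended chains and counts planted overlaps", {
  # ideal extended peptide: straight Calpha trace at 3.8 A spacing
  n <- 30
  ca <- cbind(3.8 * seq_len(n), 0, 0)
  atoms <- alamsa:::trace_to_atoms(ca, alamsa:::hinge_sequence(n))
  ext <- structure_model(atoms, model_id = "extended")
  s0 <- clash_proxy_score(ext)
  expect_identical(attr(s0, "clashes"), 0L)
  expect_equal(as.numeric(s0), 0)
  # force two atoms 1.0 A apart, isolated from the rest: exactly one clash
  m1 <- ext
  i5 <- which(m1$atoms$res_index == 5 & m1$atoms$elety == "CB")
  i10 <- which(m1$atoms$res_index == 20 & m1$atoms$elety == "CB")
  m1$atoms[i5, c("x", "y", "z")] <- c(50, 50, 0)
  m1$atoms[i10, c("x", "y", "z")] <- c(50, 51, 0)
  s1 <- clash_proxy_score(m1)
  expect_identical(attr(s1, "clashes"), 1L)
  expect_equal(as.numeric(s1), 1000 / nrow(m1$atoms))
  # planted overlaps equal the O(n^2) pair enumeration
  set.seed(31)
  m2 <- hinge_model(toy_spec(noise_sd = 0.3), 150)
  got <- clash_proxy_score(m2)
  at <- m2$atoms
  r <- alamsa:::vdw_radius(at$elety)
  cnt <- 0L
  for (p in seq_len(nrow(at) - 1L)) for (q in (p + 1L):nrow(at)) {
    if (abs(at$res_index[p] - at$res_index[q]) <= 1L) next
    d <- sqrt(sum((at[p, c("x", "y", "z")] - at[q, c("x", "y", "z")])^2))
    if (d < r[p] + r[q] - 0.4) cnt <- cnt + 1L
  }
  expect_identical(attr(got, "clashes"), cnt)
})

test_that("ensemble PCA conserves variance with orthonormal components", {
  ens <- make_hinge_ensemble(hinge_spec(modes = 2, noise_sd = 0.2), 15,
                             seed = 13)
  pca <- ensemble_pca(ens)
  ev <- pca$eigenvalues
  expect_true(all(diff(ev) <= 1e-10))          # descending
  expect_true(all(ev >= -1e-10))
  G <- crossprod(pca$components)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8) # orthonormal
  # trace conservation against the superposed coordinates
  arr <- alamsa:::iterative_mean_fit(alamsa:::ensemble_ca_array(ens))
  flat <- t(apply(arr$aligned, 3, as.vector))
  expect_equal(sum(ev), sum(apply(flat, 2, var)), tolerance = 1e-6)
})

test_that("two distinct conformations plus their mean give one mode", {
  a <- toy_closed(); b <- toy_open()
  mid <- a
  mid$atoms[, c("x", "y", "z")] <-
    (as.matrix(a$atoms[, c("x", "y", "z")]) +
       as.matrix(b$atoms[, c("x", "y", "z")])) / 2
  mid$model_id <- "mid"
  pca <- ensemble_pca(list(a, b, mid))
  ev <- pca$eigenvalues
  expect_gt(ev[1], 1)
  # rank collapses onto one mode; the Procrustes fit of each conformation
  # onto the mean bends exact coordinate collinearity slightly
  expect_lt(ev[2] / ev[1], 1e-2)
})

test_that("PCA projections are invariant to model order up to sign", {
  ens <- make_hinge_ensemble(toy_spec(noise_sd = 0.1), 8, seed = 17)
  p1 <- ensemble_pca(ens)$projections
  p2 <- ensemble_pca(rev(ens))$projections
  p2 <- p2[match(p1$model_id, p2$model_id), ]
  expect_equal(abs(p1$PC1), abs(p2$PC1), tolerance = 1e-6)
  expect_equal(abs(p1$PC2), abs(p2$PC2), tolerance = 1e-4)
})

test_that("references are projected without shaping the covariance", {
  ens <- make_hinge_ensemble(toy_spec(noise_sd = 0.1), 10, seed = 19)
  refA <- toy_closed(); refB <- toy_open()
  pca <- ensemble_pca(ens, references = list(refA, refB))
  pr <- pca$projections
  expect_identical(sum(pr$is_reference), 2L)
  # covariance fitted on models only: eigenvalues match the no-ref fit
  expect_equal(pca$eigenvalues, ensemble_pca(ens)$eigenvalues,
               tolerance = 1e-8)
  # the references bracket the sampled angle range along PC1
  mods <- pr[!pr$is_reference, ]
  refs <- pr[pr$is_reference, ]
  expect_gt(max(refs$PC1) + 1e-6, max(mods$PC1) - 5)
  expect_lt(min(refs$PC1) - 1e-6, min(mods$PC1) + 5)
})

test_that("outlier pruning removes planted outliers and reaches a fixed point", {
  spec <- toy_spec(noise_sd = 0.1)
  cluster <- make_hinge_ensemble(spec, 40, seed = 23,
                                 angles = runif(40, 134, 138))
  # tight cluster: nothing to prune
  res0 <- prune_outliers(cluster)
  expect_length(res0$kept, 40)
  expect_identical(nrow(res0$removed), 0L)
  # plant 5 models far outside the cluster's angle range
  outl <- make_hinge_ensemble(spec, 5, seed = 24,
                              angles = c(170, 171, 172, 173, 174))
  outl <- lapply(outl, function(m) {
    m$model_id <- paste0("out_", m$model_id); m
  })
  res <- prune_outliers(c(cluster, outl))
  expect_setequal(res$removed$model_id,
                  vapply(outl, function(m) m$model_id, character(1)))
  expect_length(res$kept, 40)
  # pruning the pruned set removes nothing further
  kept_models <- c(cluster, outl)[match(res$kept, vapply(
    c(cluster, outl), function(m) m$model_id, character(1)))]
  res2 <- prune_outliers(kept_models)
  expect_identical(nrow(res2$removed), 0L)
  # monotonicity: a laxer threshold never removes more
  res_lax <- prune_outliers(c(cluster, outl), k = 8)
  expect_lte(nrow(res_lax$removed), nrow(res$removed))
  # manual exclusion honored
  res_man <- prune_outliers(cluster,
                            manual_exclude = cluster[[1]]$model_id)
  expect_false(cluster[[1]]$model_id %in% res_man$kept)
})
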