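test_that("confusion_metrics matches the worked confusion-table example", {
  m <- confusion_metrics(10, 90, 2, 9)
  # independent oracle: TP = 8, FN = 2, TN = 81, FP = 9
  expect_equal(m$sn, 0.8)
  expect_equal(m$sp, 0.9)
  expect_equal(m$acc, 0.89)
  expect_equal(m$mcc, (8 * 81 - 9 * 2) / sqrt(17 * 10 * 90 * 83))
  expect_equal(m$mcc, 0.559, tolerance = 1e-3)
})

test_that("confusion_metrics handles the perfect and all-wrong limits", {
  perfect <- confusion_metrics(5, 20, 0, 0)
  expect_equal(c(perfect$sn, perfect$sp, perfect$acc, perfect$mcc), c(1, 1, 1, 1))
  wrong <- confusion_metrics(5, 20, 5, 20)
  expect_equal(c(wrong$sn, wrong$sp, wrong$acc, wrong$mcc), c(0, 0, 0, -1))

  # everything called positive: MCC denominator is zero -> flagged 0
  degenerate <- confusion_metrics(5, 20, 0, 20)
  expect_false(degenerate$mcc_defined)
  expect_equal(degenerate$mcc, 0)

  expect_error(confusion_metrics(5, 20, 6, 0), class = "nitrotyr_contract_error")
  expect_error(confusion_metrics(0, 20, 0, 0), class = "nitrotyr_contract_error")
})

test_that("jackknife twins are classified by their own class matrix", {
  b <- make_bench(pos = c("AYC", "AYC"), neg = c("GYG", "GYG"))
  ev <- jackknife_eval(b, xi = 0)
  expect_equal(ev$metrics$acc, 1)
  expect_equal(ev$scores$call, b$label)
  # held-out positive still matches the matrix built from its twin
  expect_equal(ev$scores$phi_pos[1], 2)
})

test_that("symmetric classes give delta zero everywhere at xi = 0", {
  b <- make_bench(pos = c("AYC", "AYC"), neg = c("AYC", "AYC"))
  ev <- jackknife_eval(b, xi = 0)
  expect_equal(ev$scores$delta_raw, rep(0, 4))
})

test_that("decremental jackknife equals explicit retraining", {
  sizes <- list(c(7, 19), c(16, 28))
  for (case in seq_along(sizes)) {
    b <- random_bench(n_pos = sizes[[case]][1], n_neg = sizes[[case]][2],
                      half_width = 2, seed = 100 + case)
    ev <- jackknife_eval(b, xi = 0)
    oracle <- oracle_jackknife_calls(b, xi = 0)
    expect_equal(ev$scores$phi_pos, oracle$phi_pos, tolerance = 1e-12)
    expect_equal(ev$scores$phi_neg, oracle$phi_neg, tolerance = 1e-12)
    expect_equal(ev$scores$call, oracle$call)
  }
  # single-residue encoder takes the same decremental path
  b <- random_bench(8, 10, 2, seed = 103)
  ev <- jackknife_eval(b, encoder = "single", xi = 0)
  oracle <- oracle_jackknife_calls(b, encoder = "single", xi = 0)
  expect_equal(ev$scores$phi_pos, oracle$phi_pos, tolerance = 1e-12)
  expect_equal(ev$scores$phi_neg, oracle$phi_neg, tolerance = 1e-12)
})

test_that("nested-xi jackknife tunes without the held-out sample", {
  b <- random_bench(6, 8, 2, seed = 104)
  ev <- jackknife_eval(b, xi = "nested")
  # oracle: explicit leave-one-out with per-fold tuning on the rest
  for (i in c(1, 7, 14)) {
    m0 <- nitro_train(b[-i, ], xi = 0)
    xi_i <- tune_xi(score_peptides(b$peptide[-i], m0)$delta, b$label[-i])
    expect_equal(ev$scores$xi[i], xi_i)
  }
})

test_that("k-fold with singleton folds degenerates to the jackknife", {
  b <- random_bench(6, 9, 2, seed = 111)
  jk <- jackknife_eval(b, xi = "shared")
  kf <- kfold_eval(b, k = nrow(b), seed = 1, xi = "shared")
  expect_equal(kf$scores$delta_raw, jk$scores$delta_raw)
  expect_equal(kf$scores$call, jk$scores$call)
  expect_equal(kf$metrics[c("sn", "sp", "acc", "mcc")],
               jk$metrics[c("sn", "sp", "acc", "mcc")])
})

test_that("k-fold is reproducible and validates its preconditions", {
  b <- random_bench(12, 20, 2, seed = 112)
  e1 <- kfold_eval(b, k = 4, seed = 7)
  e2 <- kfold_eval(b, k = 4, seed = 7)
  expect_equal(e1$scores, e2$scores)
  expect_equal(e1$metrics, e2$metrics)
  e3 <- kfold_eval(b, k = 4, seed = 8)
  expect_false(identical(e1$scores$fold, e3$scores$fold))

  expect_error(kfold_eval(b, k = 13, seed = 1), class = "nitrotyr_data_error")
  expect_error(kfold_eval(b, k = 1, seed = 1), class = "nitrotyr_data_error")
})

test_that("k-fold recovers a strongly planted motif", {
  motif <- motif_spec(subsite = c(1, 2, 5), first = c("D", "E", "Y"),
                      second = c("E", "Y", "D"), prob = c(1, 1, 1))
  b <- generate_benchmark(n_pos = 120, n_neg = 240, half_width = 3,
                          motif = motif, seed = 5)
  ev <- kfold_eval(b, k = 10, seed = 2, xi = "shared")
  expect_gt(ev$metrics$acc, 0.95)
})

test_that("roc_curve is monotone, exact on separable data, and rank-equivalent", {
  perfect <- roc_curve(c(1, 2, 10, 11), c("negative", "negative", "positive", "positive"))
  expect_equal(perfect$auc, 1)

  withr::with_seed(21, {
    scores <- rnorm(300)
    labels <- sample(c("positive", "negative"), 300, TRUE)
  })
  rc <- roc_curve(scores, labels)
  expect_true(all(diff(rc$points$fpr) >= 0))
  expect_true(all(diff(rc$points$tpr) >= 0))
  expect_equal(rc$points$fpr[1], 0)
  expect_equal(utils::tail(rc$points$tpr, 1), 1)

  # AUC equals the normalized Mann-Whitney U statistic
  u <- stats::wilcox.test(scores[labels == "positive"],
                          scores[labels == "negative"], exact = FALSE)$statistic
  expect_equal(rc$auc, unname(u) / (sum(labels == "positive") * sum(labels == "negative")),
               tolerance = 1e-12)

  expect_error(roc_curve(1:3, rep("positive", 3)), class = "nitrotyr_data_error")
})

test_that("roc_curve agrees with pROC on random scores", {
  withr::with_seed(33, {
    scores <- c(rnorm(80, 0.5), rnorm(120))
    labels <- rep(c("positive", "negative"), c(80, 120))
  })
  ours <- roc_curve(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores,
    levels = c("negative", "positive"), direction = "<", quiet = TRUE
  )))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("labels independent of scores give chance-level AUC", {
  withr::with_seed(41, {
    scores <- rnorm(2000)
    labels <- sample(c("positive", "negative"), 2000, TRUE)
  })
  expect_equal(roc_curve(scores, labels)$auc, 0.5, tolerance = 0.05)
})

test_that("jackknife accuracy grows with the planted effect size", {
  accs <- vapply(seq_along(seq(0, 1, by = 0.25)), function(i) {
    p <- seq(0, 1, by = 0.25)[i]
    motif <- if (p == 0) NULL else {
      motif_spec(subsite = c(1, 2), first = c("D", "E"),
                 second = c("E", "Y"), prob = c(p, p))
    }
    b <- generate_benchmark(n_pos = 250, n_neg = 250, half_width = 3,
                            motif = motif, seed = 300 + i)
    jackknife_eval(b, xi = "shared")$metrics$acc
  }, numeric(1))
  expect_gt(stats::cor(accs, seq(0, 1, by = 0.25), method = "spearman"), 0.9)
})

test_that("window sweep returns one AUC per half-width and favors windows containing the signal", {
  motif <- motif_spec(subsite = 1, first = "D", second = "E", prob = 0.9)
  gen <- generate_annotated_proteins(n_proteins = 120, protein_length = 60,
                                     sites_per_protein = 2, motif = motif,
                                     half_width = 2, seed = 9)
  sweep <- window_size_sweep(gen$proteins, gen$sites, half_widths = c(1, 2),
                             k = 5, seed = 3)
  expect_equal(sweep$half_width, c(1L, 2L))
  expect_equal(nrow(sweep), 2L)
  # the planted pair sits at offsets (-2, -1): only l = 2 contains all of it
  expect_gte(sweep$auc[2], sweep$auc[1])

  single <- window_size_sweep(gen$proteins, gen$sites, half_widths = 2, k = 5, seed = 3)
  b2 <- build_benchmark(gen$proteins, gen$sites, half_width = 2)
  expect_equal(single$auc, kfold_eval(b2, k = 5, seed = 3)$auc)
})

test_that("evaluation reports serialize to TSV and key-value text", {
  b <- random_bench(8, 12, 2, seed = 121)
  ev <- jackknife_eval(b, xi = 0)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_eval_report(ev, f)
  tab <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(tab$acc, ev$metrics$acc)
  expect_equal(tab$method, "jackknife")
  kv <- readLines(paste0(f, ".txt"))
  expect_true(any(grepl("^acc: ", kv)))
})

test_that("tidy, glance and autoplot expose evaluation results", {
  b <- random_bench(10, 15, 2, seed = 131)
  ev <- kfold_eval(b, k = 5, seed = 2)
  td <- tidy(ev)
  expect_equal(nrow(td), nrow(b))
  gl <- glance(ev)
  expect_equal(gl$acc, ev$metrics$acc)
  expect_s3_class(autoplot(ev), "ggplot")

  m <- nitro_train(b)
  expect_s3_class(autoplot(m), "ggplot")
  expect_equal(glance(m)$n_pos, 10L)
  td_m <- tidy(m)
  expect_true(all(td_m$frequency > 0))
  # triplets reproduce the matrix
  z <- m$z_plus
  pos_rows <- td_m[td_m$class == "positive", ]
  expect_equal(sum(pos_rows$frequency), sum(z))
})
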