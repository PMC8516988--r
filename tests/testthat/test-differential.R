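test_that("unpaired t-test matches the textbook formulas and documented limits", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  got <- unpaired_t_test(x, y)
  want <- oracle_student_t(x, y)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$df, want$df)
  expect_equal(got$p, want$p, tolerance = 1e-12)

  set.seed(3)
  for (i in 1:10) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1), 0.5)
    expect_equal(unpaired_t_test(a, b)$p, oracle_student_t(a, b)$p,
                 tolerance = 1e-10)
    expect_equal(unpaired_t_test(a, b, "welch")$p, oracle_welch_t(a, b)$p,
                 tolerance = 1e-10)
  }

  same <- c(2, 4, 9)
  expect_equal(unpaired_t_test(same, same), list(t = 0, df = 4, p = 1))
  expect_equal(unpaired_t_test(c(5, 5), c(5, 5))$p, 1)
  expect_equal(unpaired_t_test(c(5, 5), c(7, 7))$p, 0)
  expect_error(unpaired_t_test(1, c(1, 2)), "at least 2")
  expect_error(unpaired_t_test(c(1, NA, 3), c(1, 2)), "finite")
})

test_that("fold changes are T-relative-to-N group-mean contrasts", {
  # identical groups -> null fold changes
  m <- matrix(c(0.4, 0.6, 0.4, 0.6, 0.4, 0.6, 0.4, 0.6), 2)
  e <- matrix(2, 2, 4)
  prof <- manual_profile(m, e, group = c("T", "T", "N", "N"))
  fc <- fold_changes(prof)
  expect_equal(fc$fc_meth_ratio, c(1, 1))
  expect_equal(fc$fc_m6a_log2, c(0, 0))
  expect_equal(fc$fc_ge_log2, c(0, 0))

  # 2-probe, (2,2)-sample toy instance against hand arithmetic
  meth <- rbind(c(0.2, 0.4, 0.5, 0.5), c(0.8, 0.6, 0.7, 0.7))
  expr <- rbind(c(8, 4, 16, 16), c(2, 2, 4, 4))
  prof <- manual_profile(meth, expr, group = c("T", "T", "N", "N"))
  fc <- fold_changes(prof)
  expect_equal(fc$fc_meth_ratio, c(mean(c(0.2, 0.4)) / 0.5,
                                   mean(c(0.8, 0.6)) / 0.7))
  expect_equal(fc$fc_m6a_log2,
               c(mean(log2(c(8 * 0.2, 4 * 0.4))) - mean(log2(c(16 * 0.5, 16 * 0.5))),
                 mean(log2(c(2 * 0.8, 2 * 0.6))) - mean(log2(c(4 * 0.7, 4 * 0.7)))))
  expect_equal(fc$fc_ge_log2, c(mean(log2(c(8, 4))) - 4, 1 - 2))

  # a planted IP-channel shift of -3 log2 with no expression shift appears as
  # fc_m6a_log2 = -3 and a small negative fc_ge_log2 at zero noise
  cfg <- sim_config(n_probes = 40, noise_log2_sd = 0, flag_absent_rate = 0,
                    frac_diff_meth = 0.25, meth_effect_log2 = -3,
                    frac_diff_expr = 0, seed = 31)
  sim <- generate_dataset(cfg)
  prof <- quantify(sim$dataset, quantile_norm = FALSE)
  fc <- fold_changes(prof)
  truth <- sim$truth[match(fc$probe_id, sim$truth$probe_id), ]
  planted <- truth$is_diff_meth != 0
  expect_equal(fc$fc_m6a_log2[planted], rep(-3, sum(planted)),
               tolerance = 1e-9)
  expect_true(all(fc$fc_ge_log2[planted] < 0 & fc$fc_ge_log2[planted] > -3))
})

test_that("regulation classes follow the two independent axes", {
  thr <- classification_thresholds()
  rec <- data.frame(fc_m6a_log2 = -3.1482429, fc_ge_log2 = -0.873422863,
                    p_m6a = 0.01, p_ge = 0.01)
  expect_identical(classify_regulation(rec, thr), "Hypo-down")
  rec2 <- data.frame(fc_m6a_log2 = -3.8966634, fc_ge_log2 = 3.489528549,
                     p_m6a = 0.01, p_ge = 0.01)
  expect_identical(classify_regulation(rec2, thr), "Hypo-up")
  null_rec <- data.frame(fc_m6a_log2 = 0, fc_ge_log2 = 0, p_m6a = 1, p_ge = 1)
  expect_identical(classify_regulation(null_rec, thr), "ns")

  # exactly one label per record, whatever the inputs
  set.seed(5)
  recs <- data.frame(fc_m6a_log2 = rnorm(200), fc_ge_log2 = rnorm(200),
                     p_m6a = runif(200), p_ge = runif(200))
  labels <- classify_regulation(recs, thr)
  expect_length(labels, 200)
  expect_true(all(labels %in% c("Hyper-up", "Hyper-down", "Hypo-up",
                                "Hypo-down", "ns")))
  # significance on one axis only is not enough for a combined class
  one_axis <- data.frame(fc_m6a_log2 = -2, fc_ge_log2 = -2,
                         p_m6a = 0.01, p_ge = 0.8)
  expect_identical(classify_regulation(one_axis, thr), "ns")

  # fold-change thresholds tighten the calls
  tight <- classification_thresholds(fc_log2_min = 1)
  weak <- data.frame(fc_m6a_log2 = -0.5, fc_ge_log2 = -2,
                     p_m6a = 0.01, p_ge = 0.01)
  expect_identical(classify_regulation(weak, tight), "ns")

  # the meth axis classifies on the linear methylation ratio
  mrec <- data.frame(fc_meth_ratio = 0.67, fc_ge_log2 = -1,
                     p_meth = 0.01, p_ge = 0.01)
  expect_identical(classify_regulation(mrec, thr, axis = "meth"), "Hypo-down")
})

test_that("top_table sorts stably with probe_id tie-breaks and respects filters", {
  recs <- reference_mrna_records()
  recs$meth_status <- "hypo"
  recs$expr_status <- ifelse(recs$fc_ge_log2 < 0, "down", "up")
  recs$regulation <- paste0("Hypo-", recs$expr_status)

  # n larger than available rows returns everything
  expect_identical(nrow(top_table(recs, n = 100, key = "m6a_fc_asc")), 20L)

  # within the Hypo-down class the most hypo-methylated mRNA comes first
  top <- top_table(recs, n = 10, key = "m6a_fc_asc",
                   filter = list(regulation = "Hypo-down"))
  expect_identical(top$gene_symbol[1], "BCL2A1")
  expect_identical(nrow(top), 10L)

  # random records: ordering equals a brute-force sort, ties by probe_id
  set.seed(9)
  rnd <- data.frame(probe_id = sprintf("P%02d", sample(1:50)),
                    fc_m6a_log2 = sample(rep(rnorm(10), 5)),
                    stringsAsFactors = FALSE)
  got <- top_table(rnd, n = 50, key = "m6a_fc_asc")
  want <- rnd[order(rnd$fc_m6a_log2, rnd$probe_id), ]
  expect_identical(got$probe_id, want$probe_id)
  desc <- top_table(rnd, n = 50, key = "m6a_fc_desc")
  expect_identical(desc$probe_id,
                   rnd[order(-rnd$fc_m6a_log2, rnd$probe_id), ]$probe_id)
})

test_that("hierarchical clustering is deterministic and agglomerates nearest pairs first", {
  # two identical rows among four merge first
  x <- rbind(a = c(0, 0), b = c(5, 5), c = c(0, 0), d = c(9, 1))
  cl <- hierarchical_cluster(x)
  first <- cl$tree$merge[1, ]
  expect_setequal(cl$tree$labels[-first], c("a", "c"))

  # 1-D set {0, 1, 10, 11}: (0,1) and (10,11) merge before the final join
  y <- matrix(c(0, 1, 10, 11), 4, 1,
              dimnames = list(c("p", "q", "r", "s"), NULL))
  cl <- hierarchical_cluster(y)
  merged_pairs <- lapply(1:2, function(i) {
    idx <- cl$tree$merge[i, ]
    cl$tree$labels[-idx]
  })
  expect_true(any(vapply(merged_pairs, setequal, TRUE, y = c("p", "q"))))
  expect_true(any(vapply(merged_pairs, setequal, TRUE, y = c("r", "s"))))

  # permuting the input rows changes nothing (rows sorted by name internally)
  set.seed(2)
  z <- matrix(rnorm(40), 8, dimnames = list(letters[1:8], NULL))
  cl1 <- hierarchical_cluster(z)
  cl2 <- hierarchical_cluster(z[sample(1:8), ])
  expect_identical(cl1$newick, cl2$newick)
  expect_identical(cl1$order, cl2$order)
  expect_match(cl1$newick, "^\\(.*\\);$")

  expect_error(hierarchical_cluster(matrix(c(1, NA), 2, 1,
                                           dimnames = list(c("u", "v"), NULL))),
               "non-finite")
})

test_that("swapping group labels negates log2 fold changes, inverts the ratio, keeps p-values", {
  sim <- generate_dataset(sim_config(n_probes = 60, seed = 17))
  prof <- quantify(sim$dataset)
  tab <- differential_table(prof)
  swapped <- prof
  swapped$samples$group <- c(T = "N", N = "T")[prof$samples$group]
  tab2 <- differential_table(swapped)
  expect_equal(tab2$fc_m6a_log2, -tab$fc_m6a_log2, tolerance = 1e-10)
  expect_equal(tab2$fc_ge_log2, -tab$fc_ge_log2, tolerance = 1e-10)
  expect_equal(tab2$fc_meth_ratio, 1 / tab$fc_meth_ratio, tolerance = 1e-10)
  expect_equal(tab2$p_m6a, tab$p_m6a, tolerance = 1e-10)
  expect_equal(tab2$p_meth, tab$p_meth, tolerance = 1e-10)
  expect_equal(tab2$p_ge, tab$p_ge, tolerance = 1e-10)
})

test_that("differential_table carries consistent classes and optional BH columns", {
  sim <- generate_dataset(sim_config(n_probes = 80, seed = 23))
  prof <- quantify(sim$dataset)
  tab <- differential_table(prof, adjust = TRUE)
  expect_true(all(tab$p_m6a >= 0 & tab$p_m6a <= 1, na.rm = TRUE))
  expect_true(all(tab$fc_meth_ratio > 0, na.rm = TRUE))
  expect_identical(tab$regulation,
                   classify_regulation(tab, classification_thresholds()))
  expect_equal(tab$padj_m6a, p.adjust(tab$p_m6a, "BH"))
  combined <- tab$meth_status != "ns" & tab$expr_status != "ns"
  expect_true(all(tab$regulation[!combined] == "ns"))
  expect_true(all(tab$regulation[combined] != "ns"))
})
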