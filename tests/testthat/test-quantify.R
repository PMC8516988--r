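test_that("spike-in normalization subtracts the mean log2 spike intensity per sample and channel", {
  # all spike-ins at raw 1 -> mean log2 spike = 0 -> log2 values unchanged
  ds <- tiny_dataset(matrix(c(2, 4, 8, 16), 2), matrix(c(1, 1, 2, 2), 2),
                     spike_value = 1)
  nc <- spikein_normalize(ds)
  expect_equal(unname(nc$ip_norm), log2(matrix(c(2, 4, 8, 16), 2)))
  expect_false(any(nc$probes$rna_type == "spike-in"))

  # one spike-in at raw 4, probe at raw 8 -> normalized log2 = 3 - 2 = 1
  ds <- tiny_dataset(matrix(8, 1, 2), matrix(8, 1, 2), spike_value = 4,
                     group = c("T", "N"))
  nc <- spikein_normalize(ds)
  expect_equal(unname(nc$ip_norm), matrix(1, 1, 2))

  # random 10x4 fixture equals per-column geometric-mean division on the
  # linear scale
  set.seed(42)
  ip <- matrix(2^rnorm(40, 8), 10)
  sup <- matrix(2^rnorm(40, 8), 10)
  ds <- tiny_dataset(ip, sup, group = c("T", "T", "N", "N"), n_spike = 3,
                     spike_value = 5)
  nc <- spikein_normalize(ds)
  spike <- ds$probes$rna_type == "spike-in"
  geo <- function(m) apply(m, 2, function(v) exp(mean(log(v))))
  expect_equal(2^nc$ip_norm,
               sweep(ds$ip[!spike, ], 2, geo(ds$ip[spike, , drop = FALSE]), "/"),
               tolerance = 1e-12)
  expect_equal(2^nc$sup_norm,
               sweep(ds$sup[!spike, ], 2, geo(ds$sup[spike, , drop = FALSE]), "/"),
               tolerance = 1e-12)
})

test_that("normalization fails without spike-ins", {
  ds <- tiny_dataset(matrix(c(2, 4, 8, 16), 2), matrix(c(1, 1, 2, 2), 2))
  ds$probes$rna_type <- rep("mRNA", nrow(ds$probes))
  expect_error(spikein_normalize(ds), "spike-in")
})

test_that("flag filter keeps probes with enough Present/Marginal calls", {
  flags <- rbind(rep("A", 10),
                 c("M", rep("A", 9)),
                 c("P", "M", rep("A", 8)))
  expect_identical(filter_by_flags(flags, min_present = 1),
                   c(FALSE, TRUE, TRUE))
  expect_identical(filter_by_flags(flags, min_present = 2),
                   c(FALSE, FALSE, TRUE))
  # random matrix against a brute-force count
  set.seed(7)
  fl <- matrix(sample(c("P", "M", "A"), 200, replace = TRUE), 20)
  brute <- vapply(seq_len(20), function(i) {
    sum(fl[i, ] %in% c("P", "M")) >= 3
  }, logical(1))
  expect_identical(filter_by_flags(fl, min_present = 3), brute)
  expect_error(filter_by_flags(fl, min_present = 0))
})

test_that("% Modified is IP/(IP+Sup) with a missing-value floor", {
  expect_equal(percent_modified(3, 3), 0.5)
  expect_equal(percent_modified(5, 0), 1.0)
  expect_equal(percent_modified(3, 1), 0.75)
  expect_true(is.na(percent_modified(0, 0)))
  expect_true(is.na(percent_modified(2^-22, 2^-22)))
  expect_error(percent_modified(-1, 2), "non-negative")
  m <- percent_modified(matrix(c(1, 0, 3, 0), 2), matrix(c(1, 0, 1, 8), 2))
  expect_equal(m, matrix(c(0.5, NA, 0.75, 0), 2))
})

test_that("quantile normalization matches the sorted-mean oracle and its postconditions", {
  # identical columns are a fixed point
  x <- matrix(rep(c(3, 1, 2), 3), 3)
  expect_equal(quantile_normalize(x), x)

  # 3x3 integer instance against the brute-force oracle
  y <- matrix(c(5, 2, 3, 4, 1, 4, 3, 4, 6), 3)
  expect_equal(quantile_normalize(y), oracle_quantile_normalize(y))

  # definitional postconditions on a random instance
  set.seed(11)
  z <- matrix(rexp(60), 12)
  q <- quantile_normalize(z)
  for (j in 2:ncol(q)) expect_equal(sort(q[, j]), sort(q[, 1]))
  for (j in seq_len(ncol(q))) {
    expect_identical(order(q[, j]), order(z[, j]))
  }
  # idempotent
  expect_equal(quantile_normalize(q), q, tolerance = 1e-12)

  expect_warning(out <- quantile_normalize(z[, 1, drop = FALSE]), "2 columns")
  expect_equal(out, z[, 1, drop = FALSE])
})

test_that("quantify composes the stages and drops flag-failing probes", {
  cfg <- sim_config(n_probes = 50, noise_log2_sd = 0, flag_absent_rate = 0,
                    frac_diff_meth = 0, frac_diff_expr = 0,
                    meth_baseline_range = c(0.6, 0.6), seed = 4)
  prof <- quantify(generate_dataset(cfg)$dataset)
  expect_equal(unname(prof$meth_level),
               matrix(0.6, nrow(prof$meth_level), ncol(prof$meth_level)),
               tolerance = 1e-10)

  # a probe flagged A everywhere is absent from the profile
  ds <- tiny_dataset(matrix(2, 3, 4), matrix(2, 3, 4),
                     flags = rbind(matrix("P", 2, 4), rep("A", 4)),
                     group = c("T", "T", "N", "N"))
  prof <- quantify(ds)
  expect_identical(rownames(prof$meth_level), c("P001", "P002"))
  expect_identical(unname(prof$kept_probes), c(TRUE, TRUE, FALSE))

  # algebraic identity of the three statistics
  sim <- generate_dataset(sim_config(seed = 8))
  prof <- quantify(sim$dataset)
  expect_equal(prof$expression * prof$meth_level, prof$m6a_quantity)
})

test_that("meth_level is invariant to common per-sample rescaling and per-channel dye effects", {
  sim <- generate_dataset(sim_config(n_probes = 30, seed = 15))
  ds <- sim$dataset
  prof <- quantify(ds)

  # common positive rescaling of both channels of each sample (spike-ins
  # included) cancels entirely
  f <- runif(ncol(ds$ip), 0.5, 2)
  ds2 <- ds
  ds2$ip <- sweep(ds$ip, 2, f, "*")
  ds2$sup <- sweep(ds$sup, 2, f, "*")
  prof2 <- quantify(ds2)
  expect_equal(prof2$meth_level, prof$meth_level, tolerance = 1e-12)
  expect_equal(prof2$expression, prof$expression, tolerance = 1e-12)

  # channel-specific multiplicative dye effects leave meth_level unchanged
  f_ip <- runif(ncol(ds$ip), 0.5, 2)
  f_sup <- runif(ncol(ds$ip), 0.5, 2)
  ds3 <- ds
  ds3$ip <- sweep(ds$ip, 2, f_ip, "*")
  ds3$sup <- sweep(ds$sup, 2, f_sup, "*")
  prof3 <- quantify(ds3)
  expect_equal(prof3$meth_level, prof$meth_level, tolerance = 1e-12)
})
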