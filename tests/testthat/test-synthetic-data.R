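test_that("configuration validation catches bad proportions and dispersion", {
  expect_error(cohort_config(prognostic_fraction = 1.2, seed = 1),
               "proportion")
  expect_error(cohort_config(nb_dispersion = 0, seed = 1), "> 0")
  expect_error(cohort_config(block_rho = 1, seed = 1), "0, 1")
  bad_mix <- data.frame(bin = c("<10", "10-99"), prop = c(0.5, 0.4))
  expect_error(cohort_config(abundance_mix = bad_mix, seed = 1), "sum to 1")
  expect_error(cohort_config(seed = 1, n_events_target = NULL,
                             censor_rate = NULL), "required")
  expect_error(cohort_config(), "seed")
})

test_that("a fixed seed reproduces the cohort byte for byte", {
  cfg <- cohort_config(n_patients = 30L, n_features = 100L,
                       n_events_target = 10L, block_sizes = c(10L, 5L),
                       seed = 9L)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$counts, c2$counts)
  expect_identical(c1$survival, c2$survival)
  expect_identical(c1$truth, c2$truth)
})

test_that("zero prognostic fraction gives an all-null truth table and flat p", {
  coh <- simulate_cohort(cohort_config(
    n_patients = 136L, n_features = 500L, prognostic_fraction = 0,
    n_events_target = 26L, seed = 77L))
  expect_true(all(coh$truth$beta_true == 0))
  keep <- max_count_filter(coh$counts)$keep
  norm <- third_quartile_normalize(log2_transform(coh$counts[keep, ]))
  scr <- survival_screen(norm, coh$survival)
  # null p-values are approximately uniform: KS test should not reject badly
  expect_gt(suppressWarnings(ks.test(scr$p, "punif"))$p.value, 1e-4)
})

test_that("tight blocks stay correlated on the observed count scale", {
  # the check isolates the latent correlation mechanism: mid-to-high
  # abundance and mild dispersion keep count-noise attenuation secondary
  mix <- data.frame(bin = c("100-999", ">=1000"), prop = c(0.8, 0.2))
  all_high <- vapply(1:200, function(i) {
    coh <- simulate_cohort(cohort_config(
      n_patients = 136L, n_features = 30L, n_events_target = 26L,
      block_sizes = 10L, block_rho = 0.95, abundance_mix = mix,
      nb_dispersion = 0.1, seed = 3000L + i))
    x <- log2_transform(coh$counts[coh$truth$block == 1L, ])
    cc <- cor(t(x))
    all(cc[upper.tri(cc)] > 0.6)
  }, NA)
  expect_gte(mean(all_high), 0.99)
})

test_that("realized event counts track the calibration target", {
  events <- vapply(1:100, function(i)
    sum(simulate_cohort(cohort_config(
      n_patients = 136L, n_features = 50L, n_events_target = 26L,
      block_sizes = integer(), seed = 400L + i))$survival$event), 0L)
  expect_lt(abs(mean(events) - 26), 3 * sqrt(26) / sqrt(100) * 3)
  expect_true(all(abs(events - 26) <= 3 * sqrt(26) + 1))
})

test_that("censor_rate drives censoring when no event target is given", {
  coh <- simulate_cohort(cohort_config(
    n_patients = 400L, n_features = 20L, n_events_target = NULL,
    block_sizes = integer(), censor_rate = 0.75, seed = 55L))
  expect_lt(abs(mean(coh$survival$event) - 0.25), 0.08)
})

test_that("per-bin feature medians land in their abundance bins", {
  coh <- simulate_cohort(cohort_config(
    n_patients = 136L, n_features = 2000L, seed = 66L))
  med <- apply(coh$counts, 1, median)
  # NB noise moves some features across bin edges; the bulk must agree
  lo <- c("<10" = 0, "10-99" = 10, "100-999" = 100, ">=1000" = 1000)
  hi <- c("<10" = 10, "10-99" = 100, "100-999" = 1000, ">=1000" = Inf)
  in_bin <- med >= lo[coh$truth$bin] * 0.5 &
    med < pmin(hi[coh$truth$bin] * 2, Inf)
  expect_gte(mean(in_bin), 0.95)
  # and bin occupancy matches the configured mix within sampling error
  frac <- table(coh$truth$bin)[coh$config$abundance_mix$bin] / 2000
  expect_true(all(abs(frac - coh$config$abundance_mix$prop) < 0.05))
})

test_that("simulated intron counts co-express with their features", {
  mix <- data.frame(bin = c("100-999", ">=1000"), prop = c(0.8, 0.2))
  coh <- simulate_cohort(cohort_config(
    n_patients = 136L, n_features = 300L, abundance_mix = mix,
    block_sizes = integer(), seed = 88L))
  introns <- simulate_intron_counts(coh)
  x <- log2_transform(coh$counts)
  xi <- log2_transform(introns)
  cors <- vapply(seq_len(nrow(x)), function(i) cor(x[i, ], xi[i, ]), 0)
  expect_gt(median(cors), 0.5)
  expect_lt(median(cors), 0.85)
  # intron abundance runs about threefold higher
  expect_gt(median(rowMeans(introns) / rowMeans(coh$counts)), 2)
})

test_that("two-platform simulation spans the zero-noise and pure-noise poles", {
  sim0 <- simulate_two_platform(rnorm(50, 0, 0.4), 0, 0, seed = 5)
  expect_equal(lin_ccc(sim0$log_hr_a, sim0$log_hr_b), 1)
  expect_identical(sim0, simulate_two_platform(rnorm(50, 0, 0.4), 0, 0,
                                               seed = 5))

  # large equal noise on zero effects: CCC ~ 0 on average
  cccs <- vapply(1:100, function(i) {
    sim <- simulate_two_platform(rep(0, 200), 1, 1, seed = 600 + i)
    lin_ccc(sim$log_hr_a, sim$log_hr_b)
  }, 0)
  expect_lt(abs(mean(cccs)), 0.05)
})

test_that("cohort files round-trip through the writers", {
  coh <- simulate_cohort(cohort_config(
    n_patients = 12L, n_features = 40L, n_events_target = 4L,
    block_sizes = integer(), seed = 14L))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  counts <- read_count_matrix(file.path(dir, "counts.tsv"))
  expect_equal(counts, coh$counts)
  surv <- read_survival(file.path(dir, "survival.csv"), counts = counts)
  expect_equal(surv$event, coh$survival$event)
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg$seed, 14L)
})
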