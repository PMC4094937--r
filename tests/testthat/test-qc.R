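test_that("detection p-value is the upper tail of the summed background model", {
  negs <- data.table::data.table(
    probe_id = rep(sprintf("neg%02d", 1:40), 2),
    sample_id = rep(c("s1", "s2"), each = 40),
    meth = rep(c(90, 110), 40), unmeth = rep(c(190, 210), 40),
    beads = 10L)
  mu <- 100 + 200
  sdsum <- sqrt(stats::sd(rep(c(90, 110), 20))^2 +
                stats::sd(rep(c(190, 210), 20))^2)
  sig <- data.table::data.table(
    probe_id = rep(c("cgA", "cgB"), 2),
    sample_id = rep(c("s1", "s2"), each = 2),
    meth = c(150, 150 + 5 * sdsum, 150, 150),
    unmeth = c(mu - 150, 150 + 5 * sdsum, mu - 150, mu - 150),
    beads = 10L)
  p <- detection_pvalue(sig, negs)
  expect_equal(p["cgA", "s1"], 0.5)
  expect_equal(p["cgA", "s2"], 0.5)
  expect_lt(p["cgB", "s1"], 1e-15)   # 10 sds above background
  expect_error(detection_pvalue(sig, negs[sample_id == "s1"]),
               "s2")
  expect_error(detection_pvalue(sig, negs[1:30]), "negative-control")
})

test_that("planted detection failures are recovered at close to the planted rate", {
  cfg <- sim_config(n_pairs = 6, n_control_replicates = 0,
                    strata = list(stratum_spec("s", "gene_body", "nonCGI", 1500,
                                               c(0.2, 0.6, 0.2), 0.5)),
                    fail_fraction = 0.01, zero_fraction = 0, seed = 3L)
  ds <- simulate_dataset(cfg)
  p <- detection_pvalue(ds$signal, ds$negcontrols)
  expect_true(all(p >= 0 & p <= 1))
  expect_lt(abs(mean(p > 0.01) - 0.01), 0.003)
  # the planted cells themselves are uniform under the null: ~99% flagged
  fc <- ds$truth$fail_cells
  flagged <- mapply(function(pr, sm) p[pr, sm] > 0.01, fc$probe_id, fc$sample_id)
  expect_gt(mean(flagged), 0.95)
})

test_that("sample signal check separates CpG signal from background", {
  ds <- small_sim()
  chk <- sample_signal_check(ds$signal, ds$negcontrols)
  expect_true(all(chk$pass))
  expect_true(all(chk$median_cpg_signal > chk$background_median))
  # odd-count median and an all-background sample
  sig <- data.table::data.table(probe_id = c("a", "b", "c"), sample_id = "s1",
                                meth = c(100, 200, 300), unmeth = 0, beads = 5L)
  negs <- data.table::data.table(probe_id = sprintf("n%d", 1:25),
                                 sample_id = "s1",
                                 meth = 200, unmeth = 200, beads = 5L)
  chk2 <- sample_signal_check(sig, negs)
  expect_equal(chk2$median_meth, 200)
  expect_false(chk2$pass)  # 200 total vs background 200: no separation
})


test_that("probe filtering matches the documented counts on a planted fixture", {
  fx <- make_filter_fixture(1000, 6)
  fx$manifest$ambiguous[1:10] <- TRUE
  fx$manifest$snp_at_cpg[11:15] <- TRUE
  # three clean probes lose one cell each: success 5/6 < 0.95
  for (k in 1:3) fx$meth[20 + k, k] <- 0
  res <- filter_probes(as_long_signal(fx$meth, fx$unmeth, fx$beads),
                       fx$manifest, fx$detp)
  expect_length(res$report$surviving_probes, 982)
  st <- res$report$stages
  expect_equal(st$removed[-1], c(10L, 5L, 3L))
  expect_true(all(st$remaining + cumsum(st$removed) == st$remaining[1]))
  # vacuous success threshold drops nothing at stage 4
  res0 <- filter_probes(as_long_signal(fx$meth, fx$unmeth, fx$beads),
                        fx$manifest, fx$detp,
                        qc_thresholds(probe_success_min = 0))
  expect_equal(res0$report$stages[stage == "success_rate", removed], 0L)
  # unknown probe in signal
  sig_extra <- rbind(as_long_signal(fx$meth, fx$unmeth, fx$beads),
                     data.table::data.table(probe_id = "cgX", sample_id = "s01",
                                            meth = 1, unmeth = 1, beads = 5L))
  expect_error(filter_probes(sig_extra, fx$manifest, fx$detp), "cgX")
})

test_that("a probe failing 2 of 24 samples is dropped, 1 of 24 is kept", {
  fx <- make_filter_fixture(20, 24)
  fx$meth[5, 1:2] <- 0    # success 22/24 ~ 0.917
  fx$meth[6, 1] <- 0      # success 23/24 ~ 0.958
  res <- filter_probes(as_long_signal(fx$meth, fx$unmeth, fx$beads),
                       fx$manifest, fx$detp)
  expect_false("cg0005" %in% res$report$surviving_probes)
  expect_true("cg0006" %in% res$report$surviving_probes)
})

test_that("filtering equals an exhaustive per-cell re-check of every rule", {
  fx <- make_filter_fixture(50, 6, seed = 7)
  withr::with_seed(8, {
    fx$manifest$ambiguous[sample(50, 3)] <- TRUE
    fx$manifest$snp_at_cpg[sample(50, 3)] <- TRUE
    fx$meth[cbind(sample(50, 4), sample(6, 4, replace = TRUE))] <- 0
    fx$detp[cbind(sample(50, 4), sample(6, 4, replace = TRUE))] <- 0.5
    fx$beads[cbind(sample(50, 4), sample(6, 4, replace = TRUE))] <- 1L
  })
  th <- qc_thresholds(probe_success_min = 0.8)
  res <- filter_probes(as_long_signal(fx$meth, fx$unmeth, fx$beads),
                       fx$manifest, fx$detp, th)
  orc <- oracle_filter(fx$meth, fx$unmeth, fx$beads, fx$detp,
                       fx$manifest$ambiguous, fx$manifest$snp_at_cpg, th)
  expect_setequal(res$report$surviving_probes, orc$surviving)
  # NA pattern agrees cell by cell
  ok_pkg <- !is.na(res$signal$meth[orc$surviving, , drop = FALSE])
  expect_identical(unname(ok_pkg), unname(orc$ok[orc$surviving, , drop = FALSE]))
  # accounting conserves probes at every stage
  st <- res$report$stages
  expect_equal(st$remaining[1] - sum(st$removed), length(orc$surviving))
})

test_that("filtering is idempotent and monotone in the detection threshold", {
  fx <- make_filter_fixture(60, 6, seed = 11)
  withr::with_seed(12, {
    fx$detp[cbind(sample(60, 10), sample(6, 10, replace = TRUE))] <-
      stats::runif(10, 0.005, 0.5)
  })
  th <- qc_thresholds()
  res1 <- filter_probes(as_long_signal(fx$meth, fx$unmeth, fx$beads),
                        fx$manifest, fx$detp, th)
  sig2 <- as_long_signal(res1$signal$meth, res1$signal$unmeth, res1$signal$beads)
  res2 <- filter_probes(sig2, fx$manifest,
                        fx$detp[res1$signal$probes, , drop = FALSE], th)
  expect_identical(res2$report$surviving_probes, res1$report$surviving_probes)
  expect_equal(res2$signal$meth, res1$signal$meth)
  n_prev <- -1L
  for (pmax_ in c(0.001, 0.01, 0.05, 0.5, 1)) {
    n <- length(filter_probes(
      as_long_signal(fx$meth, fx$unmeth, fx$beads), fx$manifest, fx$detp,
      qc_thresholds(detection_p_max = pmax_))$report$surviving_probes)
    expect_gte(n, n_prev)
    n_prev <- n
  }
})

test_that("cluster QC: duplicates at distance zero, anticorrelation at the bound", {
  nb <- small_norm()
  beta <- nb$beta
  dup <- beta[, 1, drop = FALSE]
  colnames(dup) <- "dup"
  beta2 <- cbind(beta, dup)
  sheet <- rbind(nb$dataset$samples,
                 data.table::data.table(sample_id = "dup",
                                        pair_id = nb$dataset$samples$pair_id[1],
                                        twin_index = NA_integer_, role = "twin",
                                        sex = "F", age_group = "8-12"))
  cl <- sample_cluster_qc(beta2, nb$dataset$manifest, sheet)
  orig <- colnames(beta)[1]
  expect_equal(cl$dist[orig, "dup"], 0)
  fm <- cl$first_merge
  expect_true(grepl(orig, fm[sample_id == "dup", partners], fixed = TRUE))
  # r = -1 maps to the maximum of the distance transform
  x <- seq(0.05, 0.95, length.out = 100)
  b3 <- cbind(s1 = x, s2 = 1 - x, s3 = plogis(stats::qlogis(x) + 0.3))
  rownames(b3) <- sprintf("cg%03d", 1:100)
  man3 <- data.table::data.table(probe_id = rownames(b3), chrom = "chr1",
                                 position = 1:100, probe_type = "II",
                                 ambiguous = FALSE, snp_at_cpg = FALSE)
  sheet3 <- data.table::data.table(sample_id = c("s1", "s2", "s3"),
                                   pair_id = c("p1", "p1", "p2"),
                                   twin_index = c(1L, 2L, 1L), role = "twin",
                                   sex = "F", age_group = "8-12")
  cl3 <- sample_cluster_qc(b3, man3, sheet3)
  expect_equal(cl3$dist["s1", "s2"], 2)
  expect_error(sample_cluster_qc(b3, man3, sheet3,
                                 qc_thresholds(cluster_sd_min = 10)),
               "SD filter")
})

test_that("control replicates cluster together before joining any twin sample", {
  nb <- small_norm()
  ds <- nb$dataset
  cl <- sample_cluster_qc(nb$beta, ds$manifest, ds$samples)
  reps <- ds$samples[role == "control_replicate", sample_id]
  idx <- match(reps, cl$hclust$labels)
  members <- hclust_members(cl$hclust)
  first_all <- which(vapply(members, function(m) all(idx %in% m), logical(1)))[1]
  expect_identical(sort(members[[first_all]]), sort(idx))
  expect_true(all(cl$first_merge[sample_id %in% reps, co_twin_first]))
  # X/Y and SNP probes are excluded from the probe subset
  expect_lte(cl$n_probes_used, sum(!ds$manifest$snp_at_cpg))
})
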