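test_that("per-CpG statistics apply the class and variability cutoffs exactly", {
  sheet <- make_sheet(2)  # 4 subjects
  b <- rbind(
    constant = rep(0.5, 4),
    boundary_hypo = c(0.3, 0.3, 0.3, 0.3),     # mean 0.3 -> intermediate
    boundary_hyper = rep(0.7, 4),              # mean 0.7 -> hyper
    sparse = c(0.2, 0.4, NA, NA),              # < 3 subjects -> missing
    variable = c(0.2, 0.3, 0.4, 0.5))
  colnames(b) <- sheet$sample_id
  st <- cpg_stats(b, sheet)
  expect_equal(st[probe_id == "constant", sd_beta], 0)
  expect_identical(st[probe_id == "constant", meth_class], "intermediate")
  expect_false(st[probe_id == "constant", most_variable])
  expect_identical(st[probe_id == "boundary_hypo", meth_class], "intermediate")
  expect_identical(st[probe_id == "boundary_hyper", meth_class], "hyper")
  expect_true(is.na(st[probe_id == "sparse", mean_beta]))
  expect_true(is.na(st[probe_id == "sparse", meth_class]))
  # sample SD with n-1 denominator; SD = 0.05 is inclusive-variable
  expect_equal(st[probe_id == "variable", sd_beta],
               sd(c(0.2, 0.3, 0.4, 0.5)))
  b2 <- matrix(c(0.5, 0.55, 0.45, 0.5), 1,
               dimnames = list("edge", sheet$sample_id))
  st2 <- cpg_stats(b2, sheet)
  expect_equal(st2$sd_beta, sd(c(0.5, 0.55, 0.45, 0.5)))
  b3 <- matrix(c(0.4, 0.4, 0.5, 0.5), 1, dimnames = list("e2", sheet$sample_id))
  expect_true(cpg_stats(b3, sheet)$most_variable)  # sd 0.0577 >= 0.05
})

test_that("a nearly pure hypo stratum is classified hypo for >= 95% of CpGs", {
  cfg <- sim_config(n_pairs = 10, n_control_replicates = 0,
                    strata = list(stratum_spec("h", "gene_body", "CGI", 800,
                                               c(1, 0, 0), 0.5)), seed = 13L)
  ds <- simulate_dataset(cfg)
  sheet <- ds$samples
  st <- cpg_stats(plogis(ds$truth$latent), sheet)
  expect_gt(mean(st$meth_class == "hypo"), 0.95)
})

test_that("pair profile correlation reproduces the hand-ranked example and bounds", {
  sheet <- make_sheet(1)
  b <- cbind(c(0.1, 0.2, 0.3, 0.4, 0.5), c(0.1, 0.3, 0.2, 0.4, 0.5))
  dimnames(b) <- list(sprintf("cg%d", 1:5), sheet$sample_id)
  pr <- pairwise_profile_rho(b, sheet)
  expect_equal(pr$rho, 0.9)          # d^2 = 2 -> 1 - 12/120
  expect_equal(pr$n_cpgs, 5L)
  # identity and reversal
  b_id <- cbind(b[, 1], b[, 1]); dimnames(b_id) <- dimnames(b)
  expect_equal(pairwise_profile_rho(b_id, sheet)$rho, 1)
  b_rev <- cbind(b[, 1], 1 - b[, 1]); dimnames(b_rev) <- dimnames(b)
  expect_equal(pairwise_profile_rho(b_rev, sheet)$rho, -1)
  expect_warning(out <- pairwise_profile_rho(b, sheet, cpg_subset = character()),
                 "empty")
  expect_true(is.na(out$rho))
})

test_that("unrelated pairings exclude self and co-twins and detect familial structure", {
  sheet <- make_sheet(2)
  b <- matrix(stats::runif(40), 10, 4,
              dimnames = list(sprintf("cg%d", 1:10), sheet$sample_id))
  un <- unrelated_profile_rho(b, sheet)
  expect_equal(nrow(un$correlations), 4L)  # choose(4,2)=6 minus 2 co-twin
  expect_false(any(un$correlations$subject1 == un$correlations$subject2))
  pairs <- paste(sheet$pair_id[match(un$correlations$subject1, sheet$sample_id)],
                 sheet$pair_id[match(un$correlations$subject2, sheet$sample_id)])
  expect_false(any(pairs %in% c("p01 p01", "p02 p02")))
  # degenerate: all subjects identical
  b_same <- matrix(rep(b[, 1], 4), 10, 4, dimnames = dimnames(b))
  expect_equal(unrelated_profile_rho(b_same, sheet)$mean, 1)
  # generated data: MZ co-twins correlate higher than unrelated subjects
  nb <- small_norm()
  ds <- nb$dataset
  st <- cpg_stats(nb$beta, ds$samples)
  var_ids <- st[most_variable == TRUE, probe_id]
  mz <- pairwise_profile_rho(nb$beta, ds$samples, var_ids)
  un2 <- unrelated_profile_rho(nb$beta, ds$samples, var_ids)
  expect_gt(mean(mz$rho), un2$mean)
})

test_that("cross-pair rho matches an independent mid-rank oracle and its edge rules", {
  sheet <- make_sheet(3)
  b <- rbind(mono = c(0.1, 0.15, 0.2, 0.25, 0.3, 0.35),
             const2 = c(0.1, 0.5, 0.2, 0.5, 0.3, 0.5))
  colnames(b) <- sheet$sample_id  # twin1/twin2 interleaved
  cp <- cross_pair_rho(b, sheet)
  expect_equal(cp[probe_id == "mono", rho], 1)        # co-monotone
  expect_true(is.na(cp[probe_id == "const2", rho]))   # twin-2 constant
  # random 10-pair fixtures against the oracle
  sheet10 <- make_sheet(10)
  withr::with_seed(41, {
    bm <- matrix(stats::runif(200), 10, 20,
                 dimnames = list(sprintf("cg%d", 1:10), sheet10$sample_id))
    bm[sample(200, 12)] <- NA  # some missing cells
  })
  cp10 <- cross_pair_rho(bm, sheet10)
  t1 <- sheet10[twin_index == 1, sample_id]
  t2 <- sheet10[twin_index == 2, sample_id]
  for (i in 1:10) {
    ok <- !is.na(bm[i, t1]) & !is.na(bm[i, t2])
    expected <- if (sum(ok) >= 3)
      oracle_spearman(bm[i, t1][ok], bm[i, t2][ok]) else NA_real_
    expect_equal(cp10$rho[i], expected, tolerance = 1e-12)
  }
  # exchanging the two twin vectors wholesale leaves rho unchanged
  sheet_swap <- data.table::copy(sheet10)
  sheet_swap$twin_index <- 3L - sheet_swap$twin_index
  expect_equal(cross_pair_rho(bm, sheet_swap)$rho, cp10$rho)
})

test_that("rank correlations are exactly invariant to strictly monotone transforms", {
  nb <- small_norm()
  ds <- nb$dataset
  beta <- nb$beta
  cube <- beta^3
  logit_like <- log2(pmax(beta, 1e-12) / pmax(1 - beta, 1e-12))
  r0 <- cross_pair_rho(beta, ds$samples)
  expect_identical(r0$rho, cross_pair_rho(cube, ds$samples)$rho)
  expect_identical(r0$rho, cross_pair_rho(logit_like, ds$samples)$rho)
  p0 <- pairwise_profile_rho(beta, ds$samples)
  expect_identical(p0$rho, pairwise_profile_rho(cube, ds$samples)$rho)
})

test_that("region summaries partition the analyzed CpGs consistently", {
  nb <- small_norm()
  ds <- nb$dataset
  ann <- annotate_cpgs(ds$manifest, ds$genes, ds$tracks)
  st <- cpg_stats(nb$beta, ds$samples)
  rho <- cross_pair_rho(nb$beta, ds$samples)
  summ <- region_summaries(st, ann, rho = rho, variable_only = TRUE)
  all_row <- summ[axis == "all"]
  for (ax in c("gene_region", "cgi_class", "meth_class")) {
    part <- summ[axis == ax]
    expect_equal(sum(part$n_cpgs), all_row$n_cpgs)
    expect_equal(sum(part$pct), 100, tolerance = 1e-9)
    expect_equal(sum(part$mean_rho * part$n_cpgs) / sum(part$n_cpgs),
                 all_row$mean_rho, tolerance = 1e-12)
    expect_true(all(part$min_rho <= part$median_rho &
                    part$median_rho <= part$max_rho))
  }
  # constant rho collapses all summaries to that value
  rho_c <- data.table::copy(rho)
  rho_c$rho[!is.na(rho_c$rho)] <- 0.5
  summ_c <- region_summaries(st, ann, rho = rho_c)
  expect_true(all(summ_c$mean_rho == 0.5 & summ_c$median_rho == 0.5 &
                  summ_c$min_rho == 0.5 & summ_c$max_rho == 0.5))
})

test_that("the imprinted subset keeps only intermediate DMR CpGs", {
  nb <- small_norm()
  ds <- nb$dataset
  ann <- annotate_cpgs(ds$manifest, ds$genes, ds$tracks)
  st <- cpg_stats(nb$beta, ds$samples)
  rho <- cross_pair_rho(nb$beta, ds$samples)
  imp <- imprinted_subset_summary(st, ann, rho = rho)
  expect_gt(imp$n_cpgs, 0)
  expect_equal(imp$n_genes, 1L)
  # the generated imprinted cassette is centered at beta 0.5: most CpGs pass
  n_dmr <- sum(!is.na(ann$imprinted_gene))
  expect_gt(imp$n_cpgs / n_dmr, 0.8)
  # a hyper DMR CpG is excluded
  st2 <- data.table::copy(st)
  dmr_ids <- ann$probe_id[!is.na(ann$imprinted_gene)]
  st2[probe_id %in% dmr_ids, meth_class := "hyper"]
  imp2 <- imprinted_subset_summary(st2, ann, rho = rho)
  expect_equal(imp2$n_cpgs, 0L)
  # no imprinted track -> empty summary
  ann0 <- data.table::copy(ann)
  ann0$imprinted_gene <- NA_character_
  expect_equal(imprinted_subset_summary(st, ann0, rho = rho)$n_cpgs, 0L)
})

test_that("cell-composition weights recover pure, mixed and midpoint samples", {
  withr::with_seed(51, {
    ref <- data.table::data.table(
      probe_id = sprintf("cg%03d", 1:60),
      buccal = stats::runif(60, 0.05, 0.95))
    ref$blood <- pmin(0.98, pmax(0.02, ref$buccal +
                                   sample(c(-1, 1), 60, TRUE) *
                                   stats::runif(60, 0.25, 0.5)))
    noise <- matrix(stats::rnorm(60 * 3, 0, 0.02), 60, 3)
  })
  obs <- cbind(pure = ref$buccal,
               mid = 0.5 * ref$buccal + 0.5 * ref$blood,
               mixed = 0.7 * ref$buccal + 0.3 * ref$blood)
  obs_noisy <- pmin(pmax(obs + noise, 0), 1)
  obs_noisy[, "pure"] <- ref$buccal            # exact pure-tissue case
  obs_noisy[, "mid"] <- obs[, "mid"]           # exact midpoint
  rownames(obs_noisy) <- ref$probe_id
  cc <- cell_composition_check(obs_noisy, ref)
  expect_equal(cc[sample_id == "pure", w], 1)
  expect_equal(cc[sample_id == "mid", w], 0.5)
  expect_lt(abs(cc[sample_id == "mixed", w] - 0.7), 0.05)
  expect_identical(cc$flagged, c(FALSE, TRUE, TRUE))
  expect_error(cell_composition_check(obs_noisy[1:5, ], ref[1:5]),
               "at least 10")
})

test_that("sensitivity reruns drop whole pairs and recompute the summaries", {
  nb <- small_norm()
  ds <- nb$dataset
  ann <- annotate_cpgs(ds$manifest, ds$genes, ds$tracks)
  sens <- sensitivity_excluding_pairs(nb$beta, ds$samples, ann,
                                      exclude_pairs = c("pair01", "pair02"))
  expect_false(any(c("pair01", "pair02") %in%
                   sens$samples[role == "twin", pair_id]))
  expect_true(all(sens$rho$n_pairs <= ds$config$n_pairs - 2))
  expect_s3_class(sens$summaries, "data.table")
  expect_error(sensitivity_excluding_pairs(nb$beta, ds$samples, ann,
                                           unique(ds$samples$pair_id)),
               "fewer than 3")
})
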