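test_that("generators are bit-reproducible for a fixed seed", {
  spec <- sim_spec(seed = 123, n_genes = 30, snps_per_gene = 5)
  s1 <- simulate_study(spec)
  s2 <- simulate_study(spec)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_promoter_fasta(s1$promoters, f1)
  write_promoter_fasta(s2$promoters, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(s1$snps, s2$snps)
  expect_identical(s1$annotations, s2$annotations)
  expect_identical(s1$contests, s2$contests)
})

test_that("motif_fraction controls consensus embedding", {
  cfg <- default_model_config()
  cons <- pwm_consensus(cfg)
  all_motif <- gen_promoters(sim_spec(seed = 2, n_genes = 25,
                                      motif_fraction = 1), cfg)
  expect_true(all(vapply(all_motif$records, function(r)
    grepl(cons, r$sequence, fixed = TRUE), TRUE)))
  # embedded-motif count within 99% binomial bounds at motif_fraction = 0.5
  half <- gen_promoters(sim_spec(seed = 3, n_genes = 200,
                                 motif_fraction = 0.5), cfg)
  n_motif <- sum(half$genes$site_type == "consensus")
  expect_gte(n_motif, qbinom(0.005, 200, 0.5))
  expect_lte(n_motif, qbinom(0.995, 200, 0.5))
  # infeasible class requests are configuration errors
  expect_error(
    gen_variants(gen_promoters(sim_spec(seed = 4, n_genes = 10,
                                        motif_fraction = 0), cfg),
                 sim_spec(seed = 4, n_genes = 10, motif_fraction = 0), cfg),
    "no promoter carries a motif")
  expect_error(
    gen_variants(all_motif, sim_spec(seed = 2, n_genes = 25,
                                     motif_fraction = 1), cfg),
    "already carries")
})

test_that("generated variants are structurally consistent with the promoters", {
  cfg <- default_model_config()
  spec <- sim_spec(seed = 17, n_genes = 60, snps_per_gene = 8)
  proms <- gen_promoters(spec, cfg)
  snps <- gen_variants(proms, spec, cfg)
  # ancestral alleles always match the reference sequence
  for (i in seq_len(nrow(snps))) {
    p <- proms$records[[snps$gene_id[i]]]
    idx <- snps$offset[i] - p$start_offset + 1L
    expect_identical(substr(p$sequence, idx, idx), snps$wt_allele[i])
  }
  # disrupting SNPs hit the embedded site and strictly lower its PWM score
  L <- cfg$window_length
  disr <- snps[snps$effect_class == "disrupting", ]
  for (i in seq_len(nrow(disr))) {
    p <- proms$records[[disr$gene_id[i]]]
    site <- proms$sites[proms$sites$gene_id == disr$gene_id[i], ]
    idx <- disr$offset[i] - p$start_offset + 1L
    expect_true(idx >= site$site_start && idx < site$site_start + L)
    wt_win <- substr(p$sequence, site$site_start, site$site_start + L - 1L)
    mut <- apply_variant(p, disr$offset[i], disr$wt_allele[i],
                         disr$min_allele[i])
    mn_win <- substr(mut$sequence, site$site_start, site$site_start + L - 1L)
    expect_lt(pwm_score(mn_win, cfg$pwm), pwm_score(wt_win, cfg$pwm))
  }
  # background SNPs avoid every planted site
  bg <- snps[snps$effect_class == "background", ]
  for (i in seq_len(nrow(bg))) {
    sites <- proms$sites[proms$sites$gene_id == bg$gene_id[i], ]
    idx <- bg$offset[i] + 70L + 1L
    inside <- any(idx >= sites$site_start & idx < sites$site_start + L)
    expect_false(inside)
  }
  # creating SNPs restore a latent mismatch to the consensus base
  cons <- strsplit(pwm_consensus(cfg), "")[[1]]
  cre <- snps[snps$effect_class == "creating", ]
  expect_gt(nrow(cre), 0)
  for (i in seq_len(nrow(cre))) {
    sites <- proms$sites[proms$sites$gene_id == cre$gene_id[i], ]
    idx <- cre$offset[i] + 70L + 1L
    j <- which(idx >= sites$site_start & idx < sites$site_start + L)
    expect_length(j, 1L)
    expect_identical(cre$min_allele[i],
                     cons[idx - sites$site_start[j] + 1L])
  }
})

test_that("the pipeline recovers planted effect directions", {
  cfg <- default_model_config()
  spec <- sim_spec(seed = 101, n_genes = 60, snps_per_gene = 9,
                   effect_mix = c(disrupting = 0.1, creating = 0.1,
                                  background = 0.8))
  sim <- simulate_study(spec)
  expect_gte(nrow(sim$snps), 400)
  res <- compare_snps(sim$promoters, sim$snps, cfg)
  cls <- split(res$decision, sim$snps$effect_class)
  rate <- function(x, what) mean(x == what)
  expect_gte(rate(cls$disrupting, "underexpression"), 0.7)
  expect_gte(rate(cls$creating, "overexpression"), 0.7)
  bg_sig <- mean(cls$background != "insignificant")
  expect_lte(bg_sig, 0.05)
  # planted effects are recovered at rates far above background
  expect_gt(rate(cls$disrupting, "underexpression"), 10 * max(bg_sig, 0.01))
  expect_gt(rate(cls$creating, "overexpression"), 10 * max(bg_sig, 0.01))
})

test_that("balanced polarity and effects give a balanced marker dichotomy", {
  cfg <- default_model_config()
  ok <- vapply(1:10, function(r) {
    spec <- sim_spec(seed = 500 + r, n_genes = 40, snps_per_gene = 7,
                     effect_mix = c(disrupting = 0.12, creating = 0.12,
                                    background = 0.76),
                     polarity_mix = 0.5)
    sim <- simulate_study(spec)
    res <- compare_snps(sim$promoters, sim$snps, cfg)
    tl <- tally_markers(res, sim$annotations)
    tot <- tl[tl$system == "TOTAL", ]
    binom_equal_test(tot$n_dom, tot$n_sub)$p.value > 0.05
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})

test_that("contest outcomes follow the drawn winners and p_dom", {
  spec1 <- sim_spec(seed = 6, p_dom = 1)
  contests <- gen_contests(spec1)
  expect_equal(nrow(contests$pairs), 115L)
  ct <- tabulate_crosses(contests)
  tot <- ct[ct$maternal_strain == "TOTAL", ]
  expect_equal(c(tot$balb_dominant, tot$cba_dominant), c(115, 0))
  # score_contest recovers every drawn winner by construction
  spec2 <- sim_spec(seed = 8, p_dom = 0.7)
  c2 <- gen_contests(spec2)
  s <- score_contest(c2)
  expect_equal(s$outcome,
               ifelse(attr(c2, "drawn_dominant") == "a",
                      "a_dominant", "b_dominant"))
  # at the observed dominance rate the mean total tracks 79 of 115
  totals <- vapply(1:40, function(r) {
    ct <- tabulate_crosses(gen_contests(sim_spec(seed = 1000 + r,
                                                 p_dom = 79 / 115)))
    ct[ct$maternal_strain == "TOTAL", "balb_dominant"]
  }, 0)
  expect_equal(mean(totals), 79, tolerance = 0.03)
})
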