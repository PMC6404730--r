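test_that("pwm_score is the additive column sum and the consensus maximizes it", {
  cfg <- toy_config()
  # hand sum: TATA hits the weight-2 base in all four columns
  expect_equal(pwm_score("TATA", cfg$pwm), 8)
  expect_equal(pwm_score("GATA", cfg$pwm), 6)
  expect_equal(pwm_score("GGGG", cfg$pwm), 0)

  dcfg <- default_model_config()
  cons <- pwm_consensus(dcfg)
  cons_score <- pwm_score(cons, dcfg$pwm)
  set.seed(11)
  for (i in 1:200)
    expect_lte(pwm_score(random_sequence(15), dcfg$pwm), cons_score)
  # any single substitution away from the consensus can only lose score
  chars <- strsplit(cons, "")[[1]]
  for (pos in seq_along(chars)) for (b in setdiff(BASES, chars[pos])) {
    mut <- chars; mut[pos] <- b
    expect_lte(pwm_score(paste(mut, collapse = ""), dcfg$pwm), cons_score)
  }
})

test_that("pwm_score rejects malformed windows", {
  cfg <- toy_config()
  expect_error(pwm_score("TAT", cfg$pwm), "does not match pwm width")
  expect_error(pwm_score("TANA", cfg$pwm), "non-ACGT")
})

test_that("slide and bend terms are means over overlapping dinucleotides", {
  dinucs <- sort(as.vector(outer(BASES, BASES, paste0)))
  tab <- stats::setNames(rep(0.7, 16), dinucs)
  # homopolymer: mean of a constant is the AA table value
  expect_equal(slide_term("AAAAA", tab), 0.7)
  tab2 <- tab; tab2[c("TA", "AT")] <- c(2, 1)
  expect_equal(slide_term("TATA", tab2), (2 + 1 + 2) / 3)
  expect_equal(bend_term("TATA", tab2), (2 + 1 + 2) / 3)
  # a symmetric (palindromic) property table makes reversal a no-op
  sym <- tab
  for (d in dinucs) sym[d] <- sym[paste0(substr(d, 2, 2), substr(d, 1, 1))] <-
      sum(utf8ToInt(d))
  w <- "ACGTTGA"
  rw <- paste(rev(strsplit(w, "")[[1]]), collapse = "")
  expect_equal(slide_term(w, sym), slide_term(rw, sym))
  expect_error(slide_term("A", tab), "length >= 2")
  expect_error(slide_term("ACGT", tab[-1]), "missing")
})

test_that("estimate_affinity equals brute-force enumeration over all windows", {
  set.seed(42)
  for (cfg in list(default_model_config(), toy_config())) {
    for (i in 1:15) {
      n <- sample(cfg$window_length:30, 1)
      s <- random_sequence(n)
      got <- estimate_affinity(promoter_record("g", s, start_offset = -n), cfg)
      want <- naive_affinity(s, cfg, start_offset = -n)
      expect_equal(got$neg_log_kd, want$neg_log_kd)
      expect_equal(got$delta, want$delta)
      expect_equal(got$best_window_offset, want$best_window_offset)
    }
  }
})

test_that("a 16-bp two-window example reproduces the hand-enumerated maximum", {
  cfg <- toy_config(window_length = 15L)
  s <- "TATATATATATATATG" # windows: s[1..15] and s[2..16]
  w1 <- substr(s, 1, 15); w2 <- substr(s, 2, 16)
  E <- function(w) c(pwm_score(w, cfg$pwm), slide_term(w, cfg$slide),
                     bend_term(w, cfg$bend))
  e1 <- E(w1); e2 <- E(w2)
  expect_gt(mean(e1), mean(e2)) # so the left window must win
  got <- estimate_affinity(promoter_record("g", s, start_offset = -16L), cfg)
  expect_equal(got$neg_log_kd, mean(e1))
  expect_equal(got$delta, sd(e1) / sqrt(3))
  expect_equal(got$best_window_offset, -16L)
})

test_that("embedding the consensus never decreases affinity", {
  cfg <- default_model_config()
  cons <- strsplit(pwm_consensus(cfg), "")[[1]]
  set.seed(7)
  for (i in 1:100) {
    bg <- strsplit(random_sequence(70), "")[[1]]
    base <- estimate_affinity(promoter_record("g", paste(bg, collapse = "")), cfg)
    at <- sample(70 - 15 + 1, 1)
    bg[at:(at + 14)] <- cons
    emb <- estimate_affinity(promoter_record("g", paste(bg, collapse = "")), cfg)
    expect_gte(emb$neg_log_kd, base$neg_log_kd)
  }
  # against a uniform background the embedding site is the best window
  bg <- rep("G", 70)
  bg[21:35] <- cons
  est <- estimate_affinity(promoter_record("g", paste(bg, collapse = "")), cfg)
  expect_equal(est$best_window_offset, -70L + 20L)
  expect_gt(est$neg_log_kd,
            estimate_affinity(promoter_record("g", strrep("G", 70)), cfg)$neg_log_kd)
})

test_that("shifting the embedding site shifts only the best-window offset", {
  cfg <- default_model_config()
  cons <- strsplit(pwm_consensus(cfg), "")[[1]]
  place <- function(at) {
    bg <- rep("C", 70)
    bg[at:(at + 14)] <- cons
    estimate_affinity(promoter_record("g", paste(bg, collapse = "")), cfg)
  }
  e1 <- place(10); e2 <- place(37)
  expect_equal(e1$neg_log_kd, e2$neg_log_kd)
  expect_equal(e2$best_window_offset - e1$best_window_offset, 27L)
})

test_that("estimates are deterministic and delta behaves as specified", {
  cfg <- default_model_config()
  p <- promoter_record("g", random_sequence(70))
  expect_identical(estimate_affinity(p, cfg), estimate_affinity(p, cfg))
  # delta is zero exactly when the three partial estimates coincide
  dcfg <- degenerate_config()
  est <- estimate_affinity("ACGTACGT", dcfg) # bare string: offsets [-8, -1]
  expect_identical(est$delta, 0)
  expect_true(all(est$partials == est$partials[1]))
  est2 <- estimate_affinity(promoter_record("g", "TATATATA"), toy_config())
  expect_true(sd(est2$partials) > 0 && est2$delta > 0)
  # ties in the combined score resolve to the most upstream window
  expect_equal(est$best_window_offset, -8L)
})

test_that("degenerate inputs are rejected with clear errors", {
  cfg <- default_model_config()
  expect_error(estimate_affinity(promoter_record("g", "ACGTACGT"), cfg),
               "shorter")
  expect_error(promoter_record("g", "ACGTN"), "non-ACGT")
  expect_warning(p <- promoter_record("g", strrep("ACGTN", 4), lenient = TRUE),
                 "IUPAC")
  expect_equal(p$sequence, strrep("ACGTA", 4))
  bad_calib <- matrix(c(0, 0, 0, 1, Inf, 1), 3, 2,
                      dimnames = list(c("stop", "slide", "bend"), c("a", "b")))
  expect_error(model_config(toy_config()$pwm, toy_config()$slide,
                            toy_config()$bend, bad_calib),
               "non-finite")
  expect_error(model_config(toy_config()$pwm, toy_config()$slide,
                            toy_config()$bend, toy_config()$calibration,
                            window_length = 1L), "window_length")
})

test_that("the shipped configuration round-trips through the flat-file reader", {
  cfg <- default_model_config()
  expect_s3_class(cfg, "model_config")
  expect_equal(cfg$window_length, 15L)
  expect_equal(dim(cfg$pwm), c(4L, 15L))
  expect_equal(length(cfg$slide), 16L)
  expect_equal(cfg$alpha_threshold, 0.95)
  # consensus anchor: all three calibrated step estimates agree at ~20.8
  est <- estimate_affinity(
    promoter_record("g", paste0(strrep("C", 30), pwm_consensus(cfg),
                                strrep("C", 25))), cfg)
  expect_equal(unname(est$partials), rep(20.8, 3), tolerance = 1e-4)
})
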