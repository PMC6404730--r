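#' Specify a synthetic study
#'
#' Collects every knob of the synthetic-data generators: the promoter pool,
#' the variant classes, the gene annotations and the mouse contest design.
#' Defaults mirror the scale of the genome-wide screen the pipeline is built
#' for (231 genes averaging ~21.9 promoter SNPs each, three body systems)
#' and the diallel contest design of 115 pairs split 31/20/21/20/23 across
#' five maternal strains.
#'
#' A fixed `seed` makes every generator bit-reproducible; each generator
#' derives its own substream as `seed + k` (promoters k = 1, variants k = 2,
#' annotations k = 3, contests k = 4), so regenerating one input leaves the
#' others unchanged.
#'
#' @param seed integer below 2^31 - 5.
#' @param n_genes number of genes / promoter records.
#' @param snps_per_gene Poisson mean of the per-gene SNP count.
#' @param motif_fraction probability that a promoter carries an embedded
#'   PWM-consensus TATA site; motif-free promoters instead carry
#'   `latent_sites` near-consensus sites (consensus with one core position
#'   carrying its most disruptive substitution) that a single SNP can
#'   restore.
#' @param gc background GC content of the promoter sequences (human core
#'   promoters are GC-rich; default 0.6).
#' @param effect_mix named fractions of `disrupting` (a core consensus
#'   position of an embedded site changed to its most disruptive base),
#'   `creating`
#'   (a latent-site mismatch restored to consensus) and `background` SNPs.
#' @param polarity_mix fraction of genes annotated `excess_marks_dominance`.
#' @param pairs_per_strain named integer vector of contest pairs per
#'   maternal strain.
#' @param p_dom probability that the BALB/cLac-sired male of a pair is the
#'   drawn dominant (default the observed 79/115).
#' @param obs_per_pair observations per pair (default 14).
#' @param attack_rates,pose_rates named Poisson rates per observation for
#'   the `dominant` and `subordinate` male; attacks are frequent for the
#'   dominant, submissive poses frequent for the subordinate.
#' @param latent_sites latent near-consensus sites per motif-free promoter.
#' @return object of class `sim_spec`.
#' @export
sim_spec <- function(seed = 1L,
                     n_genes = 231L,
                     snps_per_gene = 21.9,
                     motif_fraction = 0.5,
                     gc = 0.6,
                     effect_mix = c(disrupting = 0.04, creating = 0.04,
                                    background = 0.92),
                     polarity_mix = 0.5,
                     pairs_per_strain = c("PT" = 31L, "C57BL/6J" = 20L,
                                          "YT" = 21L, "DD" = 20L,
                                          "A/He" = 23L),
                     p_dom = 79 / 115,
                     obs_per_pair = 14L,
                     attack_rates = c(dominant = 3.0, subordinate = 0.5),
                     pose_rates = c(dominant = 0.3, subordinate = 2.5),
                     latent_sites = 2L) {
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0L || seed > .Machine$integer.max - 5L)
    stop("seed must be a non-negative integer below 2^31 - 5")
  probs <- c(motif_fraction = motif_fraction, gc = gc,
             polarity_mix = polarity_mix, p_dom = p_dom, effect_mix)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  if (!all(c("disrupting", "creating", "background") %in% names(effect_mix)))
    stop("effect_mix needs fractions disrupting, creating, background")
  if (abs(sum(effect_mix) - 1) > 1e-8) stop("effect_mix must sum to 1")
  if (n_genes < 1L || snps_per_gene < 0 || obs_per_pair < 1L ||
      latent_sites < 1L || any(pairs_per_strain < 0L))
    stop("counts must be positive (pair counts non-negative)")
  bad <- setdiff(names(pairs_per_strain), MATERNAL_STRAINS)
  if (length(bad)) stop("unknown maternal strain: ", paste(bad, collapse = ", "))
  stopifnot(all(c("dominant", "subordinate") %in% names(attack_rates)),
            all(c("dominant", "subordinate") %in% names(pose_rates)),
            attack_rates["dominant"] > attack_rates["subordinate"],
            pose_rates["dominant"] < pose_rates["subordinate"])
  structure(
    list(seed = seed, n_genes = as.integer(n_genes),
         snps_per_gene = snps_per_gene, motif_fraction = motif_fraction,
         gc = gc, effect_mix = effect_mix, polarity_mix = polarity_mix,
         pairs_per_strain = pairs_per_strain, p_dom = p_dom,
         obs_per_pair = as.integer(obs_per_pair),
         attack_rates = attack_rates, pose_rates = pose_rates,
         latent_sites = as.integer(latent_sites)),
    class = "sim_spec"
  )
}

# strong-information PWM columns (weight range >= 4 bits); fall back to all
core_positions <- function(config) {
  rng <- apply(config$pwm, 2L, max) - apply(config$pwm, 2L, min)
  core <- which(rng >= 4)
  if (!length(core)) core <- seq_len(config$window_length)
  core
}

# combined calibrated score of one window (mean of the three step estimates)
window_combined_score <- function(window_chars, config) {
  w <- paste(window_chars, collapse = "")
  f <- c(stop = pwm_score(w, config$pwm),
         slide = slide_term(w, config$slide),
         bend = bend_term(w, config$bend))
  calib <- config$calibration
  mean(calib[, "a"] + calib[, "b"] * f[rownames(calib)])
}

# for each core position, the substitution of the consensus window that is
# most damaging under the full three-step model (named by position)
disruptive_alleles <- function(config, core) {
  cons <- strsplit(pwm_consensus(config), "")[[1]]
  out <- vapply(core, function(p) {
    alts <- setdiff(DNA_BASES, cons[p])
    scores <- vapply(alts, function(b) {
      w <- cons
      w[p] <- b
      window_combined_score(w, config)
    }, 0)
    alts[which.min(scores)]
  }, "")
  names(out) <- core
  out
}

#' Generate synthetic promoter records
#'
#' Draws length-70 promoter sequences at TSS-relative offsets -70 .. -1
#' with i.i.d. background at the specified GC content. A fraction
#' `motif_fraction` of promoters receives the PWM consensus embedded at a
#' random window; every other promoter receives `latent_sites`
#' non-overlapping near-consensus sites, each consensus with one core
#' position carrying the substitution most damaging under the full
#' three-step model.
#'
#' @param spec a [sim_spec()].
#' @param config a [model_config()] supplying the PWM.
#' @return object of class `promoter_set`: a named list `records` of
#'   [promoter_record()]s, a `genes` table (`gene_id`, `transcript_id`,
#'   `site_type`), and a `sites` table of planted site coordinates
#'   (`gene_id`, `site_start` 1-based in the sequence, `mismatch_pos`
#'   within-site core mismatch position, NA for consensus sites).
#' @export
gen_promoters <- function(spec, config = default_model_config()) {
  stopifnot(inherits(spec, "sim_spec"), inherits(config, "model_config"))
  set.seed(spec$seed + 1L)
  L <- config$window_length
  plen <- 70L
  if (plen < L) stop("promoter length shorter than the model window")
  nw <- plen - L + 1L
  cons <- strsplit(pwm_consensus(config), "")[[1]]
  core <- core_positions(config)
  disr <- disruptive_alleles(config, core)
  base_prob <- c((1 - spec$gc) / 2, spec$gc / 2, spec$gc / 2, (1 - spec$gc) / 2)
  k <- spec$latent_sites
  seg <- plen %/% k
  if (seg < L) stop("latent_sites do not fit into the promoter")
  records <- vector("list", spec$n_genes)
  genes <- data.frame(gene_id = sprintf("G%04d", seq_len(spec$n_genes)),
                      transcript_id = sprintf("G%04d.t1", seq_len(spec$n_genes)),
                      site_type = NA_character_, stringsAsFactors = FALSE)
  sites <- list()
  for (i in seq_len(spec$n_genes)) {
    s <- sample(DNA_BASES, plen, replace = TRUE, prob = base_prob)
    if (stats::runif(1) < spec$motif_fraction) {
      genes$site_type[i] <- "consensus"
      start <- sample.int(nw, 1L)
      s[start:(start + L - 1L)] <- cons
      sites[[length(sites) + 1L]] <- data.frame(
        gene_id = genes$gene_id[i], site_start = start,
        mismatch_pos = NA_integer_, stringsAsFactors = FALSE)
    } else {
      genes$site_type[i] <- "latent"
      for (j in seq_len(k)) {
        lo <- (j - 1L) * seg + 1L
        start <- lo + sample.int(seg - L + 1L, 1L) - 1L
        site <- cons
        mpos <- core[sample.int(length(core), 1L)]
        site[mpos] <- disr[[as.character(mpos)]]
        s[start:(start + L - 1L)] <- site
        sites[[length(sites) + 1L]] <- data.frame(
          gene_id = genes$gene_id[i], site_start = start,
          mismatch_pos = mpos, stringsAsFactors = FALSE)
      }
    }
    records[[i]] <- promoter_record(genes$gene_id[i], paste(s, collapse = ""),
                                    transcript_id = genes$transcript_id[i],
                                    start_offset = -plen)
  }
  names(records) <- genes$gene_id
  structure(list(records = records, genes = genes,
                 sites = do.call(rbind, sites)),
            class = "promoter_set")
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("<promoter_set> %d promoters (%d consensus, %d latent)\n",
              nrow(x$genes), sum(x$genes$site_type == "consensus"),
              sum(x$genes$site_type == "latent")))
  invisible(x)
}

#' Generate a synthetic SNP table
#'
#' Draws a Poisson number of SNPs per gene and partitions them into the
#' three effect classes of the specification. Disrupting SNPs (on
#' motif-bearing promoters only) change a strong-information consensus
#' position of the embedded site to its most disruptive base; creating SNPs (on
#' motif-free promoters only) restore a latent-site mismatch to consensus;
#' background SNPs are random substitutions outside the planted sites.
#' Within a gene, class counts follow the rounded conditional fractions
#' `effect_mix / realized class availability`, capped by the number of
#' distinct variants a promoter offers.
#'
#' @param promoters a `promoter_set` from [gen_promoters()].
#' @param spec a [sim_spec()].
#' @param config a [model_config()].
#' @return data frame with columns `variant_id`, `gene_id`, `offset`,
#'   `wt_allele`, `min_allele`, `effect_class`.
#' @export
gen_variants <- function(promoters, spec, config = default_model_config()) {
  stopifnot(inherits(promoters, "promoter_set"), inherits(spec, "sim_spec"))
  set.seed(spec$seed + 2L)
  L <- config$window_length
  cons <- strsplit(pwm_consensus(config), "")[[1]]
  core <- core_positions(config)
  disr <- disruptive_alleles(config, core)
  frac_motif <- mean(promoters$genes$site_type == "consensus")
  mix <- spec$effect_mix
  if (mix[["disrupting"]] > 0 && frac_motif == 0)
    stop("motif-disrupting SNPs requested but no promoter carries a motif")
  if (mix[["creating"]] > 0 && frac_motif == 1)
    stop("motif-creating SNPs requested but every promoter already carries ",
         "a consensus motif")
  q_d <- if (frac_motif > 0) min(1, mix[["disrupting"]] / frac_motif) else 0
  q_c <- if (frac_motif < 1) min(1, mix[["creating"]] / (1 - frac_motif)) else 0
  rows <- list()
  vid <- 0L
  for (i in seq_len(nrow(promoters$genes))) {
    g <- promoters$genes$gene_id[i]
    rec <- promoters$records[[g]]
    seq_chars <- strsplit(rec$sequence, "")[[1]]
    gsites <- promoters$sites[promoters$sites$gene_id == g, , drop = FALSE]
    site_idx <- unlist(lapply(gsites$site_start, function(s) s:(s + L - 1L)))
    k <- stats::rpois(1L, spec$snps_per_gene)
    if (k == 0L) next
    is_motif <- promoters$genes$site_type[i] == "consensus"
    add <- function(idx, min_allele, cls) {
      vid <<- vid + 1L
      rows[[length(rows) + 1L]] <<- data.frame(
        variant_id = sprintf("rs%06d", vid), gene_id = g,
        offset = rec$start_offset + idx - 1L,
        wt_allele = seq_chars[idx], min_allele = min_allele,
        effect_class = cls, stringsAsFactors = FALSE)
    }
    n_d <- n_c <- 0L
    if (is_motif) {
      n_d <- min(round(q_d * k), length(core), k)
      if (n_d > 0L) {
        pos <- core[sample.int(length(core), n_d)]
        for (p in pos)
          add(gsites$site_start[1L] + p - 1L, disr[[as.character(p)]],
              "disrupting")
      }
    } else {
      n_c <- min(round(q_c * k), nrow(gsites), k)
      if (n_c > 0L) {
        which_sites <- sample.int(nrow(gsites), n_c)
        for (j in which_sites) {
          mp <- gsites$mismatch_pos[j]
          add(gsites$site_start[j] + mp - 1L, cons[mp], "creating")
        }
      }
    }
    n_b <- k - n_d - n_c
    if (n_b > 0L) {
      avail <- setdiff(seq_along(seq_chars), site_idx)
      n_b <- min(n_b, length(avail))
      pos <- if (length(avail) == 1L) avail else sample(avail, n_b)
      for (p in pos)
        add(p, sample(setdiff(DNA_BASES, seq_chars[p]), 1L), "background")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate synthetic gene annotations
#'
#' Assigns each gene a body system (neuropeptidergic, non-neuropeptidergic
#' or neurotrophinergic, at the 27:109:95 proportions of the screen's gene
#' panel) and a marker polarity, `excess_marks_dominance` with probability
#' `polarity_mix`.
#'
#' @param spec a [sim_spec()].
#' @return data frame with `gene_id`, `system`, `polarity`, `evidence`.
#' @export
gen_annotations <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed + 3L)
  data.frame(
    gene_id = sprintf("G%04d", seq_len(spec$n_genes)),
    system = sample(MARKER_SYSTEMS, spec$n_genes, replace = TRUE,
                    prob = c(27, 109, 95)),
    polarity = ifelse(stats::runif(spec$n_genes) < spec$polarity_mix,
                      "excess_marks_dominance", "excess_marks_subordination"),
    evidence = "synthetic annotation",
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic contest records
#'
#' For every pair the dominant male is drawn as the BALB/cLac-sired one
#' with probability `p_dom`. Observation-level attack and submissive-pose
#' counts are Poisson with dominant/subordinate rate asymmetry, redrawn for
#' a pair until the totals satisfy the strict conjunctive dominance rule,
#' so that [score_contest()] recovers the drawn winner by construction.
#'
#' @param spec a [sim_spec()].
#' @return a [contest_set()]; the drawn winners are attached as attribute
#'   `drawn_dominant` (`"a"` = BALB/cLac-sired male).
#' @export
gen_contests <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed + 4L)
  counts <- spec$pairs_per_strain[spec$pairs_per_strain > 0L]
  n_pairs <- sum(counts)
  maternal <- rep(names(counts), counts)
  pair_id <- sprintf("P%03d", seq_len(n_pairs))
  a_dom <- stats::runif(n_pairs) < spec$p_dom
  nobs <- spec$obs_per_pair
  draw <- function(rate) matrix(stats::rpois(nobs * n_pairs, rate), nrow = nobs)
  att_dom <- draw(spec$attack_rates[["dominant"]])
  att_sub <- draw(spec$attack_rates[["subordinate"]])
  pos_dom <- draw(spec$pose_rates[["dominant"]])
  pos_sub <- draw(spec$pose_rates[["subordinate"]])
  bad <- which(!(colSums(att_dom) > colSums(att_sub) &
                   colSums(pos_dom) < colSums(pos_sub)))
  tries <- 0L
  while (length(bad)) {
    if ((tries <- tries + 1L) > 1000L)
      stop("failed to realize drawn contest winners; rates too symmetric")
    redraw <- function(rate) matrix(stats::rpois(nobs * length(bad), rate),
                                    nrow = nobs)
    att_dom[, bad] <- redraw(spec$attack_rates[["dominant"]])
    att_sub[, bad] <- redraw(spec$attack_rates[["subordinate"]])
    pos_dom[, bad] <- redraw(spec$pose_rates[["dominant"]])
    pos_sub[, bad] <- redraw(spec$pose_rates[["subordinate"]])
    bad <- bad[!(colSums(att_dom[, bad, drop = FALSE]) >
                   colSums(att_sub[, bad, drop = FALSE]) &
                   colSums(pos_dom[, bad, drop = FALSE]) <
                   colSums(pos_sub[, bad, drop = FALSE]))]
  }
  pick <- function(dom_mat, sub_mat, dom_is_a) {
    out <- sub_mat
    out[, dom_is_a] <- dom_mat[, dom_is_a]
    out
  }
  attacks_a <- pick(att_dom, att_sub, a_dom)
  attacks_b <- pick(att_dom, att_sub, !a_dom)
  submissive_a <- pick(pos_dom, pos_sub, a_dom)
  submissive_b <- pick(pos_dom, pos_sub, !a_dom)
  observations <- data.frame(
    pair_id = rep(pair_id, each = nobs),
    observation = rep(seq_len(nobs), n_pairs),
    attacks_a = as.vector(attacks_a), attacks_b = as.vector(attacks_b),
    submissive_a = as.vector(submissive_a),
    submissive_b = as.vector(submissive_b),
    stringsAsFactors = FALSE
  )
  pairs <- data.frame(pair_id = pair_id, maternal_strain = maternal,
                      male_a_paternal = "BALB/cLac",
                      male_b_paternal = "CBA/Lac", stringsAsFactors = FALSE)
  out <- contest_set(pairs, observations)
  attr(out, "drawn_dominant") <- ifelse(a_dom, "a", "b")
  out
}

#' Generate every pipeline input
#'
#' Runs all four generators from one specification and optionally writes
#' the FASTA / TSV files a pipeline run would consume.
#'
#' @param spec a [sim_spec()].
#' @param config a [model_config()].
#' @param out_dir optional directory; when given, writes `promoters.fasta`,
#'   `snps.tsv`, `annotations.tsv` and `contests.tsv` there.
#' @return list with `promoters`, `snps`, `annotations`, `contests`, `spec`.
#' @export
simulate_study <- function(spec, config = default_model_config(),
                           out_dir = NULL) {
  promoters <- gen_promoters(spec, config)
  snps <- gen_variants(promoters, spec, config)
  annotations <- gen_annotations(spec)
  contests <- gen_contests(spec)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_promoter_fasta(promoters, file.path(out_dir, "promoters.fasta"))
    write_tsv(snps, file.path(out_dir, "snps.tsv"))
    write_tsv(annotations, file.path(out_dir, "annotations.tsv"))
    write_contests(contests, file.path(out_dir, "contests.tsv"))
  }
  list(promoters = promoters, snps = snps, annotations = annotations,
       contests = contests, spec = spec)
}
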