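#' Apply a variant to a promoter record
#'
#' Returns the minor-allele version of a promoter. Substitutions preserve
#' length. Indels shift the downstream part of the sequence and the record
#' is re-trimmed (insertions) or re-padded from the upstream flanking
#' sequence (deletions) so that the TSS-relative coordinate frame, anchored
#' at the TSS on the right, is preserved. Deletions therefore require a
#' flank (on the record or via `flank`); insertions drop their most
#' upstream bases.
#'
#' @param promoter a [promoter_record()].
#' @param offset integer, TSS-relative position of the first base of the
#'   ancestral allele.
#' @param wt_allele ancestral allele as found in the reference sequence.
#' @param min_allele minor allele (may differ in length for indels).
#' @param variant_id identifier used in error messages.
#' @param flank optional upstream flank overriding `promoter$flank`.
#' @return a [promoter_record()] carrying the minor allele.
#' @export
apply_variant <- function(promoter, offset, wt_allele, min_allele,
                          variant_id = "variant", flank = NULL) {
  stopifnot(inherits(promoter, "promoter_record"))
  wt_allele <- normalize_sequence(wt_allele)
  min_allele <- normalize_sequence(min_allele)
  offset <- as.integer(offset)
  n <- nchar(promoter$sequence)
  idx <- offset - promoter$start_offset + 1L
  if (idx < 1L || idx + nchar(wt_allele) - 1L > n)
    stop(variant_id, ": offset ", offset, " outside promoter ",
         promoter$gene_id)
  observed <- substr(promoter$sequence, idx, idx + nchar(wt_allele) - 1L)
  if (observed != wt_allele)
    stop(variant_id, ": ancestral allele mismatch in ", promoter$gene_id,
         " at offset ", offset, " (expected ", wt_allele, ", found ",
         observed, ")")
  new_seq <- paste0(substr(promoter$sequence, 1L, idx - 1L), min_allele,
                    substr(promoter$sequence, idx + nchar(wt_allele), n))
  shift <- nchar(min_allele) - nchar(wt_allele)
  flank <- if (!is.null(flank)) normalize_sequence(flank) else promoter$flank
  if (shift < 0L) { # deletion: pad upstream from the flank
    if (is.null(flank) || nchar(flank) < -shift)
      stop(variant_id, ": deletion needs ", -shift,
           " bp of upstream flank for ", promoter$gene_id,
           " but none (or too little) was supplied")
    pad <- substr(flank, nchar(flank) + shift + 1L, nchar(flank))
    new_seq <- paste0(pad, new_seq)
    flank <- substr(flank, 1L, nchar(flank) + shift)
  } else if (shift > 0L) { # insertion: trim the most upstream bases
    flank <- paste0(if (is.null(flank)) "" else flank,
                    substr(new_seq, 1L, shift))
    new_seq <- substr(new_seq, shift + 1L, nchar(new_seq))
  }
  promoter_record(promoter$gene_id, new_seq,
                  transcript_id = promoter$transcript_id,
                  start_offset = promoter$start_offset,
                  flank = if (is.null(flank) || !nzchar(flank)) NULL else flank)
}

#' Fisher Z-score between two allele affinity estimates
#'
#' Z = |ln(KD_min / KD_wt)| / sqrt(delta_min^2 + delta_wt^2); the numerator
#' equals the absolute difference of the two -ln(KD) estimates.
#'
#' @param wt,mn `affinity_estimate` objects for the ancestral and minor
#'   alleles.
#' @return non-negative numeric scalar.
#' @export
z_score <- function(wt, mn) {
  stopifnot(inherits(wt, "affinity_estimate"), inherits(mn, "affinity_estimate"))
  num <- abs(wt$neg_log_kd - mn$neg_log_kd)
  den <- sqrt(wt$delta^2 + mn$delta^2)
  if (den == 0) {
    if (num == 0) return(0)
    stop("both allele uncertainties are zero but the estimates differ; ",
         "Z-score undefined")
  }
  num / den
}

#' Significance of a Z-score
#'
#' Two-tailed standard-normal tail probability of `z`, and the significance
#' level alpha = 1 - p.
#'
#' @param z non-negative numeric.
#' @return named list with `p_value` and `alpha`.
#' @export
significance <- function(z) {
  if (any(z < 0)) stop("z must be non-negative")
  p <- 2 * stats::pnorm(-z)
  list(p_value = p, alpha = 1 - p)
}

#' Expression-direction decision for one SNP
#'
#' If the allele difference is insignificant (alpha below the threshold) the
#' decision is `insignificant`. Otherwise a minor allele with higher TBP
#' affinity (-ln KD) is called `overexpression` (protein excess) and one
#' with lower affinity `underexpression` (deficit), following the
#' experimentally established direction between TBP-site affinity and
#' expression.
#'
#' @inheritParams z_score
#' @param alpha significance level 1 - p for the comparison.
#' @param threshold decision threshold on alpha, in (0, 1).
#' @return one of `"overexpression"`, `"underexpression"`, `"insignificant"`.
#' @export
classify_expression <- function(wt, mn, alpha, threshold = 0.95) {
  stopifnot(threshold > 0, threshold < 1)
  if (alpha < threshold) return("insignificant")
  if (mn$neg_log_kd > wt$neg_log_kd) "overexpression"
  else if (mn$neg_log_kd < wt$neg_log_kd) "underexpression"
  else "insignificant" # unreachable when alpha >= threshold (Z = 0 -> alpha = 0)
}

RANK_BINS <- c(A = 0.9999, B = 0.999, C = 0.99, D = 0.95)

#' Heuristic prediction rank
#'
#' Monotone binning of the significance level alpha into ranks A ("best")
#' through E ("worst"): A >= 0.9999, B >= 0.999, C >= 0.99, D >= 0.95,
#' otherwise E.
#'
#' @param alpha numeric vector in \[0, 1\].
#' @return character vector of ranks.
#' @export
assign_rank <- function(alpha) {
  if (any(alpha < 0 | alpha > 1)) stop("alpha must lie in [0, 1]")
  vapply(alpha, function(a) {
    hit <- names(RANK_BINS)[a >= RANK_BINS]
    if (length(hit)) hit[1] else "E"
  }, "")
}

#' Compare ancestral and minor alleles for a table of SNPs
#'
#' For every SNP the ancestral promoter and its minor-allele version are
#' scored with [estimate_affinity()], the Fisher Z-score and its two-tailed
#' significance are computed, and the expression-direction decision and
#' heuristic rank are assigned. Reported KD values are exp(-neg_log_kd)
#' expressed in nM.
#'
#' @param promoters a named list of [promoter_record()] objects (names =
#'   gene ids) or a `promoter_set` from [gen_promoters()].
#' @param snps data frame with columns `variant_id`, `gene_id`, `offset`,
#'   `wt_allele`, `min_allele` (see [read_snp_table()]).
#' @param config a [model_config()]; defaults to [default_model_config()].
#' @return data frame with one row per SNP: affinity estimates for both
#'   alleles, `kd_wt_nm`, `kd_min_nm`, `z`, `p_value`, `alpha`, `decision`
#'   and `rank`.
#' @export
compare_snps <- function(promoters, snps, config = default_model_config()) {
  promoters <- as_promoter_list(promoters)
  required <- c("variant_id", "gene_id", "offset", "wt_allele", "min_allele")
  if (!all(required %in% names(snps)))
    stop("snps table must have columns: ", paste(required, collapse = ", "))
  missing <- setdiff(unique(snps$gene_id), names(promoters))
  if (length(missing))
    stop("no promoter record for gene(s): ", paste(missing, collapse = ", "))
  # one affinity estimate per distinct ancestral promoter
  wt_cache <- lapply(promoters, estimate_affinity, config = config)
  rows <- lapply(seq_len(nrow(snps)), function(i) {
    s <- snps[i, ]
    prom <- promoters[[s$gene_id]]
    wt <- wt_cache[[s$gene_id]]
    mn_prom <- apply_variant(prom, s$offset, s$wt_allele, s$min_allele,
                             variant_id = s$variant_id)
    mn <- estimate_affinity(mn_prom, config)
    z <- z_score(wt, mn)
    sig <- significance(z)
    decision <- classify_expression(wt, mn, sig$alpha,
                                    threshold = config$alpha_threshold)
    data.frame(
      variant_id = s$variant_id, gene_id = s$gene_id, offset = s$offset,
      neg_log_kd_wt = wt$neg_log_kd, delta_wt = wt$delta,
      neg_log_kd_min = mn$neg_log_kd, delta_min = mn$delta,
      kd_wt_nm = exp(-wt$neg_log_kd) * 1e9,
      kd_min_nm = exp(-mn$neg_log_kd) * 1e9,
      best_window_wt = wt$best_window_offset,
      best_window_min = mn$best_window_offset,
      z = z, p_value = sig$p_value, alpha = sig$alpha,
      decision = decision, rank = assign_rank(sig$alpha),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# accept a promoter_set, a list of records, or a single record
as_promoter_list <- function(promoters) {
  if (inherits(promoters, "promoter_set")) promoters <- promoters$records
  if (inherits(promoters, "promoter_record")) promoters <- list(promoters)
  stopifnot(is.list(promoters),
            all(vapply(promoters, inherits, TRUE, "promoter_record")))
  names(promoters) <- vapply(promoters, `[[`, "", "gene_id")
  promoters
}
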