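#' Read promoter records from FASTA
#'
#' Record ids follow `gene_id|transcript_id`; the description may carry the
#' TSS-relative offset of the first base as `offset=-70` (the default when
#' absent) and an upstream flank as `flank=ACGT...`.
#'
#' @param path FASTA file.
#' @param lenient passed to [promoter_record()] for IUPAC handling.
#' @return named list of [promoter_record()] objects (names = gene ids).
#' @export
read_promoter_fasta <- function(path, lenient = FALSE) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (!length(seqs)) {
    warning("no records in ", path)
    return(list())
  }
  headers <- names(seqs)
  records <- lapply(seq_along(seqs), function(i) {
    header <- headers[i]
    id <- strsplit(header, "\\s+")[[1]][1]
    parts <- strsplit(id, "|", fixed = TRUE)[[1]]
    off <- regmatches(header, regexec("offset=(-?[0-9]+)", header))[[1]]
    flank <- regmatches(header, regexec("flank=([ACGTacgt]+)", header))[[1]]
    promoter_record(
      gene_id = parts[1],
      sequence = as.character(seqs[[i]]),
      transcript_id = if (length(parts) > 1L) parts[2] else parts[1],
      start_offset = if (length(off)) as.integer(off[2]) else -70L,
      flank = if (length(flank)) flank[2] else NULL,
      lenient = lenient
    )
  })
  names(records) <- vapply(records, `[[`, "", "gene_id")
  records
}

#' Write promoter records to FASTA
#'
#' @param promoters a `promoter_set`, a list of [promoter_record()]s, or a
#'   single record.
#' @param path output file.
#' @export
write_promoter_fasta <- function(promoters, path) {
  promoters <- as_promoter_list(promoters)
  seqs <- Biostrings::DNAStringSet(vapply(promoters, `[[`, "", "sequence"))
  names(seqs) <- vapply(promoters, function(p) {
    h <- sprintf("%s|%s offset=%d", p$gene_id, p$transcript_id, p$start_offset)
    if (!is.null(p$flank)) h <- paste0(h, " flank=", p$flank)
    h
  }, "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_checked <- function(path, required, what) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (nrow(df) == 0L) warning("empty ", what, " table: ", path)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(what, " table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Read a SNP table
#'
#' Tab-separated with columns `variant_id`, `gene_id`, `offset` (1-based
#' TSS-relative, negative upstream), `wt_allele`, `min_allele`. When
#' `promoters` is supplied each ancestral allele is validated against the
#' reference sequence; mismatches are reported with the variant id, line
#' number and both bases.
#'
#' @param path TSV file.
#' @param promoters optional promoter list for wt-allele validation.
#' @return data frame.
#' @export
read_snp_table <- function(path, promoters = NULL) {
  df <- read_tsv_checked(path, c("variant_id", "gene_id", "offset",
                                 "wt_allele", "min_allele"), "SNP")
  df$offset <- as.integer(df$offset)
  if (anyNA(df$offset)) stop("non-integer offset in SNP table ", path)
  if (any(df$offset >= 0)) stop("offsets must be negative (upstream of the TSS)")
  if (!is.null(promoters)) {
    promoters <- as_promoter_list(promoters)
    for (i in seq_len(nrow(df))) {
      g <- df$gene_id[i]
      if (!g %in% names(promoters))
        stop("SNP table line ", i + 1L, ": unknown gene ", g)
      p <- promoters[[g]]
      idx <- df$offset[i] - p$start_offset + 1L
      wt <- toupper(df$wt_allele[i])
      found <- substr(p$sequence, idx, idx + nchar(wt) - 1L)
      if (idx < 1L || found != wt)
        stop("SNP table line ", i + 1L, " (", df$variant_id[i],
             "): ancestral allele mismatch at offset ", df$offset[i],
             " of ", g, " (expected ", wt, ", found ", found, ")")
    }
  }
  df
}

#' Read a gene annotation table
#'
#' Tab-separated with columns `gene_id`, `system` (one of neuropeptidergic,
#' non-neuropeptidergic, neurotrophinergic), `polarity`
#' (excess_marks_dominance / excess_marks_subordination) and free-text
#' `evidence`.
#'
#' @param path TSV file.
#' @return data frame.
#' @export
read_annotations <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "system", "polarity"),
                         "annotation")
  bad <- which(!(df$system %in% MARKER_SYSTEMS))
  if (length(bad))
    stop("annotation table line ", bad[1] + 1L, ": unknown system '",
         df$system[bad[1]], "'")
  bad <- which(!(df$polarity %in% MARKER_POLARITIES))
  if (length(bad))
    stop("annotation table line ", bad[1] + 1L, ": unknown polarity '",
         df$polarity[bad[1]], "'")
  if (anyDuplicated(df$gene_id))
    stop("duplicated gene_id in annotation table: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  df
}

#' Read contest records from long-format TSV
#'
#' One row per pair, observation and side with columns `pair_id`,
#' `maternal_strain`, `male_a_paternal`, `male_b_paternal`, `observation`,
#' `side` (`a`/`b`), `attacks`, `submissive_poses`.
#'
#' @param path TSV file.
#' @return a [contest_set()].
#' @export
read_contests <- function(path) {
  df <- read_tsv_checked(path, c("pair_id", "maternal_strain",
                                 "male_a_paternal", "male_b_paternal",
                                 "observation", "side", "attacks",
                                 "submissive_poses"), "contest")
  if (!all(df$side %in% c("a", "b")))
    stop("contest table: side must be 'a' or 'b'")
  pairs <- unique(df[, c("pair_id", "maternal_strain", "male_a_paternal",
                         "male_b_paternal")])
  a <- df[df$side == "a", ]
  b <- df[df$side == "b", ]
  key_a <- paste(a$pair_id, a$observation)
  key_b <- paste(b$pair_id, b$observation)
  if (!setequal(key_a, key_b))
    stop("contest table: sides a and b must cover the same observations")
  m <- match(key_a, key_b)
  observations <- data.frame(
    pair_id = a$pair_id, observation = a$observation,
    attacks_a = a$attacks, attacks_b = b$attacks[m],
    submissive_a = a$submissive_poses, submissive_b = b$submissive_poses[m],
    stringsAsFactors = FALSE
  )
  contest_set(pairs, observations)
}

#' Write contest records to long-format TSV
#'
#' @param contests a [contest_set()].
#' @param path output file.
#' @export
write_contests <- function(contests, path) {
  stopifnot(inherits(contests, "contest_set"))
  obs <- contests$observations
  m <- match(obs$pair_id, contests$pairs$pair_id)
  long <- rbind(
    data.frame(pair_id = obs$pair_id,
               maternal_strain = contests$pairs$maternal_strain[m],
               male_a_paternal = contests$pairs$male_a_paternal[m],
               male_b_paternal = contests$pairs$male_b_paternal[m],
               observation = obs$observation, side = "a",
               attacks = obs$attacks_a, submissive_poses = obs$submissive_a,
               stringsAsFactors = FALSE),
    data.frame(pair_id = obs$pair_id,
               maternal_strain = contests$pairs$maternal_strain[m],
               male_a_paternal = contests$pairs$male_a_paternal[m],
               male_b_paternal = contests$pairs$male_b_paternal[m],
               observation = obs$observation, side = "b",
               attacks = obs$attacks_b, submissive_poses = obs$submissive_b,
               stringsAsFactors = FALSE)
  )
  long <- long[order(long$pair_id, long$observation, long$side), ]
  write_tsv(long, path)
}

#' Run the full candidate-marker pipeline
#'
#' Compares alleles for every SNP, tallies the expression and marker
#' dichotomies per body system, applies the equiprobable and 4:1
#' neutral-drift binomial tests to every tally row, and (when contest data
#' are given) cross-tabulates the mouse contests with per-strain chi-squared
#' tests. Inputs may be in-memory objects or file paths.
#'
#' @param promoters promoter list / `promoter_set`, or FASTA path.
#' @param snps SNP data frame or TSV path.
#' @param annotations annotation data frame or TSV path.
#' @param contests optional [contest_set()] or TSV path.
#' @param config a [model_config()] or path to a config file.
#' @param out_dir optional output directory for `comparisons.tsv`,
#'   `dichotomy.tsv`, `dichotomy_tests.tsv`, `cross_table.tsv`.
#' @return list with `comparisons`, `tally`, `tests` (one row per system
#'   with the equal-split and neutral-drift p-values), and `cross_table`
#'   (NULL without contest data).
#' @export
run_pipeline <- function(promoters, snps, annotations, contests = NULL,
                         config = default_model_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_model_config(config)
  if (is.character(promoters)) promoters <- read_promoter_fasta(promoters)
  if (is.character(snps)) snps <- read_snp_table(snps, promoters)
  if (is.character(annotations)) annotations <- read_annotations(annotations)
  if (is.character(contests)) contests <- read_contests(contests)
  comparisons <- compare_snps(promoters, snps, config)
  tally <- tally_markers(comparisons, annotations)
  tests <- do.call(rbind, lapply(seq_len(nrow(tally)), function(i) {
    r <- tally[i, ]
    eq_markers <- if (r$n_res >= 1)
      binom_equal_test(r$n_dom, r$n_sub)$p.value else NA_real_
    eq_expr <- if (r$n_res >= 1)
      binom_equal_test(r$n_over, r$n_under)$p.value else NA_real_
    neutral <- if (r$n_res >= 1)
      binom_neutral_test(r$n_over, r$n_under)$p.value else NA_real_
    data.frame(system = r$system, n_res = r$n_res,
               p_equal_markers = eq_markers, p_equal_expression = eq_expr,
               p_neutral_drift = neutral, stringsAsFactors = FALSE)
  }))
  cross <- if (!is.null(contests)) tabulate_crosses(contests) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(comparisons, file.path(out_dir, "comparisons.tsv"))
    write_tsv(as.data.frame(tally), file.path(out_dir, "dichotomy.tsv"))
    write_tsv(tests, file.path(out_dir, "dichotomy_tests.tsv"))
    if (!is.null(cross))
      write_tsv(as.data.frame(cross), file.path(out_dir, "cross_table.tsv"))
  }
  list(comparisons = comparisons, tally = tally, tests = tests,
       cross_table = cross)
}
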