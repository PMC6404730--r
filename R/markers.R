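MARKER_SYSTEMS <- c("neuropeptidergic", "non-neuropeptidergic",
                    "neurotrophinergic")
MARKER_POLARITIES <- c("excess_marks_dominance", "excess_marks_subordination")

#' Map an expression decision and a gene polarity to a candidate marker
#'
#' The decision-making rule: if an excess of the encoded protein is an
#' experimentally known physiological marker of a dominance-like phenotype
#' (`excess_marks_dominance`), then a SNP causing overexpression is a
#' candidate marker of the tendency in social dominance and one causing
#' underexpression a marker of subordination; the mapping is reversed for
#' `excess_marks_subordination` genes. Insignificant decisions yield no
#' marker.
#'
#' @param decision character vector over `overexpression`,
#'   `underexpression`, `insignificant`.
#' @param polarity character vector over `excess_marks_dominance`,
#'   `excess_marks_subordination` (recycled if length 1).
#' @return character vector over `dominance`, `subordination`, `none`.
#' @export
classify_marker <- function(decision, polarity) {
  ok_d <- decision %in% c("overexpression", "underexpression", "insignificant")
  if (!all(ok_d)) stop("invalid decision value: ",
                       paste(unique(decision[!ok_d]), collapse = ", "))
  ok_p <- polarity %in% MARKER_POLARITIES
  if (!all(ok_p)) stop("invalid polarity value: ",
                       paste(unique(polarity[!ok_p]), collapse = ", "))
  n <- max(length(decision), length(polarity))
  decision <- rep_len(decision, n)
  polarity <- rep_len(polarity, n)
  out <- rep("none", n)
  excess_dom <- polarity == "excess_marks_dominance"
  out[decision == "overexpression"] <-
    ifelse(excess_dom[decision == "overexpression"], "dominance", "subordination")
  out[decision == "underexpression"] <-
    ifelse(excess_dom[decision == "underexpression"], "subordination", "dominance")
  out
}

#' Tally expression and marker dichotomies per body system
#'
#' Joins per-SNP comparison results with gene annotations, classifies
#' candidate markers with [classify_marker()], and counts, per body system
#' and in TOTAL: significant results (`n_res`), overexpression (`n_over`)
#' and underexpression (`n_under`) calls, and dominance (`n_dom`) and
#' subordination (`n_sub`) markers. By construction
#' `n_res = n_over + n_under = n_dom + n_sub` in every row.
#'
#' @param comparisons data frame from [compare_snps()] (needs `gene_id` and
#'   `decision`).
#' @param annotations data frame with columns `gene_id`, `system`,
#'   `polarity` (see [read_annotations()]); every gene with a significant
#'   result must be annotated.
#' @return data frame of class `dichotomy_counts` with one row per system
#'   plus `TOTAL`. The per-SNP marker calls are attached as attribute
#'   `markers`.
#' @export
tally_markers <- function(comparisons, annotations) {
  stopifnot(all(c("gene_id", "decision") %in% names(comparisons)),
            all(c("gene_id", "system", "polarity") %in% names(annotations)))
  if (anyDuplicated(annotations$gene_id))
    stop("duplicated gene_id in annotations: ",
         paste(unique(annotations$gene_id[duplicated(annotations$gene_id)]),
               collapse = ", "))
  bad_sys <- setdiff(unique(annotations$system), MARKER_SYSTEMS)
  if (length(bad_sys)) stop("unknown body system: ",
                            paste(bad_sys, collapse = ", "))
  sig <- comparisons$decision != "insignificant"
  unannotated <- setdiff(unique(comparisons$gene_id[sig]),
                         annotations$gene_id)
  if (length(unannotated))
    stop("significant results lack annotation for gene(s): ",
         paste(unannotated, collapse = ", "))
  m <- match(comparisons$gene_id, annotations$gene_id)
  system <- annotations$system[m]
  polarity <- annotations$polarity[m]
  marker <- rep("none", nrow(comparisons))
  marker[sig] <- classify_marker(comparisons$decision[sig], polarity[sig])
  one_row <- function(keep, label) {
    data.frame(
      system = label,
      n_res = sum(sig & keep),
      n_dom = sum(marker == "dominance" & keep),
      n_sub = sum(marker == "subordination" & keep),
      n_over = sum(comparisons$decision == "overexpression" & keep),
      n_under = sum(comparisons$decision == "underexpression" & keep),
      stringsAsFactors = FALSE
    )
  }
  rows <- lapply(MARKER_SYSTEMS, function(s)
    one_row(!is.na(system) & system == s, s))
  rows <- c(rows, list(one_row(rep(TRUE, nrow(comparisons)), "TOTAL")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "markers") <- data.frame(
    variant_id = comparisons$variant_id, gene_id = comparisons$gene_id,
    decision = comparisons$decision, marker = marker,
    stringsAsFactors = FALSE
  )
  class(out) <- c("dichotomy_counts", class(out))
  out
}

#' @export
print.dichotomy_counts <- function(x, ...) {
  cat("Dichotomy counts (significant results, expression and marker splits)\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
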