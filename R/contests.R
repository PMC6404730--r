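MATERNAL_STRAINS <- c("PT", "C57BL/6J", "YT", "DD", "A/He")
PATERNAL_STRAINS <- c("BALB/cLac", "CBA/Lac")

#' Construct a set of dyadic contest records
#'
#' A contest set pairs two F1 hybrid males, sired by the two analytic
#' paternal strains on the same maternal inbred strain, and records their
#' agonistic interactions over repeated observations.
#'
#' @param pairs data frame with columns `pair_id`, `maternal_strain`,
#'   `male_a_paternal`, `male_b_paternal`; the two paternal strains of a
#'   pair must differ.
#' @param observations data frame with columns `pair_id`, `observation`,
#'   `attacks_a`, `attacks_b`, `submissive_a`, `submissive_b`; at least one
#'   observation per pair, all counts non-negative.
#' @return object of class `contest_set`.
#' @export
contest_set <- function(pairs, observations) {
  need_p <- c("pair_id", "maternal_strain", "male_a_paternal", "male_b_paternal")
  need_o <- c("pair_id", "observation", "attacks_a", "attacks_b",
              "submissive_a", "submissive_b")
  stopifnot(all(need_p %in% names(pairs)), all(need_o %in% names(observations)))
  if (anyDuplicated(pairs$pair_id)) stop("duplicated pair_id in pairs")
  bad <- !(pairs$maternal_strain %in% MATERNAL_STRAINS)
  if (any(bad)) stop("unknown maternal strain: ",
                     paste(unique(pairs$maternal_strain[bad]), collapse = ", "))
  bad <- !(pairs$male_a_paternal %in% PATERNAL_STRAINS) |
    !(pairs$male_b_paternal %in% PATERNAL_STRAINS)
  if (any(bad)) stop("unknown paternal strain in pairs: ",
                     paste(unique(pairs$pair_id[bad]), collapse = ", "))
  if (any(pairs$male_a_paternal == pairs$male_b_paternal))
    stop("the two males of a pair must have different paternal strains")
  counts <- as.matrix(observations[, c("attacks_a", "attacks_b",
                                       "submissive_a", "submissive_b")])
  if (any(counts < 0) || any(counts != round(counts)))
    stop("observation counts must be non-negative integers")
  orphan <- setdiff(observations$pair_id, pairs$pair_id)
  if (length(orphan)) stop("observations reference unknown pair(s): ",
                           paste(orphan, collapse = ", "))
  empty <- setdiff(pairs$pair_id, observations$pair_id)
  if (length(empty)) stop("pair(s) without observations: ",
                          paste(empty, collapse = ", "))
  structure(list(pairs = pairs, observations = observations),
            class = "contest_set")
}

#' @export
print.contest_set <- function(x, ...) {
  cat(sprintf("<contest_set> %d pairs, %d observations\n",
              nrow(x$pairs), nrow(x$observations)))
  invisible(x)
}

# per-pair totals in pairs order
contest_totals <- function(contests) {
  obs <- contests$observations
  agg <- function(col) tapply(obs[[col]], obs$pair_id, sum)
  tot <- data.frame(
    pair_id = names(agg("attacks_a")),
    attacks_a = as.vector(agg("attacks_a")),
    attacks_b = as.vector(agg("attacks_b")),
    submissive_a = as.vector(agg("submissive_a")),
    submissive_b = as.vector(agg("submissive_b")),
    stringsAsFactors = FALSE
  )
  tot[match(contests$pairs$pair_id, tot$pair_id), ]
}

#' Score dyadic contests for social dominance
#'
#' Sums attacks and submissive poses over all observations of each pair and
#' applies the dominance rule. Under the default conjunctive rule male `a`
#' is dominant iff it delivered strictly more attacks AND displayed strictly
#' fewer submissive poses than male `b` (and symmetrically for `b`); any
#' other asymmetry pattern is `unresolved`. The `attacks_only` rule uses
#' strict attack asymmetry alone.
#'
#' @param contests a [contest_set()].
#' @param rule `"attacks_and_poses"` (default) or `"attacks_only"`.
#' @return data frame with `pair_id`, `maternal_strain`, totals, and
#'   `outcome` in `a_dominant` / `b_dominant` / `unresolved`.
#' @export
score_contest <- function(contests, rule = c("attacks_and_poses", "attacks_only")) {
  rule <- match.arg(rule)
  stopifnot(inherits(contests, "contest_set"))
  tot <- contest_totals(contests)
  a_dom <- if (rule == "attacks_and_poses") {
    tot$attacks_a > tot$attacks_b & tot$submissive_a < tot$submissive_b
  } else tot$attacks_a > tot$attacks_b
  b_dom <- if (rule == "attacks_and_poses") {
    tot$attacks_b > tot$attacks_a & tot$submissive_b < tot$submissive_a
  } else tot$attacks_b > tot$attacks_a
  outcome <- rep("unresolved", nrow(tot))
  outcome[a_dom] <- "a_dominant"
  outcome[b_dom] <- "b_dominant"
  data.frame(pair_id = tot$pair_id,
             maternal_strain = contests$pairs$maternal_strain,
             tot[, -1, drop = FALSE], outcome = outcome,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-tabulate contest outcomes by maternal strain
#'
#' Counts, per maternal strain and in TOTAL, how many resolved pairs were
#' won by the BALB/cLac-sired versus the CBA/Lac-sired male, and applies
#' [chi2_equal_split()] to every row. Unresolved pairs are excluded from
#' the counts and reported via the `unresolved` attribute (and a message).
#'
#' @inheritParams score_contest
#' @return data frame of class `cross_table` with columns
#'   `maternal_strain`, `balb_dominant`, `cba_dominant`, `chi2`, `p_value`.
#' @export
tabulate_crosses <- function(contests,
                             rule = c("attacks_and_poses", "attacks_only")) {
  scored <- score_contest(contests, rule)
  pairs <- contests$pairs
  winner_paternal <- ifelse(scored$outcome == "a_dominant",
                            pairs$male_a_paternal,
                     ifelse(scored$outcome == "b_dominant",
                            pairs$male_b_paternal, NA))
  unresolved <- scored$pair_id[is.na(winner_paternal)]
  if (length(unresolved))
    message(length(unresolved), " unresolved pair(s) excluded: ",
            paste(unresolved, collapse = ", "))
  strains <- intersect(MATERNAL_STRAINS, unique(pairs$maternal_strain))
  one_row <- function(keep, label) {
    balb <- sum(winner_paternal[keep] == "BALB/cLac", na.rm = TRUE)
    cba <- sum(winner_paternal[keep] == "CBA/Lac", na.rm = TRUE)
    if (balb + cba >= 1) {
      ht <- chi2_equal_split(balb, cba)
      data.frame(maternal_strain = label, balb_dominant = balb,
                 cba_dominant = cba, chi2 = unname(ht$statistic),
                 p_value = ht$p.value, stringsAsFactors = FALSE)
    } else {
      data.frame(maternal_strain = label, balb_dominant = 0L,
                 cba_dominant = 0L, chi2 = NA_real_, p_value = NA_real_,
                 stringsAsFactors = FALSE)
    }
  }
  rows <- lapply(strains, function(s) one_row(scored$maternal_strain == s, s))
  rows <- c(rows, list(one_row(rep(TRUE, nrow(scored)), "TOTAL")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "unresolved") <- unresolved
  class(out) <- c("cross_table", class(out))
  out
}

#' @export
print.cross_table <- function(x, ...) {
  cat("Dominance cross-tabulation (BALB/cLac- vs CBA/Lac-sired winners)\n")
  print.data.frame(x, row.names = FALSE)
  un <- attr(x, "unresolved")
  if (length(un)) cat("unresolved pairs:", length(un), "\n")
  invisible(x)
}
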