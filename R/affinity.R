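#' @importFrom stats sd
NULL

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC ambiguity codes that may legally appear in input sequences before
# normalization; each maps to its alphabetically first compatible base.
IUPAC_FIRST <- c(
  R = "A", Y = "C", S = "C", W = "A", K = "G", M = "A",
  B = "C", D = "A", H = "A", V = "A", N = "A"
)

#' Normalize a nucleotide sequence
#'
#' Uppercases the sequence and handles IUPAC ambiguity codes. In strict mode
#' (the default) any non-ACGT character is an error; in lenient mode each
#' ambiguity code is resolved to its alphabetically first compatible base and
#' a warning is issued.
#'
#' @param sequence character scalar, nucleotide sequence.
#' @param lenient logical; resolve ambiguity codes instead of failing.
#' @return character scalar over A/C/G/T.
#' @export
normalize_sequence <- function(sequence, lenient = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- !(chars %in% DNA_BASES)
  if (any(bad)) {
    amb <- chars[bad] %in% names(IUPAC_FIRST)
    if (!lenient || !all(amb)) {
      stop("sequence contains non-ACGT characters: ",
           paste(unique(chars[bad]), collapse = ", "),
           if (!lenient && all(amb)) " (use lenient = TRUE to resolve IUPAC codes)")
    }
    warning("resolved ", sum(bad), " IUPAC ambiguity code(s) to first compatible base")
    chars[bad] <- IUPAC_FIRST[chars[bad]]
    s <- paste(chars, collapse = "")
  }
  s
}

#' Construct a promoter record
#'
#' A promoter record holds the strand-oriented 5'->3' sequence of the core
#' promoter region upstream of the protein-coding transcription start site
#' (TSS), together with the TSS-relative coordinate of its first base. The
#' conventional region is the 70 bp immediately upstream of the TSS, i.e.
#' offsets -70 .. -1 with `start_offset = -70`.
#'
#' @param gene_id gene identifier.
#' @param sequence nucleotide sequence (A/C/G/T after normalization).
#' @param transcript_id transcript identifier; defaults to `gene_id`.
#' @param start_offset integer, TSS-relative position of the first base.
#' @param flank optional upstream flanking sequence (5' of the region), used
#'   to re-pad the coordinate frame when a deletion variant is applied.
#' @param lenient passed to [normalize_sequence()].
#' @return object of class `promoter_record`.
#' @export
promoter_record <- function(gene_id, sequence, transcript_id = gene_id,
                            start_offset = -70L, flank = NULL,
                            lenient = FALSE) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))
  sequence <- normalize_sequence(sequence, lenient = lenient)
  start_offset <- as.integer(start_offset)
  if (!is.null(flank)) flank <- normalize_sequence(flank, lenient = lenient)
  structure(
    list(gene_id = gene_id, transcript_id = transcript_id,
         sequence = sequence, start_offset = start_offset, flank = flank),
    class = "promoter_record"
  )
}

#' @export
print.promoter_record <- function(x, ...) {
  cat(sprintf("<promoter_record> %s (%s), %d bp, offsets [%d, %d]\n",
              x$gene_id, x$transcript_id, nchar(x$sequence), x$start_offset,
              x$start_offset + nchar(x$sequence) - 1L))
  invisible(x)
}

# integer encoding A=1 C=2 G=3 T=4; errors on anything else
encode_bases <- function(sequence) {
  enc <- match(strsplit(sequence, "", fixed = TRUE)[[1]], DNA_BASES)
  if (anyNA(enc)) stop("sequence contains non-ACGT characters after normalization")
  enc
}

# validate and order a 16-entry dinucleotide property table (named vector)
as_dinuc_vector <- function(table, what = "property") {
  dinucs <- as.vector(outer(DNA_BASES, DNA_BASES, paste0)) # AA AC AG AT CA ...
  dinucs <- sort(dinucs)
  if (!all(dinucs %in% names(table)))
    stop(what, " table must cover all 16 dinucleotides; missing: ",
         paste(setdiff(dinucs, names(table)), collapse = ", "))
  v <- as.numeric(table[dinucs])
  if (any(!is.finite(v))) stop(what, " table contains non-finite values")
  names(v) <- dinucs
  v
}

#' Construct a three-step TBP affinity model configuration
#'
#' The model scores every window of `window_length` bases of a promoter by
#' three physical steps of TBP-promoter complex formation: (i) TBP sliding
#' along the double helix, captured by a dinucleotide step-flexibility scale;
#' (ii) TBP stopping at a putative binding site, captured by a position
#' weight matrix (PWM) of the TATA motif; and (iii) fixation of the complex
#' by DNA bending, captured by a dinucleotide bending-propensity scale.
#' Each raw step term f_i is mapped onto the -ln(KD) scale by a linear
#' calibration E_i = a_i + b_i * f_i.
#'
#' @param pwm 4 x window_length numeric matrix of stop-step weights, rows
#'   named A, C, G, T.
#' @param slide named numeric vector of length 16 (dinucleotide ->
#'   sliding-step property).
#' @param bend named numeric vector of length 16 (dinucleotide -> bending
#'   propensity).
#' @param calibration 3 x 2 numeric matrix with rows `stop`, `slide`, `bend`
#'   and columns `a`, `b` (intercept and slope of each per-step linear map).
#' @param window_length integer >= 2, width of the scanned site.
#' @param alpha_threshold significance level alpha = 1 - p above which an
#'   allele difference is called significant (default 0.95).
#' @return object of class `model_config`.
#' @seealso [default_model_config()], [read_model_config()]
#' @export
model_config <- function(pwm, slide, bend, calibration,
                         window_length = ncol(pwm), alpha_threshold = 0.95) {
  window_length <- as.integer(window_length)
  if (window_length < 2L) stop("window_length must be >= 2")
  if (!is.matrix(pwm) || nrow(pwm) != 4L || ncol(pwm) != window_length)
    stop("pwm must be a 4 x window_length matrix")
  if (is.null(rownames(pwm))) rownames(pwm) <- DNA_BASES
  pwm <- pwm[DNA_BASES, , drop = FALSE]
  if (any(!is.finite(pwm))) stop("pwm contains non-finite weights")
  calibration <- as.matrix(calibration)
  if (!all(c("stop", "slide", "bend") %in% rownames(calibration)) ||
      !all(c("a", "b") %in% colnames(calibration)))
    stop("calibration must have rows stop/slide/bend and columns a/b")
  calibration <- calibration[c("stop", "slide", "bend"), c("a", "b")]
  if (any(!is.finite(calibration))) stop("calibration contains non-finite values")
  if (!(alpha_threshold > 0 && alpha_threshold < 1))
    stop("alpha_threshold must lie in (0, 1)")
  structure(
    list(window_length = window_length, pwm = pwm,
         slide = as_dinuc_vector(slide, "slide"),
         bend = as_dinuc_vector(bend, "bend"),
         calibration = calibration, alpha_threshold = alpha_threshold),
    class = "model_config"
  )
}

#' Read a model configuration from a flat key-value file
#'
#' The file format is `key = value` with one key per line; `#` starts a
#' comment. Keys: `window_length`, `alpha_threshold`, `pwm_A` .. `pwm_T`
#' (space-separated weights, one row per base), `slide_AA` .. `slide_TT` and
#' `bend_AA` .. `bend_TT` (one value per dinucleotide), and
#' `calibration_stop`/`calibration_slide`/`calibration_bend` (two values:
#' intercept a and slope b).
#'
#' @param path file path.
#' @return object of class `model_config`.
#' @export
read_model_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- regmatches(lines, regexec("^([A-Za-z_0-9]+)\\s*=\\s*(.+)$", lines))
  if (any(lengths(kv) != 3L)) stop("malformed config line: ",
                                   lines[which(lengths(kv) != 3L)[1]])
  keys <- vapply(kv, `[`, "", 2L)
  vals <- lapply(kv, function(m) as.numeric(strsplit(trimws(m[3]), "\\s+")[[1]]))
  names(vals) <- keys
  need <- function(k) {
    if (is.null(vals[[k]])) stop("config is missing key: ", k)
    vals[[k]]
  }
  wl <- as.integer(need("window_length"))
  pwm <- do.call(rbind, lapply(DNA_BASES, function(b) need(paste0("pwm_", b))))
  rownames(pwm) <- DNA_BASES
  dinucs <- sort(as.vector(outer(DNA_BASES, DNA_BASES, paste0)))
  slide <- vapply(dinucs, function(d) need(paste0("slide_", d))[1], 0)
  bend <- vapply(dinucs, function(d) need(paste0("bend_", d))[1], 0)
  calib <- rbind(stop = need("calibration_stop"),
                 slide = need("calibration_slide"),
                 bend = need("calibration_bend"))
  colnames(calib) <- c("a", "b")
  model_config(pwm = pwm, slide = slide, bend = bend, calibration = calib,
               window_length = wl,
               alpha_threshold = need("alpha_threshold"))
}

#' Default TBP affinity model configuration
#'
#' Reads the configuration shipped with the package: a 15-position TATA-box
#' PWM (log2-odds of a consensus probability matrix against uniform base
#' composition), AT/GC-contrasted dinucleotide sliding-flexibility and
#' bending-propensity scales, and per-step calibrations anchored so that the
#' PWM consensus site maps to -ln(KD) = 20.8 (KD ~ 0.9 nM) on every step.
#'
#' @return object of class `model_config`.
#' @export
default_model_config <- function() {
  read_model_config(system.file("extdata", "tbp_model.cfg",
                                package = "tatadom", mustWork = TRUE))
}

#' PWM consensus sequence
#'
#' Per-position argmax of the stop-step weight matrix (ties resolved to the
#' alphabetically first base). Because the PWM score is additive, the
#' consensus attains the global maximum over all windows.
#'
#' @param config a `model_config`.
#' @return character scalar of length `window_length`.
#' @export
pwm_consensus <- function(config) {
  paste(DNA_BASES[apply(config$pwm, 2L, which.max)], collapse = "")
}

#' Score one window against the stop-step PWM
#'
#' Additive column-wise weight sum of a window of exactly the PWM width.
#'
#' @param window nucleotide string of length `ncol(pwm)`.
#' @param pwm 4 x L weight matrix with rows A, C, G, T.
#' @return numeric scalar.
#' @export
pwm_score <- function(window, pwm) {
  if (is.null(rownames(pwm))) rownames(pwm) <- DNA_BASES
  enc <- encode_bases(normalize_sequence(window))
  if (length(enc) != ncol(pwm))
    stop("window length (", length(enc), ") does not match pwm width (",
         ncol(pwm), ")")
  sum(pwm[cbind(enc, seq_along(enc))])
}

dinuc_term <- function(window, table, what) {
  enc <- encode_bases(normalize_sequence(window))
  if (length(enc) < 2L) stop(what, " term requires a window of length >= 2")
  v <- as_dinuc_vector(table, what)
  idx <- 4L * (enc[-length(enc)] - 1L) + enc[-1L]
  mean(v[idx])
}

#' Sliding-step term of a window
#'
#' Mean of the configured dinucleotide sliding property over the window's
#' overlapping dinucleotide steps.
#'
#' @param window nucleotide string, length >= 2.
#' @param table named numeric vector covering all 16 dinucleotides.
#' @return numeric scalar.
#' @export
slide_term <- function(window, table) dinuc_term(window, table, "slide")

#' Bending-step term of a window
#'
#' Mean of the configured dinucleotide bending propensity over the window's
#' overlapping dinucleotide steps.
#'
#' @inheritParams slide_term
#' @return numeric scalar.
#' @export
bend_term <- function(window, table) dinuc_term(window, table, "bend")

# raw per-window terms for an encoded sequence; returns nw x 3 matrix
raw_window_terms <- function(enc, config) {
  L <- config$window_length
  n <- length(enc)
  nw <- n - L + 1L
  idx <- outer(seq_len(nw), 0:(L - 1L), "+")
  stop_raw <- rowSums(matrix(config$pwm[cbind(as.vector(enc[idx]),
                                              rep(seq_len(L), each = nw))],
                             nrow = nw))
  din <- 4L * (enc[-n] - 1L) + enc[-1L]
  roll_mean <- function(v) {
    cs <- cumsum(c(0, unname(v)))
    (cs[(L - 1L) + seq_len(nw)] - cs[seq_len(nw)]) / (L - 1L)
  }
  cbind(stop = stop_raw,
        slide = roll_mean(config$slide[din]),
        bend = roll_mean(config$bend[din]))
}

#' Estimate TBP binding affinity of a promoter
#'
#' Applies the three-step model to every window fully inside the promoter
#' sequence. For window w the three calibrated partial estimates are
#' E_i(w) = a_i + b_i * f_i(w), i in (slide, stop, bend); the combined
#' window score is their unweighted mean. The reported affinity is the
#' maximum combined score over windows (argmax ties resolved to the
#' leftmost, i.e. most upstream, window), the uncertainty delta is the
#' sample standard deviation of the three partial estimates at the
#' maximizing window divided by sqrt(3), and `best_window_offset` is the
#' TSS-relative start of that window. Deterministic for a fixed
#' configuration.
#'
#' @param promoter a [promoter_record()] (or a plain nucleotide string, in
#'   which case `start_offset` is taken as -nchar(sequence)).
#' @param config a [model_config()].
#' @return object of class `affinity_estimate` with fields `neg_log_kd`,
#'   `delta`, `best_window_offset` and `partials` (the three calibrated
#'   partial estimates at the best window).
#' @export
estimate_affinity <- function(promoter, config) {
  if (is.character(promoter))
    promoter <- promoter_record("seq", promoter,
                                start_offset = -nchar(promoter))
  stopifnot(inherits(promoter, "promoter_record"),
            inherits(config, "model_config"))
  enc <- encode_bases(promoter$sequence)
  if (length(enc) < config$window_length)
    stop("sequence of ", promoter$gene_id, " is shorter (", length(enc),
         ") than the model window (", config$window_length, ")")
  raw <- raw_window_terms(enc, config)
  calib <- config$calibration
  E <- sweep(raw %*% diag(calib[, "b"]), 2L, -calib[, "a"])
  colnames(E) <- rownames(calib)
  combined <- rowMeans(E)
  j <- which.max(combined) # leftmost on ties
  partials <- E[j, ]
  structure(
    list(neg_log_kd = combined[[j]],
         delta = stats::sd(partials) / sqrt(3),
         best_window_offset = promoter$start_offset + j - 1L,
         partials = partials),
    class = "affinity_estimate"
  )
}

#' @export
print.affinity_estimate <- function(x, ...) {
  cat(sprintf("<affinity_estimate> -ln(KD) = %.3f +/- %.3f (best window at %d)\n",
              x$neg_log_kd, x$delta, x$best_window_offset))
  invisible(x)
}
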