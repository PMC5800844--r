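# Oxygen-dependent degradation (ODD) degron motif scanning.
#
# The strict consensus is the octamer L[D/E]x[L/R]AP[F/Y]I whose proline
# is hydroxylated under oxygen; the core tetramer [L/R]AP[F/Y] captures
# "similar motif" cases (e.g. LAMRAPYI) that fail the strict consensus.
# The clade variant of a hit is the tetramer at octamer positions 4-7:
# LAPY (vertebrate), RAPY (most protostomes; also cnidarians), RAPF
# (cnidarians), LAPF (placozoans).

# allowed residues per strict-pattern position; NULL = any (x)
.STRICT_PATTERN <- list("L", c("D", "E"), NULL, c("L", "R"), "A", "P",
                        c("F", "Y"), "I")
.CORE_PATTERN <- list(c("L", "R"), "A", "P", c("F", "Y"))

.motif_pattern <- function(mode) {
  switch(mode,
         strict = .STRICT_PATTERN,
         core = .CORE_PATTERN,
         stop("mode must be 'strict' or 'core'"))
}

.check_sequence <- function(chars) {
  ok <- chars %in% c(.AA20, "X", "*")
  if (!all(ok))
    stop("invalid sequence characters: ",
         paste(unique(chars[!ok]), collapse = ", "))
}

#' Scan a sequence region for ODD degron motifs
#'
#' Strict mode matches the full octamer consensus `L[D/E]x[L/R]AP[F/Y]I`;
#' core mode matches the tetramer `[L/R]AP[F/Y]`. All (possibly
#' overlapping) matches are reported, sorted by start. `X` in the
#' sequence matches only the unconstrained `x` position of the strict
#' pattern.
#'
#' @param sequence Uppercase amino-acid string (the 20 standard letters
#'   plus `X` and `*`).
#' @param region Integer `c(start, end)`, 0-based half-open, within the
#'   sequence; default the whole sequence.
#' @param mode `"strict"` or `"core"`.
#' @return Data.frame with columns `start` (0-based offset within the
#'   scanned region), `match` (the matched octamer or tetramer), `mode`,
#'   and `variant` (`LAPY`, `RAPY`, `RAPF` or `LAPF`).
#' @examples
#' scan_motif("AALEMLAPYIPA")            # strict hit at offset 2
#' scan_motif("GGLAMRAPYIGG", mode = "core")
#' @export
scan_motif <- function(sequence, region = NULL, mode = "strict") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  pat <- .motif_pattern(mode)
  k <- length(pat)
  n <- nchar(sequence)
  if (is.null(region)) region <- c(0L, n)
  if (region[1] < 0 || region[2] > n || region[1] > region[2])
    stop("region out of bounds")
  chars <- strsplit(sequence, "")[[1]]
  .check_sequence(chars)
  sub <- chars[seq.int(region[1] + 1L, length.out = region[2] - region[1])]
  starts <- .match_starts(sub, pat)
  if (length(starts) == 0L)
    return(data.frame(start = integer(0), match = character(0),
                      mode = character(0), variant = character(0),
                      stringsAsFactors = FALSE))
  match <- vapply(starts, function(s)
    paste(sub[(s + 1):(s + k)], collapse = ""), character(1))
  data.frame(start = starts, match = match, mode = mode,
             variant = if (mode == "strict") substr(match, 4, 7)
                       else match,
             stringsAsFactors = FALSE)
}

# vectorized window matching: 0-based starts of all pattern matches
.match_starts <- function(sub, pat) {
  L <- length(sub)
  k <- length(pat)
  if (L < k) return(integer(0))
  nwin <- L - k + 1L
  ok <- rep(TRUE, nwin)
  for (p in seq_len(k)) {
    allowed <- pat[[p]]
    if (is.null(allowed)) next  # unconstrained position
    ok <- ok & sub[seq.int(p, length.out = nwin)] %in% allowed
  }
  which(ok) - 1L
}

#' Residue composition of a sequence region
#'
#' Exact residue counts and frequencies over the 20-letter alphabet
#' (`X`/`*` are excluded from the denominator), plus the combined
#' proline+serine+glutamine fraction that characterizes bHLH-PAS
#' C-terminal tails.
#'
#' @inheritParams scan_motif
#' @return List of class `composition_stats`: `length` (region length in
#'   residues), `counts` (named integer over the 20 letters), `freq`
#'   (named numeric, `NA` when the region is empty), `psq_fraction`.
#' @export
composition <- function(sequence, region = NULL) {
  n <- nchar(sequence)
  if (is.null(region)) region <- c(0L, n)
  if (region[1] < 0 || region[2] > n || region[1] > region[2])
    stop("region out of bounds")
  chars <- strsplit(sequence, "")[[1]]
  .check_sequence(chars)
  sub <- chars[seq.int(region[1] + 1L, length.out = region[2] - region[1])]
  counts <- table(factor(sub[sub %in% .AA20], levels = .AA20))
  counts <- setNames(as.integer(counts), .AA20)
  tot <- sum(counts)
  freq <- if (tot > 0) counts / tot else setNames(rep(NA_real_, 20), .AA20)
  structure(
    list(length = length(sub), counts = counts, freq = freq,
         psq_fraction = if (tot > 0) unname(freq["P"] + freq["S"] + freq["Q"])
                        else NA_real_),
    class = "composition_stats")
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf("composition_stats: %d residues, P+S+Q fraction %s\n",
              x$length,
              if (is.na(x$psq_fraction)) "undefined"
              else sprintf("%.3f", x$psq_fraction)))
  invisible(x)
}

#' Expected chance motif count under an i.i.d. residue model
#'
#' Expected number of (overlapping) windows matching the motif in a
#' region of the given length and composition, assuming independent
#' residues: `E = (L - k + 1) * prod_p sum(freq[allowed at p])`, with the
#' unconstrained position contributing a factor of 1. Returns 0 when the
#' region is shorter than the pattern.
#'
#' @param stats A [composition()] result.
#' @param mode `"strict"` or `"core"`.
#' @return Expected match count (real, >= 0).
#' @export
expected_motif_count <- function(stats, mode = "strict") {
  stopifnot(inherits(stats, "composition_stats"))
  pat <- .motif_pattern(mode)
  k <- length(pat)
  L <- stats$length
  if (L < k) return(0)
  p_window <- prod(vapply(pat, function(allowed) {
    if (is.null(allowed)) 1 else sum(stats$freq[allowed])
  }, numeric(1)))
  (L - k + 1) * p_window
}

#' Permutation p-value for the observed motif count
#'
#' Residues within the region are permuted uniformly `n_shuffles` times;
#' the p-value is `(1 + #{shuffles with match count >= observed}) /
#' (n_shuffles + 1)`. The permutation null preserves the region's exact
#' composition (but not residue runs).
#'
#' @inheritParams scan_motif
#' @param n_shuffles Number of permutations (>= 1).
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return List: `observed` count, `p_value`, `mean_shuffled` and
#'   `sd_shuffled` (mean and SD of the match count across shuffles).
#' @export
motif_permutation_pvalue <- function(sequence, region = NULL,
                                     mode = "strict", n_shuffles = 999,
                                     seed = 1) {
  stopifnot(n_shuffles >= 1)
  n <- nchar(sequence)
  if (is.null(region)) region <- c(0L, n)
  observed <- nrow(scan_motif(sequence, region, mode))
  chars <- strsplit(sequence, "")[[1]]
  idx <- seq.int(region[1] + 1L, length.out = region[2] - region[1])
  sub <- chars[idx]
  pat <- .motif_pattern(mode)
  counts <- .with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i)
      length(.match_starts(sample(sub), pat)), numeric(1))
  })
  list(observed = observed,
       p_value = (1 + sum(counts >= observed)) / (n_shuffles + 1),
       mean_shuffled = mean(counts),
       sd_shuffled = stats::sd(counts))
}
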