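#' 5'-UTR sequence
#'
#' A DNA sequence with a marked transcription start site (TSS). Hairpin
#' scanning operates on the transcribed region downstream of the TSS.
#'
#' @param seq DNA string over A/C/G/T (case-insensitive).
#' @param tss_offset 0-based index of the transcription start within `seq`.
#' @return An object of class `utr_sequence`.
#' @export
utr_sequence <- function(seq, tss_offset = 0) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("sequence must be non-empty.", call. = FALSE)
  if (grepl("[^ACGT]", seq))
    stop("invalid characters in DNA sequence (A/C/G/T only).", call. = FALSE)
  if (tss_offset < 0 || tss_offset >= nchar(seq))
    stop("tss_offset must index into the sequence.", call. = FALSE)
  structure(list(seq = seq, tss_offset = as.integer(tss_offset)),
            class = "utr_sequence")
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcomp_chars <- function(chars) rev(unname(DNA_COMPLEMENT[chars]))

#' Reverse-complement a DNA string
#'
#' @param seq DNA string over A/C/G/T.
#' @return The reverse complement string.
#' @export
reverse_complement <- function(seq) {
  paste(revcomp_chars(strsplit(toupper(seq), "")[[1L]]), collapse = "")
}

#' Count stem-loop (hairpin) structures downstream of the TSS
#'
#' Scans the transcribed region left to right for perfect inverted repeats:
#' a hairpin is a stem of `>= min_stem` base pairs whose two arms are exact
#' reverse complements, separated by a loop of `loop_min`-`loop_max`
#' unconstrained nucleotides. At each position the longest qualifying stem is
#' taken (shortest loop on ties); accepted hairpins are non-overlapping and
#' the scan resumes immediately after each acceptance. This is a structural
#' count (no thermodynamic folding): consecutive hairpin counts of 7 versus 3
#' in an operator region are what separates blocked from near-full expression
#' (see [utr_penalty()]).
#'
#' @param utr A [utr_sequence()] (or plain DNA string, TSS at 0).
#' @param min_stem Minimal stem length (bp).
#' @param loop_min,loop_max Allowed loop length range (nt).
#' @param window Scan window downstream of the TSS (nt).
#' @return List with `count` and `calls`, a data.frame with 0-based
#'   `stem_start`, `stem_len`, `loop_len`, `arm5`, `arm3`.
#' @export
count_hairpins <- function(utr, min_stem = 4, loop_min = 3, loop_max = 8,
                           window = 120) {
  if (is.character(utr)) utr <- utr_sequence(utr)
  stopifnot(inherits(utr, "utr_sequence"))
  region <- substr(utr$seq, utr$tss_offset + 1L,
                   min(nchar(utr$seq), utr$tss_offset + window))
  if (nchar(region) == 0L)
    stop("no sequence downstream of the TSS.", call. = FALSE)
  chars <- strsplit(region, "")[[1L]]
  L <- length(chars)
  calls <- list()
  i <- 1L
  while (i <= L) {
    hit <- NULL
    max_stem <- (L - i + 1L - loop_min) %/% 2L
    if (max_stem >= min_stem) {
      for (stem in seq(max_stem, min_stem)) {
        for (loop in loop_min:loop_max) {
          end <- i + 2L * stem + loop - 1L
          if (end > L) next
          left <- chars[i:(i + stem - 1L)]
          right <- chars[(i + stem + loop):end]
          if (all(revcomp_chars(right) == left)) {
            hit <- list(stem = stem, loop = loop, end = end)
            break
          }
        }
        if (!is.null(hit)) break
      }
    }
    if (is.null(hit)) {
      i <- i + 1L
    } else {
      calls[[length(calls) + 1L]] <- data.frame(
        stem_start = utr$tss_offset + i - 1L,   # 0-based in the full sequence
        stem_len = hit$stem, loop_len = hit$loop,
        arm5 = paste(chars[i:(i + hit$stem - 1L)], collapse = ""),
        arm3 = paste(chars[(hit$end - hit$stem + 1L):hit$end], collapse = ""))
      i <- hit$end + 1L
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(stem_start = integer(), stem_len = integer(),
               loop_len = integer(), arm5 = character(), arm3 = character())
  list(count = nrow(calls), calls = calls)
}

#' Dyad symmetry score of an operator site
#'
#' Fraction of positions that are complementary to their mirror position
#' about the site's centre (the middle base of odd-length sites is ignored).
#' 1.0 means a perfect dyad (the site equals its own reverse complement), the
#' geometry that maximises both repressor affinity and hairpin formation in
#' the transcript.
#'
#' @param site DNA string, length >= 4.
#' @return Fraction in `[0, 1]`.
#' @export
dyad_symmetry_score <- function(site) {
  site <- toupper(site)
  if (grepl("[^ACGT]", site))
    stop("invalid characters in DNA sequence (A/C/G/T only).", call. = FALSE)
  L <- nchar(site)
  if (L < 4L) stop("site must be at least 4 nt long.", call. = FALSE)
  chars <- strsplit(site, "")[[1L]]
  idx <- setdiff(seq_len(L), if (L %% 2L == 1L) (L + 1L) %/% 2L else integer())
  matches <- sum(DNA_COMPLEMENT[chars[idx]] == chars[L + 1L - idx])
  matches / length(idx)
}

#' UTR expression penalty from sequence
#'
#' Composition of [count_hairpins()] and [utr_penalty()]: the predicted
#' expression multiplier of a transcript whose 5'-UTR is the given sequence.
#'
#' @inheritParams count_hairpins
#' @param ... Passed to [count_hairpins()].
#' @return Multiplier in `(0, 1]`.
#' @export
utr_penalty_from_sequence <- function(utr, ...) {
  utr_penalty(count_hairpins(utr, ...)$count)
}

#' Read 5'-UTR sequences from a FASTA file
#'
#' @param path FASTA file.
#' @param tss_offset 0-based TSS index applied to every record.
#' @return Named list of [utr_sequence()] objects.
#' @export
read_utr_fasta <- function(path, tss_offset = 0) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA requires the Biostrings package.", call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  out <- lapply(as.character(set), utr_sequence, tss_offset = tss_offset)
  names(out) <- names(set)
  out
}
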