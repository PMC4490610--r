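# Independent oracles used across the suite.

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Exhaustive O(L^3) inverted-repeat enumerator: every (start, stem, loop)
# triple whose arms are exact reverse complements. Complementarity is checked
# through a precomputed pairing matrix, a mechanism unrelated to the scanner.
enumerate_inverted_repeats <- function(seq, min_stem = 4, loop_min = 3,
                                       loop_max = 8) {
  chars <- strsplit(toupper(seq), "")[[1L]]
  L <- length(chars)
  comp_pair <- outer(chars, chars, function(a, b)
    (a == "A" & b == "T") | (a == "T" & b == "A") |
      (a == "C" & b == "G") | (a == "G" & b == "C"))
  cand <- list()
  for (i in seq_len(L)) {
    max_stem <- (L - i + 1L - loop_min) %/% 2L
    if (max_stem < min_stem) next
    for (stem in min_stem:max_stem) {
      for (loop in loop_min:loop_max) {
        end <- i + 2L * stem + loop - 1L
        if (end > L) next
        # arm positions i+k must pair with end-k
        if (all(comp_pair[cbind(i:(i + stem - 1L), end:(end - stem + 1L))]))
          cand[[length(cand) + 1L]] <- c(start = i, stem = stem,
                                         loop = loop, end = end)
      }
    }
  }
  if (length(cand)) do.call(rbind, cand)
  else matrix(integer(), ncol = 4L,
              dimnames = list(NULL, c("start", "stem", "loop", "end")))
}

# Greedy non-overlap selection over the exhaustive candidate list: leftmost
# start, longest stem, shortest loop, resume after the accepted hairpin.
oracle_hairpin_count <- function(seq, min_stem = 4, loop_min = 3,
                                 loop_max = 8) {
  cm <- enumerate_inverted_repeats(seq, min_stem, loop_min, loop_max)
  L <- nchar(seq)
  count <- 0L
  i <- 1L
  while (i <= L) {
    here <- cm[cm[, "start"] == i, , drop = FALSE]
    if (nrow(here)) {
      here <- here[order(-here[, "stem"], here[, "loop"]), , drop = FALSE]
      count <- count + 1L
      i <- here[1L, "end"] + 1L
    } else {
      i <- i + 1L
    }
  }
  count
}

# A synthetic UTR made of n perfect stem-5/loop-4 hairpin units separated by
# non-complementary spacers.
synthetic_hairpin_utr <- function(n) {
  unit <- "GGCGCAAAAGCGCC"
  spacers <- c("ATTACT", "TCCTAA", "ATCTAC", "TTCATA", "ACTATT", "TATCAT",
               "TCATTA")
  if (n == 0L) return(paste(rep("ATTACT", 4L), collapse = ""))
  paste0(paste0(vapply(seq_len(n - 1L), function(k)
    paste0(unit, spacers[((k - 1L) %% length(spacers)) + 1L], ""), ""),
    collapse = ""), unit)
}

# Random valid Hill parameter sets for property tests.
random_hill_params <- function() {
  hill_params(A = stats::runif(1, 0, 100), B = stats::runif(1, 10, 5000),
              C = 10^stats::runif(1, -6, -2), n = stats::runif(1, 0.5, 4))
}

logic_grid_outputs <- function(predict_fun) {
  cond <- logic_conditions()
  mapply(predict_fun, cond$conc_a, cond$conc_b)
}
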