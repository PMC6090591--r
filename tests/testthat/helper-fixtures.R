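# Shared fixtures built in code: tiny count matrices, metadata sheets and
# motifs used across the module tests.

tinyCounts <- function() {
  m <- matrix(c(10L, 30L, 20L, 60L), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  m
}

tinyMeta <- function(samples, transition = "RB", time_h = 0) {
  data.frame(sample_id = samples,
             transition = rep_len(transition, length(samples)),
             time_h = rep_len(time_h, length(samples)),
             colony_id = rep_len(paste0("col", 1:2), length(samples)),
             stringsAsFactors = FALSE)
}

# sharp single-peak PWM of a given consensus word
sharpPwm <- function(word = "ACGTACGTACGT", peak = 0.97) {
  bases <- c("A", "C", "G", "T")
  L <- nchar(word)
  probs <- matrix((1 - peak) / 3, 4, L, dimnames = list(bases, NULL))
  idx <- match(strsplit(word, "")[[1]], bases)
  probs[cbind(idx, seq_len(L))] <- peak
  new("PositionWeightMatrix", name = "sharp",
      counts = probs * 100, probs = probs, pseudocount = 0)
}

# balanced two-transition design sheet used by DE tests
designSheet <- function(nControl = 4L, nRep = 8L, nColonies = 8L,
                        times = c(12, 24, 48, 96)) {
  rows <- list()
  for (tr in c("RB", "BR")) {
    rows[[length(rows) + 1L]] <- data.frame(
      transition = tr, time_h = 0, replicate = seq_len(nControl),
      colony_id = paste0("col", seq_len(nControl)))
    for (t0 in times)
      rows[[length(rows) + 1L]] <- data.frame(
        transition = tr, time_h = t0, replicate = seq_len(nRep),
        colony_id = paste0("col", ((seq_len(nRep) - 1L) %% nColonies) + 1L))
  }
  sheet <- do.call(rbind, rows)
  sheet$sample_id <- sprintf("%s_%d_r%d", sheet$transition, sheet$time_h,
                             sheet$replicate)
  sheet
}

# random partition of `genes` into `k` labelled clusters (all non-empty)
randomPartition <- function(genes, k) {
  repeat {
    lab <- sample.int(k, length(genes), replace = TRUE)
    if (length(unique(lab)) == k) break
  }
  setNames(lab, genes)
}
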