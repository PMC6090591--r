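# explicit hypergeometric tail by enumeration, independent of phyper
enumFisherP <- function(cluster, target, universe) {
  N <- length(universe); K <- length(target); n <- length(cluster)
  a <- length(intersect(cluster, target))
  kk <- a:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

test_that("Fisher enrichment matches exhaustive enumeration on small
           universes", {
  set.seed(5)
  for (i in 1:20) {
    N <- sample(8:25, 1)
    universe <- paste0("g", seq_len(N))
    cluster <- sample(universe, sample(2:(N - 2), 1))
    target <- sample(universe, sample(2:(N - 2), 1))
    r <- fisherEnrichment(cluster, target, universe)
    expect_equal(r$pvalue, enumFisherP(cluster, target, universe),
                 tolerance = 1e-12)
    # hypergeometric symmetry: cluster and target are exchangeable
    expect_equal(fisherEnrichment(target, cluster, universe)$pvalue,
                 r$pvalue, tolerance = 1e-12)
  }
  universe <- paste0("g", 1:20)
  half <- universe[1:10]
  expect_equal(fisherEnrichment(half, half, universe)$pvalue,
               enumFisherP(half, half, universe), tolerance = 1e-14)
  expect_equal(fisherEnrichment(universe, half, universe)$pvalue, 1)
  expect_error(fisherEnrichment(c(half, "zz"), half, universe), "outside")
})

test_that("cluster-wide enrichment recovers planted concentrations and stays
           calibrated under random labels", {
  set.seed(8)
  genes <- paste0("g", 1:500)
  lab <- setNames(rep(1:10, each = 50), genes)
  # DEGs concentrated in clusters 1-3 at far above background rate
  deg <- c(sample(genes[lab %in% 1:3], 90), sample(genes[lab %in% 4:10], 10))
  res <- enrichAllClusters(lab, list(DEG = deg))
  expect_equal(nrow(res), 10)
  expect_setequal(res$cluster[res$enriched], 1:3)
  expect_true(all(res$padj >= res$pvalue))
  # uniform random labels: flagged fraction stays near the FDR level
  flagged <- replicate(20, {
    degR <- sample(genes, 100)
    mean(enrichAllClusters(lab, list(DEG = degR))$enriched)
  })
  expect_lte(mean(flagged), 0.05)
  expect_warning(enrichAllClusters(lab, list(a = character(0), b = deg)),
                 "empty")
})

test_that("PWM scanning matches hand-computed and brute-force oracles", {
  # single-column motif heavily favoring A on "ACGT": forward hit at 0 and a
  # reverse-strand hit on the complement of T at position 3
  probs <- matrix(c(0.97, 0.01, 0.01, 0.01), 4, 1,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm1 <- new("PositionWeightMatrix", name = "a1", counts = probs,
              probs = probs, pseudocount = 0)
  hits <- scanPwm("ACGT", pwm1, threshold = 1)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$position, c(0, 3))
  expect_equal(hits$strand, c("+", "-"))
  expect_true(all(hits$relScore == 1))
  # no consensus word, threshold 1: nothing
  expect_equal(nrow(scanPwm("CCCC", pwm1, threshold = 1)), 0)
  expect_error(scanPwm("ACGX", pwm1), "invalid")

  # brute-force oracle over all windows and strands
  rcmap <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  bruteScan <- function(s, pwm, thr) {
    L <- rbind(log2(pwmProbs(pwm) / 0.25), N = 0)
    w <- ncol(L)
    smax <- sum(apply(L[1:4, , drop = FALSE], 2, max))
    smin <- sum(apply(L[1:4, , drop = FALSE], 2, min))
    ch <- strsplit(s, "")[[1]]
    out <- list()
    for (st in seq_len(nchar(s) - w + 1)) {
      win <- ch[st:(st + w - 1)]
      for (strand in c("+", "-")) {
        word <- if (strand == "+") win else rev(unname(rcmap[win]))
        sc <- sum(vapply(seq_len(w), function(j) L[word[j], j], numeric(1)))
        rel <- (sc - smin) / (smax - smin)
        if (rel >= thr)
          out[[length(out) + 1]] <- data.frame(position = st - 1,
                                               strand = strand,
                                               relScore = rel)
      }
    }
    if (length(out)) do.call(rbind, out) else
      data.frame(position = integer(0), strand = character(0),
                 relScore = numeric(0))
  }
  set.seed(10)
  pwm <- sharpPwm("ACGGTA", peak = 0.7)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 60, replace = TRUE,
                      prob = c(.24, .24, .24, .24, .04)), collapse = "")
    thr <- sample(c(0.6, 0.75, 0.9), 1)
    mine <- scanPwm(s, pwm, thr)
    oracle <- bruteScan(s, pwm, thr)
    o <- order(oracle$position, oracle$strand)
    expect_equal(mine$position, oracle$position[o])
    expect_equal(mine$strand, oracle$strand[o])
    expect_equal(mine$relScore, oracle$relScore[o], tolerance = 1e-12)
  }
})

test_that("reverse-complementing a sequence mirrors the hit set", {
  set.seed(12)
  pwm <- sharpPwm("ACGGTA", peak = 0.7)
  w <- ncol(pwmProbs(pwm))
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
               collapse = "")
    h1 <- scanPwm(s, pwm, 0.5)
    h2 <- scanPwm(rc(s), pwm, 0.5)
    expect_gt(nrow(h1), 0)
    # map reverse-complement coordinates back to the original
    mapped <- data.frame(position = nchar(s) - w - h2$position,
                         strand = as.character(ifelse(h2$strand == "+",
                                                      "-", "+")),
                         relScore = h2$relScore)
    o1 <- order(h1$position, h1$strand)
    o2 <- order(mapped$position, mapped$strand)
    expect_equal(h1$position[o1], mapped$position[o2])
    expect_equal(h1$strand[o1], mapped$strand[o2])
    expect_equal(h1$relScore[o1], mapped$relScore[o2], tolerance = 1e-12)
  }
})

test_that("relative scores are normalized to the achievable range", {
  pwm <- sharpPwm("ACGT", peak = 0.7)
  s <- "TTACGTAGGACGTT"
  h <- scanPwm(s, pwm, threshold = 0)
  expect_true(all(h$relScore >= 0 & h$relScore <= 1))
  # the consensus word scores exactly 1, a worst-case word exactly 0
  expect_equal(max(scanPwm("ACGT", pwm, 0)$relScore), 1)
  expect_equal(min(scanPwm("CAAA", pwm, 0)$relScore), 0)
})

test_that("genesWithSite separates planted from background promoters", {
  pwm <- sharpPwm("ACGTTGCAACGTAT")   # 14-mer: chance consensus ~ 4^-14
  genes <- sprintf("g%02d", 1:30)
  site <- genes[1:8]
  prom <- simulatePromoters(genes, pwm, site, length = 200, seed = 3)
  found <- genesWithSite(prom, pwm, threshold = 0.95)
  expect_true(all(site %in% found))
  # all-background promoters carry no hit at the strict threshold
  bg <- simulatePromoters(genes, pwm, character(0), length = 200, seed = 4)
  expect_length(genesWithSite(bg, pwm, threshold = 1), 0)
  expect_setequal(genesWithSite(bg, pwm, threshold = 0), genes)
})
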