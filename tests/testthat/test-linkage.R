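test_that("allele-frequency arithmetic and folding behave at the boundaries", {
  expect_equal(mutant_allele_frequency(c(0, 12, 1), c(10, 0, 3)),
               c(1, 0, 0.75))
  expect_true(is.na(mutant_allele_frequency(0, 0)))
  expect_error(mutant_allele_frequency(-1, 5), "non-negative")

  expect_equal(fold_frequency(c(0.5, 0.1, 1.0, 0)), c(0.5, 0.9, 1.0, 1.0))
  expect_true(all(fold_frequency(seq(0, 1, 0.05)) >= 0.5))
  expect_error(fold_frequency(1.2), "\\[0, 1\\]")
})

test_that("centered sliding windows reproduce hand-computed and constant profiles", {
  pr <- data.frame(chrom = "c1", pos = 1:5, folded_freq = c(1, 1, 1, 0.5, 0.5))
  out <- sliding_window_profile(pr, window = 3, quiet = TRUE)
  expect_equal(out$window_freq, c(NA, 1, 5/6, 2/3, NA))

  pr2 <- data.frame(chrom = "c1", pos = 1:60, folded_freq = rep(0.5, 60))
  out2 <- sliding_window_profile(pr2, window = 50, quiet = TRUE)
  defined <- !is.na(out2$window_freq)
  expect_equal(sum(defined), 11)             # 60 - 50 + 1 full windows
  expect_true(all(out2$window_freq[defined] == 0.5))
})

test_that("sliding windows match the naive per-window oracle and stay bounded", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(55:200, 1)
    x <- runif(n, 0.5, 1)
    pr <- data.frame(chrom = "c1", pos = seq_len(n), folded_freq = x)
    for (w in c(1, 2, 3, 7, 50)) {
      got <- sliding_window_profile(pr, window = w, quiet = TRUE)$window_freq
      expect_equal(got, naive_window_mean(x, w))
      ok <- which(!is.na(got))
      left <- (w - 1) %/% 2; right <- w - 1 - left
      for (i in ok[c(1, length(ok))]) {      # bounds at both edges
        win <- x[(i - left):(i + right)]
        expect_gte(got[i], min(win)); expect_lte(got[i], max(win))
      }
    }
  }
})

test_that("windows never span chromosome boundaries and short chromosomes stay undefined", {
  pr <- data.frame(chrom = rep(c("c1", "c2"), c(6, 3)), pos = c(1:6, 1:3),
                   folded_freq = c(rep(1, 6), rep(0.6, 3)))
  expect_message(out <- sliding_window_profile(pr, window = 5),
                 "fewer than 5 usable markers")
  expect_true(all(is.na(out$window_freq[pr$chrom == "c2"])))
  expect_equal(sum(!is.na(out$window_freq[pr$chrom == "c1"])), 2)
})

test_that("no-data markers are excluded from windows but conserved in the profile", {
  cnt <- make_counts("c1", 1:8, mut_ref = c(5, 0, 5, 5, 5, 5, 0, 5),
                     mut_alt = c(5, 0, 15, 15, 5, 5, 0, 5))
  fit <- linkage_scan(cnt, window = 3, quiet = TRUE)
  expect_equal(nrow(fit$profile), 8)         # retained + no-data = input
  expect_equal(fit$n_no_data, 2)
  expect_true(all(is.na(fit$profile$window_freq[c(2, 7)])))
  # window at marker 3 averages usable neighbors 1, 3, 4 (skipping row 2)
  expect_equal(fit$profile$window_freq[3],
               mean(fold_frequency(c(0.5, 0.75, 0.75))))
})

test_that("the peak interval matches a brute-force argmax plus run expansion", {
  set.seed(7)
  pos <- sort(sample.int(3e7, 300))
  wf <- 0.55 + runif(300, 0, 0.02)
  wf[120:180] <- 1.0                          # plateau
  pr <- data.frame(chrom = "c9", pos = pos, window_freq = wf)
  iv <- find_linkage_region(pr, quiet = TRUE)
  expect_equal(iv$status, "linked")
  expect_equal(iv$chrom, "c9")
  expect_equal(iv$start, pos[120])
  expect_equal(iv$end, pos[180])
  expect_equal(iv$peak_window_freq, 1.0)
  expect_equal(iv$n_markers_in_interval, 61)
})

test_that("flat profiles yield a no-linkage call and ties resolve to the longest, leftmost plateau", {
  flat <- data.frame(chrom = "c1", pos = 1:80,
                     window_freq = rep(0.55, 80))
  iv <- find_linkage_region(flat, quiet = TRUE)
  expect_equal(iv$status, "no_linkage")
  expect_true(is.na(iv$chrom))

  wf <- rep(0.6, 60)
  wf[10:14] <- 0.95                           # length-5 plateau on c1
  wf[40:42] <- 0.95                           # length-3 plateau, later
  pr <- data.frame(chrom = "c1", pos = 1:60, window_freq = wf)
  iv2 <- find_linkage_region(pr, quiet = TRUE)
  expect_equal(c(iv2$start, iv2$end), c(10, 14))

  wf3 <- rep(0.6, 60)
  wf3[30:32] <- 0.95
  wf3[50:52] <- 0.95                          # equal length: leftmost wins
  pr3 <- data.frame(chrom = "c1", pos = 1:60, window_freq = wf3)
  expect_message(iv3 <- find_linkage_region(pr3), "tied peak plateaus")
  expect_equal(c(iv3$start, iv3$end), c(30, 32))
})

test_that("an error-free recombination-suppressed cross drives the peak window to exactly 1", {
  g <- make_genome(list(chr1 = sort(sample.int(5e7, 60)),
                        chr2 = sort(sample.int(5e7, 60))),
                   length_cM = c(0, 100))
  cr <- simulate_cross(g, cross_config(
    n_mutant_pool = 20, n_wildtype_pool = 20,
    causative = list(chrom = "chr1", pos = g$markers$pos[30]),
    seq_error_rate = 0, seed = 17))
  fit <- linkage_scan(cr$counts, window = 50, quiet = TRUE)
  expect_equal(fit$interval$peak_window_freq, 1.0)
  expect_equal(fit$interval$chrom, "chr1")
})

test_that("interval runs touching the windowed edge extend to the chromosome end", {
  n <- 100
  wf <- c(rep(NA, 10), rep(1, 20), seq(0.9, 0.55, length.out = 60),
          rep(NA, 10))
  pr <- data.frame(chrom = "cE", pos = seq_len(n) * 1000, window_freq = wf)
  iv <- find_linkage_region(pr, quiet = TRUE)
  expect_equal(iv$start, 1000)               # extended through the flank
  expect_equal(iv$end, pr$pos[30])
})

test_that("the unlinked-genome baseline keeps folded frequencies well below the peak", {
  g <- make_genome(list(chr1 = c(1e7, 2.5e7, 4e7),
                        chr2 = seq(2e6, 4.8e7, length.out = 30)))
  folded <- sapply(1:40, function(s) {
    cr <- simulate_cross(g, cross_config(
      n_mutant_pool = 108, n_wildtype_pool = 108,
      causative = list(chrom = "chr1", pos = 2.5e7), seed = 400 + s))
    un <- which(cr$counts$chrom == "chr2")   # unlinked chromosome
    mean(fold_frequency(mutant_allele_frequency(
      cr$counts$mut_ref[un], cr$counts$mut_alt[un])), na.rm = TRUE)
  })
  expect_lt(mean(folded), 0.60)
})
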