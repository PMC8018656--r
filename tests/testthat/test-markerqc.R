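# Marker statistics.

test_that("allele frequencies: hand-counted examples", {
  g <- dplyr::bind_rows(
    geno_row("s1", L1 = c(1, 1)),
    geno_row("s2", L1 = c(1, 2)),
    geno_row("s3", L1 = c(2, 3))
  )
  fr <- allele_frequencies(g, "L1")
  expect_equal(fr$freq, c(0.5, 1 / 3, 1 / 6))

  all_aa <- geno_row("s1", L1 = c(7, 7))
  expect_equal(allele_frequencies(all_aa, "L1")$freq, 1)
  one_het <- geno_row("s1", L1 = c(1, 2))
  expect_equal(allele_frequencies(one_het, "L1")$freq, c(0.5, 0.5))
  none <- geno_row("s1", L1 = c(0, 0))
  expect_error(allele_frequencies(none, "L1"), "No typed individuals")
})

test_that("locus statistics match closed forms for equifrequent alleles", {
  # 2 equifrequent alleles: construct AA, BB, AB, AB -> p = (.5, .5)
  g <- dplyr::bind_rows(
    geno_row("s1", L1 = c(1, 1)),
    geno_row("s2", L1 = c(2, 2)),
    geno_row("s3", L1 = c(1, 2)),
    geno_row("s4", L1 = c(1, 2))
  )
  st <- locus_stats(g, "L1", include_hwe = FALSE)
  expect_equal(st$PIC, 0.375, tolerance = 1e-12)
  expect_equal(st$PID, 0.375, tolerance = 1e-12)
  expect_equal(st$H_E, 0.5, tolerance = 1e-12)
  expect_equal(st$A_e, 2, tolerance = 1e-12)
  expect_equal(st$H_O, 0.5)
  expect_equal(st$n_typed, 4L)

  mono <- dplyr::bind_rows(
    geno_row("s1", L1 = c(5, 5)),
    geno_row("s2", L1 = c(5, 5))
  )
  sm <- locus_stats(mono, "L1", include_hwe = FALSE)
  expect_equal(
    unlist(sm[c("A_n", "A_e", "H_O", "H_E", "PIC", "PID")]),
    c(A_n = 1, A_e = 1, H_O = 0, H_E = 0, PIC = 0, PID = 1)
  )
  expect_true(sm$null_flag)
})

test_that("PID follows (2k-1)/k^3 for k equifrequent alleles and multiplies across loci", {
  for (k in 2:10) {
    p <- rep(1 / k, k)
    s2 <- sum(p^2)
    s4 <- sum(p^4)
    expect_equal(2 * s2^2 - s4, (2 * k - 1) / k^3, tolerance = 1e-12)
  }
  expect_equal(cumulative_pid(c(0.375, 0.375)), 0.140625, tolerance = 1e-12)
  expect_equal(cumulative_pid(0.42), 0.42)
  expect_error(cumulative_pid(numeric(0)), "one locus")
})

test_that("statistics are invariant under allele-size relabeling and obey PIC <= H_E", {
  world <- simulate_world(51, quota = 120, anomalies = FALSE)
  stats <- marker_stats(world$farm, include_hwe = FALSE)
  expect_true(all(stats$PIC <= stats$H_E + 1e-12))
  expect_true(all(stats$A_e <= stats$A_n + 1e-12))
  ok <- c("H_O", "H_E", "PIC", "PID", "Pe1", "Pe2")
  expect_true(all(as.matrix(stats[ok]) >= 0 & as.matrix(stats[ok]) <= 1))

  # relabel allele sizes with an order-scrambling injective map
  relabeled <- world$farm
  for (l in str_loci(relabeled)) {
    for (suffix in c(".1", ".2")) {
      col <- paste0(l, suffix)
      a <- relabeled[[col]]
      relabeled[[col]] <- ifelse(a == 0L, 0L, 997L - 3L * a %% 601L)
    }
    # restore sorted-pair storage
    c1 <- paste0(l, ".1")
    c2 <- paste0(l, ".2")
    lo <- pmin(relabeled[[c1]], relabeled[[c2]])
    hi <- pmax(relabeled[[c1]], relabeled[[c2]])
    relabeled[[c1]] <- lo
    relabeled[[c2]] <- hi
  }
  stats2 <- marker_stats(relabeled, include_hwe = FALSE)
  for (col in c("A_n", "A_e", "H_O", "H_E", "PIC", "PID", "Pe1", "Pe2", "null_freq")) {
    expect_equal(stats2[[col]], stats[[col]], tolerance = 1e-12)
  }
})

test_that("exclusion probabilities agree with the brute-force oracle", {
  withr::with_seed(53, {
    for (k in c(2, 3, 5)) {
      p <- rgamma(k, 1)
      p <- p / sum(p)
      impl <- bonematch:::pe_exclusion(p)
      oracle <- pe_oracle(p)
      expect_equal(impl$Pe1, unname(oracle["Pe1"]), tolerance = 1e-12)
      expect_equal(impl$Pe2, unname(oracle["Pe2"]), tolerance = 1e-12)
    }
  })
})

test_that("null-allele estimate follows the heterozygote deficit", {
  # all homozygotes at a 2-allele locus: H_O = 0, He = 0.5 -> null = 1
  g <- dplyr::bind_rows(
    geno_row("s1", L1 = c(1, 1)),
    geno_row("s2", L1 = c(2, 2))
  )
  st <- locus_stats(g, "L1", include_hwe = FALSE)
  expect_equal(st$null_freq, 1)
  # heterozygote excess clips at zero
  g2 <- dplyr::bind_rows(
    geno_row("s1", L1 = c(1, 2)),
    geno_row("s2", L1 = c(1, 2))
  )
  expect_equal(locus_stats(g2, "L1", include_hwe = FALSE)$null_freq, 0)
})
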