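# Shared fixtures and independent oracles. Everything is generated in code;
# oracles are deliberately written with a different parameterization than
# the implementation they check.

# Minimal wide genotype tibble from a list of per-locus allele pairs.
geno_row <- function(sample_id, ..., tag = sample_id, facility_id = "FAC01",
                     site = "FARM", year = 2018L) {
  pairs <- list(...)
  cols <- list(
    sample_id = sample_id, tag = tag, facility_id = facility_id,
    site = site, year = year, claimed_species = "LION"
  )
  for (l in names(pairs)) {
    p <- sort(pairs[[l]])
    cols[[paste0(l, ".1")]] <- as.integer(p[1])
    cols[[paste0(l, ".2")]] <- as.integer(p[2])
  }
  tibble::as_tibble(cols)
}

# Draw F1 hybrids: one allele per locus from each species' frequency table.
simulate_f1_hybrids <- function(panels, n, seed) {
  withr::with_seed(seed, {
    loci <- unique(panels$lion$locus)
    cols <- lapply(loci, function(l) {
      sl <- panels$lion[panels$lion$locus == l, ]
      st <- panels$tiger[panels$tiger$locus == l, ]
      a1 <- sample(sl$allele, n, TRUE, sl$freq)
      a2 <- sample(st$allele, n, TRUE, st$freq)
      stats::setNames(list(pmin(a1, a2), pmax(a1, a2)), paste0(l, c(".1", ".2")))
    })
    dplyr::bind_cols(
      tibble::tibble(sample_id = sprintf("HYB-%04d", seq_len(n))),
      tibble::as_tibble(unlist(cols, recursive = FALSE))
    )
  })
}

# Fully simulated 2018-like world: cohort + references + weights.
simulate_world <- function(seed, quota = 800, anomalies = TRUE, ...) {
  cfg <- if (anomalies) {
    cohort_config_2018(seed = seed, quota_size = quota, ...)
  } else {
    cohort_config(seed = seed, quota_size = quota, ...)
  }
  panels <- make_species_panels(
    n_loci = cfg$n_str_loci,
    allele_count_range = cfg$allele_count_range, seed = seed
  )
  sim <- simulate_cohort(cfg, panels)
  sim$lion_reference <- simulate_reference_genotypes(panels$lion, seed = seed + 1)
  sim$tiger_reference <- simulate_reference_genotypes(panels$tiger, seed = seed + 2)
  sim$weights <- simulate_weights(sim$consignments,
    port_tags = sim$port$tag, seed = seed + 3
  )
  sim$panels <- panels
  sim
}

# --- independent oracles ----------------------------------------------------

# Brute-force exclusion probabilities: explicit loops over every parent,
# transmission and candidate genotype configuration.
pe_oracle <- function(p) {
  k <- length(p)
  gl <- list()
  gp <- numeric(0)
  for (i in 1:k) {
    for (j in i:k) {
      gl[[length(gl) + 1]] <- c(i, j)
      gp <- c(gp, if (i == j) p[i]^2 else 2 * p[i] * p[j])
    }
  }
  compatible_second_parent <- function(cand, o, known) {
    for (pos in 1:2) {
      if (o[pos] %in% cand && o[-pos] %in% known) {
        return(TRUE)
      }
    }
    FALSE
  }
  pe1 <- 0
  for (mi in seq_along(gl)) {
    for (fi in seq_along(gl)) {
      m <- gl[[mi]]
      f <- gl[[fi]]
      for (xm in 1:2) {
        for (xf in 1:2) {
          o <- sort(c(m[xm], f[xf]))
          excl <- 0
          for (ci in seq_along(gl)) {
            if (!compatible_second_parent(gl[[ci]], o, m)) excl <- excl + gp[ci]
          }
          pe1 <- pe1 + gp[mi] * gp[fi] * 0.25 * excl
        }
      }
    }
  }
  pe2 <- 0
  for (oi in seq_along(gl)) {
    o <- gl[[oi]]
    excl <- 0
    for (c1 in seq_along(gl)) {
      for (c2 in seq_along(gl)) {
        ok <- (o[1] %in% gl[[c1]] && o[2] %in% gl[[c2]]) ||
          (o[2] %in% gl[[c1]] && o[1] %in% gl[[c2]])
        if (!ok) excl <- excl + gp[c1] * gp[c2]
      }
    }
    pe2 <- pe2 + gp[oi] * excl
  }
  c(Pe1 = pe1, Pe2 = pe2)
}

# Exhaustive HWE oracle parameterized by heterozygote counts (2 or 3
# alleles): enumerates all feasible het configurations, derives homozygote
# cells, and sums Levene probabilities as extreme as the observed table.
hwe_oracle <- function(counts) {
  k <- nrow(counts)
  stopifnot(k %in% 2:3)
  n <- sum(counts[upper.tri(counts, diag = TRUE)])
  m <- integer(k)
  for (i in 1:k) {
    m[i] <- 2 * counts[i, i] + sum(counts[i, -i][seq_len(k)[-i] > i]) +
      sum(counts[-i, i][seq_len(k)[-i] < i])
  }
  levene <- function(tab) {
    het <- sum(tab[upper.tri(tab)])
    cells <- tab[upper.tri(tab, diag = TRUE)]
    factorial(n) * prod(factorial(m)) * 2^het /
      (factorial(2 * n) * prod(factorial(cells)))
  }
  tables <- list()
  if (k == 2) {
    for (h12 in 0:min(m[1], m[2])) {
      r1 <- m[1] - h12
      r2 <- m[2] - h12
      if (r1 %% 2 == 0 && r2 %% 2 == 0) {
        tab <- matrix(0, 2, 2)
        tab[1, 2] <- h12
        tab[1, 1] <- r1 / 2
        tab[2, 2] <- r2 / 2
        tables[[length(tables) + 1]] <- tab
      }
    }
  } else {
    for (h12 in 0:min(m[1], m[2])) {
      for (h13 in 0:min(m[1] - h12, m[3])) {
        for (h23 in 0:min(m[2] - h12, m[3] - h13)) {
          r <- m - c(h12 + h13, h12 + h23, h13 + h23)
          if (all(r >= 0) && all(r %% 2 == 0)) {
            tab <- matrix(0, 3, 3)
            tab[1, 2] <- h12
            tab[1, 3] <- h13
            tab[2, 3] <- h23
            diag(tab) <- r / 2
            tables[[length(tables) + 1]] <- tab
          }
        }
      }
    }
  }
  probs <- vapply(tables, levene, numeric(1))
  obs <- levene(counts)
  sum(probs[probs <= obs * (1 + 1e-9)])
}

# Minimal independent GENEPOP reader: returns a long tibble of sample,
# population, locus and the two decoded alleles.
parse_genepop <- function(path) {
  lines <- readLines(path)
  pop_breaks <- grep("^Pop$", lines, ignore.case = TRUE)
  loci <- lines[2:(pop_breaks[1] - 1)]
  out <- list()
  pop <- 0
  for (i in seq(pop_breaks[1], length(lines))) {
    if (grepl("^Pop$", lines[i], ignore.case = TRUE)) {
      pop <- pop + 1
      next
    }
    parts <- strsplit(lines[i], ",")[[1]]
    id <- trimws(parts[1])
    codes <- strsplit(trimws(parts[2]), "\\s+")[[1]]
    for (j in seq_along(codes)) {
      out[[length(out) + 1]] <- tibble::tibble(
        sample_id = id, pop = pop, locus = loci[j],
        a1 = as.integer(substr(codes[j], 1, 3)),
        a2 = as.integer(substr(codes[j], 4, 6))
      )
    }
  }
  dplyr::bind_rows(out)
}
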