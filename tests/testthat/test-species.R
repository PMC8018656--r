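# Species assignment: SNP consensus, diagnostic alleles, admixture.

test_that("SNP consensus follows the unanimity rule", {
  expect_equal(call_species_snp(c("LION", "LION", "LION")), "LION")
  expect_equal(call_species_snp(c("TIGER", "TIGER", "TIGER")), "TIGER")
  expect_equal(call_species_snp(c("LION", "TIGER", "LION")), "INCONCLUSIVE")
  expect_equal(call_species_snp(c("UNDETERMINED", "UNDETERMINED", "UNDETERMINED")), "INCONCLUSIVE")
  expect_equal(call_species_snp(c("LION", "UNDETERMINED", "LION")), "LION")
  snp_row <- tibble::tibble(
    control_region = "TIGER", rRNA_12S = "TIGER", rRNA_16S = "UNDETERMINED"
  )
  expect_equal(call_species_snp(snp_row), "TIGER")
  expect_error(call_species_snp(snp_row[, 1:2]), "locus")
  expect_error(call_species_snp(c("LION", "CAT", "LION")), "Invalid")
})

test_that("diagnostic alleles are exact set differences of the panels", {
  lion <- dplyr::bind_rows(
    geno_row("l1", L1 = c(1, 2)),
    geno_row("l2", L1 = c(2, 2))
  )
  tiger <- dplyr::bind_rows(
    geno_row("t1", L1 = c(2, 3)),
    geno_row("t2", L1 = c(3, 3))
  )
  d <- diagnostic_alleles(lion, tiger)
  expect_equal(d$table$status, c("lion_private", "shared", "tiger_private"))
  same <- diagnostic_alleles(lion, lion)
  expect_true(all(same$table$status == "shared"))
  expect_error(diagnostic_alleles(lion[0, ], tiger), "non-empty")
})

test_that("private-allele totals equal a brute-force set scan on synthetic panels", {
  panels <- make_species_panels(n_loci = 10, divergence = 0.3, seed = 41)
  lion_ref <- simulate_reference_genotypes(panels$lion, n = 40, seed = 42)
  tiger_ref <- simulate_reference_genotypes(panels$tiger, n = 40, seed = 43)
  d <- diagnostic_alleles(lion_ref, tiger_ref)
  # brute-force scan over observed (locus, allele) pairs
  seen <- function(g) {
    loci <- str_loci(g)
    unique(unlist(lapply(loci, function(l) {
      a <- c(g[[paste0(l, ".1")]], g[[paste0(l, ".2")]])
      paste(l, a[a != 0])
    })))
  }
  sl <- seen(lion_ref)
  st <- seen(tiger_ref)
  expect_equal(unname(d$totals[["lion_private"]]), length(setdiff(sl, st)))
  expect_equal(unname(d$totals[["tiger_private"]]), length(setdiff(st, sl)))
  expect_equal(unname(d$totals[["shared"]]), length(intersect(sl, st)))
})

test_that("admixture is panel-symmetric and flags flat curves", {
  panels <- make_species_panels(n_loci = 8, divergence = 0.4, seed = 45)
  g <- simulate_reference_genotypes(panels$lion, n = 5, seed = 46)
  for (i in 1:5) {
    a <- assign_admixture(g[i, ], panels$lion, panels$tiger)
    b <- assign_admixture(g[i, ], panels$tiger, panels$lion)
    expect_equal(a$q_lion, 1 - b$q_lion, tolerance = 1e-12)
    expect_equal(a$loglik, b$loglik, tolerance = 1e-9)
    # likelihood at the maximum dominates both endpoints
    expect_gte(a$loglik, a$curve$loglik[1])
    expect_gte(a$loglik, a$curve$loglik[nrow(a$curve)])
  }

  p0 <- make_species_panels(n_loci = 8, divergence = 0, seed = 47)
  g0 <- simulate_reference_genotypes(p0$lion, n = 1, seed = 48)
  flat <- assign_admixture(g0, p0$lion, p0$tiger)
  expect_true(flat$flat)
  expect_true(is.na(flat$q_lion))

  few <- g[1, c("sample_id", "L01.1", "L01.2", "L02.1", "L02.2")]
  expect_error(assign_admixture(few, panels$lion, panels$tiger), ">= 5 loci")
})

test_that("final species call combines mtDNA and nuclear evidence", {
  expect_equal(finalize_species("TIGER", q_lion = 0.01), "TIGER")
  expect_equal(finalize_species("LION", q_lion = 0.99), "LION")
  expect_equal(
    finalize_species("LION",
      q_lion = 0.50,
      diag_hits = c(lion_private = 3L, tiger_private = 4L)
    ),
    "HYBRID_SUSPECT"
  )
  # nuclear vs maternal mtDNA conflict
  expect_equal(finalize_species("TIGER", q_lion = 0.99), "HYBRID_SUSPECT")
  # middle band
  expect_equal(finalize_species("LION", q_lion = 0.5), "HYBRID_SUSPECT")
  # no nuclear follow-up: the mtDNA call stands
  expect_equal(finalize_species("LION"), "LION")
  expect_equal(finalize_species("INCONCLUSIVE"), "INCONCLUSIVE")
  expect_equal(finalize_species("INCONCLUSIVE", q_lion = 0.99), "LION")
  expect_error(finalize_species("LION", q_lion = 1.2), "\\[0, 1\\]")
})

test_that("assign_species gates nuclear follow-up on the mtDNA call", {
  world <- simulate_world(49, quota = 80)
  sa <- assign_species(
    world$farm_snp,
    genotypes = world$farm,
    lion_panel = world$lion_reference, tiger_panel = world$tiger_reference
  )
  truth <- world$truth$farm
  tiger_tag <- truth$tag[truth$species == "TIGER"]
  tiger_row <- sa[world$farm$tag[match(sa$sample_id, world$farm$sample_id)] == tiger_tag, ]
  expect_equal(tiger_row$final_call, "TIGER")
  expect_false(is.na(tiger_row$q_lion)) # follow-up ran for the non-lion
  lions <- sa[sa$snp_call == "LION", ]
  expect_true(all(is.na(lions$q_lion))) # no follow-up for clean lions
  expect_true(all(lions$final_call == "LION"))
})
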