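# Farm-to-port matching, duplicates and anomaly classification.

world <- simulate_world(201, quota = 150)

test_that("identical genotypes give MATCH with r = 1; planted anomalies classify correctly", {
  mr <- match_port_samples(world$port, world$farm)
  truth <- world$truth$port
  got <- mr$match_class[match(truth$sample_id, mr$port_sample_id)]
  expect_true(all(got[truth$anomaly_class == "none"] == "MATCH"))
  expect_true(all(got[truth$anomaly_class == "reassigned_tag"] == "REASSIGNED_SAME_FARM"))
  expect_true(all(got[truth$anomaly_class == "pooled_no_match"] == "NO_MATCH"))
  clean <- mr[mr$match_class == "MATCH", ]
  expect_equal(clean$r_same_tag, rep(1, nrow(clean)), tolerance = 1e-12)
  expect_true(all(clean$esd_significant))
  # reassigned samples matched a different tag at the same facility
  re <- mr[mr$match_class == "REASSIGNED_SAME_FARM", ]
  expect_true(all(re$best_farm_tag != re$declared_tag))
  expect_gte(min(re$r_best), 0.9)
})

test_that("match outcome is invariant to farm cohort ordering", {
  perm <- withr::with_seed(202, sample(nrow(world$farm)))
  m1 <- match_port_sample(world$port[1, ], world$farm)
  m2 <- match_port_sample(world$port[1, ], world$farm[perm, ])
  expect_equal(m1$match_class, m2$match_class)
  expect_equal(m1$best_farm_tag, m2$best_farm_tag)
  expect_equal(m1$r_same_tag, m2$r_same_tag, tolerance = 1e-12)
})

test_that("declared tag absent from the cohort is its own outcome", {
  stray <- world$port[1, ]
  stray$tag <- "ZA2018-9999"
  res <- match_port_sample(stray, world$farm)
  expect_equal(res$match_class, "DECLARED_TAG_ABSENT")
  expect_error(match_port_sample(world$port[1, ], world$farm[1:5, ]), "at least 10")
})

test_that("duplicate detection finds planted pairs, tolerates dropout, and is collision-free", {
  dup_tags <- world$truth$farm$tag[world$truth$farm$anomaly_class == "duplicate_individual"]
  d <- find_duplicates(world$farm)
  expect_equal(nrow(d), 1)
  expect_setequal(c(d$tag_a, d$tag_b), dup_tags)
  expect_equal(d$r, 1, tolerance = 1e-12)
  expect_lt(attr(d, "cumulative_pid"), 1e-6)

  # dropout-corrupted duplicate recovered at tolerance 1
  corrupted <- world$farm
  i <- which(corrupted$tag == dup_tags[1])
  corrupted$L01.1[i] <- 0L
  corrupted$L01.2[i] <- 0L
  d0 <- find_duplicates(corrupted, mismatch_tolerance = 0)
  d1 <- find_duplicates(corrupted, mismatch_tolerance = 1)
  expect_setequal(c(d1$tag_a, d1$tag_b), dup_tags)

  # no spurious pairs among unrelated profiles across several seeds
  for (s in 211:215) {
    clean <- simulate_world(s, quota = 120, anomalies = FALSE)
    expect_equal(nrow(find_duplicates(clean$farm)), 0)
  }
})

test_that("anomaly ledger mirrors the compliance summary shape", {
  report <- run_pipeline(world, seed = 201)
  led <- report$ledger
  expect_equal(led$summary$n_anomalies[led$summary$site == "FARM"], 3L)
  expect_equal(led$summary$n_anomalies[led$summary$site == "PORT"], 5L)
  expect_true(all(
    led$anomalies$type_interpretation %in%
      c("TYPE_I_POOLING", "TYPE_II_MISLABEL", "UNRESOLVED")
  ))
  by_class <- table(led$anomalies$class)
  expect_equal(unname(by_class[["pooled_no_match"]]), 4L)
  expect_equal(unname(by_class[["reassigned_tag"]]), 1L)
  expect_equal(unname(by_class[["duplicate_individual"]]), 2L)
  expect_equal(unname(by_class[["non_target_species"]]), 1L)
  # reassignment and pooling map to the two irregularity types
  expect_true(all(
    led$anomalies$type_interpretation[led$anomalies$class == "reassigned_tag"] ==
      "TYPE_II_MISLABEL"
  ))
  expect_true(all(
    led$anomalies$type_interpretation[led$anomalies$class == "pooled_no_match"] ==
      "TYPE_I_POOLING"
  ))
  # a constructed 3-of-25 port scenario formats as 3/25
  expect_match(
    led$summary$label[led$summary$site == "FARM"],
    sprintf("^3/%d", nrow(world$farm))
  )
})

test_that("pending results are rejected by the classifier", {
  mr <- match_port_samples(world$port, world$farm)
  mr$match_class[1] <- "PENDING"
  sa <- tibble::tibble(
    sample_id = "x", site = "FARM", year = 2018L, final_call = "LION"
  )
  expect_error(classify_anomalies(mr, find_duplicates(world$farm), sa), "resolved")
})
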