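# File formats and custody digests.

test_that("genotype CSV round trip is the identity and writes are deterministic", {
  world <- simulate_world(31, quota = 60, anomalies = FALSE)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_genotype_table(world$farm, f1)
  write_genotype_table(world$farm, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
  back <- read_genotype_table(f1)
  expect_equal(as.data.frame(back), as.data.frame(world$farm))
})

test_that("single-row parse, missing convention and empty table", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,tag,facility_id,site,year,claimed_species,L1.1,L1.2,L2.1,L2.2",
    "s1,t1,f1,FARM,2018,LION,124,120,0,0"
  ), f)
  g <- read_genotype_table(f)
  expect_equal(g$L1.1, 120L) # pairs stored sorted ascending
  expect_equal(g$L1.2, 124L)
  expect_equal(c(g$L2.1, g$L2.2), c(0L, 0L)) # missing locus

  fe <- withr::local_tempfile(fileext = ".csv")
  write_genotype_table(g[0, ], fe)
  expect_equal(nrow(read_genotype_table(fe)), 0)
  expect_match(readLines(fe)[1], "^sample_id,")
})

test_that("malformed tables raise located errors", {
  base <- "sample_id,tag,facility_id,site,year,claimed_species,L1.1,L1.2"
  f <- withr::local_tempfile(fileext = ".csv")

  writeLines(c(base, "s1,t1,f1,FARM,2018,LION,12x,124"), f)
  expect_error(read_genotype_table(f), "row 1, column L1.1")

  writeLines(c(base, "s1,t1,f1,DEPOT,2018,LION,120,124"), f)
  expect_error(read_genotype_table(f), "Unknown site")

  writeLines(c(
    base,
    "s1,t1,f1,FARM,2018,LION,120,124",
    "s2,t1,f1,FARM,2018,LION,120,124"
  ), f)
  expect_error(read_genotype_table(f), "Duplicate \\(tag, site, year\\)")

  writeLines(c(base, "s1,t1,f1,FARM,2018,LION,120"), f)
  expect_error(read_genotype_table(f), "row 1")

  writeLines(c("sample_id,tag,L1.1,L1.2", "s1,t1,120,124"), f)
  expect_error(read_genotype_table(f), "Missing header")
})

test_that("GENEPOP export uses three-digit coding and an independent parse agrees", {
  g <- dplyr::bind_rows(
    geno_row("s1", L1 = c(120, 124), L2 = c(0, 0)),
    geno_row("s2", L1 = c(98, 98), L2 = c(120, 130), facility_id = "FAC02")
  )
  f <- withr::local_tempfile(fileext = ".gen")
  export_genepop(g, f)
  txt <- readLines(f)
  expect_true(any(grepl("120124", txt)))
  expect_true(any(grepl("000000", txt)))

  parsed <- parse_genepop(f)
  expect_equal(nrow(parsed), 4) # 2 samples x 2 loci
  expect_equal(length(unique(parsed$pop)), 2) # Pop block per facility
  p1 <- parsed[parsed$sample_id == "s1" & parsed$locus == "L1", ]
  expect_equal(c(p1$a1, p1$a2), c(120L, 124L))
  p2 <- parsed[parsed$sample_id == "s1" & parsed$locus == "L2", ]
  expect_equal(c(p2$a1, p2$a2), c(0L, 0L))

  big <- geno_row("s3", L1 = c(1000, 124))
  expect_error(export_genepop(big, f), "> 999")
})

test_that("genepop export of a synthetic cohort preserves genotype counts", {
  world <- simulate_world(33, quota = 50, anomalies = FALSE)
  f <- withr::local_tempfile(fileext = ".gen")
  export_genepop(world$farm, f)
  parsed <- parse_genepop(f)
  loci <- str_loci(world$farm)
  for (l in loci[c(1, length(loci))]) {
    orig <- table(paste(world$farm[[paste0(l, ".1")]], world$farm[[paste0(l, ".2")]]))
    sub <- parsed[parsed$locus == l, ]
    got <- table(paste(pmin(sub$a1, sub$a2), pmax(sub$a1, sub$a2)))
    expect_equal(as.list(got), as.list(orig))
  }
})

test_that("custody digest matches known SHA-256 values and detects changes", {
  f <- withr::local_tempfile()
  writeLines(character(0), f, sep = "")
  d <- custody_digest(f)
  expect_equal(
    d$sha256,
    "e3b0c44298fc1c149afbf4c8996fb92427ae41e4649b934ca495991b7852b855"
  )
  expect_identical(custody_digest(f)$sha256, d$sha256)
  writeBin(as.raw(1), f)
  expect_false(custody_digest(f)$sha256 == d$sha256)
  expect_error(custody_digest("/nonexistent/file"), "Unreadable")
})

test_that("weight manifest and SNP table round trips validate their columns", {
  world <- simulate_world(35, quota = 40, anomalies = FALSE)
  fw <- withr::local_tempfile(fileext = ".csv")
  write_weight_manifest(world$weights, fw)
  back <- read_weight_manifest(fw)
  expect_equal(as.data.frame(back), as.data.frame(world$weights), tolerance = 1e-12)

  fs <- withr::local_tempfile(fileext = ".csv")
  write_snp_table(world$farm_snp, fs)
  snp <- read_snp_table(fs)
  expect_equal(as.data.frame(snp), as.data.frame(world$farm_snp))

  bad <- world$farm_snp
  bad$control_region[1] <- "LEOPARD"
  write_snp_table(bad, fs)
  expect_error(read_snp_table(fs), "Invalid SNP call")
})
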