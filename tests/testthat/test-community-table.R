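test_that("community tables validate counts and carry row-sum depths", {
  ct <- community_table(toy_counts(), "fungi")
  expect_equal(unname(ct$depth), c(3, 6))
  expect_equal(ct$guild, "fungi")

  bad <- toy_counts(); bad[2, 1] <- -1L
  expect_error(community_table(bad, "fungi"), "s2.*otu1")
  frac <- toy_counts(); storage.mode(frac) <- "double"; frac[1, 1] <- 1.5
  expect_error(community_table(frac, "fungi"), "non-negative integers")

  dup <- toy_counts(); rownames(dup) <- c("s1", "s1")
  expect_error(community_table(dup, "fungi"), "duplicated sample")
  expect_error(community_table(toy_counts()[1, , drop = FALSE], "fungi"),
               "at least 2 samples")
})

test_that("TSV round trip preserves counts, ids and guild", {
  ct <- random_table(n = 7, S = 5, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_community_table(ct, path)
  back <- read_community_table(path, "fungi")
  expect_equal(back$counts, ct$counts)
  expect_equal(back$sample_ids, ct$sample_ids)
  back_t <- read_community_table(path, "fungi", transposed = FALSE)
  expect_equal(dim(back_t), dim(ct))
})

test_that("a reader option accepts transposed (OTU-by-sample) tables", {
  ct <- random_table(n = 6, S = 4, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- tibble::as_tibble(as.data.frame(t(ct$counts)), rownames = "otu_id")
  readr::write_tsv(df, path)
  back <- read_community_table(path, "fungi", transposed = TRUE)
  expect_equal(back$counts, ct$counts)
})

test_that("reading a file with a negative cell names the offending cell", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\totuA\totuB", "s1\t3\t-2", "s2\t1\t5"), path)
  expect_error(read_community_table(path, "fungi"), "otuB")
})

test_that("rare-OTU filter applies strict prevalence and inclusive abundance rules", {
  # one OTU present in exactly 1/10 samples at 50% relative abundance:
  # prevalence 0.10 is not > 0.10 -> removed
  m <- matrix(0L, 10, 2, dimnames = list(paste0("s", 1:10), c("rare", "common")))
  m[, "common"] <- 10L
  m[1, "rare"] <- 10L
  ct <- community_table(m, "fungi")
  kept <- filter_otus(ct, filter_spec(0.10, 0.005))
  expect_equal(kept$otu_ids, "common")

  # present in 3/10 samples but max relative abundance below 0.005 -> removed
  m2 <- matrix(0L, 10, 2, dimnames = list(paste0("s", 1:10), c("thin", "common")))
  m2[, "common"] <- 1000L
  m2[1:3, "thin"] <- 4L   # 4/1004 < 0.005
  ct2 <- community_table(m2, "fungi")
  expect_equal(filter_otus(ct2, filter_spec(0.10, 0.005))$otu_ids, "common")

  # zero thresholds disable the filter entirely
  ct3 <- random_table(n = 8, S = 5, seed = 2)
  expect_equal(filter_otus(ct3, filter_spec(0, 0))$otu_ids, ct3$otu_ids)

  # removing everything is an error with advice
  m3 <- matrix(5L, 10, 2, dimnames = list(paste0("s", 1:10), c("u", "v")))
  expect_error(filter_otus(community_table(m3, "fungi"),
                           filter_spec(0.99, 0.6)), "relax")
})

test_that("filtering is idempotent and monotone in the thresholds", {
  for (seed in 1:5) {
    ct <- random_table(n = 12, S = 10, seed = seed, lambda_mean = 2)
    spec <- filter_spec(0.2, 0.01)
    once <- filter_otus(ct, spec)
    twice <- filter_otus(once, spec)
    expect_identical(once$otu_ids, twice$otu_ids)
    stricter <- filter_otus(ct, filter_spec(0.4, 0.05))
    expect_true(all(stricter$otu_ids %in% once$otu_ids))
  }
})

test_that("long-format view exposes relative abundances", {
  ct <- community_table(toy_counts(), "bacteria")
  tb <- tibble::as_tibble(ct)
  expect_equal(nrow(tb), 4)
  expect_equal(unname(tb$relabund[tb$sample_id == "s1" & tb$otu_id == "otu1"]), 1)
})
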