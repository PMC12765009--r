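test_that("flat dialect round-trips bit-for-bit", {
  tab <- as_call_table(tiny_call_table(2, 3))
  expect_equal(nrow(tab), 6)
  expect_equal(length(unique(tab$individual_id)), 2)

  # awkward doubles survive the round trip exactly
  tab$duration_s[1] <- 1 / 3
  tab$pfc_01[2] <- 632.10000000000002

  path <- withr::local_tempfile(fileext = ".tsv")
  write_call_table(tab, path)
  back <- read_call_table(path)
  expect_identical(plain_df(back), plain_df(tab))

  big <- simulate_population(sim_config(n_individuals = 22, seed = 5))$table
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_call_table(big, path2)
  expect_identical(plain_df(read_call_table(path2)),
                   plain_df(big))
})

write_raven_fixture <- function(path, contours, begin, end, ind,
                                grp = NULL, n_slices = max(lengths(contours))) {
  hdr <- c("Selection", "Begin Time (s)", "End Time (s)", "Individual",
           if (!is.null(grp)) "Group",
           sprintf("Peak Freq Contour %d (Hz)", seq_len(n_slices)))
  rows <- lapply(seq_along(contours), function(i) {
    f <- contours[[i]]
    c(i, begin[i], end[i], ind[i], if (!is.null(grp)) grp[i],
      f, rep("", n_slices - length(f)))
  })
  lines <- c(paste(hdr, collapse = "\t"),
             vapply(rows, paste, character(1), collapse = "\t"))
  writeLines(lines, path)
}

test_that("raven dialect resamples variable-length contours to 10 points", {
  path <- withr::local_tempfile(fileext = ".txt")
  f20 <- 600 + 40 * sin(seq(0, 3, length.out = 20))
  write_raven_fixture(path, list(f20, rep(700, 8)),
                      begin = c(1.000, 2.0), end = c(1.400, 2.3),
                      ind = c("mA", "mA"), grp = c("G", "G"))
  tab <- read_call_table(path, dialect = "raven")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$duration_s, c(0.4, 0.3), tolerance = 1e-12)
  expect_equal(unname(unlist(tab[1, sprintf("pfc_%02d", 1:10)])),
               resample_evenly(f20), tolerance = 1e-12)
  expect_equal(unname(unlist(tab[2, sprintf("pfc_%02d", 1:10)])),
               rep(700, 10))
})

test_that("raven ingestion equals flat ingestion for 10-sample contours", {
  flat <- as_call_table(tiny_call_table(2, 2))
  path <- withr::local_tempfile(fileext = ".txt")
  pfc <- lapply(seq_len(nrow(flat)), function(i)
    unname(unlist(flat[i, sprintf("pfc_%02d", 1:10)])))
  write_raven_fixture(path, pfc, begin = rep(0, 4),
                      end = flat$duration_s, ind = flat$individual_id,
                      grp = flat$group_label)
  raven <- read_call_table(path, dialect = "raven")
  pcols <- sprintf("pfc_%02d", 1:10)
  expect_equal(as.matrix(raven[pcols]), as.matrix(flat[pcols]),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(raven$duration_s, flat$duration_s, tolerance = 1e-12)
})

test_that("malformed tables fail with informative errors", {
  df <- tiny_call_table(2, 3)
  path <- withr::local_tempfile(fileext = ".tsv")

  write_call_table(as_call_table(df), path)
  txt <- readLines(path)
  writeLines(sub("pfc_07", "pfc_7x", txt), path)
  expect_error(read_call_table(path), "pfc_07")

  write_call_table(as_call_table(df), path)
  txt <- readLines(path)
  parts <- strsplit(txt[3], "\t")[[1]]
  parts[4] <- "NA"
  txt[3] <- paste(parts, collapse = "\t")
  writeLines(txt, path)
  expect_error(read_call_table(path), "row.*2")

  expect_error(as_call_table(df[0, ]), "non-empty")
  df2 <- df
  df2$call_id[2] <- df2$call_id[1]
  expect_error(as_call_table(df2), "duplicate")
})

test_that("validation reports band violations and thin individuals", {
  tab <- as_call_table(tiny_call_table(3, 3))
  rep0 <- validate_call_table(tab)
  expect_equal(nrow(rep0$violations), 0)

  df <- as.data.frame(tab)
  df$pfc_05[4] <- 3000
  tab2 <- as_call_table(df)
  rep2 <- validate_call_table(tab2)
  expect_equal(rep2$violations$type, "out_of_band")
  expect_equal(rep2$violations$row, 4)

  df3 <- tiny_call_table(2, 3)[-(1:2), ] # first individual keeps 1 call
  expect_warning(tab3 <- as_call_table(df3), "< 2 calls")
  expect_true(any(grepl("< 2 calls", attr(tab3, "provenance"))))
  rep3 <- validate_call_table(tab3)
  expect_true("insufficient_calls" %in% rep3$violations$type)
})
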