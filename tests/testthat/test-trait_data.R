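test_that("trait_matrix construction, validation and errors", {
  df <- make_tidy_df(c("A", "B"), "RWC", replicates = 3)
  tm <- trait_matrix(df)
  expect_s3_class(tm, "trait_matrix")
  expect_equal(nrow(tm$data), 12)
  expect_equal(tm$genotypes, c("A", "B"))

  # duplicated key names the key
  dup <- rbind(df, df[1, ])
  expect_error(trait_matrix(dup), "integrity error.*A/RWC/control/1")

  # missing cell is a hard error
  expect_error(trait_matrix(df[-(1:3), ]), "missing cell")

  # missing column
  expect_error(trait_matrix(df[, -5]), "format error")

  # unknown condition
  bad <- df; bad$condition[1] <- "drought"
  expect_error(trait_matrix(bad), "condition")

  # index not declared in spec
  expect_error(trait_matrix(df, spec = index_spec("EL", "negative")),
               "spec error.*RWC")
})

test_that("read/write round trip preserves the panel and decimal strings", {
  df <- make_tidy_df(c("S1", "S2"), c("RWC", "EL"))
  tm <- trait_matrix(df, spec = index_spec(c("RWC", "EL"),
                                           c("positive", "negative")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trait_table(tm, path)
  tm2 <- read_trait_table(path, spec = tm$spec)
  expect_equal(tm2$data, tm$data)
  expect_equal(tm2$genotypes, tm$genotypes)

  # decimal strings round-trip bit-for-bit
  lines1 <- readLines(path)
  write_trait_table(tm2, path)
  expect_identical(readLines(path), lines1)

  # shuffled row order gives the same panel content (display order may
  # differ: it follows first appearance)
  shuf <- df[sample(nrow(df)), ]
  canon <- function(cm) {
    cm <- cm[order(cm$genotype, cm$index, cm$condition), ]
    rownames(cm) <- NULL
    cm
  }
  expect_equal(canon(cell_means(trait_matrix(shuf))),
               canon(cell_means(trait_matrix(df))))
})

test_that("read_trait_table reports parse errors with row numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("genotype,index,condition,replicate,value",
               "A,RWC,control,1,1.5",
               "A,RWC,treatment,1,oops"), path)
  expect_error(read_trait_table(path), "parse error.*row 2")
})

test_that("cell_means: sample SD, idempotence, fixture value", {
  df <- data.frame(genotype = "A", index = "RWC", condition = "control",
                   replicate = 1:3, value = c(1, 2, 3))
  df <- rbind(df, within(df, condition <- "treatment"))
  cm <- cell_means(trait_matrix(df))
  expect_equal(cm$mean, c(2, 2))
  expect_equal(cm$sd, c(1, 1))   # sample (n-1) convention

  one <- df[df$replicate == 1, ]
  one$value <- 5.5
  cm1 <- cell_means(trait_matrix(one))
  expect_equal(cm1$mean, c(5.5, 5.5))
  expect_equal(cm1$sd, c(0, 0))

  # aggregating an aggregated (1-replicate) panel changes nothing
  agg <- data.frame(genotype = cm$genotype, index = cm$index,
                    condition = cm$condition, replicate = 1L,
                    value = cm$mean)
  expect_equal(cell_means(trait_matrix(agg))$mean, cm$mean)

  # bundled panel: S22 control total chlorophyll mean is 1.144
  cm_fix <- cell_means(pigment_panel())
  expect_equal(cm_fix$mean[cm_fix$genotype == "S22" & cm_fix$index == "Chl" &
                             cm_fix$condition == "control"], 1.144)
})

test_that("cell_means is invariant to replicate order", {
  df <- make_tidy_df(c("A", "B"), c("X", "Y"), replicates = 4)
  set.seed(11)
  for (i in 1:5) {
    shuf <- df[sample(nrow(df)), ]
    shuf$replicate <- ave(seq_len(nrow(shuf)),
                          shuf$genotype, shuf$index, shuf$condition,
                          FUN = seq_along)
    expect_equal(sort(cell_means(trait_matrix(shuf))$mean),
                 sort(cell_means(trait_matrix(df))$mean))
  }
})

test_that("wide means reader normalizes to a tidy single-replicate panel", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("genotype,RWC_control,RWC_treatment,EL_control,EL_treatment",
               "A,90,80,20,35",
               "B,88,70,22,50"), path)
  tm <- read_wide_means(path)
  expect_equal(length(tm$genotypes), 2)
  expect_equal(sort(tm$indices), c("EL", "RWC"))
  expect_equal(means_matrix(tm, "treatment")["B", "EL"], 50)
  writeLines(c("genotype,RWC_ctrl", "A,90"), path)
  expect_error(read_wide_means(path), "format error")
})

test_that("index_spec validates directions and duplicates", {
  expect_error(index_spec(c("a", "a")), "unique")
  expect_error(index_spec("a", "sideways"), "direction")
  spec <- default_index_spec()
  expect_equal(nrow(spec), 13)
  expect_equal(spec$direction[spec$index %in% c("EL", "MDA")],
               c("negative", "negative"))
})
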