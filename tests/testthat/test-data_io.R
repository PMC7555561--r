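test_that("response CSV/TSV round-trips and errors are located", {
  set.seed(23)
  X <- matrix(sample(0:3, 40, TRUE), 10, 4,
              dimnames = list(NULL, paste0("it", 1:4)))
  for (ext in c(".csv", ".tsv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_responses(X, path)
    back <- read_responses(path)
    expect_identical(unname(back$data), unname(X))
    expect_equal(back$items, colnames(X))
  }

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "0,1", ",1"), bad)
  expect_error(read_responses(bad), "missing value at row 2, column 'a'")
  writeLines(c("a,b", "0,x"), bad)
  expect_error(read_responses(bad), "non-integer value 'x' at row 1")

  tiny <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "0,1", "1,0", "1,1"), tiny)
  rm <- read_responses(tiny)
  expect_equal(rm$K, c(1L, 1L))
  expect_equal(rm$N, 3L)
})

test_that("distractor recoding orders by frequency and is a bijection", {
  raw <- spmls_synthetic_raw()
  rec <- recode_by_distractor_frequency(raw)
  map <- rec$map

  # most attractive distractor of SPM1 is original option 3; the correct
  # option 7 becomes category 0
  m1 <- map[map$item == "SPM1", ]
  expect_equal(m1$original_code[m1$new_category == 0], 7L)
  expect_equal(m1$original_code[m1$new_category == 1], 3L)
  # least attractive distractor of SPM12 is original option 8
  m12 <- map[map$item == "SPM12", ]
  expect_equal(m12$original_code[m12$new_category == 7], 8L)

  for (it in unique(map$item)) {
    sub <- map[map$item == it, ]
    # bijection between original codes and 0..K
    expect_equal(sort(sub$new_category), seq_len(nrow(sub)) - 1L)
    expect_equal(length(unique(sub$original_code)), nrow(sub))
    # non-increasing distractor frequencies for categories >= 1
    expect_true(all(diff(sub$count[sub$new_category >= 1]) <= 0))
  }

  # recoded data realize the mapped frequencies
  for (k in 0:6) {
    expect_equal(sum(rec$data$data[, "SPM1"] == k),
                 m1$count[m1$new_category == k])
  }

  # frequency ties: lower original code gets the smaller new category
  tied <- raw_choice_data(cbind(item = c(1, 2, 2, 3, 3, 4)), key = 1)
  tm <- recode_by_distractor_frequency(tied)$map
  expect_equal(tm$original_code[tm$new_category == 1], 2L)
  expect_equal(tm$original_code[tm$new_category == 2], 3L)
  expect_equal(tm$original_code[tm$new_category == 3], 4L)

  # declared-but-unobserved options get the highest categories
  opt <- raw_choice_data(cbind(c(1, 2, 2)), key = 1, options = list(1:4))
  om <- recode_by_distractor_frequency(opt)$map
  expect_equal(om$new_category[om$original_code == 2], 1L)
  expect_equal(om$count[om$new_category %in% 2:3], c(0L, 0L))
})

test_that("dichotomization pools distractors and commutes with recoding", {
  raw <- spmls_synthetic_raw()
  di <- dichotomize(raw)
  expect_true(all(di$data %in% 0:1))
  # per-item mean equals the correct-response frequency
  expect_equal(mean(di$data[, "SPM1"]), 0.760)
  expect_equal(mean(di$data[, "SPM2"]), 0.910)

  # the correct indicator is the same whether recoding runs first
  rec <- recode_by_distractor_frequency(raw)
  expect_identical(unname(di$data == 1L), unname(rec$data$data == 0L))

  # all-correct column dichotomizes to all ones
  allc <- raw_choice_data(cbind(rep(2L, 5), c(1L, 1L, 2L, 2L, 1L)),
                          key = c(2L, 1L))
  expect_equal(unname(dichotomize(allc)$data[, 1]), rep(1L, 5))
})

test_that("fit JSON serialization round-trips and criteria recompute", {
  sim <- simulate_lcm(fixture_design("table1_dichotomous"), 150, seed = 30)
  spec <- penalty_spec("mcp", "fused_classes", lambda1 = 0.2)
  fit <- rlca_fit(sim$data, 2, spec, n_starts = 2, seed = 1, max_iter = 100)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  back <- read_fit_json(path)
  expect_equal(back$loglik, fit$loglik)
  expect_equal(back$n_params, fit$n_params)
  expect_equal(back$spec$lambda1, 0.2)
  ic <- information_criteria(back$loglik, back$n_params, back$N)
  expect_equal(back$aic, ic$aic)
  expect_equal(back$bic, ic$bic)
  expect_equal(back$class_probs, unname(fit$class_probs))

  csvp <- withr::local_tempfile(fileext = ".csv")
  write_prob_table_csv(fit, csvp)
  tab <- read.csv(csvp)
  expect_equal(nrow(tab), 12 * 2)
  expect_equal(tab$class1[1:2], unname(signif(fit$item_probs[[1]][, 1], 6)))
})

test_that("the CLI runs simulate/fit/select/order/recode end to end", {
  out <- withr::local_tempdir()
  datafile <- file.path(out, "sim.csv")

  expect_equal(rlca_cli(c("simulate", "--design", "table1", "--n", "120",
                          "--seed", "5", "--out", datafile)), 0L)
  expect_true(file.exists(datafile))
  expect_true(file.exists(file.path(out, "sim_classes.csv")))

  # determinism: the same seed writes byte-identical data
  datafile2 <- file.path(out, "sim2.csv")
  rlca_cli(c("simulate", "--design", "table1", "--n", "120",
             "--seed", "5", "--out", datafile2))
  expect_identical(readLines(datafile), readLines(datafile2))

  fitdir <- file.path(out, "fit")
  expect_equal(rlca_cli(c("fit", "--data", datafile, "--classes", "2",
                          "--family", "mcp", "--strategy", "fused_classes",
                          "--lambda1", "0.2", "--starts", "2", "--seed", "1",
                          "--out", fitdir)), 0L)
  expect_true(file.exists(file.path(fitdir, "fit.json")))
  expect_true(file.exists(file.path(fitdir, "item_probs.csv")))

  seldir <- file.path(out, "sel")
  expect_equal(rlca_cli(c("select", "--data", datafile, "--classes", "2",
                          "--strategy", "fused_classes",
                          "--grid1", "0.1:0.3:0.1", "--criterion", "bic",
                          "--starts", "1", "--seed", "1",
                          "--out", seldir)), 0L)
  sel <- read.csv(file.path(seldir, "selection.csv"))
  expect_equal(nrow(sel), 3L)
  expect_true(file.exists(file.path(seldir, "best_fit.json")))

  # order subcommand on the bundled class profile
  probfile <- file.path(out, "probs.csv")
  P <- spmls_class_profile()
  write.csv(data.frame(item = rownames(P), P), probfile, row.names = FALSE)
  orderfile <- file.path(out, "edges.csv")
  expect_equal(rlca_cli(c("order", "--probs", probfile, "--iota", "2",
                          "--out", orderfile)), 0L)
  expect_true(nrow(read.csv(orderfile)) > 0)

  # recode subcommand
  raw <- spmls_synthetic_raw()
  rawfile <- file.path(out, "raw.csv")
  write.table(raw$responses, rawfile, sep = ",", row.names = FALSE,
              quote = FALSE)
  keyfile <- file.path(out, "key.csv")
  write.csv(data.frame(item = raw$items, correct = raw$key), keyfile,
            row.names = FALSE)
  recfile <- file.path(out, "rec.csv")
  expect_equal(rlca_cli(c("recode", "--data", rawfile, "--key", keyfile,
                          "--mode", "polytomous", "--out", recfile)), 0L)
  expect_true(file.exists(file.path(out, "rec_map.csv")))
  expect_equal(unname(read_responses(recfile)$data),
               unname(recode_by_distractor_frequency(raw)$data$data))

  # unknown command and invalid combinations exit nonzero
  expect_equal(rlca_cli("frobnicate"), 1L)
  expect_equal(rlca_cli(c("select", "--data", datafile, "--classes", "2",
                          "--strategy", "group_categories",
                          "--grid1", "0.1:0.3:0.1", "--out", seldir)), 1L)
})

test_that("YAML config supplies defaults that flags override", {
  out <- withr::local_tempdir()
  datafile <- file.path(out, "sim.csv")
  cfg <- file.path(out, "run.yaml")
  # n comes from the config; the output path and seed from the flags
  writeLines(c("design: table1", "n: 60"), cfg)
  expect_equal(rlca_cli(c("simulate", "--config", cfg, "--seed", "2",
                          "--out", datafile)), 0L)
  expect_equal(read_responses(datafile)$N, 60L)
  # an explicit flag overrides the config value
  expect_equal(rlca_cli(c("simulate", "--config", cfg, "--n", "25",
                          "--seed", "2", "--out", datafile)), 0L)
  expect_equal(read_responses(datafile)$N, 25L)
})
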