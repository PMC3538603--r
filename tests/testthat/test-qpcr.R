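make_ct <- function(ct_gene, ct_ref = 20, condition = "Ctr",
                    gene = "g", reps = 3) {
  dplyr::bind_rows(
    tibble::tibble(condition = condition, gene = "Gapdh",
                   replicate = seq_len(reps), ct = ct_ref),
    tibble::tibble(condition = condition, gene = gene,
                   replicate = seq_len(reps), ct = ct_gene))
}

test_that("delta-Ct averages replicates before normalising to the reference", {
  dct <- delta_ct(make_ct(25))
  expect_equal(dct$delta_ct, 5)
  expect_equal(dct$relative_level, 2^-5)
  # gene amplifying exactly with the reference
  dct0 <- delta_ct(make_ct(20))
  expect_equal(dct0$delta_ct, 0)
  expect_equal(dct0$relative_level, 1)
  # averaging happens before subtraction
  ct <- make_ct(c(24, 25, 26))
  expect_equal(delta_ct(ct)$delta_ct, 5)
  expect_error(delta_ct(dplyr::filter(make_ct(25), gene != "Gapdh")),
               "Ctr")
  expect_error(delta_ct(dplyr::mutate(make_ct(25), ct = -ct)), "positive")
})

test_that("a plate offset hitting all wells of a condition cancels out", {
  ct <- dplyr::bind_rows(make_ct(25, condition = "Ctr"),
                         make_ct(24, condition = "C4"))
  shifted <- dplyr::mutate(ct, ct = ct + ifelse(condition == "C4", 1.7, 0))
  expect_equal(delta_ct(shifted)$delta_ct, delta_ct(ct)$delta_ct)
})

test_that("log2 fold change is minus delta-delta-Ct with control at zero", {
  dct <- tibble::tibble(gene = "g", condition = c("Ctr", "C4"),
                        n_replicates = 3, delta_ct = c(5, 3),
                        relative_level = 2^-c(5, 3))
  fc <- log2_fold_change(dct, "Ctr")
  expect_equal(fc$log2_fc[fc$condition == "Ctr"], 0)
  expect_equal(fc$log2_fc[fc$condition == "C4"], 2)  # ddCt = -2, 4-fold up
  expect_error(log2_fold_change(dplyr::filter(dct, condition == "C4"), "Ctr"),
               "missing in control")
})

test_that("zero-noise synthetic Ct recovers planted fold changes exactly", {
  truth <- tibble::tibble(
    probe_id = paste0("p", 1:4), gene = paste0("g", 1:4),
    true_lfc_C2 = c(0, 0, 1.25, -0.5),
    true_lfc_C4 = c(0, 2.5, 1.25, -1.5))
  ct <- generate_ct_table(truth, truth$gene, ct_noise_sd = 0, seed = 2)
  fc <- log2_fold_change(delta_ct(ct), "Ctr")
  for (g in truth$gene) {
    expect_equal(fc$log2_fc[fc$gene == g & fc$condition == "C4"],
                 truth$true_lfc_C4[truth$gene == g], tolerance = 1e-12)
    expect_equal(fc$log2_fc[fc$gene == g & fc$condition == "C2"],
                 truth$true_lfc_C2[truth$gene == g], tolerance = 1e-12)
    expect_equal(fc$log2_fc[fc$gene == g & fc$condition == "Ctr"], 0)
  }
})

test_that("triplicate averaging keeps noisy recovery within the 3-sigma bound", {
  set.seed(29)
  truth <- tibble::tibble(probe_id = "p1", gene = "g1",
                          true_lfc_C2 = 0.8, true_lfc_C4 = 2)
  sigma <- 0.2
  errs <- replicate(200, {
    ct <- generate_ct_table(truth, "g1", ct_noise_sd = sigma)
    fc <- log2_fold_change(delta_ct(ct), "Ctr")
    abs(fc$log2_fc[fc$condition == "C4"] - 2)
  })
  expect_lte(mean(errs), 3 * sigma)
})

test_that("validation genes need a two-fold change in every comparison and q < 0.01", {
  expr <- tibble::tibble(probe_id = c("both", "c2only", "highq"),
                         Ctr = c(5, 5, 5),
                         C2 = c(6.2, 6.2, 6.2),
                         C4 = c(6.5, 5.5, 6.5))
  q <- tibble::tibble(probe_id = expr$probe_id, q = c(0.005, 0.005, 0.02))
  callsets <- list(classify_fold_change(expr, "Ctr", "C2"),
                   classify_fold_change(expr, "Ctr", "C4"))
  map <- tibble::tibble(probe_id = expr$probe_id,
                        gene = c("gA", "gB", "gC"))
  sel <- select_validation_genes(callsets, q, map)
  expect_equal(sel$gene, "gA")
  expect_error(select_validation_genes(callsets, q[-1, ], map), "missing q")
})

test_that("concordance reports the OLS coefficient of determination", {
  d <- tibble::tibble(gene = c("a", "b", "c"), x = c(0, 1, 2), y = c(0, 1, 3))
  fit <- concordance(d, "x", "y")
  g <- glance(fit)
  expect_equal(g$r_squared, 27 / 28, tolerance = 1e-12)
  expect_equal(g$slope, 1.5, tolerance = 1e-12)
  expect_equal(g$intercept, -1 / 6, tolerance = 1e-12)

  # suppress lm's "essentially perfect fit" notes on exact lines
  ident <- suppressWarnings(concordance(tibble::tibble(x = 1:5, y = 1:5),
                                        "x", "y"))
  expect_equal(glance(ident)$r_squared, 1)
  # determination measures fit quality, not direction
  anti <- suppressWarnings(concordance(tibble::tibble(x = 1:5, y = -(1:5)),
                                       "x", "y"))
  expect_equal(glance(anti)$r_squared, 1)

  set.seed(37)
  for (rep in 1:10) {
    d <- tibble::tibble(x = rnorm(10), y = rnorm(10))
    r2 <- glance(concordance(d, "x", "y"))$r_squared
    expect_gte(r2, 0)
    expect_lte(r2, 1)
  }
  expect_error(concordance(tibble::tibble(x = 1:2, y = 1:2), "x", "y"),
               "at least 3")
  expect_error(concordance(tibble::tibble(x = rep(1, 5), y = 1:5), "x", "y"),
               "zero variance")
  td <- tidy(fit)
  expect_equal(td$estimate, c(-1 / 6, 1.5), tolerance = 1e-12)
})
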