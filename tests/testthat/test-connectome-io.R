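test_that("bundled atlas has the 68 + 14 structure and valid labels", {
  atlas <- default_atlas()
  expect_s3_class(atlas, "parcellation_atlas")
  expect_equal(nrow(atlas), 82)
  census <- table(atlas$network)
  expect_equal(unname(census[["subcortical"]]), 14)
  cortical <- setdiff(names(census), "subcortical")
  expect_equal(sum(census[cortical]), 68)
  expect_equal(sum(atlas$hemisphere == "left"), 41)
  sub_names <- c("thalamus", "caudate", "putamen", "pallidum",
                 "hippocampus", "amygdala", "accumbens")
  expect_true(all(paste0("left_", sub_names) %in% atlas$name))
  expect_true(all(paste0("right_", sub_names) %in% atlas$name))
})

test_that("atlas validation rejects bad tables", {
  df <- data.frame(name = c("a", "b"), hemisphere = c("left", "right"),
                   network = c("visual", "cerebellum"))
  expect_error(as_parcellation_atlas(df), "unknown network label")
  df2 <- data.frame(name = c("a", "a"), hemisphere = c("left", "right"),
                    network = c("visual", "visual"))
  expect_error(as_parcellation_atlas(df2), "duplicate")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines("name\themisphere\tnetwork\nx\tleft\tvisual", tmp)
  expect_equal(nrow(load_atlas(tmp)), 1)
})

test_that("network_of resolves regions and errors on unknowns", {
  atlas <- default_atlas()
  expect_equal(network_of(atlas, "right_supramarginal"), "ventral_attention")
  expect_equal(network_of(atlas, "right_thalamus"), "subcortical")
  expect_error(network_of(atlas, "no_such_region"), "unknown region")
})

test_that("connectivity_matrix enforces the boundary invariants", {
  W <- sym_from_upper(3, c(1, 2, 3))
  m <- connectivity_matrix(W, c("r1", "r2", "r3"), "s1")
  expect_equal(diag(m$weights), c(r1 = 0, r2 = 0, r3 = 0))
  # tiny asymmetry is averaged, large asymmetry errors
  Wa <- W; Wa[1, 2] <- W[1, 2] + 5e-10
  ma <- connectivity_matrix(Wa, c("r1", "r2", "r3"))
  expect_equal(ma$weights[1, 2], ma$weights[2, 1])
  Wb <- W; Wb[1, 2] <- W[1, 2] + 1
  expect_error(connectivity_matrix(Wb, c("r1", "r2", "r3")), "asymmetric")
  expect_error(connectivity_matrix(W - 2, c("r1", "r2", "r3")), "negative")
  expect_error(connectivity_matrix(W * NA, c("r1", "r2", "r3")),
               "non-finite")
  expect_error(connectivity_matrix(W[, 1:2], c("r1", "r2", "r3")),
               "square")
})

test_that("load_matrix accepts valid files and rejects malformed ones", {
  atlas <- toy_atlas3()
  dir <- withr::local_tempdir()
  z <- file.path(dir, "zero.csv")
  writeLines(c("0,0,0", "0,0,0", "0,0,0"), z)
  m <- load_matrix(z, atlas)
  expect_equal(length(m$regions), 3)
  expect_true(all(m$weights == 0))

  neg <- file.path(dir, "neg.csv")
  writeLines(c("0,1,2", "1,0,-1", "2,-1,0"), neg)
  expect_error(load_matrix(neg, atlas), "negative")

  wide <- file.path(dir, "wide.csv")
  writeLines(c("0,1", "1,0"), wide)
  expect_error(load_matrix(wide, atlas), "atlas length")

  hdr <- file.path(dir, "hdr.csv")
  writeLines(c("r1,r3,r2", "0,1,2", "1,0,3", "2,3,0"), hdr)
  expect_error(load_matrix(hdr, atlas), "header")
})

test_that("write/load round trip preserves weights to 1e-9", {
  atlas <- default_atlas()
  set.seed(7)
  W <- rand_graph(82, 0.4) * 1234.56789
  m <- connectivity_matrix(W, atlas$name, "rt")
  f <- withr::local_tempfile(fileext = ".csv")
  write_matrix(m, f)
  m2 <- load_matrix(f, atlas)
  expect_lt(max(abs(m2$weights - m$weights)), 1e-9)
  # tsv dialect too
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, f2)
  expect_lt(max(abs(load_matrix(f2, atlas)$weights - m$weights)), 1e-9)
})

test_that("loading is order-stable under joint permutation", {
  set.seed(11)
  atlas <- toy_atlas3()
  W <- sym_from_upper(3, c(5, 2, 9))
  dir <- withr::local_tempdir()
  perm <- c(3, 1, 2)
  atlas_p <- as_parcellation_atlas(as.data.frame(atlas)[perm, ])
  f1 <- file.path(dir, "orig.csv"); f2 <- file.path(dir, "perm.csv")
  write_matrix(connectivity_matrix(W, atlas$name), f1)
  write_matrix(connectivity_matrix(W[perm, perm], atlas_p$name), f2)
  m1 <- load_matrix(f1, atlas)
  m2 <- load_matrix(f2, atlas_p)
  expect_equal(unname(m2$weights), unname(m1$weights[perm, perm]))
})

test_that("phenotype validation enforces score ranges and week-6 rules", {
  sim <- small_cohort()
  subj <- sim$cohort$subjects
  bad <- subj; bad$adhdrs_total_w0[1] <- 60
  expect_error(validate_subjects_wrap(bad), "out of range")
  bad2 <- subj
  tdc_row <- which(bad2$group == "TDC")[1]
  bad2$adhdrs_total_w6[tdc_row] <- 10
  expect_error(validate_subjects_wrap(bad2), "TDC")
  # ADHD subject without week-6: flagged with warning, retained
  flag <- subj
  adhd_row <- which(flag$group == "ADHD")[1]
  flag[adhd_row, c("adhdrs_total_w6", "adhdrs_inatt_w6",
                   "adhdrs_hyper_w6")] <- NA
  expect_warning(
    ct <- cohort_table(flag[, setdiff(names(flag), "has_week6")],
                       sim$cohort$matrices, sim$cohort$atlas),
    "week-6")
  expect_false(ct$subjects$has_week6[adhd_row])
  expect_equal(nrow(ct$subjects), nrow(subj))
})

test_that("simulated cohort round-trips through disk exactly", {
  dir <- withr::local_tempdir()
  sim <- small_cohort(seed = 5)
  sim2 <- simulate_cohort(simulation_config(n_adhd = 6, n_tdc = 5,
                                            n_regions = 16, seed = 5),
                          dir = dir)
  ct <- load_cohort(file.path(dir, "cohort.csv"),
                    file.path(dir, "matrices"), sim$cohort$atlas)
  expect_equal(nrow(ct$subjects), 11)
  ids <- ct$subjects$subject_id
  expect_setequal(ids, sim$cohort$subjects$subject_id)
  for (id in ids)
    expect_lt(max(abs(ct$matrices[[id]]$weights -
                        sim$cohort$matrices[[id]]$weights)), 1e-9)
  expect_error(load_cohort(file.path(dir, "cohort.csv"),
                           withr::local_tempdir(), sim$cohort$atlas),
               "missing matrix")
})
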