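make_records <- function(n_per_clade = 40, n_loc = 2, seed = 1) {
  with_loc <- function(clade) {
    tibble::tibble(
      specimen_id = sprintf("%s%03d", substr(clade, 1, 1), seq_len(n_per_clade)),
      clade = clade,
      location = sprintf("%s_loc%d", substr(clade, 1, 1),
                         rep_len(seq_len(n_loc), n_per_clade)))
  }
  dplyr::bind_rows(with_loc("Northern"), with_loc("Southern"))
}

test_that("cap_locations keeps exactly the cap and conserves specimens", {
  recs <- tibble::tibble(specimen_id = sprintf("s%03d", 1:230),
                         clade = "Northern",
                         location = rep(c("A", "B"), c(150, 80)))
  out <- cladescan:::with_seed(3, cap_locations(recs, 100))
  expect_equal(sum(out$kept$location == "A"), 100)
  expect_equal(sum(out$overflow$location == "A"), 50)
  expect_equal(sum(out$kept$location == "B"), 80)
  expect_equal(nrow(out$overflow[out$overflow$location == "B", ]), 0)
  expect_setequal(c(out$kept$specimen_id, out$overflow$specimen_id),
                  recs$specimen_id)
  empty <- cap_locations(recs[0, ], 100)
  expect_equal(nrow(empty$kept), 0)
  expect_equal(nrow(empty$overflow), 0)
})

test_that("make_split assigns the configured counts, disjointly", {
  recs <- make_records(300)
  cfg <- protocol_config(n_train_per_class = 120, n_val_per_class = 30,
                         n_even_test_per_class = 20, base_seed = 50)
  sp <- make_split(recs, cfg, 1)
  expect_equal(length(sp$train_ids), 240)
  expect_equal(length(sp$val_ids), 60)
  expect_equal(length(sp$even_test_ids), 40)
  lab <- sp$label_map[sp$even_test_ids]
  expect_equal(as.vector(table(lab)), c(20L, 20L))
  all_ids <- c(sp$train_ids, sp$val_ids, sp$even_test_ids, sp$full_test_ids)
  expect_equal(anyDuplicated(all_ids), 0)
  expect_setequal(all_ids, recs$specimen_id)
  # per-class training counts are exact
  expect_equal(as.vector(table(sp$label_map[sp$train_ids])), c(120L, 120L))
})

test_that("splits are reproducible by iteration id and differ across ids", {
  recs <- make_records(200)
  cfg <- protocol_config(n_train_per_class = 60, n_val_per_class = 15,
                         n_even_test_per_class = 20, base_seed = 7)
  a <- make_split(recs, cfg, 4)
  b <- make_split(recs, cfg, 4)
  expect_identical(a, b)
  c <- make_split(recs, cfg, 5)
  expect_false(setequal(a$train_ids, c$train_ids))
})

test_that("make_split reports the class and shortfall when the pool is short", {
  recs <- make_records(50)
  cfg <- protocol_config(n_train_per_class = 60, n_val_per_class = 15,
                         n_even_test_per_class = 5)
  expect_error(make_split(recs, cfg, 1), "insufficient pool.*Northern")
})

test_that("location overflow is routed to the test pool", {
  recs <- make_records(120, n_loc = 1)
  cfg <- protocol_config(n_train_per_class = 30, n_val_per_class = 10,
                         n_even_test_per_class = 10, location_cap = 80)
  sp <- make_split(recs, cfg, 1)
  # 120 per clade at one location, cap 80: 40 overflow per clade must be in
  # the test pool, so the pool is 80 - 40 = 40 assignable + 40 overflow
  expect_equal(length(c(sp$even_test_ids, sp$full_test_ids)), 2 * (40 + 40))
})

test_that("mixed groups are exactly balanced and independent of clade", {
  recs <- make_records(100)
  mx <- make_mixed_groups(recs, seed = 2)
  tab <- table(mx$mixed_class, mx$clade)
  expect_true(all(tab == 50))
  expect_equal(suppressWarnings(stats::chisq.test(tab)$statistic[[1]]), 0)
  # odd clade counts: one specimen dropped with a message
  expect_message(mx2 <- make_mixed_groups(recs[-1, ], seed = 2), "parity")
  expect_equal(nrow(mx2), 198)
  expect_true(all(table(mx2$mixed_class, mx2$clade) == 49 |
                    table(mx2$mixed_class, mx2$clade) == 50))
})

test_that("augmentation identities hold exactly", {
  img <- matrix(runif(32 * 32), 32, 32)
  ident <- list(rotation_degrees = c(0, 0), flip_horizontal = FALSE,
                flip_vertical = FALSE, scale_range = c(1, 1))
  expect_identical(augment_image(img, ident, seed = 1), img)
  # a flip applied twice restores the original
  f1 <- cladescan:::affine_resample(img, flip_h = TRUE)
  expect_equal(cladescan:::affine_resample(f1, flip_h = TRUE), img)
  # output shape equals input shape under any transform
  aug <- protocol_config()$augmentation
  out <- augment_image(img, aug, seed = 3)
  expect_identical(dim(out), dim(img))
  expect_false(identical(out, img))
  # seeded: same seed, same augmentation
  expect_identical(augment_image(img, aug, seed = 3), out)
})

test_that("split plans serialize to JSON and read back", {
  recs <- make_records(60)
  cfg <- protocol_config(n_train_per_class = 20, n_val_per_class = 5,
                         n_even_test_per_class = 10)
  sp <- make_split(recs, cfg, 2)
  path <- tempfile(fileext = ".json")
  write_split_plan(sp, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$iteration_id, 2)
  expect_setequal(back$train_ids, sp$train_ids)
  expect_false(back$mixed)
})
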